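# End-to-end rebuild-and-refine driver for one kinked TMH: rigid-body
# sampling of the helix fragments, de novo re-closure of the bend and of
# the loop junctions the move displaced, constrained refinement, and the
# energy/cluster model selection.

# close every broken junction of a sampled structure using the annotated
# loop segments (or the bend window) around each break
close_breaks <- function(s, spec, lib, constraints = NULL, ...) {
  for (pass in 1:4) {
    brs <- chain_breaks(s)
    if (!length(brs)) break
    b <- brs[1L]
    if (b >= spec$bend_range[1L] - 1L && b <= spec$bend_range[2L]) {
      w <- loop_window(spec$bend_range[1L], spec$bend_range[2L])
    } else {
      rows <- which(!is.na(s$segment) & !grepl("^TM", s$segment))
      loop_of <- function(res) {
        i <- match(res, s$resno)
        if (is.na(i) || !(i %in% rows)) return(NULL)
        lab <- s$segment[i]
        rr <- s$resno[which(s$segment %in% lab)]
        c(min(rr), max(rr))
      }
      rg <- loop_of(b)
      if (is.null(rg)) rg <- loop_of(b + 1L)
      if (is.null(rg)) rg <- c(max(min(s$resno), b - 2L),
                               min(max(s$resno) - 1L, b + 2L))
      w <- loop_window(rg[1L], min(rg[2L], max(s$resno) - 1L),
                       min(max(b, rg[1L]), rg[2L]))
    }
    s <- rebuild_region(s, w, lib, constraints = constraints, ...)
  }
  s
}

#' Rebuild and refine models of a kinked TMH from a template
#'
#' Generates `n_models` candidate models: each runs a Metropolis Monte
#' Carlo rigid-body search over the kinked-helix move set starting from
#' the template, re-closes the bend window and any loop junction the
#' accepted moves displaced, and applies constrained refinement.  The
#' ensemble is then truncated to the 1000-or-10-percent lowest-energy
#' models, the TM region is clustered into structural families, and the
#' final models are selected from the five largest families.
#'
#' @param template a [tmh_structure()] with segment labels.
#' @param spec a [kink_spec()] for the TMH being rebuilt.
#' @param constraints a `constraint_set` (see [derive_constraints()]).
#' @param n_models candidate models to generate.
#' @param sampler_params a [move_set()].
#' @param lib fragment library (default ideal).
#' @param sched a [refine_schedule()].
#' @param tm_ranges list of TMH residue intervals used for clustering
#'   (default: segments labelled TM in the template).
#' @param cluster_radius leader-clustering radius (Angstrom).
#' @param membrane membrane slab parameters.
#' @return a clustered, selected [model_ensemble()].
#' @export
rebuild_and_refine <- function(template, spec, constraints = NULL,
                               n_models = 200L,
                               sampler_params = move_set(steps = 100L),
                               lib = build_fragment_library("ideal"),
                               sched = refine_schedule(n_cycles = 2L),
                               tm_ranges = NULL, cluster_radius = 2.0,
                               membrane = list(half_width = 15)) {
  if (is.null(tm_ranges)) {
    labs <- unique(stats::na.omit(template$segment))
    labs <- labs[grepl("^TM", labs)]
    tm_ranges <- lapply(labs, function(l) {
      rr <- template$resno[which(template$segment %in% l)]
      c(min(rr), max(rr))
    })
  }
  models <- vector("list", n_models)
  energies <- numeric(n_models)
  for (k in seq_len(n_models)) {
    m <- NULL
    for (attempt in 1:3) {
      st <- mc_run(template, spec, constraints = constraints,
                   params = sampler_params, membrane = membrane)
      m <- tryCatch(
        close_breaks(st$best_structure, spec, lib,
                     constraints = constraints),
        tmh_closure_error = function(e) e$best)
      if (!is.null(m) && length(chain_breaks(m)) == 0L) break
    }
    if (length(chain_breaks(m)) == 0L) {
      ref <- refine(m, constraints = constraints, sched = sched,
                    flex = list(spec$bend_range))
      models[[k]] <- ref$structure
      energies[k] <- ref$energy
    } else {
      # unclosable sample: keep it, but make sure it can never be selected
      models[[k]] <- m
      energies[k] <- refine_energy(m, constraints, 1.0, 1.0,
                                   flex = list(spec$bend_range)) + 1e6
    }
  }
  e <- model_ensemble(models, energies)
  e <- rank_and_truncate(e)
  e <- cluster_tm(e, tm_ranges, radius = cluster_radius)
  select_final(e)
}
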