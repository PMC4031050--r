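# Shared fixtures, built once per test session.  Everything is generated
# in code from fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# standard 3-helix bundle with one 30-degree kink on TM2
std_spec <- function() bundle_spec(
  n_helices = 3L, helix_length = 18L, loop_length = 5L,
  kinks = list(list(helix = 2L, kink_angle = 30, swing = 0)),
  seq_identity_target = 0.35, perturbation = 0.3, seed = 2L)

std_target <- function() cached("std_target", function()
  make_kinked_bundle(std_spec()))

# straightened, perturbed, mutated template + alignment + profile
std_template <- function() cached("std_template", function()
  make_template_from_target(std_target(), std_spec(),
                            straighten_kinks = TRUE))

# kink-recovery setup: straight template, no noise, target-derived
# constraints excluding every region rebuilt de novo (bend and loops)
recovery_setup <- function() cached("recovery_setup", function() {
  sp <- bundle_spec(n_helices = 3L, helix_length = 18L, loop_length = 5L,
                    kinks = list(list(helix = 2L, kink_angle = 30,
                                      swing = 0)),
                    seed = 2L)
  tg <- make_kinked_bundle(sp)
  ks <- tg$kinks[[1L]]
  tpl <- make_template_from_target(tg, sp, straighten_kinks = TRUE)
  aln <- parse_alignment(c(">t", tg$sequence, ">p", tg$sequence))
  loops <- lapply(
    tg$annotations$segment_id[tg$annotations$kind == "loop"],
    function(l) {
      row <- tg$annotations[tg$annotations$segment_id == l, ]
      c(row$first_res, row$last_res)
    })
  cst <- derive_constraints(aln, tg$structure,
                            rebuilt_regions = c(list(ks$bend_range),
                                                loops))
  tm_ranges <- lapply(which(tg$annotations$kind == "TMH"), function(i)
    c(tg$annotations$first_res[i], tg$annotations$last_res[i]))
  list(spec = sp, target = tg, kink = ks, template = tpl,
       constraints = cst, tm_ranges = tm_ranges)
})

# geometric cooling schedule used by the desk-scale sampler runs
cooling <- function(n, from = 3, to = 0.3)
  from * exp(seq(0, log(to / from), length.out = n))

# independent quaternion-based superposition oracle (Horn's method)
quaternion_rmsd <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2L, ca); Bc <- sweep(B, 2L, cb)
  S <- crossprod(Ac, Bc)
  K <- matrix(0, 4L, 4L)
  K[1L, 1L] <- S[1L, 1L] + S[2L, 2L] + S[3L, 3L]
  K[1L, 2L] <- K[2L, 1L] <- S[2L, 3L] - S[3L, 2L]
  K[1L, 3L] <- K[3L, 1L] <- S[3L, 1L] - S[1L, 3L]
  K[1L, 4L] <- K[4L, 1L] <- S[1L, 2L] - S[2L, 1L]
  K[2L, 2L] <- S[1L, 1L] - S[2L, 2L] - S[3L, 3L]
  K[2L, 3L] <- K[3L, 2L] <- S[1L, 2L] + S[2L, 1L]
  K[2L, 4L] <- K[4L, 2L] <- S[3L, 1L] + S[1L, 3L]
  K[3L, 3L] <- -S[1L, 1L] + S[2L, 2L] - S[3L, 3L]
  K[3L, 4L] <- K[4L, 3L] <- S[2L, 3L] + S[3L, 2L]
  K[4L, 4L] <- -S[1L, 1L] - S[2L, 2L] + S[3L, 3L]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

# random proper rotation matrix
random_rotation <- function() {
  rot_axis <- stats::rnorm(3L)
  tmhrebuild:::rot_axis_angle(rot_axis, stats::runif(1L, 0, 360))
}
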