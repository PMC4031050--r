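# helper: a tiny ensemble whose structures differ by displacing the
# C-terminal half of one helix (an internal change that superposition
# cannot undo); energies are assigned explicitly.  Displacing half of
# the 18 residues by dx gives a TM RMSD of about 0.27 * dx.
shifted_ensemble <- function(shifts, energies, base = ideal_helix(18)) {
  base$segment[] <- "TM1"
  models <- lapply(shifts, function(dx)
    apply_rigid_transform(base, 10, 18, t = c(dx, 0, 0)))
  model_ensemble(models, energies)
}

test_that("refinement never ends above its starting energy", {
  setup <- recovery_setup()
  lib <- build_fragment_library("ideal")
  set.seed(10)
  st <- mc_run(setup$template$structure, setup$kink,
               constraints = setup$constraints,
               params = move_set(steps = 50L))
  m <- tryCatch(
    tmhrebuild:::close_breaks(st$best_structure, setup$kink, lib,
                              constraints = setup$constraints),
    tmh_closure_error = function(e) e$best)
  skip_if(length(chain_breaks(m)) > 0L, "sampled structure not closable")
  e0 <- tmhrebuild:::refine_energy(m, setup$constraints, 1.0, 3.0,
                                   flex = list(setup$kink$bend_range))
  set.seed(11)
  out <- refine(m, constraints = setup$constraints,
                sched = refine_schedule(n_cycles = 3L),
                flex = list(setup$kink$bend_range))
  expect_lte(out$energy, e0 + 1e-9)
  expect_length(chain_breaks(out$structure), 0L)
})

test_that("zero perturbation is a fixed point and the ramp is logged", {
  h <- ideal_helix(16)
  set.seed(3)
  out <- refine(h, sched = refine_schedule(
    n_cycles = 3L, perturbation_magnitude = 0,
    repulsive_ramp = c(0.1, 0.5, 1.0)))
  expect_equal(out$structure$CA, h$CA, tolerance = 1e-6)
  expect_equal(out$ramp_log, c(0.1, 0.5, 1.0))
  expect_error(refine_schedule(repulsive_ramp = c(0.5, 0.4, 1.0)),
               "increasing")
  expect_error(refine_schedule(repulsive_ramp = c(0.5, 0.9)),
               "end at 1")
  broken <- apply_rigid_transform(h, 9, 16, t = c(8, 0, 0))
  expect_error(refine(broken), "chain breaks")
})

test_that("rank_and_truncate keeps 1000 or up to 10 percent", {
  e50 <- shifted_ensemble(seq(0, 4.9, by = 0.1), energies = 50:1)
  expect_length(rank_and_truncate(e50)$models, 5L)
  # the five lowest energies (49:46, 50 -> ids 50, 49, 48, 47, 46)
  expect_setequal(rank_and_truncate(e50)$ids, 46:50)

  e3 <- shifted_ensemble(c(0, 1, 2), energies = c(3, 1, 2))
  kept <- rank_and_truncate(e3)
  expect_length(kept$models, 1L)
  expect_equal(kept$ids, 2L)

  # the absolute cap: 20000 dummy models (energies only matter)
  base <- ideal_helix(18)
  eN <- model_ensemble(rep(list(base), 20000L),
                       energies = rev(seq_len(20000L)))
  expect_length(rank_and_truncate(eN)$models, 1000L)

  # deterministic tie-break by id
  etie <- shifted_ensemble(c(0, 1, 2, 3), energies = c(1, 1, 1, 1))
  expect_equal(rank_and_truncate(etie)$ids, 1L)
})

test_that("leader clustering groups by TM-region RMSD", {
  # two basins about 3 A apart in TM RMSD, radius 2 A
  e <- shifted_ensemble(c(0, 0.3, 0.2, 12, 12.2), energies = 1:5)
  ec <- cluster_tm(e, list(c(1, 18)), radius = 2)
  expect_equal(ec$cluster_labels, c(1L, 1L, 1L, 2L, 2L))

  # all identical: one cluster
  eid <- shifted_ensemble(rep(0, 4), energies = 4:1)
  expect_equal(unique(cluster_tm(eid, list(c(1, 18)))$cluster_labels), 1L)

  # clustering depends only on the energy order, not input order
  perm <- c(3, 5, 1, 4, 2)
  ep <- shifted_ensemble(c(0, 0.3, 0.2, 12, 12.2)[perm],
                         energies = (1:5)[perm])
  ecp <- cluster_tm(ep, list(c(1, 18)), radius = 2)
  lab_perm <- integer(5L)
  lab_perm[perm] <- ecp$cluster_labels   # labels mapped back to originals
  expect_equal(outer(lab_perm, lab_perm, "=="),
               outer(ec$cluster_labels, ec$cluster_labels, "=="))
})

test_that("select_final picks lowest energy from the largest families", {
  # 5 clusters with sizes 5, 4, 3, 2, 1 plus a 6th singleton
  shifts <- c(rep(0, 5), rep(12, 4), rep(24, 3), rep(36, 2), 48, 60)
  energies <- c(5, 4, 3, 2, 1,   8, 7, 6, 9,   12, 11, 10,  14, 13,
                15, 16)
  e <- cluster_tm(shifted_ensemble(shifts + runif(16, 0, 0.2), energies),
                  list(c(1, 18)), radius = 2)
  sel <- select_final(e)
  expect_length(sel$selected_ids, 5L)
  # brute-force check: every selected model is the energy minimum of its
  # cluster, and the chosen clusters are the 5 largest
  labs <- sel$cluster_labels
  sizes <- table(labs)
  chosen <- labs[match(sel$selected_ids, sel$ids)]
  expect_setequal(chosen,
                  as.integer(names(sort(sizes, decreasing = TRUE)))[1:5])
  for (id in sel$selected_ids) {
    i <- match(id, sel$ids)
    members <- which(labs == labs[i])
    expect_equal(sel$energies[i], min(sel$energies[members]))
  }

  # fewer than five clusters: one per cluster
  e2 <- cluster_tm(shifted_ensemble(c(0, 0.1, 12, 12.1),
                                    energies = c(2, 1, 4, 3)),
                   list(c(1, 18)), radius = 2)
  sel2 <- select_final(e2)
  expect_length(sel2$selected_ids, 2L)
  expect_setequal(sel2$selected_ids, c(2L, 4L))
  expect_error(select_final(shifted_ensemble(0, 1)), "clustered")
})

test_that("benchmarking mode returns the most accurate selected model", {
  base <- ideal_helix(18)
  base$segment[] <- "TM1"
  e <- cluster_tm(shifted_ensemble(c(0, 12, 24), energies = c(3, 2, 1)),
                  list(c(1, 18)), radius = 2)
  sel <- select_final(e)
  best <- most_accurate_model(sel, base, list(c(1, 18)))
  expect_equal(best$id, 1L)
  expect_lt(best$rmsd, 1e-9)
})

test_that("ensemble manifests serialize cluster and selection state", {
  e <- cluster_tm(shifted_ensemble(c(0, 12), energies = c(1, 2)),
                  list(c(1, 18)), radius = 2)
  e <- select_final(e)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(e, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 2L)
  expect_true(all(df$selected))
  expect_equal(df$cluster, c(1L, 2L))
})
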