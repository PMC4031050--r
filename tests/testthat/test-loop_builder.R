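test_that("fragment libraries satisfy their structural contracts", {
  lib <- build_fragment_library("ideal")
  frs9 <- lib$fragments[["9"]]
  helical <- vapply(frs9, function(f)
    all(abs(f$phi + 57) < 1e-9) && all(abs(f$psi + 47) < 1e-9),
    logical(1L))
  expect_true(any(helical))
  for (size in c("3", "9"))
    for (f in lib$fragments[[size]]) {
      expect_true(all(abs(tmhrebuild:::wrap_angle(f$omega - 180)) <= 10))
      expect_true(all(f$phi > -180 & f$phi <= 180))
    }

  set.seed(4)
  r1 <- build_fragment_library("ramachandran", n_per_size = 10L)
  set.seed(4)
  r2 <- build_fragment_library("ramachandran", n_per_size = 10L)
  expect_identical(r1, r2)
})

test_that("fragment files load and malformed input names the line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- c("frag_id position aa phi psi omega",
            vapply(1:3, function(i)
              sprintf("f1 %d A -57 -47 180", i), character(1L)),
            vapply(1:9, function(i)
              sprintf("f2 %d G -120 130 179", i), character(1L)))
  writeLines(rows, path)
  lib <- build_fragment_library("file", path = path)
  expect_length(lib$fragments[["3"]], 1L)
  expect_length(lib$fragments[["9"]], 1L)
  expect_equal(lib$fragments[["3"]][[1L]]$phi, rep(-57, 3))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("f1 1 A -57 -47 180", "f1 2 A -57 nonsense 180",
               "f1 3 A -57 -47 180"), bad)
  expect_error(build_fragment_library("file", path = bad), "line 2")
})

test_that("fragment insertion is exact and local", {
  set.seed(42)
  h <- ideal_helix(24)
  tor <- backbone_torsions(h)
  w <- loop_window(10, 14)

  # inserting the current torsions changes nothing
  ident <- data.frame(phi = tor$phi[11:13], psi = tor$psi[11:13],
                      omega = tor$omega[11:13])
  expect_equal(insert_fragment(h, w, ident, at = 11)$CA, h$CA,
               tolerance = 1e-6)

  # helical 3-mer into an extended window
  open <- rebuild_window(h, 10, 14, phi = rep(-120, 5), psi = rep(130, 5))
  helical <- data.frame(phi = rep(-57, 3), psi = rep(-47, 3),
                        omega = rep(180, 3))
  ins <- insert_fragment(open, w, helical, at = 10)
  tor2 <- backbone_torsions(ins)
  expect_equal(tor2$phi[11:12], c(-57, -57), tolerance = 1e-6)

  # locality: atoms upstream of the insertion and beyond the break are
  # bit-identical over repeated random insertions
  lib <- build_fragment_library("ideal")
  for (k in 1:25) {
    frag <- lib$fragments[["3"]][[sample.int(
      length(lib$fragments[["3"]]), 1L)]]
    at <- sample(10:12, 1L)
    out <- insert_fragment(open, w, frag, at = at)
    expect_identical(out$CA[seq_len(at - 1L), ],
                     open$CA[seq_len(at - 1L), ])
    expect_identical(out$CA[15:24, ], open$CA[15:24, ])
  }
  expect_error(insert_fragment(h, loop_window(10, 12),
                               lib$fragments[["9"]][[1L]]), "fit")
})

test_that("CCD closes feasible breaks and reports infeasible ones", {
  set.seed(42)
  h <- ideal_helix(24)
  w <- loop_window(10, 14)

  # already-closed window: zero cycles, ~zero gap
  res0 <- ccd_close(h, w)
  expect_equal(res0$cycles, 0L)
  expect_lt(res0$final_gap, 0.02)

  # opened window: gap reduced dramatically
  open <- rebuild_window(h, 10, 14, phi = runif(5, -150, -40),
                         psi = runif(5, -60, 150))
  g0 <- chain_break_deviation(open, 14)
  res <- ccd_close(open, w)
  expect_lt(res$final_gap, g0 / 4)

  # geometrically infeasible span: large residual, no exception
  far <- apply_rigid_transform(h, 15, 24, t = c(40, 0, 0))
  resf <- ccd_close(far, w, max_cycles = 20L)
  expect_gt(resf$final_gap, 1)
  expect_error(ccd_close(h, loop_window(20, 24, 24)), "terminus")
})

test_that("the analytic CCD torsion update matches a grid search", {
  # two-torsion window: CCD should reach the brute-force optimum of the
  # ghost-triad objective over (phi, psi) of the single moving residue
  h <- ideal_helix(9)
  open <- rebuild_window(h, 5, 5, phi = -100, psi = 60)
  w <- loop_window(5, 5)
  res <- ccd_close(open, w, max_cycles = 50L)

  obj <- function(phi, psi) {
    x <- rebuild_window(open, 5, 5, phi = phi, psi = psi)
    chain_break_deviation(x, 5)
  }
  grid <- expand.grid(phi = seq(-180, 175, by = 5),
                      psi = seq(-180, 175, by = 5))
  vals <- mapply(obj, grid$phi, grid$psi)
  expect_lte(res$final_gap, min(vals) + 0.05)
})

test_that("rebuild_region closes bends within the 12-step protocol", {
  set.seed(42)
  h <- ideal_helix(24)
  lib <- build_fragment_library("ideal")
  open <- rebuild_window(h, 10, 13, phi = runif(4, -150, -40),
                         psi = runif(4, -60, 150))
  w <- loop_window(10, 13)
  set.seed(9)
  out <- rebuild_region(open, w, lib)
  expect_lte(attr(out, "final_gap"), 0.2)
  expect_length(chain_breaks(out), 0L)
  # flanking helix untouched on the upstream side
  expect_identical(out$CA[1:9, ], open$CA[1:9, ])

  # determinism under a fixed seed
  set.seed(9)
  out2 <- rebuild_region(open, w, lib)
  expect_identical(out$CA, out2$CA)

  # covalent geometry stays near ideal inside the rebuilt region
  n_d <- sqrt(rowSums((out$CA[10:14, ] - out$N[10:14, ])^2))
  expect_true(all(abs(n_d - 1.458) / 1.458 < 0.05))
  c_d <- sqrt(rowSums((out$C[10:14, ] - out$CA[10:14, ])^2))
  expect_true(all(abs(c_d - 1.525) / 1.525 < 0.05))
})

test_that("unclosable windows raise a condition carrying the best attempt", {
  h <- ideal_helix(24)
  far <- apply_rigid_transform(h, 15, 24, t = c(60, 0, 0))
  set.seed(1)
  err <- tryCatch(
    rebuild_region(far, loop_window(10, 14), build_fragment_library("ideal"),
                   max_expansions = 1L),
    tmh_closure_error = function(e) e)
  expect_s3_class(err, "tmh_closure_error")
  expect_s3_class(err$best, "tmh_structure")
  expect_gt(err$best_gap, 0.2)
})

test_that("bend remodeling uses the annotated window by default", {
  tg <- std_target()
  ks <- tg$kinks[[1L]]
  lib <- build_fragment_library("ideal")
  set.seed(5)
  out <- remodel_bend(tg$structure, ks, lib)
  expect_lte(attr(out, "final_gap"), 0.2)
  w <- attr(out, "window")
  expect_equal(c(w$first, w$last), ks$bend_range)
  tor <- backbone_torsions(out)
  bend_rows <- ks$bend_range[1L]:ks$bend_range[2L]
  expect_true(all(tor$phi[bend_rows] > -180 & tor$phi[bend_rows] <= 180))
  # m and f helices untouched outside the window
  expect_identical(out$CA[1:(ks$bend_range[1L] - 1L), ],
                   tg$structure$CA[1:(ks$bend_range[1L] - 1L), ])
  expect_error(remodel_bend(tg$structure, ks, lib, window_size = 9),
               "between 5 and 8")
})

test_that("feasible synthetic loops close at a high rate", {
  closed <- 0L
  lengths <- rep(6:12, length.out = 12L)
  for (k in seq_along(lengths)) {
    lp <- make_loop_problem(lengths[k], seed = 100L + k)
    set.seed(200L + k)
    out <- tryCatch(
      rebuild_region(lp$structure, lp$window,
                     build_fragment_library("ideal"),
                     max_expansions = 2L),
      tmh_closure_error = function(e) e)
    if (!inherits(out, "error") && attr(out, "final_gap") <= 0.2)
      closed <- closed + 1L
  }
  expect_gte(closed, 11L)
})
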