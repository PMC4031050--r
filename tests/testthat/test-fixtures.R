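test_that("kinked bundles realize their requested geometry", {
  tg <- std_target()
  ks <- tg$kinks[[1L]]
  mk <- measure_kink(tg$structure, ks)
  expect_lt(abs(mk$kink_angle - 30), 2)
  expect_length(chain_breaks(tg$structure), 0L)
  expect_silent(tmhrebuild:::validate_structure(tg$structure))
  # proline at the kink reference position
  expect_equal(tg$structure$aa[ks$ref_residue], "P")
  # membrane frame: TM spans within the slab
  tm_rows <- which(grepl("^TM", tg$structure$segment))
  expect_true(all(abs(tg$structure$CA[tm_rows, 3L]) < 16))
})

test_that("an unkinked bundle has parallel or antiparallel helices", {
  sp <- bundle_spec(n_helices = 3L, helix_length = 16L, loop_length = 5L,
                    seed = 4L)
  b <- make_kinked_bundle(sp)
  dirs <- lapply(1:3, function(k) {
    h <- tmhrebuild:::helix_interval(sp, k)
    fit_helix_axis(b$structure$CA[h[1L]:h[2L], ])$direction
  })
  for (i in 1:2) for (j in (i + 1):3) {
    c_ij <- abs(sum(dirs[[i]] * dirs[[j]]))
    expect_gt(c_ij, cos(10 * pi / 180))
  }
  # neighbor axis spacing near 10 A
  d12 <- sqrt(sum((colMeans(b$structure$CA[1:16, 1:2, drop = FALSE]) -
                   colMeans(b$structure$CA[22:37, 1:2, drop = FALSE]))^2))
  expect_lt(abs(d12 - 10), 1.5)
})

test_that("bundle generation is deterministic given the seed", {
  sp <- bundle_spec(n_helices = 2L, helix_length = 14L, loop_length = 5L,
                    seed = 9L)
  b1 <- make_kinked_bundle(sp)
  b2 <- make_kinked_bundle(sp)
  expect_identical(b1$structure$CA, b2$structure$CA)
  expect_identical(b1$sequence, b2$sequence)
})

test_that("bundle_spec validates its inputs", {
  expect_error(bundle_spec(n_helices = 0L), "n_helices")
  expect_error(bundle_spec(helix_length = 8L), "helix_length")
  expect_error(bundle_spec(kinks = list(list(helix = 1L,
                                             kink_angle = 120))),
               "kink_angle")
  expect_error(bundle_spec(kinks = list(list(helix = 5L,
                                             kink_angle = 30))),
               "outside")
})

test_that("identity-preserving template derivation is a no-op", {
  sp <- bundle_spec(n_helices = 2L, helix_length = 14L, loop_length = 5L,
                    seq_identity_target = 1.0, perturbation = 0,
                    seed = 6L)
  tg <- make_kinked_bundle(sp)
  tpl <- make_template_from_target(tg, sp, straighten_kinks = FALSE)
  expect_equal(tpl$structure$CA, tg$structure$CA, tolerance = 1e-9)
  expect_false(grepl("-", tpl$alignment$target_seq, fixed = TRUE))
  expect_false(grepl("-", tpl$alignment$template_seq, fixed = TRUE))
  g <- gate_tmh(tpl$alignment, tg$annotations, tpl$annotations,
                tpl$proline_profile)
  expect_false(any(g$rebuild))
})

test_that("requested sequence identity is realized within tolerance", {
  for (ident in c(0.2, 0.5)) {
    sp <- bundle_spec(n_helices = 3L, helix_length = 18L,
                      loop_length = 5L, seq_identity_target = ident,
                      seed = 8L)
    tg <- make_kinked_bundle(sp)
    tpl <- make_template_from_target(tg, sp, straighten_kinks = FALSE)
    expect_lt(abs(tpl$alignment$identity_full - ident), 0.03)
  }
})

test_that("loop deletions produce consistent alignment gaps", {
  sp <- bundle_spec(n_helices = 3L, helix_length = 16L, loop_length = 6L,
                    seed = 12L)
  tg <- make_kinked_bundle(sp)
  tpl <- make_template_from_target(tg, sp, straighten_kinks = FALSE,
                                   delete_loop = 1L)
  a <- tpl$alignment
  expect_equal(sum(a$template_chars == "-"), 6L)
  expect_equal(nres(tpl$structure),
               nres(tg$structure) - 6L)
  # maps stay consistent: every non-gap template column maps to a residue
  tcols <- which(!is.na(a$template_map))
  expect_equal(max(a$template_map[tcols]), nres(tpl$structure))
  g <- gate_tmh(a, tg$annotations, tpl$annotations, tpl$proline_profile)
  expect_false(any(grepl("gap_in_tmh", g$reasons)))
})

test_that("loop problems open a feasible break inside the loop", {
  lp <- make_loop_problem(8L, seed = 3L)
  expect_gt(chain_break_deviation(lp$structure,
                                  lp$window$break_position), 0.5)
  expect_length(chain_breaks(lp$closed), 0L)
  # anchors are untouched by the opening
  rows <- c(1:(lp$window$first - 1L),
            (lp$window$last + 2L):nres(lp$structure))
  expect_identical(lp$structure$CA[rows, ], lp$closed$CA[rows, ])
})

test_that("fixture sets write all four artifact kinds", {
  tg <- std_target()
  tpl <- std_template()
  dir <- withr::local_tempdir()
  write_fixture_set(tg, tpl, dir)
  expect_setequal(list.files(dir),
                  c("target.pdb", "template.pdb", "alignment.fasta",
                    "target_segments.tsv", "template_segments.tsv",
                    "proline_profile.tsv"))
  back <- read_backbone(paste(readLines(file.path(dir, "target.pdb")),
                              collapse = "\n"))
  expect_equal(nres(back), nres(tg$structure))
})
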