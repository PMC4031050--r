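test_that("pairwise alignments parse with correct maps and identity", {
  a <- parse_alignment(c(">t", "AC-D", ">p", "ACED"))
  expect_equal(a$target_map, c(1L, 2L, NA, 3L))
  expect_equal(a$template_map, 1:4)
  expect_equal(a$identity_full, 1.0)   # 3/3 mutually aligned columns

  b <- parse_alignment(c(">t", "ACDEF", ">p", "ACDEF"))
  expect_equal(b$identity_full, 1.0)

  expect_error(parse_alignment(c(">t", "ACD", ">p", "AC")),
               "gapped length")
  expect_error(parse_alignment(c(">a", "AC", ">b", "AC", ">c", "AC")),
               "exactly 2")
})

test_that("alignment maps invert on fixture alignments", {
  a <- std_template()$alignment
  cols <- which(!is.na(a$target_map))
  expect_equal(a$target_map[cols], seq_along(cols))
  tcols <- which(!is.na(a$template_map))
  expect_equal(a$template_map[tcols], seq_along(tcols))
})

test_that("gate_tmh applies the three rebuild rules", {
  tmhs <- data.frame(segment_id = "TM1", first_res = 2L, last_res = 11L,
                     kind = "TMH", stringsAsFactors = FALSE)
  base_t <- "ALIVFALIVFAL"
  # identical sequences, no gaps, equal lengths -> keep template helix
  a0 <- parse_alignment(c(">t", base_t, ">p", base_t))
  g0 <- gate_tmh(a0, tmhs, tmhs)
  expect_false(g0$rebuild)

  # gap inside the helix
  a1 <- parse_alignment(c(">t", "ALIVFALIVFAL", ">p", "ALIVF--IVFAL"))
  g1 <- gate_tmh(a1, tmhs, tmhs)
  expect_true(g1$rebuild)
  expect_match(g1$reasons, "gap_in_tmh")

  # target proline aligned to leucine, no homolog support
  a2 <- parse_alignment(c(">t", "ALIVFPLIVFAL", ">p", "ALIVFLLIVFAL"))
  g2 <- gate_tmh(a2, tmhs, tmhs)
  expect_true(g2$rebuild)
  expect_match(g2$reasons, "bend_mismatch")

  # homolog proline fraction above threshold triggers the same rule
  prof <- numeric(12); prof[6] <- 0.2
  a3 <- parse_alignment(c(">t", "ALIVFLLIVFAL", ">p", "ALIVFLLIVFAL"))
  g3 <- gate_tmh(a3, tmhs, tmhs, proline_profile = prof)
  expect_match(g3$reasons, "bend_mismatch")
  # below threshold: no rebuild
  prof[6] <- 0.05
  expect_false(gate_tmh(a3, tmhs, tmhs, proline_profile = prof)$rebuild)

  # annotated length difference beyond the margin
  short <- data.frame(segment_id = "TM1", first_res = 2L, last_res = 6L,
                      kind = "TMH", stringsAsFactors = FALSE)
  g4 <- gate_tmh(a0, tmhs, short)
  expect_match(g4$reasons, "length_mismatch")
  expect_error(
    gate_tmh(a0, data.frame(segment_id = "TM1", first_res = 2L,
                            last_res = 40L, kind = "TMH"), tmhs),
    "outside")
})

test_that("self-alignment of the fixture gates nothing for rebuilding", {
  tg <- std_target()
  a <- parse_alignment(c(">t", tg$sequence, ">p", tg$sequence))
  g <- gate_tmh(a, tg$annotations, tg$annotations,
                as.numeric(strsplit(tg$sequence, "")[[1L]] == "P"))
  expect_false(any(g$rebuild))
})

test_that("straightened template triggers bend_mismatch on the kinked TMH", {
  tg <- std_target()
  tpl <- std_template()
  g <- gate_tmh(tpl$alignment, tg$annotations, tpl$annotations,
                tpl$proline_profile)
  expect_true(g$rebuild[g$tmh_id == "TM2"])
  expect_match(g$reasons[g$tmh_id == "TM2"], "bend_mismatch")
  expect_false(any(g$rebuild[g$tmh_id != "TM2"]))
})

test_that("constraint derivation follows width and budget rules", {
  tg <- std_target()
  a <- parse_alignment(c(">t", tg$sequence, ">p", tg$sequence))

  # identical sequences (identity 1 > 25%): every qualifying contact kept
  cst <- derive_constraints(a, tg$structure)
  expect_gt(nrow(cst), 0L)
  expect_true(all(abs(cst$res_j - cst$res_i) >= 4))
  expect_true(all(cst$d0 <= 8))
  expect_true(all(cst$width > 0))
  # width schedule: 0.2 up to 5 A, 0.5 near 8 A, linear between
  expect_true(all(abs(cst$width[cst$d0 <= 5] - 0.2) < 1e-9))
  mid <- cst$d0 > 5 & cst$d0 < 8
  expect_true(all(abs(cst$width[mid] -
                        (0.2 + 0.3 * (cst$d0[mid] - 5) / 3)) < 1e-9))

  # distant-homolog budget: ~5 percent of modeled residues
  n_modeled <- sum(!is.na(a$target_map) & !is.na(a$template_map))
  cst18 <- derive_constraints(a, tg$structure, identity_modeled = 0.18)
  expect_lte(nrow(cst18), max(1L, round(0.05 * n_modeled)))
  cst22 <- derive_constraints(a, tg$structure, identity_modeled = 0.225)
  expect_lte(nrow(cst22), max(1L, round(0.075 * n_modeled)))
  expect_gte(nrow(cst), nrow(cst22))

  # deterministic selection
  expect_identical(derive_constraints(a, tg$structure,
                                      identity_modeled = 0.18), cst18)

  # rebuilt regions excluded
  cst_ex <- derive_constraints(a, tg$structure,
                               rebuilt_regions = list(c(1, 18)))
  expect_false(any(cst_ex$res_i <= 18 | cst_ex$res_j <= 18))
})

test_that("constraint energy is a flat-bottom harmonic", {
  h1 <- ideal_helix(10, start = c(0, 0, 0))
  cst <- structure(data.frame(res_i = 1L, res_j = 8L,
                              d0 = sqrt(sum((h1$CA[1, ] - h1$CA[8, ])^2)),
                              width = 0.3, weight = 1),
                   class = c("constraint_set", "data.frame"))
  expect_equal(constraint_energy(h1, cst), 0)
  # at the flat-bottom edge: still zero
  stretched <- apply_rigid_transform(h1, 8, 10,
    t = 0.3 * tmhrebuild:::unitv(h1$CA[8, ] - h1$CA[1, ]))
  expect_lt(constraint_energy(stretched, cst), 1e-6)
  # one sigma beyond the width: unit penalty
  far <- apply_rigid_transform(h1, 8, 10,
    t = 1.3 * tmhrebuild:::unitv(h1$CA[8, ] - h1$CA[1, ]))
  expect_equal(constraint_energy(far, cst), 1.0, tolerance = 1e-6)

  # rigid-motion invariance and zero on the defining template
  tg <- std_target()
  a <- parse_alignment(c(">t", tg$sequence, ">p", tg$sequence))
  cs <- derive_constraints(a, tg$structure)
  expect_equal(constraint_energy(tg$structure, cs), 0)
  moved <- apply_rigid_transform(tg$structure, 1, nres(tg$structure),
                                 R = tmhrebuild:::rot_axis_angle(
                                   c(1, 1, 0), 77), t = c(3, -2, 9))
  expect_equal(constraint_energy(moved, cs), 0, tolerance = 1e-9)
  expect_error(constraint_energy(ideal_helix(3), cs), "missing")
})

test_that("constraints and profiles round-trip through TSV", {
  tg <- std_target()
  a <- parse_alignment(c(">t", tg$sequence, ">p", tg$sequence))
  cst <- derive_constraints(a, tg$structure, identity_modeled = 0.18)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_constraints(cst, path)
  back <- read_constraints(path)
  expect_equal(as.data.frame(back), as.data.frame(cst),
               tolerance = 1e-6)
  prof_path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(column = c(3L, 10L), fraction = c(0.5, 0.12)),
              prof_path, sep = "\t", row.names = FALSE, quote = FALSE)
  prof <- read_proline_profile(prof_path, 12L)
  expect_equal(prof[c(3, 10)], c(0.5, 0.12))
  expect_equal(sum(prof > 0), 2L)
})
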