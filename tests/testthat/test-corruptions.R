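test_that("alphabet corruptions inject exactly one traceable violation", {
  ens <- generate_alphabet_ensemble(20, seed = 51)
  # rate 0 is the identity
  same <- corrupt_alphabet(ens, "swap_pair_order", 0, seed = 1)
  expect_identical(same$images, ens$images)
  for (mode in c("swap_pair_order", "duplicate_pair", "orphan_letter")) {
    ce <- corrupt_alphabet(ens, mode, 0.1, seed = 7)
    expect_equal(sum(ce$truth$affected), 2)
    flags <- vapply(ce$layouts, function(l) !pair_prevalence(l)$ok, logical(1))
    expect_identical(flags, ce$truth$affected)
  }
  # duplicate_pair specifically raises the Z-K count to 3
  ce <- corrupt_alphabet(ens, "duplicate_pair", 0.1, seed = 7)
  i <- which(ce$truth$affected)[1]
  expect_equal(unname(pair_prevalence(ce$layouts[[i]])$counts["ZK"]), 3L)
  # replace_letter leaves pairs intact but breaks exact prevalence
  ce <- corrupt_alphabet(ens, "replace_letter", 0.25, seed = 9)
  flags <- vapply(ce$layouts, function(l) {
    counts <- table(factor(c(l), levels = c("H", "K", "L", "V", "W", "X",
                                            "Y", "Z")))
    !letter_prevalence_gof(counts)$exact
  }, logical(1))
  expect_identical(flags, ce$truth$affected)
  pair_ok <- vapply(ce$layouts, function(l) pair_prevalence(l)$ok, logical(1))
  expect_true(all(pair_ok))
})

test_that("voronoi corruptions trip their matched detectors", {
  ens <- voronoi_bank(2)           # 8 images over the four classes
  same <- corrupt_voronoi(ens, "permute_intensities", 0, seed = 1)
  expect_identical(same$images, ens$images)
  recs <- voronoi_bank_recovered(2)
  ce <- corrupt_voronoi(ens, "permute_intensities", 0.5, seed = 31)
  for (i in seq_along(ce$images)) {
    rec <- if (ce$truth$affected[i]) recover_regions(ce$images[[i]]) else
      recs[[i]]
    expect_equal(detect_rank_violation(rec), ce$truth$affected[i])
  }
  ce <- corrupt_voronoi(ens, "off_class_count", 0.5, seed = 32)
  for (i in seq_along(ce$images)) {
    rec <- if (ce$truth$affected[i]) recover_regions(ce$images[[i]]) else
      recs[[i]]
    expect_equal(detect_off_class(rec$n_regions), ce$truth$affected[i])
  }
  ce <- corrupt_voronoi(ens, "erase_edge_segment", 0.5, seed = 33)
  for (i in seq_along(ce$images)) {
    rec <- if (ce$truth$affected[i]) recover_regions(ce$images[[i]]) else
      recs[[i]]
    expect_equal(detect_disjoint_edge(ce$images[[i]], rec),
                 ce$truth$affected[i])
  }
})

test_that("flag corruptions trip their matched detectors", {
  ens <- flag_bank(2)              # 16 images over the eight classes
  A <- ens$templates
  same <- corrupt_flags(ens, "misplace_tile", 0, seed = 1)
  expect_identical(same$images, ens$images)
  ce <- corrupt_flags(ens, "misplace_tile", 0.25, seed = 61)
  for (i in which(ce$truth$affected)) {
    res <- classify_by_rmae(recover_foreground_pattern(ce$images[[i]]), A)
    expect_length(res$error_tiles, 2)
    expect_equal(res$class_id, ce$manifest$class[i])
    expect_false(res$forbidden_violation)
  }
  ce <- corrupt_flags(ens, "forbidden_fg_tile", 0.25, seed = 62)
  flags <- vapply(seq_along(ce$images), function(i) {
    classify_by_rmae(recover_foreground_pattern(ce$images[[i]]),
                     A)$forbidden_violation
  }, logical(1))
  expect_identical(flags, ce$truth$affected)
  null_q <- flag_intensity_null()
  ce <- corrupt_flags(ens, "wrong_intensity_law", 0.25, seed = 63)
  for (i in which(ce$truth$affected)) {
    pat <- recover_foreground_pattern(ce$images[[i]])
    # the corrupted law keeps tile means above threshold: pattern intact
    expect_identical(pat, unname(A[, ce$manifest$class[i]]))
    expect_false(intensity_gof(ce$images[[i]], pat, null_q)$acceptable)
  }
})
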