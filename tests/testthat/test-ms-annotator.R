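test_that("peak-list and MS2 loaders validate schema and rows", {
  pk <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,mz,intensity,rt_min", "p1,361.2234,100,6.66",
               "p2,379.2140,50,7.42"), pk)
  peaks <- load_peaklist(pk)
  expect_identical(peaks$id, c("p1", "p2"))
  expect_equal(peaks$mz[1], 361.2234)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,mz,intensity", empty)
  expect_identical(nrow(load_peaklist(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,mz,intensity", "p1,361.2,5", "p2,-1,5"), bad)
  expect_error(load_peaklist(bad), "row 2")
  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,intensity", "p1,5"), nocol)
  expect_error(load_peaklist(nocol), "missing column")

  m2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("precursor_id,mz,intensity", "p1,145.0396,10",
               "p1,231.1128,5", "p2,161.0346,1"), m2)
  spec <- load_ms2(m2)
  expect_identical(sort(names(spec)), c("p1", "p2"))
  expect_identical(nrow(spec$p1), 2L)
})

test_that("packaged reference tables load with the expected shape", {
  r1 <- reference_metabolites("5F-ADB-PINACA")
  r2 <- reference_metabolites("5F-ADBICA")
  expect_identical(nrow(r1), 22L)  # parent + 21
  expect_identical(nrow(r2), 29L)  # parent + 28
  expect_identical(nrow(reference_peaklist("5F-ADB-PINACA",
                                           include_parent = FALSE)), 21L)
  expect_identical(length(reference_ms2("5F-ADBICA")), 29L)
})

test_that("match_ms1 reports all in-tolerance pairs and is tolerance-monotone", {
  cg <- candidate_groups("5F-ADB-PINACA")
  pk <- data.frame(id = c("a", "b"), mz = c(361.2234, 500.0),
                   intensity = 1, rt_min = NA)
  mm <- match_ms1(pk, cg$groups, 5)
  expect_true(all(mm$peak_id == "a"))
  expect_true("C19H28N4O3" %in% mm$formula)
  expect_lt(abs(mm$ppm[mm$formula == "C19H28N4O3"]), 1)
  expect_false("b" %in% mm$peak_id)
  # every Table-style peak matches at least once
  full <- reference_peaklist("5F-ADB-PINACA", include_parent = FALSE)
  m5 <- match_ms1(full, cg$groups, 5)
  expect_setequal(unique(m5$peak_id), full$id)
  # monotonicity: matched set at 5 ppm is a subset of the 10 ppm set
  m10 <- match_ms1(full, cg$groups, 10)
  k5 <- paste(m5$peak_id, m5$formula)
  k10 <- paste(m10$peak_id, m10$formula)
  expect_true(all(k5 %in% k10))
  expect_identical(nrow(match_ms1(pk[0, ], cg$groups, 5)), 0L)
})

test_that("predict_fragments shifts only fragments covering the assigned moiety", {
  cg <- candidate_groups("5F-ADB-PINACA")
  fr <- cg$fragments
  # no applied rules: base masses unchanged
  base <- predict_fragments(character(), character(), cg$ruleset, fr)
  expect_equal(base$predicted_mz, fr$base_mz)
  # F -> OH on the side chain: core fragment stays, core+chain shifts
  h <- c(f_to_oh = "side_chain")
  pred <- predict_fragments("f_to_oh", h, cg$ruleset, fr)
  expect_equal(mz_round(pred$predicted_mz[pred$label == "core_acylium"]),
               145.0396)
  expect_equal(mz_round(pred$predicted_mz[pred$label == "core_chain_acylium"]),
               231.1128)
  # hydroxylation on the core shifts the core acylium to 161.0346
  pred2 <- predict_fragments("oh", c(oh = "core"), cg$ruleset, fr)
  expect_equal(mz_round(pred2$predicted_mz[pred2$label == "core_acylium"]),
               161.0346)
  # illegal assignment rejected
  expect_error(predict_fragments("dehydro", c(dehydro = "core"),
                                 cg$ruleset, fr), "invalid hypothesis")
})

test_that("localization reproduces the worked site assignments", {
  cg <- candidate_groups("5F-ADB-PINACA")
  ms2 <- reference_ms2("5F-ADB-PINACA")
  # hydrolytic defluorination localizes to the side chain, core untouched
  loc13 <- localize_moieties(find_group(cg$groups, "C19H28N4O3"),
                             ms2[["M13"]], cg$ruleset, cg$fragments)
  expect_identical(assignment_string(loc13), "f_to_oh@side_chain")
  expect_false(loc13$ambiguous)
  expect_identical(nrow(loc13$supporting_ions), 5L)
  # monohydroxylation: core-shifted ions vs chain-shifted ions
  gOH <- find_group(cg$groups, "C19H27FN4O3")
  expect_identical(assignment_string(
    localize_moieties(gOH, ms2[["M19"]], cg$ruleset, cg$fragments)),
    "oh@core")
  expect_identical(assignment_string(
    localize_moieties(gOH, ms2[["M12"]], cg$ruleset, cg$fragments)),
    "oh@side_chain")
  # ADB-residue assignment by elimination (core & chain fragments unshifted)
  loc3 <- localize_moieties(find_group(cg$groups, "C19H28N4O4"),
                            ms2[["M3"]], cg$ruleset, cg$fragments)
  expect_identical(assignment_string(loc3),
                   "f_to_oh@side_chain+oh@adb_residue")
  # empty spectrum -> undetermined sentinel, flagged
  locE <- localize_moieties(gOH, NULL, cg$ruleset, cg$fragments)
  expect_identical(locE$assignment, "undetermined")
  expect_true(locE$ambiguous)
})

test_that("indole-core hydroxylated metabolites localize to the core", {
  cg <- candidate_groups("5F-ADBICA")
  ms2 <- reference_ms2("5F-ADBICA")
  loc25 <- localize_moieties(find_group(cg$groups, "C20H28FN3O3"),
                             ms2[["M25"]], cg$ruleset, cg$fragments)
  expect_identical(assignment_string(loc25), "oh@core")
  expect_false(loc25$ambiguous)
  loc2 <- localize_moieties(find_group(cg$groups, "C20H29N3O4"),
                            ms2[["M2"]], cg$ruleset, cg$fragments)
  expect_identical(assignment_string(loc2), "f_to_oh@side_chain+oh@core")
})

test_that("supporting ions always lie within the MS2 tolerance (soundness)", {
  for (pid in c("5F-ADB-PINACA", "5F-ADBICA")) {
    cg <- candidate_groups(pid)
    res <- annotate_dataset(reference_peaklist(pid, include_parent = FALSE),
                            reference_ms2(pid), cg$parent, cg$ruleset)
    for (r in res$records)
      if (nrow(r$localization$supporting_ions))
        expect_true(all(abs(r$localization$supporting_ions$ppm) <= 10))
  }
})

test_that("annotate_dataset mirrors the two inventories end to end, deterministically", {
  cg1 <- candidate_groups("5F-ADB-PINACA")
  res1 <- annotate_dataset(reference_peaklist("5F-ADB-PINACA",
                                              include_parent = FALSE),
                           reference_ms2("5F-ADB-PINACA"),
                           cg1$parent, cg1$ruleset)
  expect_identical(res1$summary$n_matched, 21L)
  expect_identical(res1$summary$n_unmatched, 0L)
  cg2 <- candidate_groups("5F-ADBICA")
  res2 <- annotate_dataset(reference_peaklist("5F-ADBICA",
                                              include_parent = FALSE),
                           reference_ms2("5F-ADBICA"),
                           cg2$parent, cg2$ruleset)
  expect_identical(res2$summary$n_matched, 28L)
  # byte-for-byte determinism of the flattened table on a rerun
  t1 <- annotation_table(res1)
  t1b <- annotation_table(
    annotate_dataset(reference_peaklist("5F-ADB-PINACA",
                                        include_parent = FALSE),
                     reference_ms2("5F-ADB-PINACA"),
                     cg1$parent, cg1$ruleset))
  expect_identical(t1, t1b)
  # empty input -> empty output
  e <- annotate_dataset(data.frame(id = character(), mz = numeric(),
                                   intensity = numeric(), rt_min = numeric()),
                        NULL, cg1$parent, cg1$ruleset)
  expect_identical(e$summary$n_peaks, 0L)
  expect_identical(length(e$records), 0L)
})
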