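test_that("default rule sets carry the documented deltas and scaffold asymmetry", {
  rs_az <- default_ruleset("indazole-ADB")
  rs_in <- default_ruleset("indole-ADB")
  expect_equal(rs_az$rules$oh$delta, c(O = 1))
  expect_equal(rs_az$rules$oh$max_applications, 2L)
  expect_equal(rs_az$rules$dehydro$delta, c(H = -2))
  expect_equal(rs_az$rules$amide_hydrolysis$delta, c(H = -1, N = -1, O = 1))
  expect_equal(rs_az$rules$f_to_oh$delta, c(F = -1, H = 1, O = 1))
  expect_equal(rs_az$rules$f_to_cho$delta, c(F = -1, H = -1, O = 1))
  expect_equal(rs_az$rules$f_to_cooh$delta, c(F = -1, H = -1, O = 2))
  expect_equal(rs_az$rules$ox_aldehyde$delta, c(H = -2, O = 1))
  # observed asymmetry: deamination on indazole, N-dealkylation on indole
  expect_true("deamination" %in% names(rs_az$rules))
  expect_false("n_dealkylation" %in% names(rs_az$rules))
  expect_true("n_dealkylation" %in% names(rs_in$rules))
  expect_equal(rs_in$rules$n_dealkylation$delta, c(C = -5, H = -9, F = -1))
  # toggles
  expect_true("n_dealkylation" %in%
    names(default_ruleset("indazole-ADB", enable_dealkylation = TRUE)$rules))
})

test_that("rule sets survive a JSON round trip", {
  rs <- default_ruleset("indole-ADB")
  path <- withr::local_tempfile(fileext = ".json")
  write_ruleset(rs, path)
  rs2 <- read_ruleset(path)
  expect_identical(names(rs2$rules), names(rs$rules))
  expect_identical(rs2$depth_limit, rs$depth_limit)
  expect_equal(rs2$rules$f_to_cooh$delta, rs$rules$f_to_cooh$delta)
  expect_identical(rs2$rules$n_dealkylation$consumes_side_chain, TRUE)
})

test_that("apply_rule performs the table transformations and guards preconditions", {
  rs_az <- default_ruleset("indazole-ADB")
  rs_in <- default_ruleset("indole-ADB")
  m13 <- apply_rule(parse_formula("C19H27FN4O2"), rs_az$rules$f_to_oh)
  expect_identical(format_formula(m13), "C19H28N4O3")
  m14 <- apply_rule(parse_formula("C20H28FN3O2"), rs_in$rules$n_dealkylation)
  expect_identical(format_formula(m14), "C15H19N3O2")
  # no fluorine left -> not applicable
  expect_error(apply_rule(m13, rs_az$rules$f_to_oh), "not applicable")
  # side chain gone -> F rules blocked even if F were present
  expect_error(apply_rule(parse_formula("C20H28FN3O2"), rs_in$rules$f_to_oh,
                          dealkylated = TRUE), "not applicable")
})

test_that("enumeration matches an independent nested-loop oracle", {
  # Oracle: explicit loops over per-rule counts with its own delta table,
  # mutual exclusion of the F-consuming reactions, plain vector arithmetic.
  oracle <- function(parent_formula, deltas, fmax, depth_limit) {
    base <- unclass(parse_formula(parent_formula))
    elems <- c("C", "H", "F", "N", "O")
    vec <- stats::setNames(numeric(5), elems)
    vec[names(base)] <- base
    ids <- names(deltas)
    out <- character()
    counts <- stats::setNames(integer(length(ids)), ids)
    grid <- expand.grid(lapply(ids, function(i) 0:fmax[[i]]))
    names(grid) <- ids
    for (r in seq_len(nrow(grid))) {
      ct <- unlist(grid[r, ])
      if (sum(ct) < 1 || sum(ct) > depth_limit) next
      nf <- sum(ct[intersect(names(ct),
                             c("f_to_oh", "f_to_cho", "f_to_cooh",
                               "n_dealkylation"))])
      if (nf > 1) next
      v <- vec
      ok <- TRUE
      for (i in ids) if (ct[[i]] > 0) {
        d <- deltas[[i]]
        for (k in seq_len(ct[[i]])) v[names(d)] <- v[names(d)] + d
      }
      if (any(v < 0)) next
      key <- paste(paste0(sort(rep(ids, ct)), collapse = "+"),
                   paste(v, collapse = ","))
      out <- c(out, key)
    }
    sort(out)
  }
  deltas <- list(
    oh = c(O = 1), dehydro = c(H = -2),
    amide_hydrolysis = c(H = -1, N = -1, O = 1),
    f_to_oh = c(F = -1, H = 1, O = 1),
    f_to_cho = c(F = -1, H = -1, O = 1),
    f_to_cooh = c(F = -1, H = -1, O = 2),
    ox_aldehyde = c(H = -2, O = 1),
    deamination = c(H = -1, N = -1, O = 1))
  fmax <- list(oh = 2, dehydro = 1, amide_hydrolysis = 1, f_to_oh = 1,
               f_to_cho = 1, f_to_cooh = 1, ox_aldehyde = 1,
               deamination = 1)
  expected <- oracle("C19H27FN4O2", deltas, fmax, 3)

  p <- parent_compound("5F-ADB-PINACA")
  cands <- enumerate_candidates(p, default_ruleset(p$scaffold))
  elems <- c("C", "H", "F", "N", "O")
  got <- sort(vapply(cands, function(cd) {
    v <- stats::setNames(numeric(5), elems)
    cc <- unclass(cd$composition)
    v[names(cc)] <- cc
    paste(paste0(cd$applied, collapse = "+"), paste(v, collapse = ","))
  }, ""))
  expect_identical(got, expected)
})

test_that("enumeration respects depth, F-exclusion and mass bookkeeping", {
  p <- parent_compound("5F-ADBICA")
  rs <- default_ruleset(p$scaffold)
  expect_identical(
    enumerate_candidates(p, default_ruleset(p$scaffold, depth_limit = 0L)),
    list())
  cands <- enumerate_candidates(p, rs)
  f_ids <- c("f_to_oh", "f_to_cho", "f_to_cooh", "n_dealkylation")
  for (cd in cands) {
    expect_lte(cd$depth, rs$depth_limit)
    expect_lte(sum(cd$applied %in% f_ids), 1L)
    expect_true(all(unclass(cd$composition) >= 0))
    # theoretical mz differs from parent by the summed delta masses
    dm <- sum(vapply(cd$applied, function(a)
      delta_mass(rs$rules[[a]]$delta), 0))
    expect_equal(cd$theoretical_mz - p$mz_mh, dm, tolerance = 1e-9)
  }
})

test_that("every printed metabolite composition appears at depth <= 3", {
  for (pid in c("5F-ADB-PINACA", "5F-ADBICA")) {
    cg <- candidate_groups(pid)
    ref <- reference_metabolites(pid)
    ref <- ref[ref$id != "parent", ]
    expect_true(all(ref$formula %in%
                      vapply(cg$groups, `[[`, "", "formula")),
                label = paste(pid, "coverage"))
  }
})

test_that("dedup groups formula-degenerate multisets and keeps provenance", {
  cg <- candidate_groups("5F-ADB-PINACA")
  cands <- enumerate_candidates(cg$parent, cg$ruleset)
  expect_lte(length(cg$groups), length(cands))
  # amide hydrolysis and deamination are one composition, two provenances
  g <- find_group(cg$groups, "C19H26FN3O3")
  provs <- vapply(g$provenance, paste, "", collapse = "+")
  expect_true(all(c("amide_hydrolysis", "deamination") %in% provs))
  # ordering is deterministic
  g2 <- dedup_candidates(rev(cands))
  expect_identical(vapply(g2, `[[`, "", "formula"),
                   vapply(cg$groups, `[[`, "", "formula"))
})
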