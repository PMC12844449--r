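test_that("replicate aggregation is the cell-wise mean with NA handling", {
  df <- data.frame(
    metabolite_id = rep(c("a", "b"), each = 6),
    time_h = rep(c(1, 2), each = 3, times = 2),
    replicate = rep(1:3, 4),
    intensity = c(1, 2, 3, 4, 5, 6, 7, NA, NA, NA, NA, NA))
  agg <- aggregate_replicates(intensity_matrix(df))
  expect_equal(agg["a", "1"], 2)
  expect_equal(agg["a", "2"], 5)
  expect_equal(agg["b", "1"], 7)      # single replicate: itself
  expect_true(is.na(agg["b", "2"]))   # all replicates missing
})

test_that("normalization modes scale as documented and global_max is idempotent", {
  m <- rbind(a = c(1, 5, 10), b = c(2, 4, 8))
  attr(m, "time_h") <- c(1, 2, 4)
  g <- normalize_matrix(m, "global_max")
  expect_equal(max(g), 1)
  expect_identical(sum(g == 1), 1L)
  expect_equal(normalize_matrix(g, "global_max"), g)  # idempotent
  expect_equal(order(m), order(g))                    # rank preserved
  p <- normalize_matrix(m, "per_metabolite")
  expect_equal(unname(apply(p, 1, max)), c(1, 1))
  z <- matrix(0, 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_error(normalize_matrix(z), "maximum")
})

test_that("trend classification follows the ordered rules", {
  grid <- DEFAULT_TIME_GRID
  expect_identical(classify_trend(rep(3, 6), grid)$class, "stable")
  tr <- classify_trend(c(0.2, 1.0, 0.6, 0.3, 0.2, 0.1), grid)
  expect_identical(tr$class, "early_peak_decaying")
  expect_equal(tr$peak_time, 2)
  expect_equal(tr$persistence, 0.1)
  expect_identical(classify_trend(c(1, 2, 4, 8, 16, 32), grid)$class,
                   "rising")
  expect_identical(classify_trend(c(1, NA, NA, 4, NA, 2), grid)$class,
                   "undetermined")
  # erratic late-peaking series falls through to fluctuating
  expect_identical(classify_trend(c(1, 0.2, 2, 0.3, 5, 0.8), grid)$class,
                   "fluctuating")
})

test_that("correlation matrix invariants hold on random inputs (property)", {
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(stats::runif(8 * 6), 8, 6,
                dimnames = list(paste0("m", 1:8), NULL))
    attr(m, "time_h") <- DEFAULT_TIME_GRID
    cm <- correlation_matrix(m)
    expect_true(isSymmetric(unname(cm)))
    expect_equal(unname(diag(cm)), rep(1, nrow(cm)))
    expect_true(all(cm >= -1 - 1e-12 & cm <= 1 + 1e-12))
  }
})

test_that("correlation handles identical, opposite and hand-computed series", {
  m <- rbind(x = c(1, 2, 3, 4, 5, 6), y = c(1, 2, 3, 4, 5, 6),
             z = 7 - c(1, 2, 3, 4, 5, 6))
  attr(m, "time_h") <- DEFAULT_TIME_GRID
  cm <- correlation_matrix(m)
  expect_equal(cm["x", "y"], 1)
  expect_equal(cm["x", "z"], -1)
  # textbook formula on a hand-sized case
  a <- c(1, 4, 2, 8, 5, 7); b <- c(2, 3, 1, 9, 4, 6)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  m2 <- rbind(a = a, b = b)
  attr(m2, "time_h") <- DEFAULT_TIME_GRID
  expect_equal(correlation_matrix(m2)["a", "b"], num / den)
  # zero-variance row excluded with a warning
  m3 <- rbind(a = a, b = b, flat = rep(1, 6))
  attr(m3, "time_h") <- DEFAULT_TIME_GRID
  expect_warning(cm3 <- correlation_matrix(m3), "flat")
  expect_false("flat" %in% rownames(cm3))
})

test_that("threshold clustering partitions and refines monotonically", {
  blocks <- rbind(
    a1 = c(1, 2, 4, 8, 12, 20), a2 = c(1.1, 2.1, 4.2, 8.1, 12.5, 20.4),
    b1 = c(10, 8, 5, 3, 2, 1), b2 = c(9, 8.2, 5.1, 2.7, 2.1, 0.9))
  attr(blocks, "time_h") <- DEFAULT_TIME_GRID
  cm <- correlation_matrix(blocks)
  cl <- threshold_clusters(cm, 0.99)
  members <- sort(unlist(cl$components))
  expect_identical(members, sort(rownames(cm)))          # partition
  expect_identical(sum(vapply(cl$components, length, 0L)),
                   nrow(cm))                             # no overlap
  # all-high correlations collapse to one component
  ones <- matrix(0.95, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(ones) <- 1
  expect_identical(length(threshold_clusters(ones, 0.8)$components), 1L)
  # raising the threshold never merges components (refinement)
  set.seed(3)
  m <- matrix(stats::runif(10 * 6), 10, 6,
              dimnames = list(paste0("m", 1:10), NULL))
  attr(m, "time_h") <- DEFAULT_TIME_GRID
  cmr <- correlation_matrix(m)
  lo <- threshold_clusters(cmr, 0.5)
  hi <- threshold_clusters(cmr, 0.9)
  for (comp in hi$components) {
    parent_comp <- unique(lo$membership[comp])
    expect_identical(length(parent_comp), 1L)
  }
})

test_that("categorization applies the documented precedence", {
  m <- rbind(
    dom  = c(2, 4, 6, 8, 9, 10),    # highest abundance, rising
    r1   = c(1, 2, 3, 4, 4.5, 5),   # correlated with dom
    fast = c(0.2, 1, 0.5, 0.2, 0.1, 0.05),  # early peak, decays
    lone = c(1, 0.2, 2, 0.3, 1.5, 1.8))     # uncorrelated fluctuator
  attr(m, "time_h") <- DEFAULT_TIME_GRID
  norm <- normalize_matrix(m, "global_max")
  trends <- classify_trends(norm)
  cm <- correlation_matrix(m)
  cl <- threshold_clusters(cm, 0.8)
  cats <- categorize(trends, cl, norm)
  expect_identical(unname(cats["dom"]), "dominant_stable")
  expect_identical(unname(cats["fast"]), "rapidly_decaying")
  expect_identical(unname(cats["r1"]), "core_cluster")
  expect_identical(unname(cats["lone"]), "fluctuating_independent")
  # input-order invariance
  cats2 <- categorize(trends[rev(seq_len(nrow(trends))), ], cl,
                      norm[rev(rownames(norm)), ])
  expect_identical(cats2[names(cats)], cats)
})

test_that("biomarker nomination is deterministic and favors the dominant sink", {
  m <- rbind(
    dom  = c(2, 4, 6, 8, 9, 10),
    r1   = c(1, 2, 3, 4, 4.5, 5),
    fast = c(0.2, 1, 0.5, 0.2, 0.1, 0.05),
    lone = c(1, 0.2, 2, 0.3, 1.5, 1.8))
  attr(m, "time_h") <- DEFAULT_TIME_GRID
  norm <- normalize_matrix(m, "global_max")
  trends <- classify_trends(norm)
  cm <- correlation_matrix(m)
  cl <- threshold_clusters(cm, 0.8)
  cats <- categorize(trends, cl, norm)
  nom <- nominate_biomarkers(cats, norm, cm, cl)
  expect_identical(nom$top, "dom")
  expect_true(all(nom$ranking$score >= 0 & nom$ranking$score <= 1))
  # permuting the input rows leaves the ranking unchanged
  perm <- norm[rev(rownames(norm)), ]
  attr(perm, "time_h") <- DEFAULT_TIME_GRID
  nom2 <- nominate_biomarkers(cats[rev(names(cats))], perm, cm, cl)
  expect_identical(nom2$ranking$metabolite_id, nom$ranking$metabolite_id)
  # single metabolite nominates trivially (no correlation structure)
  single <- norm["dom", , drop = FALSE]
  attr(single, "time_h") <- DEFAULT_TIME_GRID
  nom1 <- nominate_biomarkers(c(dom = "dominant_stable"), single)
  expect_identical(nom1$top, "dom")
})

test_that("metabolite-set comparison does honest set arithmetic", {
  expect_equal(compare_metabolite_sets(c("a", "b"), c("a", "b"))$jaccard, 1)
  expect_equal(compare_metabolite_sets(c("a"), c("b"))$jaccard, 0)
  hlm <- paste0("M", 1:21)
  zf <- paste0("M", 3:21)
  cmp <- compare_metabolite_sets(hlm, zf)
  expect_identical(cmp$a_only, c("M1", "M2"))
  expect_identical(length(cmp$intersection), 19L)
  expect_identical(cmp$b_only, character(0))
})
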