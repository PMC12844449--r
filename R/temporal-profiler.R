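# Temporal metabolic profiling: replicate aggregation, normalization,
# trend classification, Pearson correlation clustering, four-way
# categorization, biomarker nomination, and metabolite-set comparison.

#' Default incubation time grid, in hours
#' @export
DEFAULT_TIME_GRID <- c(1, 2, 4, 8, 12, 24)

#' Build an intensity matrix from long-format data
#'
#' @param df data.frame with columns `metabolite_id`, `time_h`,
#'   `replicate`, `intensity` (non-negative; `NA` allowed for missing
#'   cells).
#' @return An `intensity_matrix`: a 3-d array metabolite x time x
#'   replicate with dimnames, time points strictly increasing.
#' @export
intensity_matrix <- function(df) {
  need <- c("metabolite_id", "time_h", "replicate", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("intensity data missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(df$intensity < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  mets <- unique(df$metabolite_id)
  times <- sort(unique(df$time_h))
  reps <- sort(unique(df$replicate))
  arr <- array(NA_real_, dim = c(length(mets), length(times), length(reps)),
               dimnames = list(mets, as.character(times), as.character(reps)))
  idx <- cbind(match(df$metabolite_id, mets),
               match(df$time_h, times),
               match(df$replicate, reps))
  arr[idx] <- df$intensity
  structure(arr, class = c("intensity_matrix", "array"), time_h = times)
}

#' Read a long-format intensity CSV
#' @param path CSV with columns `metabolite_id`, `time_h`, `replicate`,
#'   `intensity`.
#' @return An [intensity_matrix()].
#' @export
read_intensity_csv <- function(path) {
  intensity_matrix(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Mean-aggregate replicates
#'
#' Arithmetic mean over the replicates present in each (metabolite, time)
#' cell; cells with no replicate stay missing.
#'
#' @param m an [intensity_matrix()] (or a metabolite x time matrix, which
#'   is returned unchanged).
#' @return Numeric matrix metabolite x time with attribute `time_h`.
#' @export
aggregate_replicates <- function(m) {
  if (is.matrix(m) && length(dim(m)) == 2L) return(m)
  stopifnot(inherits(m, "intensity_matrix"))
  out <- apply(m, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  attr(out, "time_h") <- attr(m, "time_h")
  out
}

#' Normalize an aggregated intensity matrix
#'
#' `"global_max"` divides every value by the dataset-wide maximum, so all
#' values lie in \[0, 1\] and exactly the maximal cell equals 1 (the
#' "normalized to the most abundant" reading). `"per_metabolite"` divides
#' each row by its own maximum instead.
#'
#' @param m metabolite x time matrix.
#' @param mode `"global_max"` or `"per_metabolite"`.
#' @return Matrix of the same shape. Errors on an all-zero matrix.
#' @export
normalize_matrix <- function(m, mode = c("global_max", "per_metabolite")) {
  mode <- match.arg(mode)
  t_h <- attr(m, "time_h")
  if (mode == "global_max") {
    mx <- max(m, na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0) stop("matrix maximum must be > 0")
    out <- m / mx
  } else {
    rmax <- apply(m, 1, max, na.rm = TRUE)
    if (any(!is.finite(rmax) | rmax <= 0))
      stop("every metabolite needs a positive maximum for per-metabolite scaling")
    out <- sweep(m, 1, rmax, "/")
  }
  attr(out, "time_h") <- t_h
  out
}

#' Default trend-classification thresholds
#'
#' The source patterns are described only verbally, so these cut points
#' are package defaults, exposed for configuration: a metabolite is
#' `rising` when final/first fold >= 2 and final/max persistence >= 0.8;
#' `early_peak_decaying` when it peaks at or before 4 h and retains at
#' most half its maximum at the end; `stable` when its coefficient of
#' variation is <= 0.3; anything else is `fluctuating`.
#' @export
default_trend_thresholds <- function() {
  list(fold_rising = 2, persistence_rising = 0.8,
       peak_time_early = 4, persistence_decay = 0.5, cv_stable = 0.3)
}

#' Classify the temporal trend of one metabolite series
#'
#' Rules are applied in order: rising, early_peak_decaying, stable,
#' fluctuating. Fewer than 4 non-missing points yields the error-free
#' sentinel class `"undetermined"`.
#'
#' @param values intensities over the time grid (NA = missing).
#' @param time_h time grid in hours (default [DEFAULT_TIME_GRID]).
#' @param thresholds see [default_trend_thresholds()].
#' @return List with `class` and diagnostics `peak_time`, `persistence`
#'   (final/max), `fold` (final/first), `cv`.
#' @export
classify_trend <- function(values, time_h = DEFAULT_TIME_GRID,
                           thresholds = default_trend_thresholds()) {
  ok <- !is.na(values)
  if (sum(ok) < 4L)
    return(list(class = "undetermined", peak_time = NA_real_,
                persistence = NA_real_, fold = NA_real_, cv = NA_real_))
  v <- values[ok]; t_h <- time_h[ok]
  mx <- max(v)
  peak_time <- t_h[which.max(v)]
  persistence <- if (mx > 0) v[length(v)] / mx else NA_real_
  fold <- if (v[1] > 0) v[length(v)] / v[1] else Inf
  cv <- if (mean(v) > 0) stats::sd(v) / mean(v) else 0
  cls <-
    if (!is.na(fold) && fold >= thresholds$fold_rising &&
        persistence >= thresholds$persistence_rising) "rising"
    else if (peak_time <= thresholds$peak_time_early &&
             persistence <= thresholds$persistence_decay) "early_peak_decaying"
    else if (cv <= thresholds$cv_stable) "stable"
    else "fluctuating"
  list(class = cls, peak_time = peak_time, persistence = persistence,
       fold = fold, cv = cv)
}

#' Classify all rows of an aggregated matrix
#' @param m metabolite x time matrix with `time_h` attribute.
#' @param thresholds see [default_trend_thresholds()].
#' @return data.frame with one row per metabolite: `metabolite_id`,
#'   `class`, `peak_time`, `persistence`, `fold`, `cv`.
#' @export
classify_trends <- function(m, thresholds = default_trend_thresholds()) {
  t_h <- attr(m, "time_h")
  if (is.null(t_h)) t_h <- suppressWarnings(as.numeric(colnames(m)))
  if (length(t_h) != ncol(m) || anyNA(t_h)) t_h <- seq_len(ncol(m))
  rows <- lapply(rownames(m), function(id) {
    tr <- classify_trend(m[id, ], t_h, thresholds)
    data.frame(metabolite_id = id, class = tr$class,
               peak_time = tr$peak_time, persistence = tr$persistence,
               fold = tr$fold, cv = tr$cv)
  })
  do.call(rbind, rows)
}

#' Pairwise Pearson correlation of metabolite time courses
#'
#' Rows with fewer than `min_points` usable time points or zero variance
#' are excluded with a warning (their correlations are not estimable, or
#' are undefined).
#'
#' @param m aggregated metabolite x time matrix.
#' @param min_points minimum non-missing time points per metabolite
#'   (default 4: at most 2 of the canonical 6 may be missing).
#' @return Symmetric correlation matrix with unit diagonal and attribute
#'   `n_timepoints`; excluded metabolites are dropped.
#' @export
correlation_matrix <- function(m, min_points = 4L) {
  usable <- apply(m, 1, function(v) sum(!is.na(v)) >= min_points)
  novar <- apply(m, 1, function(v) {
    v <- v[!is.na(v)]; length(v) > 1 && stats::sd(v) == 0
  })
  drop <- rownames(m)[!usable | novar]
  if (length(drop))
    warning("excluded from correlation (missing > allowed or zero variance): ",
            paste(drop, collapse = ", "))
  keep <- m[usable & !novar, , drop = FALSE]
  if (nrow(keep) < 2L) stop("need at least 2 usable metabolites")
  cm <- stats::cor(t(keep), use = "pairwise.complete.obs",
                   method = "pearson")
  diag(cm) <- 1
  attr(cm, "n_timepoints") <- ncol(keep)
  cm
}

#' Cluster metabolites by thresholded correlation magnitude
#'
#' Builds the graph with an edge wherever `|rho| > threshold` and returns
#' its connected components. Component ids are deterministic: sorted by
#' decreasing size, ties by the lexicographically smallest member.
#'
#' @param cm correlation matrix from [correlation_matrix()].
#' @param threshold correlation magnitude cut (default 0.8).
#' @return List of class `cluster_set`: `threshold`, `components` (list of
#'   member-id character vectors), `membership` (named integer vector),
#'   `singleton` (named logical).
#' @export
threshold_clusters <- function(cm, threshold = 0.8) {
  stopifnot(isSymmetric(unname(cm)))
  adj <- abs(cm) > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  comps <- split(names(comp$membership), comp$membership)
  comps <- lapply(comps, function(v) sort(v))
  ord <- order(-vapply(comps, length, 0L),
               vapply(comps, `[`, "", 1))
  comps <- unname(comps[ord])
  membership <- stats::setNames(
    rep(seq_along(comps), vapply(comps, length, 0L)),
    unlist(comps))
  membership <- membership[rownames(cm)]
  structure(list(threshold = threshold, components = comps,
                 membership = membership,
                 singleton = stats::setNames(
                   vapply(comps, length, 0L)[membership] == 1L,
                   rownames(cm))),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> |rho| > ", x$threshold, ": ",
      length(x$components), " component(s)\n", sep = "")
  for (i in seq_along(x$components))
    cat("  [", i, "] ", paste(x$components[[i]], collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Four-way categorization of metabolites
#'
#' Formalizes the descriptive categories used for temporal profiles:
#' \describe{
#'   \item{dominant_stable}{the metabolite with the highest mean
#'     normalized abundance, provided its trend class is stable or
#'     rising;}
#'   \item{rapidly_decaying}{trend class early_peak_decaying;}
#'   \item{core_cluster}{members of the largest correlation component;}
#'   \item{fluctuating_independent}{everything else (singletons,
#'     negatively correlated members, fluctuating trends).}
#' }
#' Precedence when rules overlap: dominant_stable > rapidly_decaying >
#' core_cluster > fluctuating_independent.
#'
#' @param trends data.frame from [classify_trends()].
#' @param clusters `cluster_set` from [threshold_clusters()].
#' @param m aggregated (normalized or raw) metabolite x time matrix.
#' @return Named character vector of categories, one per metabolite in
#'   `m`, in sorted-id order.
#' @export
categorize <- function(trends, clusters, m) {
  ids <- sort(rownames(m))
  mean_ab <- apply(m, 1, mean, na.rm = TRUE)
  cls <- stats::setNames(trends$class, trends$metabolite_id)[ids]
  dominant <- names(which.max(mean_ab))
  core <- if (length(clusters$components)) clusters$components[[1]] else character()
  out <- stats::setNames(rep("fluctuating_independent", length(ids)), ids)
  out[ids %in% core] <- "core_cluster"
  out[cls == "early_peak_decaying"] <- "rapidly_decaying"
  if (length(dominant) && cls[dominant] %in% c("stable", "rising"))
    out[dominant] <- "dominant_stable"
  out
}

#' Nominate biomarker metabolites
#'
#' Composite score over min-max scaled components: 0.5 x abundance AUC
#' (trapezoid over the time grid), 0.3 x persistence (final/max), 0.2 x
#' cluster centrality (mean |rho| to the metabolite's own component;
#' 0 for singletons). Ties break by higher raw AUC, then lexicographic
#' id, so the ranking is deterministic and invariant to input order.
#'
#' @param categories named vector from [categorize()].
#' @param m aggregated metabolite x time matrix.
#' @param cm correlation matrix.
#' @param clusters `cluster_set`.
#' @return List of class `biomarker_nomination`: `ranking` (data.frame
#'   with score components), `top` (id), `top_per_category` (named list).
#' @export
nominate_biomarkers <- function(categories, m, cm = NULL, clusters = NULL) {
  ids <- sort(rownames(m))
  t_h <- attr(m, "time_h")
  if (is.null(t_h)) t_h <- suppressWarnings(as.numeric(colnames(m)))
  if (length(t_h) != ncol(m) || anyNA(t_h)) t_h <- seq_len(ncol(m))
  auc <- vapply(ids, function(id) {
    v <- m[id, ]; ok <- !is.na(v)
    v <- v[ok]; tt <- t_h[ok]
    if (length(v) < 2) return(0)
    sum(diff(tt) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  }, 0)
  persistence <- vapply(ids, function(id) {
    v <- m[id, ]; v <- v[!is.na(v)]
    if (!length(v) || max(v) <= 0) return(0)
    v[length(v)] / max(v)
  }, 0)
  centrality <- vapply(ids, function(id) {
    if (is.null(cm) || is.null(clusters) || !(id %in% rownames(cm)) ||
        is.na(clusters$membership[[id]])) return(0)
    comp <- clusters$components[[clusters$membership[[id]]]]
    others <- setdiff(comp, id)
    if (!length(others)) return(0)
    mean(abs(cm[id, others]))
  }, 0)
  scale01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0.5, length(x)) else (x - r[1]) / diff(r)
  }
  score <- 0.5 * scale01(auc) + 0.3 * scale01(persistence) +
    0.2 * scale01(centrality)
  ranking <- data.frame(
    metabolite_id = ids, category = categories[ids],
    auc = auc, persistence = persistence, centrality = centrality,
    auc_scaled = scale01(auc), persistence_scaled = scale01(persistence),
    centrality_scaled = scale01(centrality), score = score
  )
  ranking <- ranking[order(-ranking$score, -ranking$auc,
                           ranking$metabolite_id), ]
  rownames(ranking) <- NULL
  top_per_category <- lapply(
    split(ranking, ranking$category),
    function(d) d$metabolite_id[1])
  structure(list(ranking = ranking, top = ranking$metabolite_id[1],
                 top_per_category = top_per_category),
            class = "biomarker_nomination")
}

#' @export
print.biomarker_nomination <- function(x, ...) {
  cat("<biomarker_nomination> top: ", x$top, "\n", sep = "")
  print(utils::head(x$ranking[, c("metabolite_id", "category", "score")], 5))
  invisible(x)
}

#' Compare two metabolite id sets
#'
#' Set arithmetic used to compare in vitro (e.g. liver microsome) and in
#' vivo (e.g. zebrafish) metabolite inventories.
#'
#' @param a,b character vectors of metabolite ids.
#' @return List: `intersection`, `a_only`, `b_only`, `jaccard`.
#' @export
compare_metabolite_sets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- intersect(a, b)
  uni <- union(a, b)
  list(intersection = sort(inter), a_only = sort(setdiff(a, b)),
       b_only = sort(setdiff(b, a)),
       jaccard = if (length(uni)) length(inter) / length(uni) else 1)
}
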