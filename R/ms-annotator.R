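# MS1 peak matching within a ppm tolerance and MS2 diagnostic-fragment
# based localization of modifications to structural moieties.

#' Load an MS1 peak list from CSV
#'
#' Expected columns: `id`, `mz`, `intensity`, optionally `rt_min`.
#' Row order is preserved.
#'
#' @param path CSV path (UTF-8, header required).
#' @return data.frame with columns `id`, `mz`, `intensity`, `rt_min`
#'   (`NA` when absent).
#' @export
load_peaklist <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "mz", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("peak list ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df$mz <- suppressWarnings(as.numeric(df$mz))
  bad <- which(is.na(df$mz) | df$mz <= 0)
  if (length(bad))
    stop("peak list ", path, ": non-numeric or non-positive mz at row ",
         bad[1])
  df$intensity <- suppressWarnings(as.numeric(df$intensity))
  badi <- which(is.na(df$intensity) | df$intensity < 0)
  if (length(badi))
    stop("peak list ", path, ": invalid intensity at row ", badi[1])
  if (!"rt_min" %in% names(df)) df$rt_min <- rep(NA_real_, nrow(df))
  df[, c("id", "mz", "intensity", "rt_min")]
}

#' Load MS2 spectra from CSV
#'
#' Expected columns: `precursor_id`, `mz`, `intensity`. Returns one
#' spectrum per precursor id.
#'
#' @param path CSV path.
#' @return Named list of data.frames (`mz`, `intensity`), keyed by
#'   precursor id.
#' @export
load_ms2 <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("precursor_id", "mz", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("MS2 table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df$mz <- suppressWarnings(as.numeric(df$mz))
  bad <- which(is.na(df$mz) | df$mz <= 0)
  if (length(bad))
    stop("MS2 table ", path, ": non-numeric or non-positive mz at row ",
         bad[1])
  df$intensity <- suppressWarnings(as.numeric(df$intensity))
  lapply(split(df[, c("mz", "intensity")], df$precursor_id),
         function(x) { rownames(x) <- NULL; x })
}

#' Packaged reference metabolite tables
#'
#' The transcribed metabolite inventories of the two reference parents
#' (structure-consistent neutral formulas, printed protonated m/z,
#' site-coded reactions, retention times, and printed product ions).
#'
#' @param parent `"5F-ADB-PINACA"` or `"5F-ADBICA"`.
#' @return data.frame with columns `id`, `rule_sites` (e.g.
#'   `"f_to_oh@side_chain+oh@adb_residue"`), `formula`, `mz_printed`,
#'   `rt_min`, `product_ions` (semicolon separated).
#' @export
reference_metabolites <- function(parent = c("5F-ADB-PINACA", "5F-ADBICA")) {
  parent <- match.arg(parent)
  file <- switch(parent,
    "5F-ADB-PINACA" = "adb_pinaca_metabolites.csv",
    "5F-ADBICA"     = "adbica_metabolites.csv")
  path <- system.file("extdata", file, package = "biotransformr",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @describeIn reference_metabolites The same table as an MS1 peak-list
#'   data.frame (printed m/z; unit intensities since the source tables
#'   report none). `include_parent = FALSE` drops the parent row.
#' @param include_parent keep the parent compound row?
#' @export
reference_peaklist <- function(parent = c("5F-ADB-PINACA", "5F-ADBICA"),
                               include_parent = TRUE) {
  ref <- reference_metabolites(parent)
  if (!include_parent) ref <- ref[ref$id != "parent", ]
  data.frame(id = ref$id, mz = ref$mz_printed, intensity = 1,
             rt_min = ref$rt_min)
}

#' @describeIn reference_metabolites The printed product-ion lists as MS2
#'   spectra (unit intensities).
#' @export
reference_ms2 <- function(parent = c("5F-ADB-PINACA", "5F-ADBICA")) {
  ref <- reference_metabolites(parent)
  out <- lapply(strsplit(ref$product_ions, ";", fixed = TRUE), function(v)
    data.frame(mz = as.numeric(v), intensity = 1))
  stats::setNames(out, ref$id)
}

#' Scaffold diagnostic fragment table
#'
#' The positive-mode diagnostic fragments used for site localization, per
#' scaffold. Each fragment has a base cation composition (for the
#' unmodified parent) and the subset of moieties it retains; a
#' modification assigned to a retained moiety shifts the fragment by the
#' reaction's delta mass, while modifications elsewhere leave it at its
#' base m/z. The set comprises the core acylium ion, the core+chain
#' acylium, its water-addition and water-loss congeners, the
#' ammonia-loss and formamide-loss ions of the protonated molecule (which
#' retain all moieties), and, for the indole scaffold, the bare pentyl
#' chain cation.
#'
#' @param scaffold `"indazole-ADB"` or `"indole-ADB"`.
#' @return data.frame with columns `label`, `formula` (cation
#'   composition), `mode` (`"cation"`), `covers` (plus-separated moiety
#'   subset) and `base_mz`.
#' @export
scaffold_fragments <- function(scaffold = c("indazole-ADB", "indole-ADB")) {
  scaffold <- match.arg(scaffold)
  rows <- if (scaffold == "indazole-ADB") list(
    list("core_acylium",            "C8H5N2O",     "core"),
    list("core_chain_acylium",      "C13H14FN2O",  "core+side_chain"),
    list("core_chain_acylium_h2o",  "C13H16FN2O2", "core+side_chain"),
    list("core_chain_acylium_mh2o", "C13H12FN2",   "core+side_chain"),
    list("mh_minus_nh3",            "C19H25FN3O2", "core+side_chain+adb_residue"),
    list("mh_minus_formamide",      "C18H25FN3O",  "core+side_chain+adb_residue")
  ) else list(
    list("core_acylium",            "C9H6NO",      "core"),
    list("core_chain_acylium",      "C14H15FNO",   "core+side_chain"),
    list("core_chain_acylium_h2o",  "C14H17FNO2",  "core+side_chain"),
    list("core_chain_acylium_mh2o", "C14H13FN",    "core+side_chain"),
    list("chain_cation",            "C5H10F",      "side_chain"),
    list("mh_minus_nh3",            "C20H26FN2O2", "core+side_chain+adb_residue"),
    list("mh_minus_formamide",      "C19H26FN2O",  "core+side_chain+adb_residue")
  )
  df <- data.frame(
    label = vapply(rows, `[[`, "", 1),
    formula = vapply(rows, `[[`, "", 2),
    mode = "cation",
    covers = vapply(rows, `[[`, "", 3)
  )
  df$base_mz <- vapply(df$formula, function(f) ion_mz(f, "cation"), 0)
  df
}

#' Match MS1 peaks to candidate composition groups
#'
#' Reports every (peak, group) pair whose signed mass error is within the
#' tolerance. A peak may match several groups (formula-degenerate
#' candidates); all matches are reported, none resolved.
#'
#' @param peaks data.frame from [load_peaklist()].
#' @param groups deduped candidate groups from [dedup_candidates()].
#' @param tolerance_ppm MS1 tolerance (default 5 ppm).
#' @return data.frame with columns `peak_id`, `observed_mz`, `formula`,
#'   `theoretical_mz`, `ppm`, `tolerance_ppm`, `group_index`.
#' @export
match_ms1 <- function(peaks, groups, tolerance_ppm = 5) {
  if (!nrow(peaks) || !length(groups))
    return(data.frame(peak_id = character(), observed_mz = numeric(),
                      formula = character(), theoretical_mz = numeric(),
                      ppm = numeric(), tolerance_ppm = numeric(),
                      group_index = integer()))
  theo <- vapply(groups, `[[`, 0, "theoretical_mz")
  res <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(i) {
    ppm <- ppm_error(peaks$mz[i], theo)
    hit <- which(abs(ppm) <= tolerance_ppm)
    if (!length(hit)) return(NULL)
    data.frame(peak_id = peaks$id[i], observed_mz = peaks$mz[i],
               formula = vapply(groups[hit], `[[`, "", "formula"),
               theoretical_mz = theo[hit], ppm = ppm[hit],
               tolerance_ppm = tolerance_ppm, group_index = hit)
  }))
  if (is.null(res)) res <- data.frame(peak_id = character(),
                                      observed_mz = numeric(),
                                      formula = character(),
                                      theoretical_mz = numeric(),
                                      ppm = numeric(),
                                      tolerance_ppm = numeric(),
                                      group_index = integer())
  rownames(res) <- NULL
  res
}

# All legal moiety assignments of a rule multiset, as a list of named
# character vectors (instance label -> moiety). Instances of the same rule
# are symmetric, so assignments are generated as unordered combinations.
.assignment_hypotheses <- function(applied, rules) {
  dealk <- "n_dealkylation" %in% applied
  per_instance <- lapply(seq_along(applied), function(i) {
    r <- rules[[applied[i]]]
    m <- r$moieties
    if (dealk && !r$consumes_side_chain) m <- setdiff(m, "side_chain")
    m
  })
  if (!length(applied)) return(list(stats::setNames(character(0), character(0))))
  grid <- expand.grid(per_instance, stringsAsFactors = FALSE)
  hyps <- lapply(seq_len(nrow(grid)), function(i) {
    stats::setNames(as.character(grid[i, ]), applied)
  })
  # drop permutations of identical rule instances
  keys <- vapply(hyps, function(h)
    paste(sort(paste(names(h), h, sep = "@")), collapse = "+"), "")
  hyps[!duplicated(keys)]
}

.hypothesis_key <- function(h) {
  if (!length(h)) return("(parent)")
  paste(sort(paste(names(h), h, sep = "@")), collapse = "+")
}

#' Predict diagnostic fragment m/z for an assignment hypothesis
#'
#' For each scaffold fragment, the predicted m/z is the base cation m/z
#' plus the delta masses of every rule instance assigned to a moiety the
#' fragment retains. Fragments covering a moiety removed by N-dealkylation
#' are emitted in their dealkylated form (the dealkylation delta applies
#' to them like any other side-chain modification).
#'
#' @param applied character vector of rule ids (one entry per application).
#' @param hypothesis named character vector mapping each instance (names =
#'   `applied`) to a moiety; must lie within each rule's allowed set.
#' @param ruleset the `bt_ruleset` defining the deltas.
#' @param fragments fragment table from [scaffold_fragments()].
#' @return data.frame `label`, `predicted_mz`.
#' @export
predict_fragments <- function(applied, hypothesis, ruleset, fragments) {
  rules <- ruleset$rules
  if (length(applied)) {
    if (length(hypothesis) != length(applied))
      stop("hypothesis must assign every applied rule instance")
    for (i in seq_along(applied)) {
      if (!(hypothesis[i] %in% rules[[applied[i]]]$moieties))
        stop("invalid hypothesis: ", applied[i], " cannot occur on ",
             hypothesis[i])
    }
  }
  covers <- strsplit(fragments$covers, "+", fixed = TRUE)
  pred <- vapply(seq_len(nrow(fragments)), function(j) {
    shift <- 0
    if (length(applied)) {
      for (i in seq_along(applied)) {
        if (hypothesis[i] %in% covers[[j]])
          shift <- shift + delta_mass(rules[[applied[i]]]$delta)
      }
    }
    fragments$base_mz[j] + shift
  }, 0)
  data.frame(label = fragments$label, predicted_mz = pred)
}

#' Localize modifications to moieties from an MS2 spectrum
#'
#' Enumerates every legal assignment of the candidate's rule instances to
#' moieties (across all formula-degenerate provenances of the group),
#' scores each hypothesis by the number of observed ions lying within
#' `tolerance_ppm` of a predicted fragment, and returns the argmax. Ties
#' are never silently broken: all best hypotheses are listed and the
#' ambiguity flag is set. Rules whose only allowed site is the ADB residue
#' are localized there by elimination (no diagnostic fragment shifts, but
#' the assignment is forced). An empty spectrum yields the sentinel
#' assignment `"undetermined"` with the flag set.
#'
#' @param group one candidate group from [dedup_candidates()].
#' @param ms2 data.frame with columns `mz` (and optionally `intensity`),
#'   or `NULL`.
#' @param ruleset the `bt_ruleset`.
#' @param fragments fragment table from [scaffold_fragments()].
#' @param tolerance_ppm MS2 matching tolerance (default 10 ppm; precursor
#'   identification tolerance does not bind fragment masses, so this is a
#'   package default, configurable).
#' @return List of class `annotation_localization`: `assignment` (named
#'   moiety vector, or `"undetermined"`), `score`, `ambiguous`,
#'   `best_hypotheses` (list), `supporting_ions` (data.frame
#'   `observed_mz`, `fragment`, `predicted_mz`, `ppm`).
#' @export
localize_moieties <- function(group, ms2, ruleset, fragments,
                              tolerance_ppm = 10) {
  empty_ions <- data.frame(observed_mz = numeric(), fragment = character(),
                           predicted_mz = numeric(), ppm = numeric())
  if (is.null(ms2) || !nrow(ms2)) {
    return(structure(list(assignment = "undetermined", provenance = NULL,
                          score = 0L, ambiguous = TRUE,
                          best_hypotheses = list(),
                          supporting_ions = empty_ions),
                     class = "annotation_localization"))
  }
  obs <- ms2$mz
  best <- list(); best_score <- -1L
  for (prov in group$provenance) {
    for (h in .assignment_hypotheses(prov, ruleset$rules)) {
      pred <- predict_fragments(prov, h, ruleset, fragments)
      ions <- do.call(rbind, lapply(seq_along(obs), function(i) {
        ppm <- ppm_error(obs[i], pred$predicted_mz)
        j <- which.min(abs(ppm))
        if (abs(ppm[j]) <= tolerance_ppm)
          data.frame(observed_mz = obs[i], fragment = pred$label[j],
                     predicted_mz = pred$predicted_mz[j], ppm = ppm[j])
        else NULL
      }))
      score <- if (is.null(ions)) 0L else nrow(ions)
      cand <- list(provenance = prov, assignment = h,
                   supporting_ions = if (is.null(ions)) empty_ions else ions)
      if (score > best_score) {
        best <- list(cand); best_score <- score
      } else if (score == best_score) {
        best[[length(best) + 1L]] <- cand
      }
    }
  }
  # deterministic order of tied hypotheses
  keys <- vapply(best, function(b) .hypothesis_key(b$assignment), "")
  best <- best[order(keys)]
  structure(list(
    assignment = best[[1]]$assignment,
    provenance = best[[1]]$provenance,
    score = best_score,
    ambiguous = length(best) > 1L,
    best_hypotheses = lapply(best, `[[`, "assignment"),
    supporting_ions = best[[1]]$supporting_ions
  ), class = "annotation_localization")
}

#' Annotate a peak list end to end
#'
#' Enumerates candidates of the parent, dedups them, matches the MS1 peaks
#' at the precursor tolerance, and for each matched peak localizes the
#' modifications of its best-matching (smallest |ppm|) composition group
#' using its MS2 spectrum, if one is supplied. Output ordering is
#' deterministic (peak-list order).
#'
#' @param peaks data.frame from [load_peaklist()].
#' @param ms2_set named list of MS2 data.frames keyed by peak id (may be
#'   `NULL` or partial).
#' @param parent a [parent_compound()] list (or any list with
#'   `composition` and `scaffold`).
#' @param ruleset optional `bt_ruleset`; defaults to
#'   [default_ruleset()] for the parent's scaffold.
#' @param tolerance_ppm MS1 tolerance (default 5).
#' @param ms2_tolerance_ppm MS2 tolerance (default 10).
#' @return List of class `annotation_result`: `records` (one per matched
#'   peak), `matches` (the full MS1 match table), and `summary` (counts of
#'   peaks, matched, unmatched, ambiguous localizations).
#' @export
annotate_dataset <- function(peaks, ms2_set = NULL, parent,
                             ruleset = NULL,
                             tolerance_ppm = 5, ms2_tolerance_ppm = 10) {
  if (is.null(ruleset)) ruleset <- default_ruleset(parent$scaffold)
  fragments <- scaffold_fragments(parent$scaffold)
  groups <- dedup_candidates(enumerate_candidates(parent$composition, ruleset))
  matches <- match_ms1(peaks, groups, tolerance_ppm)
  records <- list()
  for (i in seq_len(nrow(peaks))) {
    mi <- matches[matches$peak_id == peaks$id[i], , drop = FALSE]
    if (!nrow(mi)) next
    j <- mi$group_index[which.min(abs(mi$ppm))]
    grp <- groups[[j]]
    loc <- localize_moieties(grp,
                             if (!is.null(ms2_set)) ms2_set[[peaks$id[i]]],
                             ruleset, fragments, ms2_tolerance_ppm)
    records[[length(records) + 1L]] <- list(
      peak_id = peaks$id[i],
      observed_mz = peaks$mz[i],
      formula = grp$formula,
      theoretical_mz = grp$theoretical_mz,
      ppm = ppm_error(peaks$mz[i], grp$theoretical_mz),
      n_ms1_matches = nrow(mi),
      provenance = grp$provenance,
      localization = loc
    )
  }
  matched_ids <- vapply(records, `[[`, "", "peak_id")
  summary <- list(
    n_peaks = nrow(peaks),
    n_matched = length(records),
    n_unmatched = nrow(peaks) - length(records),
    n_ambiguous = sum(vapply(records, function(r) r$localization$ambiguous,
                             TRUE)),
    unmatched_ids = setdiff(peaks$id, matched_ids)
  )
  structure(list(records = records, matches = matches, summary = summary),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("<annotation_result> ", x$summary$n_matched, "/", x$summary$n_peaks,
      " peaks matched; ", x$summary$n_ambiguous,
      " ambiguous localization(s)\n", sep = "")
  invisible(x)
}

#' Flatten annotation records to a table mirroring a metabolite inventory
#'
#' @param res an `annotation_result`.
#' @return data.frame with one row per annotated peak: id, formula,
#'   theoretical and observed m/z, ppm, applied reactions with assigned
#'   sites, ambiguity flag, and supporting ion count.
#' @export
annotation_table <- function(res) {
  if (!length(res$records))
    return(data.frame(peak_id = character(), formula = character(),
                      theoretical_mz = numeric(), observed_mz = numeric(),
                      ppm = numeric(), reactions = character(),
                      ambiguous = logical(), n_supporting_ions = integer()))
  do.call(rbind, lapply(res$records, function(r) {
    loc <- r$localization
    rx <- if (identical(loc$assignment, "undetermined")) "undetermined"
          else .hypothesis_key(loc$assignment)
    data.frame(peak_id = r$peak_id, formula = r$formula,
               theoretical_mz = mz_round(r$theoretical_mz),
               observed_mz = r$observed_mz, ppm = r$ppm,
               reactions = rx, ambiguous = loc$ambiguous,
               n_supporting_ions = nrow(loc$supporting_ions))
  }))
}
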