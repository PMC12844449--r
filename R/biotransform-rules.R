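# Phase I biotransformation rules as composition deltas with site
# constraints, and bounded-depth enumeration of candidate metabolites.
#
# Moiety vocabulary (shared with the MS2 localizer):
#   core        - the indazole or indole ring system
#   side_chain  - the N-linked 5-fluoropentyl chain
#   adb_residue - the tert-leucinamide (ADB) amide residue

.MOIETIES <- c("core", "side_chain", "adb_residue")

#' Construct a biotransformation rule
#'
#' A rule is a named, signed element-count delta applied to a neutral
#' composition, with constraints on where it may occur and how often.
#'
#' @param id short unique code (used in candidate provenance).
#' @param name human-readable reaction label.
#' @param delta named numeric vector, signed element counts
#'   (e.g. `c(O = 1)` for hydroxylation).
#' @param moieties subset of `c("core","side_chain","adb_residue")` where
#'   the reaction can occur.
#' @param max_applications maximum times the rule may appear in one
#'   candidate (default 1).
#' @param requires one of `"none"`, `"fluorine"` (an F atom must remain,
#'   i.e. the fluoropentyl terminus is intact), `"intact_side_chain"`
#'   (no N-dealkylation applied and F still present).
#' @param consumes_side_chain logical; `TRUE` for N-dealkylation, which
#'   removes the whole side chain and blocks later side-chain reactions.
#' @return A `bt_rule` object.
#' @export
bt_rule <- function(id, name, delta, moieties,
                    max_applications = 1L,
                    requires = c("none", "fluorine", "intact_side_chain"),
                    consumes_side_chain = FALSE) {
  requires <- match.arg(requires)
  stopifnot(is.character(id), nzchar(id), all(moieties %in% .MOIETIES))
  structure(
    list(id = id, name = name, delta = delta, moieties = moieties,
         max_applications = as.integer(max_applications),
         requires = requires,
         consumes_side_chain = isTRUE(consumes_side_chain)),
    class = "bt_rule"
  )
}

#' @export
print.bt_rule <- function(x, ...) {
  d <- paste0(ifelse(x$delta > 0, "+", ""), x$delta, names(x$delta),
              collapse = " ")
  cat("<bt_rule> ", x$id, " (", x$name, "): ", d,
      "  [", paste(x$moieties, collapse = ","), "]\n", sep = "")
  invisible(x)
}

#' Default phase I rule set for an ADB-type synthetic cannabinoid scaffold
#'
#' Returns the reaction inventory observed for indazole-3-carboxamide
#' ("indazole-ADB", e.g. 5F-ADB-PINACA) and indole-3-carboxamide
#' ("indole-ADB", e.g. 5F-ADBICA) parents carrying a 5-fluoropentyl side
#' chain and a tert-leucinamide residue:
#' hydroxylation (+O, up to twice: dihydroxylation is modeled as two
#' applications), dehydrogenation (-2H), amide hydrolysis (NH2 -> OH),
#' deamination, hydrolytic defluorination (F -> OH), oxidative
#' defluorination to aldehyde (F -> CHO), defluorination to carboxylic
#' acid (F -> COOH), oxidation to aldehyde on the ADB residue, and
#' N-dealkylation (loss of the whole C5H9F chain). The four F-consuming
#' reactions and N-dealkylation are mutually exclusive because the parent
#' carries a single fluorine on the chain terminus.
#'
#' Deamination was observed only on the indazole parent and N-dealkylation
#' only on the indole parent; the defaults mirror that, with toggles to
#' enable either on any scaffold.
#'
#' @param scaffold `"indazole-ADB"` or `"indole-ADB"`.
#' @param depth_limit maximum number of reactions per candidate (default 3,
#'   the deepest observed combination).
#' @param enable_deamination,enable_dealkylation override the
#'   scaffold-specific defaults.
#' @return A `bt_ruleset` object (list of [bt_rule()]s plus `depth_limit`).
#' @export
default_ruleset <- function(scaffold = c("indazole-ADB", "indole-ADB"),
                            depth_limit = 3L,
                            enable_deamination = NULL,
                            enable_dealkylation = NULL) {
  scaffold <- match.arg(scaffold)
  if (is.null(enable_deamination))  enable_deamination  <- scaffold == "indazole-ADB"
  if (is.null(enable_dealkylation)) enable_dealkylation <- scaffold == "indole-ADB"
  rules <- list(
    bt_rule("oh", "hydroxylation", c(O = 1), .MOIETIES,
            max_applications = 2L),
    bt_rule("dehydro", "dehydrogenation", c(H = -2), "adb_residue"),
    bt_rule("amide_hydrolysis", "amide hydrolysis (NH2 -> OH)",
            c(H = -1, N = -1, O = 1), "adb_residue"),
    bt_rule("f_to_oh", "hydrolytic defluorination (F -> OH)",
            c(F = -1, H = 1, O = 1), "side_chain",
            requires = "intact_side_chain"),
    bt_rule("f_to_cho", "oxidative defluorination to aldehyde (F -> CHO)",
            c(F = -1, H = -1, O = 1), "side_chain",
            requires = "intact_side_chain"),
    bt_rule("f_to_cooh", "defluorination to carboxylic acid (F -> COOH)",
            c(F = -1, H = -1, O = 2), "side_chain",
            requires = "intact_side_chain"),
    bt_rule("ox_aldehyde", "oxidation to aldehyde", c(H = -2, O = 1),
            "adb_residue")
  )
  if (enable_deamination)
    rules <- c(rules, list(
      bt_rule("deamination", "deamination", c(H = -1, N = -1, O = 1),
              "adb_residue")))
  if (enable_dealkylation)
    rules <- c(rules, list(
      bt_rule("n_dealkylation", "N-dealkylation (loss of C5H9F)",
              c(C = -5, H = -9, F = -1), "side_chain",
              requires = "intact_side_chain",
              consumes_side_chain = TRUE)))
  ids <- vapply(rules, `[[`, "", "id")
  stopifnot(!anyDuplicated(ids))
  structure(
    list(rules = stats::setNames(rules, ids),
         depth_limit = as.integer(depth_limit),
         scaffold = scaffold),
    class = "bt_ruleset"
  )
}

#' @export
print.bt_ruleset <- function(x, ...) {
  cat("<bt_ruleset> scaffold=", x$scaffold,
      " depth_limit=", x$depth_limit, "\n", sep = "")
  for (r in x$rules) print(r)
  invisible(x)
}

#' Serialize / read a rule set as JSON
#'
#' Element deltas, site constraints and caps are plain data, so new
#' scaffolds can be described without code changes.
#' @param rs a `bt_ruleset`.
#' @param path file path.
#' @return `read_ruleset` returns a `bt_ruleset`.
#' @export
write_ruleset <- function(rs, path) {
  doc <- list(
    scaffold = rs$scaffold, depth_limit = rs$depth_limit,
    rules = lapply(unname(rs$rules), function(r)
      list(id = r$id, name = r$name, delta = as.list(r$delta),
           moieties = r$moieties, max_applications = r$max_applications,
           requires = r$requires,
           consumes_side_chain = r$consumes_side_chain))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(doc$rules, function(r)
    bt_rule(r$id, r$name, unlist(r$delta), unlist(r$moieties),
            max_applications = r$max_applications, requires = r$requires,
            consumes_side_chain = isTRUE(r$consumes_side_chain)))
  ids <- vapply(rules, `[[`, "", "id")
  structure(list(rules = stats::setNames(rules, ids),
                 depth_limit = as.integer(doc$depth_limit),
                 scaffold = doc$scaffold),
            class = "bt_ruleset")
}

#' Reference parent compounds
#'
#' Neutral formulas and scaffold assignments of the two ADB-type synthetic
#' cannabinoids the package ships support for.
#'
#' @param id `"5F-ADB-PINACA"` (indazole core, C19H27FN4O2) or
#'   `"5F-ADBICA"` (indole core, C20H28FN3O2).
#' @return List with `id`, `formula`, `composition`, `scaffold`, and the
#'   theoretical protonated m/z `mz_mh`.
#' @export
parent_compound <- function(id = c("5F-ADB-PINACA", "5F-ADBICA")) {
  id <- match.arg(id)
  formula <- switch(id,
    "5F-ADB-PINACA" = "C19H27FN4O2",
    "5F-ADBICA"     = "C20H28FN3O2")
  scaffold <- switch(id,
    "5F-ADB-PINACA" = "indazole-ADB",
    "5F-ADBICA"     = "indole-ADB")
  comp <- parse_formula(formula)
  list(id = id, formula = formula, composition = comp, scaffold = scaffold,
       mz_mh = ion_mz(comp, "protonated"))
}

.rule_applicable <- function(rule, comp, dealkylated) {
  f_ok <- ("F" %in% names(comp)) && comp[["F"]] >= 1
  switch(rule$requires,
    none = TRUE,
    fluorine = f_ok,
    intact_side_chain = f_ok && !dealkylated
  )
}

#' Apply one biotransformation rule to a composition
#'
#' @param comp neutral [elem_comp()].
#' @param rule a [bt_rule()].
#' @param dealkylated logical; has the side chain already been removed?
#' @return The transformed [elem_comp()]. Errors with
#'   "rule not applicable" if the rule's precondition fails (e.g. F -> OH
#'   on a fluorine-free composition).
#' @export
apply_rule <- function(comp, rule, dealkylated = FALSE) {
  if (!.rule_applicable(rule, comp, dealkylated))
    stop("rule not applicable: ", rule$id, " on ", format_formula(comp))
  comp_add(comp, rule$delta)
}

#' Enumerate candidate metabolites of a parent to a bounded depth
#'
#' Generates every multiset of rule applications of size 1..`depth_limit`
#' respecting per-rule `max_applications`, the mutual exclusion of the
#' F-consuming reactions (the parent carries a single fluorine), and the
#' unavailability of side-chain reactions after N-dealkylation. Reaction
#' order is not modeled: candidates are multisets, and formula-degenerate
#' multisets (e.g. amide hydrolysis vs deamination) are distinct candidates
#' that [dedup_candidates()] groups by composition.
#'
#' @param parent neutral [elem_comp()] (or a [parent_compound()] list).
#' @param ruleset a `bt_ruleset` from [default_ruleset()].
#' @return A list of candidates; each is a list with `applied` (character
#'   vector of rule ids, one entry per application, sorted), `composition`,
#'   `formula`, `theoretical_mz` (protonated), and `depth`.
#' @export
enumerate_candidates <- function(parent, ruleset) {
  if (is.list(parent) && !inherits(parent, "elem_comp"))
    parent <- parent$composition
  stopifnot(inherits(parent, "elem_comp"), inherits(ruleset, "bt_ruleset"))
  rules <- ruleset$rules
  ids <- names(rules)
  out <- list()
  # enumerate rule-count vectors (multisets) of total size 1..depth_limit
  recurse <- function(i, counts, depth) {
    if (i > length(ids)) {
      if (depth == 0L) return()
      cand <- .realize_candidate(parent, rules, rep(ids, counts))
      if (!is.null(cand)) out[[length(out) + 1L]] <<- cand
      return()
    }
    kmax <- min(rules[[ids[i]]]$max_applications,
                ruleset$depth_limit - depth)
    for (k in 0:kmax) {
      counts[i] <- k
      recurse(i + 1L, counts, depth + k)
    }
  }
  recurse(1L, integer(length(ids)), 0L)
  out
}

# Apply a rule multiset; NULL if invalid under the site/F constraints.
.realize_candidate <- function(parent, rules, applied) {
  dealk <- "n_dealkylation" %in% applied
  # apply side-chain-consuming / F-consuming rules first so the
  # intact-chain precondition is checked against the pre-modification state
  is_f <- vapply(applied, function(a)
    rules[[a]]$requires == "intact_side_chain", TRUE)
  if (sum(is_f) > 1L) return(NULL)  # single fluorine
  comp <- parent
  dealkylated <- FALSE
  ord <- c(applied[is_f], applied[!is_f])
  for (a in ord) {
    r <- rules[[a]]
    if (!.rule_applicable(r, comp, dealkylated)) return(NULL)
    cc <- tryCatch(comp_add(comp, r$delta), error = function(e) NULL)
    if (is.null(cc)) return(NULL)
    comp <- cc
    if (r$consumes_side_chain) dealkylated <- TRUE
  }
  applied <- sort(applied)
  list(applied = applied, composition = comp,
       formula = format_formula(comp),
       theoretical_mz = ion_mz(comp, "protonated"),
       depth = length(applied))
}

#' Group candidates by distinct composition
#'
#' Several reaction multisets can be formula-degenerate (amide hydrolysis
#' and deamination share a delta; F -> COOH equals F -> CHO plus
#' hydroxylation). Matching at MS1 can only see the composition, so
#' candidates are grouped, with every generating multiset preserved as
#' provenance.
#'
#' @param cands list from [enumerate_candidates()].
#' @return A list of groups sorted by `theoretical_mz`; each group has
#'   `formula`, `composition`, `theoretical_mz`, and `provenance` (list of
#'   rule-id character vectors).
#' @export
dedup_candidates <- function(cands) {
  if (!length(cands)) return(list())
  keys <- vapply(cands, `[[`, "", "formula")
  groups <- lapply(split(seq_along(cands), keys), function(idx) {
    prov <- lapply(cands[idx], `[[`, "applied")
    prov <- prov[order(vapply(prov, paste, "", collapse = "+"))]
    list(formula = cands[[idx[1]]]$formula,
         composition = cands[[idx[1]]]$composition,
         theoretical_mz = cands[[idx[1]]]$theoretical_mz,
         provenance = prov)
  })
  groups <- unname(groups)
  groups[order(vapply(groups, `[[`, 0, "theoretical_mz"),
               vapply(groups, `[[`, "", "formula"))]
}
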