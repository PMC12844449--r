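# Shared helpers: candidate-group lookup, hypothesis formatting, and a
# tiny random-composition generator for property tests.

candidate_groups <- local({
  cache <- list()
  function(parent_id) {
    if (is.null(cache[[parent_id]])) {
      p <- parent_compound(parent_id)
      rs <- default_ruleset(p$scaffold)
      cache[[parent_id]] <<- list(
        parent = p, ruleset = rs,
        groups = dedup_candidates(enumerate_candidates(p, rs)),
        fragments = scaffold_fragments(p$scaffold))
    }
    cache[[parent_id]]
  }
})

find_group <- function(groups, formula) {
  i <- which(vapply(groups, `[[`, "", "formula") == formula)
  stopifnot(length(i) == 1L)
  groups[[i]]
}

assignment_string <- function(loc) {
  if (identical(loc$assignment, "undetermined")) return("undetermined")
  paste(sort(paste(names(loc$assignment), loc$assignment, sep = "@")),
        collapse = "+")
}

random_composition <- function() {
  syms <- c("C", "H", "N", "O", "F", "S", "Cl")
  n <- sample(1:5, 1)
  pick <- sample(syms, n)
  elem_comp(stats::setNames(sample(1:30, n, replace = TRUE), pick))
}

# long-format intensity data from a metabolite x time matrix, 1 replicate
long_from_matrix <- function(m, time_h) {
  do.call(rbind, lapply(rownames(m), function(id)
    data.frame(metabolite_id = id, time_h = time_h, replicate = 1,
               intensity = m[id, ])))
}
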