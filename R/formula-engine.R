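# Elemental-formula algebra and exact monoisotopic mass / m/z arithmetic.
# Everything downstream (candidate enumeration, peak matching, fragment
# prediction) is built on these primitives, so masses are kept at full
# double precision and only rounded at the presentation layer.

#' Monoisotopic atomic mass table
#'
#' Monoisotopic masses (Da) of the most abundant isotope of each supported
#' element, pinned to the CODATA 2018 / IUPAC 2021 values. The table is
#' immutable and versioned so that every reported m/z in this package is
#' reproducible from a named reference.
#'
#' @return Named numeric vector of monoisotopic masses in Da, with a
#'   `"version"` attribute identifying the reference table.
#' @examples
#' atomic_masses()[["O"]]
#' @export
atomic_masses <- function() {
  m <- c(
    C  = 12.0,
    H  = 1.00782503207,
    N  = 14.0030740048,
    O  = 15.9949146196,
    F  = 18.99840322,
    S  = 31.97207100,
    P  = 30.97376163,
    Cl = 34.96885268,
    Br = 78.9183371
  )
  attr(m, "version") <- "CODATA-2018/IUPAC-2021 monoisotopic"
  m
}

#' Mass of the proton, in Da
#' @export
PROTON_MASS <- 1.00727646688

#' Mass of the electron, in Da
#' @export
ELECTRON_MASS <- 0.00054857990

.known_elements <- function() names(atomic_masses())

#' Construct an elemental composition
#'
#' An elemental composition is a multiset of element counts, represented as
#' a named integer vector carrying class `elem_comp`. All counts must be
#' non-negative; zero-count elements are dropped.
#'
#' @param counts named numeric vector of non-negative integer counts, e.g.
#'   `c(C = 19, H = 28, N = 4, O = 3)`. May be empty.
#' @return An `elem_comp` object.
#' @export
elem_comp <- function(counts = numeric()) {
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("composition counts must be named by element symbol")
    unknown <- setdiff(names(counts), .known_elements())
    if (length(unknown))
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    if (any(counts < 0) || any(counts != round(counts)))
      stop("element counts must be non-negative integers")
    counts <- counts[counts > 0]
    # merge duplicated symbols
    counts <- tapply(counts, names(counts), sum)
    counts <- counts[order(names(counts))]
  }
  structure(as.numeric(counts), names = names(counts), class = "elem_comp")
}

#' @export
print.elem_comp <- function(x, ...) {
  cat("<elem_comp> ", format_formula(x), "  (",
      format(monoisotopic_mass(x), nsmall = 5), " Da)\n", sep = "")
  invisible(x)
}

#' @export
`==.elem_comp` <- function(e1, e2) {
  identical(format_formula(e1), format_formula(e2))
}

#' Parse a molecular formula string
#'
#' Accepts plain Hill-like notation (`"C19H28N4O3"`). Underscores (as they
#' appear in subscript-mangled table extracts), whitespace and a trailing
#' `"+"` charge suffix are tolerated and ignored; unit counts may be
#' omitted (`"H2O"`). Unknown element symbols or stray characters are
#' rejected with the offending position named.
#'
#' @param text formula string.
#' @return An [elem_comp()] object.
#' @examples
#' parse_formula("C19H28N4O3")
#' parse_formula("C_19_H_28_N_4_O_3_")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[_[:space:]]", "", text)
  s <- sub("\\+$", "", s)
  if (!nzchar(s)) return(elem_comp())
  counts <- numeric()
  pos <- 1L
  n <- nchar(s)
  while (pos <= n) {
    m <- regmatches(
      substr(s, pos, n),
      regexpr("^([A-Z][a-z]?)([0-9]*)", substr(s, pos, n))
    )
    if (!length(m) || !nzchar(m))
      stop("malformed formula '", text, "' at position ", pos,
           " ('", substr(s, pos, pos), "')")
    sym <- sub("^([A-Z][a-z]?).*$", "\\1", m)
    # two-letter symbol only if known; otherwise fall back to one letter
    if (nchar(sym) == 2L && !(sym %in% .known_elements()))
      sym <- substr(sym, 1, 1)
    if (!(sym %in% .known_elements()))
      stop("unknown element '", sym, "' in formula '", text,
           "' at position ", pos)
    rest <- substr(s, pos + nchar(sym), n)
    dig <- regmatches(rest, regexpr("^[0-9]*", rest))
    cnt <- if (nzchar(dig)) as.numeric(dig) else 1
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0) + cnt
    pos <- pos + nchar(sym) + nchar(dig)
  }
  elem_comp(counts)
}

#' Format an elemental composition as a formula string
#'
#' Hill order: C first, then H, then remaining elements alphabetically.
#' Formatting then re-parsing is the identity on valid compositions.
#'
#' @param comp an [elem_comp()].
#' @return Character scalar (`""` for the empty composition).
#' @export
format_formula <- function(comp) {
  if (!length(comp)) return("")
  syms <- names(comp)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    k <- comp[[e]]
    if (k == 1) e else paste0(e, format(k, scientific = FALSE))
  }, ""), collapse = "")
}

#' Add a signed element-count delta to a composition
#'
#' Used to apply biotransformation deltas (which may remove atoms). Errors
#' if any resulting count would be negative.
#'
#' @param comp an [elem_comp()].
#' @param delta named numeric vector of signed counts, e.g.
#'   `c(F = -1, H = 1, O = 1)`.
#' @return An [elem_comp()].
#' @export
comp_add <- function(comp, delta) {
  if (!length(delta)) return(elem_comp(stats::setNames(as.numeric(comp), names(comp))))
  unknown <- setdiff(names(delta), .known_elements())
  if (length(unknown))
    stop("unknown element symbol(s) in delta: ", paste(unknown, collapse = ", "))
  syms <- union(names(comp), names(delta))
  out <- stats::setNames(numeric(length(syms)), syms)
  out[names(comp)] <- out[names(comp)] + as.numeric(comp)
  out[names(delta)] <- out[names(delta)] + delta
  if (any(out < 0))
    stop("delta yields negative count for: ",
         paste(names(out)[out < 0], collapse = ", "))
  elem_comp(out)
}

#' Exact monoisotopic mass of a composition, in Da
#'
#' Sum of pinned monoisotopic atomic masses; additive over composition
#' union. The empty composition has mass 0.
#'
#' @param comp an [elem_comp()] or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")   # 18.010565
#' @export
monoisotopic_mass <- function(comp) {
  if (is.character(comp)) comp <- parse_formula(comp)
  if (!length(comp)) return(0)
  sum(atomic_masses()[names(comp)] * as.numeric(comp))
}

#' Monoisotopic delta mass of a signed element-count delta, in Da
#' @param delta named numeric vector of signed counts.
#' @return Signed mass in Da.
#' @export
delta_mass <- function(delta) {
  if (!length(delta)) return(0)
  sum(atomic_masses()[names(delta)] * delta)
}

#' Theoretical m/z of a singly charged positive ion
#'
#' Two conventions appear in positive-mode small-molecule work and both are
#' needed to reproduce printed tables exactly:
#' \describe{
#'   \item{`"protonated"`}{`comp` is the neutral species; m/z = neutral
#'     monoisotopic mass + proton mass (the \eqn{[M+H]^+} ion).}
#'   \item{`"cation"`}{`comp` is the composition of the charged fragment
#'     itself (e.g. an acylium ion); m/z = monoisotopic mass − electron
#'     mass.}
#' }
#'
#' @param comp an [elem_comp()] or formula string.
#' @param mode `"protonated"` or `"cation"`.
#' @param charge must be `+1` (only singly charged positive ions are
#'   supported); 0 is an error.
#' @return m/z at full precision (round with [mz_round()] for display).
#' @examples
#' mz_round(ion_mz("C19H28N4O3"))            # 361.2234
#' mz_round(ion_mz("C8H5N2O", mode = "cation"))  # 145.0396
#' @export
ion_mz <- function(comp, mode = c("protonated", "cation"), charge = 1L) {
  mode <- match.arg(mode)
  if (charge == 0) stop("ion charge must be non-zero")
  if (charge != 1L) stop("only singly charged positive ions are supported")
  m <- monoisotopic_mass(comp)
  switch(mode,
    protonated = m + PROTON_MASS,
    cation     = m - ELECTRON_MASS
  )
}

#' Round an m/z for presentation (4 decimals, half-even)
#' @param mz numeric vector.
#' @param digits decimal places (default 4, as printed in metabolite tables).
#' @export
mz_round <- function(mz, digits = 4L) round(mz, digits)

#' Signed mass error in parts per million
#'
#' `1e6 * (observed - theoretical) / theoretical`; sign preserved.
#'
#' @param observed observed m/z.
#' @param theoretical theoretical m/z; must be > 0.
#' @return ppm error (vectorized).
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
  1e6 * (observed - theoretical) / theoretical
}

#' Enumerate elemental compositions matching a target m/z
#'
#' Exhaustive search over all compositions elementwise bounded by `bounds`
#' whose ion m/z (under `mode`) lies within `tolerance_ppm` of `target`.
#' Used to assign compositions to printed product ions whose formulas are
#' not stated. The search prunes on cumulative minimum mass, so realistic
#' CHNOF bounds are fast.
#'
#' @param target target m/z.
#' @param bounds an [elem_comp()] (or formula string) giving the maximum
#'   count of each element.
#' @param tolerance_ppm matching tolerance in ppm (> 0).
#' @param mode `"protonated"`, `"cation"`, or `"neutral"` (match the plain
#'   monoisotopic mass).
#' @return A data.frame with columns `formula`, `mz`, `ppm`, sorted by
#'   `abs(ppm)`; zero rows if nothing matches. The matched compositions are
#'   attached as attribute `"compositions"` (list of [elem_comp()]).
#' @export
decompose_mz <- function(target, bounds, tolerance_ppm = 5,
                         mode = c("cation", "protonated", "neutral")) {
  mode <- match.arg(mode)
  stopifnot(tolerance_ppm > 0, target > 0)
  if (is.character(bounds)) bounds <- parse_formula(bounds)
  offset <- switch(mode, protonated = PROTON_MASS,
                   cation = -ELECTRON_MASS, neutral = 0)
  neutral_target <- target - offset
  tol_da <- target * tolerance_ppm * 1e-6
  am <- atomic_masses()
  syms <- names(bounds)
  # incremental cross-join over elements, pruning partial masses above target
  partial <- list(list(counts = stats::setNames(numeric(0), character(0)), mass = 0))
  for (e in syms) {
    me <- am[[e]]
    nxt <- vector("list", 0L)
    for (p in partial) {
      kmax <- min(bounds[[e]], floor((neutral_target + tol_da - p$mass) / me))
      if (kmax < 0) next
      for (k in 0:kmax) {
        q <- p
        if (k > 0) q$counts[e] <- k
        q$mass <- p$mass + k * me
        nxt[[length(nxt) + 1L]] <- q
      }
    }
    partial <- nxt
  }
  masses <- vapply(partial, `[[`, 0, "mass")
  keep <- abs(masses - neutral_target) <= tol_da & masses > 0
  hits <- partial[keep]
  if (!length(hits)) {
    out <- data.frame(formula = character(), mz = numeric(), ppm = numeric())
    attr(out, "compositions") <- list()
    return(out)
  }
  comps <- lapply(hits, function(h) elem_comp(h$counts))
  mzs <- vapply(hits, function(h) h$mass + offset, 0)
  ppm <- ppm_error(target, mzs)  # sign: target relative to candidate theory
  ord <- order(abs(ppm), vapply(comps, format_formula, ""))
  out <- data.frame(
    formula = vapply(comps, format_formula, "")[ord],
    mz = mzs[ord], ppm = ppm[ord]
  )
  attr(out, "compositions") <- comps[ord]
  out
}
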