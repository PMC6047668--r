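# Monoisotopic m/z of molecular-formula ions, for verifying conjugate
# identity against calculated ESI-TOF values.

# IUPAC/CODATA monoisotopic masses (Da)
.monoisotopic_mass <- c(
  C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  S = 31.97207069, P = 30.97376151)
.electron_mass <- 0.0005485799

#' Parse a molecular formula string
#'
#' Accepts element-count grammar with an optional trailing charge given as
#' a run of sign characters (`"+"` for a monocation, `"++"` for a dication,
#' `"-"`, ...), e.g. `"C2H5NO2"`, `"H+"`, `"C60H69N14O10+"`.  Bare element
#' symbols have an implicit count of 1.
#'
#' @param text Formula string.
#' @return List of class `molecular_formula` with fields `counts` (named
#'   integer vector) and `charge` (integer; positive for cations).
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  body <- gsub("\\s+", "", text)
  charge <- 0L
  m <- regmatches(body, regexec("([+-]+)$", body))[[1L]]
  if (length(m) == 2L) {
    if (!m[2L] %in% c(strrep("+", 1:9), strrep("-", 1:9)))
      stop("mixed charge signs in suffix: ", m[2L], call. = FALSE)
    charge <- nchar(m[2L]) * (if (substr(m[2L], 1L, 1L) == "+") 1L else -1L)
    body <- substr(body, 1L, nchar(body) - nchar(m[2L]))
  }
  toks <- regmatches(body, gregexpr("[A-Z][a-z]?[0-9]*", body))[[1L]]
  if (paste(toks, collapse = "") != body || length(toks) == 0L)
    stop("cannot parse formula: ", text, call. = FALSE)
  counts <- integer(0)
  for (tok in toks) {
    el <- gsub("[0-9]", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.monoisotopic_mass))
      stop("unknown element symbol: ", el, call. = FALSE)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  structure(list(counts = counts, charge = charge),
            class = "molecular_formula")
}

#' Canonical text form of a molecular formula
#'
#' Hill-like order (C, H, then remaining elements alphabetically), counts
#' of 1 omitted, charge as a trailing run of `+`/`-`.
#'
#' @param x A `molecular_formula`.
#' @param ... Unused.
#' @return Character scalar.
#' @export
format.molecular_formula <- function(x, ...) {
  els <- names(x$counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  body <- paste(vapply(ord, function(e) {
    n <- x$counts[[e]]
    if (n == 1L) e else paste0(e, n)
  }, ""), collapse = "")
  suffix <- if (x$charge == 0L) "" else
    strrep(if (x$charge > 0L) "+" else "-", abs(x$charge))
  paste0(body, suffix)
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Monoisotopic mass-to-charge ratio of an ion
#'
#' Sums the monoisotopic masses of all atoms, subtracts one electron mass
#' per positive charge (adds per negative charge), and divides by the
#' absolute charge when it is at least 1 (a neutral formula returns the
#' neutral monoisotopic mass).  The result is rounded half-even to 4
#' decimals, the precision at which calculated ESI-TOF values are quoted.
#'
#' @param formula A `molecular_formula` or a formula string (parsed with
#'   [parse_formula()]).
#' @return Monoisotopic m/z in Da, rounded to 4 decimals.
#' @export
#' @examples
#' monoisotopic_mz("H+")            # 1.0073 (a bare proton)
#' monoisotopic_mz("C2H5NO2")       # 75.0320 (glycine, neutral)
monoisotopic_mz <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "molecular_formula"))
  mass <- sum(formula$counts * .monoisotopic_mass[names(formula$counts)]) -
    formula$charge * .electron_mass
  mz <- if (abs(formula$charge) >= 1L) mass / abs(formula$charge) else mass
  round(mz, 4)
}
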