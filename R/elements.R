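#' Monoisotopic element masses
#'
#' Standard monoisotopic masses (Da) of the elements occurring in the lipid
#' classes handled by this package. Carbon is exactly 12 by definition of the
#' unified atomic mass scale.
#'
#' @format Named numeric vector (Da) for C, H, N, O, P, S.
#' @export
ELEMENT_MASSES <- c(
  C = 12,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  P = 30.97376151,
  S = 31.97207069
)

# Mass of a proton corrected for the electron (Da); subtracted for the
# deprotonated [M-H]- adduct. At 2 ppm tolerance the electron mass matters
# above roughly m/z 500.
PROTON_MASS <- 1.00727646

#' Construct an element-count vector
#'
#' Element counts are the package's molecular-formula representation: a named
#' integer vector over C, H, N, O, P, S. All arithmetic on formulas is
#' element-wise.
#'
#' @param ... Named integer counts, e.g. `element_counts(C = 6, H = 10, O = 5)`.
#' @param allow_negative Internal switch used while composing residue
#'   arithmetic; user-facing formulas must be non-negative with at least one C.
#' @return Named integer vector of class `element_counts`.
#' @examples
#' element_counts(C = 36, H = 71, N = 1, O = 3)
#' @export
element_counts <- function(..., allow_negative = FALSE) {
  v <- c(C = 0L, H = 0L, N = 0L, O = 0L, P = 0L, S = 0L)
  args <- c(...)
  if (length(args)) {
    if (is.null(names(args)) || any(!nzchar(names(args)))) {
      stop("element counts must be named", call. = FALSE)
    }
    unknown <- setdiff(names(args), names(v))
    if (length(unknown)) {
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    v[names(args)] <- v[names(args)] + as.integer(args)
  }
  if (!allow_negative && any(v < 0L)) {
    stop("element counts must be non-negative", call. = FALSE)
  }
  structure(v, class = "element_counts")
}

# Element-wise formula addition/subtraction. Subtraction yielding a negative
# count is a construction error (the residue rules never remove atoms that are
# not present).
formula_add <- function(a, b) {
  v <- unclass(a)
  v[names(b)] <- v[names(b)] + unclass(b)
  structure(v, class = "element_counts")
}

formula_subtract <- function(a, b) {
  v <- unclass(a)
  v[names(b)] <- v[names(b)] - unclass(b)
  if (any(v < 0L)) {
    stop("formula construction error: negative element count after subtraction",
         call. = FALSE)
  }
  structure(v, class = "element_counts")
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula An `element_counts` vector (or a named numeric vector of
#'   element counts).
#' @return Monoisotopic mass in Da. The empty formula has mass 0.
#' @examples
#' monoisotopic_mass(element_counts(C = 36, H = 71, N = 1, O = 3))
#' @export
monoisotopic_mass <- function(formula) {
  v <- unclass(formula)
  if (is.null(names(v)) && length(v) == 0L) return(0)
  unknown <- setdiff(names(v), names(ELEMENT_MASSES))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(v * ELEMENT_MASSES[names(v)])
}

#' @export
format.element_counts <- function(x, ...) {
  v <- unclass(x)
  v <- v[v > 0L]
  if (!length(v)) return("(empty)")
  paste0(names(v), ifelse(v > 1L, v, ""), collapse = "")
}

#' @export
print.element_counts <- function(x, ...) {
  cat(format(x), sprintf(" (monoisotopic %.4f Da)\n", monoisotopic_mass(x)))
  invisible(x)
}
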