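# Element universe and exact-mass arithmetic.
#
# Every formula in the package is a named integer vector over the fixed
# 14-element universe ELEMENTS (order matters: it is the layout of the first
# 14 entries of a peak vector). Monoisotopic masses are CODATA/IUPAC values;
# adduct offsets are ion masses (proton / sodium minus an electron).

#' Supported element universe
#'
#' The fixed, ordered set of elements the framework can represent in peak
#' vectors and subformula annotations. Molecules containing any other element
#' are rejected at parse time.
#'
#' @format Character vector of length 14.
#' @export
ELEMENTS <- c("C", "H", "O", "N", "P", "S", "Cl", "F", "Br", "I",
              "B", "As", "Si", "Se")

# monoisotopic masses (Da), most abundant isotope
ELEMENT_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  O  = 15.9949146196,
  N  = 14.0030740048,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  F  = 18.99840322,
  Br = 78.9183371,
  I  = 126.904473,
  B  = 11.0093054,
  As = 74.9215965,
  Si = 27.9769265325,
  Se = 79.9165213
)[ELEMENTS]

# ion mass added to the neutral fragment under each supported adduct
ADDUCT_OFFSET <- c("[M+H]+" = 1.007276, "[M+Na]+" = 22.989218)

#' Supported adducts
#' @return Character vector of adduct labels understood by the package.
#' @export
supported_adducts <- function() names(ADDUCT_OFFSET)

#' Ion mass offset of an adduct
#'
#' @param adduct Adduct label, one of [supported_adducts()].
#' @return Mass (Da) added to a neutral fragment to obtain the observed m/z.
#' @export
adduct_offset <- function(adduct) {
  check_adduct(adduct)
  unname(ADDUCT_OFFSET[adduct])
}

check_adduct <- function(adduct) {
  bad <- !(adduct %in% names(ADDUCT_OFFSET))
  if (any(bad)) {
    rlang::abort(
      paste0("Unsupported adduct '", unique(adduct[bad])[1],
             "'. Supported adducts: ",
             paste(names(ADDUCT_OFFSET), collapse = ", ")),
      class = "massembed_adduct_error"
    )
  }
  invisible(adduct)
}

# coerce any named count vector to the full 14-element integer layout
as_formula_counts <- function(x) {
  out <- stats::setNames(integer(length(ELEMENTS)), ELEMENTS)
  if (length(x)) {
    nm <- names(x)
    unknown <- setdiff(nm, ELEMENTS)
    if (length(unknown)) {
      rlang::abort(
        paste0("Element ", unknown[1], " is not in the supported set {",
               paste(ELEMENTS, collapse = ","), "}"),
        class = "massembed_element_error"
      )
    }
    out[nm] <- as.integer(x)
  }
  if (any(out < 0)) {
    rlang::abort("Formula counts must be non-negative",
                 class = "massembed_element_error")
  }
  out
}

#' Monoisotopic mass of a formula
#'
#' @param formula Named integer vector of element counts (any subset of the
#'   supported elements), or a formula string such as `"C6H12O6"`.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass("C6H12O6") # 180.063388
#' @export
formula_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  counts <- as_formula_counts(formula)
  sum(counts * ELEMENT_MASS)
}

#' Parse a molecular formula string
#'
#' @param x Formula string, e.g. `"C6H12O6"` or `"CHO2"`.
#' @return Named integer vector over the 14 supported elements.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  if (x == "" || x == "-") return(as_formula_counts(integer(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x, perl = TRUE)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(x)) {
    rlang::abort(paste0("Cannot parse formula '", x, "'"),
                 class = "massembed_formula_error")
  }
  syms <- sub("[0-9]*$", "", toks)
  cnts <- sub("^[A-Z][a-z]?", "", toks)
  cnts <- ifelse(cnts == "", 1L, as.integer(cnts))
  out <- stats::setNames(integer(length(ELEMENTS)), ELEMENTS)
  for (i in seq_along(syms)) {
    if (!(syms[i] %in% ELEMENTS)) {
      rlang::abort(
        paste0("Element ", syms[i], " is not in the supported set"),
        class = "massembed_element_error"
      )
    }
    out[syms[i]] <- out[syms[i]] + cnts[i]
  }
  out
}

#' Format element counts as a formula string
#'
#' Elements appear in the fixed package order (C, H, O, N, ...) with zero
#' counts omitted; the empty formula prints as `"-"`. This string is also the
#' deterministic tie-break key of the peak annotator.
#'
#' @param counts Named integer vector of element counts.
#' @return Single formula string.
#' @export
format_formula <- function(counts) {
  counts <- as_formula_counts(counts)
  nz <- counts > 0
  if (!any(nz)) return("-")
  paste0(ELEMENTS[nz], ifelse(counts[nz] == 1, "", counts[nz]), collapse = "")
}

# vectorized formula-string -> counts matrix (rows in ELEMENTS order)
formula_matrix <- function(strings) {
  out <- matrix(0L, nrow = length(strings), ncol = length(ELEMENTS),
                dimnames = list(NULL, ELEMENTS))
  for (i in seq_along(strings)) out[i, ] <- parse_formula(strings[i])
  out
}
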