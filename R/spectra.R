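# Spectral views: subformula peak annotation, the element scaler, peak
# vectors, consensus spectra, and the binned-spectrum variant.

# ---- subformula enumeration -------------------------------------------------

# Enumerate all subformulas f (0 <= f_e <= parent_e) of a parent formula.
# Full enumeration up to `limit` subformulas; beyond that a meet-in-the-
# middle split over the element set is used per query window.
.FULL_ENUM_LIMIT <- 2e5

enumerate_subformulas <- function(parent) {
  parent <- as_formula_counts(parent)
  nz <- which(parent > 0)
  n_comb <- prod(parent[nz] + 1)
  if (n_comb <= .FULL_ENUM_LIMIT) {
    grid <- as.matrix(do.call(expand.grid, lapply(parent[nz], function(k) 0:k)))
    counts <- matrix(0L, nrow(grid), length(ELEMENTS),
                     dimnames = list(NULL, ELEMENTS))
    counts[, nz] <- as.integer(grid)
    list(full = TRUE, counts = counts,
         mass = as.numeric(counts %*% ELEMENT_MASS))
  } else {
    # split nonzero elements into two halves with balanced combination counts
    sizes <- log(parent[nz] + 1)
    ord <- order(sizes, decreasing = TRUE)
    gA <- logical(length(nz)); sA <- 0; sB <- 0
    for (i in ord) {
      if (sA <= sB) { gA[i] <- TRUE; sA <- sA + sizes[i] }
      else sB <- sB + sizes[i]
    }
    half <- function(idx) {
      if (!length(idx)) {
        return(list(counts = matrix(0L, 1, length(ELEMENTS),
                                    dimnames = list(NULL, ELEMENTS)),
                    mass = 0))
      }
      grid <- as.matrix(do.call(expand.grid,
                                lapply(parent[idx], function(k) 0:k)))
      counts <- matrix(0L, nrow(grid), length(ELEMENTS),
                       dimnames = list(NULL, ELEMENTS))
      counts[, idx] <- as.integer(grid)
      list(counts = counts, mass = as.numeric(counts %*% ELEMENT_MASS))
    }
    A <- half(nz[gA]); B <- half(nz[!gA])
    ordB <- order(B$mass)
    B$counts <- B$counts[ordB, , drop = FALSE]
    B$mass <- B$mass[ordB]
    list(full = FALSE, A = A, B = B)
  }
}

# candidate subformulas with neutral mass in [lo, hi]
.subformula_window <- function(enum, lo, hi) {
  if (enum$full) {
    sel <- which(enum$mass >= lo & enum$mass <= hi)
    list(counts = enum$counts[sel, , drop = FALSE], mass = enum$mass[sel])
  } else {
    counts <- NULL; mass <- numeric(0)
    for (i in seq_along(enum$A$mass)) {
      jlo <- findInterval(lo - enum$A$mass[i], enum$B$mass) + 1
      jhi <- findInterval(hi - enum$A$mass[i], enum$B$mass)
      if (jhi >= jlo) {
        j <- jlo:jhi
        cc <- enum$B$counts[j, , drop = FALSE]
        cc <- sweep(cc, 2, enum$A$counts[i, ], "+")
        counts <- rbind(counts, cc)
        mass <- c(mass, enum$A$mass[i] + enum$B$mass[j])
      }
    }
    if (is.null(counts)) {
      counts <- matrix(0L, 0, length(ELEMENTS),
                       dimnames = list(NULL, ELEMENTS))
    }
    list(counts = counts, mass = mass)
  }
}

# ---- peak annotation --------------------------------------------------------

#' Annotate peaks of one spectrum with subformulas of its parent molecule
#'
#' Keeps the `max_peaks` most abundant peaks, then assigns to each peak the
#' subformula of the parent formula whose adduct ion mass lies within
#' `ppm_tol` ppm of the observed m/z, minimizing the absolute ppm error
#' (ties broken by the lexicographically smallest formula string).
#' Unassigned peaks are dropped and the surviving intensities are divided by
#' their maximum, so the most intense annotated peak has intensity 1.
#'
#' @param peaks Tibble or data frame with columns `mz` and `intensity`.
#' @param parent Parent molecular formula (string or named counts).
#' @param adduct Adduct label, one of [supported_adducts()].
#' @param ppm_tol Matching tolerance in ppm (default 20).
#' @param max_peaks Number of most-abundant peaks retained before matching
#'   (default 60).
#' @return Tibble with columns `formula` (string), `intensity` (max-
#'   normalized), `ppm_error` (signed), ordered by decreasing intensity.
#'   Zero rows (with a warning) when nothing is annotatable.
#' @export
annotate_peaks <- function(peaks, parent, adduct, ppm_tol = 20,
                           max_peaks = 60) {
  check_adduct(adduct)
  parent <- if (is.character(parent)) parse_formula(parent) else
    as_formula_counts(parent)
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  empty <- tibble::tibble(formula = character(0), intensity = numeric(0),
                          ppm_error = numeric(0))
  if (nrow(peaks) == 0) return(empty)
  ord <- order(-peaks$intensity, peaks$mz)
  keep <- ord[seq_len(min(max_peaks, length(ord)))]
  mz <- peaks$mz[keep]; inten <- peaks$intensity[keep]

  offset <- adduct_offset(adduct)
  enum <- enumerate_subformulas(parent)
  out_formula <- character(0); out_int <- numeric(0); out_ppm <- numeric(0)
  for (i in seq_along(mz)) {
    target <- mz[i] - offset          # neutral fragment mass
    w <- ppm_tol * 1e-6 * mz[i]
    cand <- .subformula_window(enum, target - w, target + w)
    if (!length(cand$mass)) next
    ion <- cand$mass + offset
    ppm <- (mz[i] - ion) / ion * 1e6
    ok <- abs(ppm) <= ppm_tol
    if (!any(ok)) next
    ppm <- ppm[ok]
    cc <- cand$counts[ok, , drop = FALSE]
    best <- abs(ppm) <= min(abs(ppm)) + 1e-9
    strs <- apply(cc[best, , drop = FALSE], 1, format_formula)
    pick <- which(best)[order(strs)[1]]
    out_formula <- c(out_formula, format_formula(cc[pick, ]))
    out_int <- c(out_int, inten[i])
    out_ppm <- c(out_ppm, ppm[pick])
  }
  if (!length(out_formula)) {
    rlang::warn("No peak could be annotated with a subformula of the parent")
    return(empty)
  }
  ord2 <- order(-out_int, out_formula)
  tibble::tibble(
    formula = out_formula[ord2],
    intensity = out_int[ord2] / max(out_int),
    ppm_error = out_ppm[ord2]
  )
}

#' Annotate a table of spectra against their parent molecules
#'
#' Joins spectra to molecules on `molecule_id` and runs [annotate_peaks()]
#' per spectrum.
#'
#' @param spectra Tibble as returned by [read_mgf()] (columns `spectrum_id`,
#'   `adduct`, `molecule_id`, list-column `peaks`).
#' @param molecules Tibble from [parse_molecules()].
#' @inheritParams annotate_peaks
#' @return Tibble `spectrum_id`, `molecule_id`, `adduct`, `peaks`
#'   (list-column of annotated peak tibbles); spectra with no annotatable
#'   peak keep a zero-row peak table.
#' @export
annotate_spectra <- function(spectra, molecules, ppm_tol = 20,
                             max_peaks = 60) {
  idx <- match(spectra$molecule_id, molecules$molecule_id)
  if (anyNA(idx)) {
    rlang::abort(paste0("No molecule record for spectrum ",
                        spectra$spectrum_id[which(is.na(idx))[1]]),
                 class = "massembed_join_error")
  }
  ann <- vector("list", nrow(spectra))
  # enumerations are reused across spectra of the same molecule
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(spectra))) {
    ann[[i]] <- annotate_peaks(spectra$peaks[[i]],
                               molecules$formula[idx[i]],
                               spectra$adduct[i],
                               ppm_tol = ppm_tol, max_peaks = max_peaks)
  }
  tibble::tibble(
    spectrum_id = spectra$spectrum_id,
    molecule_id = spectra$molecule_id,
    adduct = spectra$adduct,
    peaks = ann
  )
}

# ---- element scaler ---------------------------------------------------------

#' Fit the per-element count scaler on annotated training spectra
#'
#' For each supported element, records the highest count observed over all
#' annotated peak formulas in the training set, floored at 1 (elements never
#' observed get 1, with a warning), so peak vectors are scaled into `[0, 1]`
#' on training data.
#'
#' @param annotated Tibble from [annotate_spectra()] (or any tibble with a
#'   `peaks` list-column of annotated peak tables).
#' @return Named integer vector of class `element_scaler`.
#' @export
fit_element_scaler <- function(annotated) {
  all_peaks <- dplyr::bind_rows(annotated$peaks)
  if (nrow(all_peaks) == 0) {
    rlang::abort("Cannot fit an element scaler on an empty training set",
                 class = "massembed_scaler_error")
  }
  counts <- formula_matrix(all_peaks$formula)
  mx <- apply(counts, 2, max)
  unseen <- mx == 0
  if (any(unseen)) {
    rlang::warn(paste0("Elements never observed in training annotations ",
                       "(scaler entry set to 1): ",
                       paste(ELEMENTS[unseen], collapse = ", ")))
  }
  structure(pmax(as.integer(mx), 1L), names = ELEMENTS,
            class = "element_scaler")
}

#' @export
print.element_scaler <- function(x, ...) {
  cat("<element_scaler>\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Convert an annotated peak to its 15-dimensional vector
#'
#' Entries 1-14 are the element counts in the fixed order
#' C,H,O,N,P,S,Cl,F,Br,I,B,As,Si,Se, each divided by the scaler's maximum
#' training count; entry 15 is the normalized intensity. Counts exceeding
#' the training maximum yield entries above 1 (warned, not clipped).
#'
#' @param formula Formula string or named counts of one peak.
#' @param intensity Normalized intensity in `[0, 1]`.
#' @param scaler An `element_scaler` from [fit_element_scaler()].
#' @return Numeric vector of length 15.
#' @export
peak_to_vector <- function(formula, intensity, scaler) {
  stopifnot(inherits(scaler, "element_scaler"))
  counts <- if (is.character(formula)) parse_formula(formula) else
    as_formula_counts(formula)
  v <- counts / as.integer(scaler)
  if (any(v > 1)) {
    rlang::warn(paste0("Peak formula ", format_formula(counts),
                       " exceeds a training maximum count; vector entries ",
                       "above 1 are not clipped"))
  }
  c(unname(v), intensity)
}

#' Peak-vector matrix of an annotated spectrum
#'
#' @param peaks Annotated peak tibble (`formula`, `intensity`).
#' @param scaler An `element_scaler`.
#' @param warn Warn on entries above 1 (default FALSE; see
#'   [peak_to_vector()]).
#' @return Matrix (n_peaks x 15).
#' @export
spectrum_to_matrix <- function(peaks, scaler, warn = FALSE) {
  stopifnot(inherits(scaler, "element_scaler"))
  if (nrow(peaks) == 0) return(matrix(0, 0, 15))
  counts <- formula_matrix(peaks$formula)
  v <- sweep(counts, 2, as.integer(scaler), "/")
  if (warn && any(v > 1)) {
    rlang::warn("Peak formulas exceed training maximum counts")
  }
  unname(cbind(v, peaks$intensity))
}

# ---- consensus spectra ------------------------------------------------------

#' Build the consensus spectrum of one molecule
#'
#' Merges all peaks across the given annotated spectra (which must all
#' belong to one molecule): the peak set is the union of the formulas, and
#' each formula keeps the maximum intensity over the contributing spectra.
#' The result is independent of input order; the consensus of a single
#' spectrum is that spectrum's peak map.
#'
#' @param annotated Tibble of annotated spectra (one molecule), or a list of
#'   annotated peak tibbles.
#' @return Tibble `formula`, `intensity`, sorted by formula string.
#' @export
build_consensus <- function(annotated) {
  peak_tables <- if (is.data.frame(annotated)) {
    if (length(unique(annotated$molecule_id)) > 1) {
      rlang::abort("Consensus requires spectra of a single molecule",
                   class = "massembed_consensus_error")
    }
    annotated$peaks
  } else annotated
  if (!length(peak_tables)) {
    rlang::abort("Cannot build a consensus from zero spectra",
                 class = "massembed_consensus_error")
  }
  all_peaks <- dplyr::bind_rows(peak_tables)
  if (nrow(all_peaks) == 0) {
    return(tibble::tibble(formula = character(0), intensity = numeric(0)))
  }
  all_peaks |>
    dplyr::group_by(.data$formula) |>
    dplyr::summarise(intensity = max(.data$intensity), .groups = "drop") |>
    dplyr::arrange(.data$formula)
}

#' Consensus spectra for every molecule in an annotated table
#'
#' @param annotated Tibble from [annotate_spectra()].
#' @return Tibble `molecule_id`, `peaks` (list-column of consensus peak
#'   tibbles).
#' @export
consensus_spectra <- function(annotated) {
  annotated |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::summarise(peaks = list(build_consensus(.data$peaks)),
                     .groups = "drop")
}

#' Export annotated spectra as a TSV for inspection
#'
#' One row per annotated peak: `spectrum_id`, `formula`, `intensity`,
#' `ppm_error`.
#'
#' @param annotated Tibble from [annotate_spectra()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_tsv <- function(annotated, path) {
  rows <- dplyr::bind_rows(lapply(seq_len(nrow(annotated)), function(i) {
    pk <- annotated$peaks[[i]]
    if (nrow(pk) == 0) return(NULL)
    dplyr::mutate(pk, spectrum_id = annotated$spectrum_id[i], .before = 1)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- binned representation --------------------------------------------------

#' Bin a raw spectrum onto a fixed m/z grid
#'
#' The binned-spectrum variant used in the comparative study: intensities
#' are summed into `bin_width`-wide bins over `[0, max_mz)` and the vector
#' is max-normalized. Peaks at or beyond `max_mz` are dropped with a
#' warning.
#'
#' @param peaks Tibble with `mz` and `intensity` columns.
#' @param bin_width Bin width in Da (default 0.1).
#' @param max_mz Upper m/z bound (default 1000).
#' @return Numeric vector of length `max_mz / bin_width`.
#' @export
bin_spectrum <- function(peaks, bin_width = 0.1, max_mz = 1000) {
  nbins <- as.integer(round(max_mz / bin_width))
  v <- numeric(nbins)
  if (nrow(peaks) == 0) return(v)
  drop <- peaks$mz >= max_mz
  if (any(drop)) {
    rlang::warn(paste0(sum(drop), " peak(s) beyond max_mz dropped"))
  }
  mz <- peaks$mz[!drop]; inten <- peaks$intensity[!drop]
  idx <- floor(mz / bin_width) + 1
  for (i in seq_along(idx)) v[idx[i]] <- v[idx[i]] + inten[i]
  if (max(v) > 0) v <- v / max(v)
  v
}
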