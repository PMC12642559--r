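# On-disk formats: MGF spectra, candidate JSON, results CSV, and the
# single-file JSON model checkpoint.
#
# MGF dialect: BEGIN IONS / END IONS blocks, case-insensitive KEY=VALUE
# headers, PEPMASS first token = precursor m/z (optional second token
# ignored), adduct from an ADDUCT= or PRECURSOR_TYPE= header, CHARGE
# optional. Unknown header keys are preserved in an `extra` list-column.

#' Read an MGF file of tandem mass spectra
#'
#' @param path Path to a Mascot generic format file.
#' @return Tibble with one row per spectrum: `spectrum_id` (from TITLE, or
#'   `spectrum_<i>`), `precursor_mz`, `adduct`, `molecule_id` (from a
#'   MOLECULE_ID header, else `NA`), `smiles` (from a SMILES header, else
#'   `NA`), `peaks` (list-column of tibbles with `mz`, `intensity`), and
#'   `extra` (list-column of remaining header fields).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("MGF file not found: ", path),
                 class = "massembed_io_error")
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  recs <- list(); block <- NULL; iblock <- 0L
  perr <- function(msg) {
    rlang::abort(paste0("MGF parse error in block ", iblock, ": ", msg),
                 class = "massembed_parse_error")
  }
  for (ln in lines) {
    up <- toupper(ln)
    if (up == "BEGIN IONS") {
      if (!is.null(block)) perr("nested BEGIN IONS")
      iblock <- iblock + 1L
      block <- list(headers = list(), mz = numeric(0),
                    intensity = numeric(0))
    } else if (up == "END IONS") {
      if (is.null(block)) perr("END IONS without BEGIN IONS")
      recs[[length(recs) + 1L]] <- block
      block <- NULL
    } else if (is.null(block)) {
      next  # stray content outside blocks is ignored
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      block$headers[[key]] <- val
    } else {
      toks <- strsplit(ln, "[ \t]+")[[1]]
      vals <- suppressWarnings(as.numeric(toks))
      if (length(vals) < 2 || anyNA(vals[1:2])) {
        perr(paste0("non-numeric peak line '", ln, "'"))
      }
      block$mz <- c(block$mz, vals[1])
      block$intensity <- c(block$intensity, vals[2])
    }
  }
  if (!is.null(block)) perr("missing END IONS")
  if (!length(recs)) {
    return(tibble::tibble(
      spectrum_id = character(0), precursor_mz = numeric(0),
      adduct = character(0), molecule_id = character(0),
      smiles = character(0), peaks = list(), extra = list()
    ))
  }
  rows <- lapply(seq_along(recs), function(i) {
    iblock <<- i
    h <- recs[[i]]$headers
    if (is.null(h$PEPMASS)) perr("missing PEPMASS")
    pm <- suppressWarnings(
      as.numeric(strsplit(trimws(h$PEPMASS), "[ \t]+")[[1]][1]))
    if (is.na(pm) || pm <= 0) perr("invalid PEPMASS")
    adduct <- h$ADDUCT %||% h$PRECURSOR_TYPE
    if (is.null(adduct)) perr("missing ADDUCT/PRECURSOR_TYPE header")
    check_adduct(adduct)
    if (!length(recs[[i]]$mz)) perr("block contains no peaks")
    if (any(recs[[i]]$mz <= 0) || any(recs[[i]]$intensity < 0)) {
      perr("peaks must have positive m/z and non-negative intensity")
    }
    known <- c("PEPMASS", "ADDUCT", "PRECURSOR_TYPE", "TITLE",
               "MOLECULE_ID", "SMILES")
    tibble::tibble(
      spectrum_id = h$TITLE %||% paste0("spectrum_", i),
      precursor_mz = pm,
      adduct = adduct,
      molecule_id = h$MOLECULE_ID %||% NA_character_,
      smiles = h$SMILES %||% NA_character_,
      peaks = list(tibble::tibble(mz = recs[[i]]$mz,
                                  intensity = recs[[i]]$intensity)),
      extra = list(h[setdiff(names(h), known)])
    )
  })
  dplyr::bind_rows(rows)
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]: numeric fields are written with full precision
#' so that `read_mgf(write_mgf(x))` reproduces `x` field-by-field.
#'
#' @param spectra Tibble in the layout returned by [read_mgf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  num <- function(x) sprintf("%.17g", x)
  for (i in seq_len(nrow(spectra))) {
    lines <- c(
      "BEGIN IONS",
      paste0("TITLE=", spectra$spectrum_id[i]),
      paste0("PEPMASS=", num(spectra$precursor_mz[i])),
      paste0("ADDUCT=", spectra$adduct[i])
    )
    if (!is.na(spectra$molecule_id[i])) {
      lines <- c(lines, paste0("MOLECULE_ID=", spectra$molecule_id[i]))
    }
    if ("smiles" %in% names(spectra) && !is.na(spectra$smiles[i])) {
      lines <- c(lines, paste0("SMILES=", spectra$smiles[i]))
    }
    if ("extra" %in% names(spectra)) {
      ex <- spectra$extra[[i]]
      for (k in names(ex)) lines <- c(lines, paste0(k, "=", ex[[k]]))
    }
    pk <- spectra$peaks[[i]]
    lines <- c(lines, paste(num(pk$mz), num(pk$intensity)), "END IONS", "")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a candidate JSON file
#'
#' The schema is a flat JSON object mapping each query id to an array of
#' candidate SMILES. Unparseable SMILES are dropped with one warning giving
#' the total count; candidate lists are truncated to `max_candidates`.
#'
#' @param path Path to the JSON file.
#' @param mode Candidate-set provenance tag: `"by_mass"`, `"by_formula"`, or
#'   `"custom"` (metadata only; stored as an attribute).
#' @param max_candidates Cap per query (default 256).
#' @param validate Validate each unique SMILES by parsing it (default TRUE).
#' @return Tibble `query_id`, `candidates` (list-column of character
#'   vectors), with attributes `mode` and `n_dropped`.
#' @export
read_candidates <- function(path, mode = c("custom", "by_mass", "by_formula"),
                            max_candidates = 256L, validate = TRUE) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    rlang::abort(paste0("Candidate file not found: ", path),
                 class = "massembed_io_error")
  }
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(obj) || (length(obj) && is.null(names(obj)))) {
    rlang::abort("Candidate JSON must be an object mapping query ids to arrays",
                 class = "massembed_parse_error")
  }
  lists <- lapply(obj, function(x) as.character(unlist(x)))
  n_dropped <- 0L
  if (validate && length(lists)) {
    uniq <- unique(unlist(lists))
    ok <- is_valid_smiles(uniq)
    bad <- uniq[!ok]
    if (length(bad)) {
      lists <- lapply(lists, function(x) x[!(x %in% bad)])
      n_dropped <- length(bad)
      rlang::warn(paste0(n_dropped, " unparseable candidate SMILES dropped"))
    }
  }
  if (any(lengths(lists) == 0) && length(lists)) {
    rlang::warn(paste0("Queries with no valid candidates (skipped at ",
                       "ranking time): ",
                       paste(names(lists)[lengths(lists) == 0],
                             collapse = ", ")))
  }
  lists <- lapply(lists, function(x) utils::head(x, max_candidates))
  out <- tibble::tibble(query_id = names(obj) %||% character(0),
                        candidates = unname(lists))
  attr(out, "mode") <- mode
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write ranking results to CSV
#'
#' Columns `query_id`, `candidate_smiles`, `score`, `rank`, sorted by
#' `(query_id, rank, candidate_smiles)`; scores are fixed to six decimal
#' places so output bytes are deterministic for a given input.
#'
#' @param results Tibble with those four columns (e.g. from
#'   [rank_candidates()] rows bound together).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  header <- "query_id,candidate_smiles,score,rank"
  if (nrow(results) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  res <- results[order(results$query_id, results$rank,
                       results$candidate_smiles), ]
  lines <- paste(res$query_id, res$candidate_smiles,
                 sprintf("%.6f", res$score), res$rank, sep = ",")
  writeLines(c(header, lines), path)
  invisible(path)
}

# ---- checkpoint -------------------------------------------------------------

.CKPT_FORMAT <- "massembed-checkpoint-1"

# doubles serialized as %.17g strings: exact round-trip, text-only file
.ser_mat <- function(m) list(dim = dim(m), data = sprintf("%.17g", m))
.deser_mat <- function(x) {
  matrix(as.numeric(unlist(x$data)), unlist(x$dim)[1], unlist(x$dim)[2])
}

#' Save a trained model to a single-file JSON checkpoint
#'
#' The checkpoint embeds all encoder parameters (full-precision text
#' serialization), the fitted element scaler, the training configuration,
#' and a format version tag. Saving, loading, and saving again yields
#' byte-identical files.
#'
#' @param model An `mvp_model` from [mvp_train()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mvp_model"))
  obj <- list(
    format = .CKPT_FORMAT,
    config = model$config,
    scaler = as.integer(model$scaler),
    params = lapply(model$params, .ser_mat),
    history = list(epoch = model$history$epoch,
                   loss = sprintf("%.17g", model$history$loss))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path to a checkpoint written by [save_checkpoint()].
#' @return An `mvp_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Checkpoint not found: ", path),
                 class = "massembed_io_error")
  }
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, .CKPT_FORMAT)) {
    rlang::abort(paste0("Checkpoint format '", obj$format %||% "<missing>",
                        "' does not match expected '", .CKPT_FORMAT, "'"),
                 class = "massembed_checkpoint_error")
  }
  cfg <- obj$config
  # un-box scalars, keep vectors
  cfg <- lapply(cfg, function(x) if (is.list(x)) unlist(x) else x)
  scaler <- structure(as.integer(unlist(obj$scaler)), names = ELEMENTS,
                      class = "element_scaler")
  params <- lapply(obj$params, .deser_mat)
  new_mvp_model(params = params, config = cfg, scaler = scaler,
                history = tibble::tibble(
                  epoch = as.integer(unlist(obj$history$epoch)),
                  loss = as.numeric(unlist(obj$history$loss))
                ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
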