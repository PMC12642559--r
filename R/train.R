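# End-to-end training: data preparation, batch construction, Adam, and the
# training loop producing an `mvp_model`.

#' Training configuration
#'
#' Defaults are the full-scale training recipe (Adam, learning rate
#' 7e-05, 1500 epochs, batch size 64, temperature 0.05); desk-scale
#' experiments override them.
#'
#' @param epochs Training epochs (default 1500).
#' @param learning_rate Adam learning rate (default 7e-05).
#' @param batch_size Distinct molecules per batch (default 64).
#' @param tau Contrastive temperature (default 0.05).
#' @param seed Integer seed controlling initialization, batching, spectrum
#'   sampling, and dropout.
#' @param adduct_filter Optional adduct label; training spectra are
#'   restricted to it (e.g. `"[M+H]+"`).
#' @param keep_partial_batch Keep a final batch smaller than `batch_size`
#'   when it still has at least 2 molecules (default TRUE).
#' @param validate_every If > 0 and validation data is supplied, compute
#'   validation loss every this many epochs.
#' @param select_best Keep the parameters of the best validation epoch
#'   instead of the last epoch (default FALSE).
#' @return Named list of class `train_config`.
#' @export
train_config <- function(epochs = 1500L, learning_rate = 7e-5,
                         batch_size = 64L, tau = 0.05, seed = 1L,
                         adduct_filter = NULL, keep_partial_batch = TRUE,
                         validate_every = 0L, select_best = FALSE) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 2, tau > 0)
  if (!is.null(adduct_filter)) check_adduct(adduct_filter)
  structure(list(
    epochs = as.integer(epochs), learning_rate = learning_rate,
    batch_size = as.integer(batch_size), tau = tau, seed = as.integer(seed),
    adduct_filter = adduct_filter, keep_partial_batch = keep_partial_batch,
    validate_every = as.integer(validate_every), select_best = select_best
  ), class = "train_config")
}

#' Prepare raw spectra and molecules for training or inference
#'
#' Annotates each spectrum against its molecule, builds per-split consensus
#' spectra, and (for the training split) fits the element scaler. Pass a
#' previously fitted `scaler` for validation/test data so that no test
#' statistics leak into the peak vectors.
#'
#' @param spectra Raw spectra tibble ([read_mgf()] layout) with
#'   `molecule_id` set.
#' @param molecules Molecule tibble from [parse_molecules()].
#' @param scaler Optional fitted `element_scaler`; fit on these annotations
#'   when `NULL`.
#' @param ppm_tol,max_peaks Annotation parameters (see [annotate_peaks()]).
#' @return List of class `mvp_dataset`: `molecules`, `annotated`,
#'   `consensus`, `scaler`.
#' @export
prepare_dataset <- function(spectra, molecules, scaler = NULL,
                            ppm_tol = 20, max_peaks = 60) {
  annotated <- annotate_spectra(spectra, molecules, ppm_tol = ppm_tol,
                                max_peaks = max_peaks)
  keep <- vapply(annotated$peaks, nrow, integer(1)) > 0
  if (!all(keep)) {
    rlang::warn(paste0(sum(!keep), " spectra had no annotatable peak and ",
                       "were dropped"))
    annotated <- annotated[keep, ]
  }
  if (is.null(scaler)) scaler <- fit_element_scaler(annotated)
  consensus <- consensus_spectra(annotated)
  molecules <- molecules[molecules$molecule_id %in% annotated$molecule_id, ]
  structure(list(molecules = molecules, annotated = annotated,
                 consensus = consensus, scaler = scaler),
            class = "mvp_dataset")
}

#' @export
print.mvp_dataset <- function(x, ...) {
  cat("<mvp_dataset> ", nrow(x$molecules), " molecules, ",
      nrow(x$annotated), " annotated spectra\n", sep = "")
  invisible(x)
}

#' Deterministic aligned view batches for one epoch
#'
#' Each batch holds `batch_size` distinct molecules; for each molecule one
#' constituent spectrum is sampled uniformly (so in-batch negatives are
#' never spectra of the same molecule), together with the molecule's
#' precomputed consensus spectrum. Batch composition is a deterministic
#' function of `(seed, epoch)`.
#'
#' @param dataset An `mvp_dataset`.
#' @param batch_size Molecules per batch.
#' @param seed,epoch Integers controlling the shuffle and spectrum draws.
#' @param keep_partial Keep a trailing batch of size in `[2, batch_size)`.
#' @return List of batches; each batch is a list with `molecule_idx`
#'   (indices into `dataset$molecules`) and `spectrum_idx` (indices into
#'   `dataset$annotated`).
#' @export
make_batches <- function(dataset, batch_size, seed = 1L, epoch = 1L,
                         keep_partial = TRUE) {
  mols <- dataset$molecules$molecule_id
  if (length(mols) < batch_size) {
    rlang::abort(paste0("Dataset has ", length(mols), " molecules but ",
                        "batch_size is ", batch_size,
                        "; use a smaller batch"),
                 class = "massembed_batch_error")
  }
  spec_by_mol <- split(seq_len(nrow(dataset$annotated)),
                       dataset$annotated$molecule_id)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed((as.integer(seed) + 1000003L * (as.integer(epoch) %% 1000L)) %%
             2147483647L)
  ord <- sample.int(length(mols))
  picks <- vapply(mols[ord], function(m) {
    s <- spec_by_mol[[m]]
    if (length(s) == 1) s else s[sample.int(length(s), 1)]
  }, integer(1))
  starts <- seq(1L, length(ord), by = batch_size)
  batches <- lapply(starts, function(s) {
    idx <- s:min(s + batch_size - 1L, length(ord))
    list(molecule_idx = ord[idx], spectrum_idx = unname(picks[idx]))
  })
  sizes <- vapply(batches, function(b) length(b$molecule_idx), integer(1))
  batches[sizes == batch_size | (keep_partial & sizes >= 2L)]
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else assign(".Random.seed", state, envir = globalenv())
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- model object -----------------------------------------------------------

new_mvp_model <- function(params, config, scaler, history) {
  structure(list(params = params, config = config, scaler = scaler,
                 history = history),
            class = "mvp_model")
}

#' @export
print.mvp_model <- function(x, ...) {
  npar <- sum(vapply(x$params, length, integer(1)))
  cat("<mvp_model> views {", paste(x$config$active_views, collapse = ","),
      "}, embed_dim ", x$config$embed_dim, ", ", npar, " parameters\n",
      sep = "")
  if (nrow(x$history)) {
    cat("  trained ", max(x$history$epoch), " epochs; final loss ",
        sprintf("%.4f", x$history$loss[nrow(x$history)]), "\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted model
#'
#' @param x An `mvp_model`.
#' @param ... Unused.
#' @return Tibble with `epoch` and `loss` (per-epoch mean training loss).
#' @method tidy mvp_model
#' @export
tidy.mvp_model <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x An `mvp_model`.
#' @param ... Unused.
#' @return Tibble with parameter count, views, dimensions and final loss.
#' @method glance mvp_model
#' @export
glance.mvp_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(vapply(x$params, length, integer(1))),
    embed_dim = x$config$embed_dim,
    views = paste(x$config$active_views, collapse = "+"),
    spectral = x$config$spectral,
    epochs = if (nrow(x$history)) max(x$history$epoch) else 0L,
    final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)]
      else NA_real_
  )
}

# ---- training loop ----------------------------------------------------------

.batch_views <- function(dataset, batch, config) {
  mols <- dataset$molecules[batch$molecule_idx, ]
  out <- list(graphs = mols$graph)
  if ("fp" %in% config$active_views) {
    out$fp <- fingerprint_matrix(mols, config$fp_nbits, config$fp_radius)
  }
  if (config$spectral == "formula") {
    out$s_sets <- lapply(dataset$annotated$peaks[batch$spectrum_idx],
                         spectrum_to_matrix, scaler = dataset$scaler)
    if ("cs" %in% config$active_views) {
      cidx <- match(mols$molecule_id, dataset$consensus$molecule_id)
      out$cs_sets <- lapply(dataset$consensus$peaks[cidx],
                            spectrum_to_matrix, scaler = dataset$scaler)
    }
  } else {
    raw <- attr(dataset, "binned")
    out$s_bins <- raw$s[batch$spectrum_idx, , drop = FALSE]
    if ("cs" %in% config$active_views) {
      cidx <- match(mols$molecule_id, raw$cs_ids)
      out$cs_bins <- raw$cs[cidx, , drop = FALSE]
    }
  }
  out
}

.forward_views <- function(tape, P, views, config, training) {
  emb <- list()
  emb$mol <- encode_mol_forward(tape, P, views$graphs, config, training)
  if ("fp" %in% config$active_views) {
    emb$fp <- encode_fp_forward(tape, P, views$fp, config, training)
  }
  if (config$spectral == "formula") {
    emb$s <- encode_set_forward(tape, P, views$s_sets, "s", config, training)
    if ("cs" %in% config$active_views) {
      emb$cs <- encode_set_forward(tape, P, views$cs_sets, "cs", config,
                                   training)
    }
  } else {
    emb$s <- encode_binned_forward(tape, P, views$s_bins, "s", config,
                                   training)
    if ("cs" %in% config$active_views) {
      emb$cs <- encode_binned_forward(tape, P, views$cs_bins, "cs", config,
                                      training)
    }
  }
  emb
}

#' Train the multiview contrastive model
#'
#' Optimizes the all-pairs contrastive objective over the configured active
#' views with Adam. Deterministic for a fixed seed: two runs with the same
#' data, configuration and seed produce bit-identical parameters.
#'
#' @param dataset An `mvp_dataset` from [prepare_dataset()].
#' @param config An `encoder_config()`.
#' @param train An `train_config()`.
#' @param validation Optional `mvp_dataset` for validation-loss tracking
#'   (annotated with the training scaler).
#' @param verbose Print per-epoch loss every 10% of training (default
#'   FALSE).
#' @return An `mvp_model` holding the encoder parameters, configuration,
#'   the training scaler, and the per-epoch loss history.
#' @export
mvp_train <- function(dataset, config = encoder_config(),
                      train = train_config(), validation = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(dataset, "mvp_dataset"))
  if (!is.null(train$adduct_filter)) {
    keep <- dataset$annotated$adduct == train$adduct_filter
    dataset$annotated <- dataset$annotated[keep, ]
    dataset$molecules <- dataset$molecules[
      dataset$molecules$molecule_id %in% dataset$annotated$molecule_id, ]
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(train$seed %% 2147483647L)
  params <- init_params(config)
  state <- adam_state(params)
  history <- vector("list", train$epochs)
  best <- NULL
  for (epoch in seq_len(train$epochs)) {
    batches <- make_batches(dataset, train$batch_size, train$seed, epoch,
                            train$keep_partial_batch)
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      views <- .batch_views(dataset, batches[[bi]], config)
      tape <- ad_tape()
      P <- .wrap_params(tape, params)
      emb <- .forward_views(tape, P, views, config, training = TRUE)
      loss <- total_loss_forward(tape, emb, train$tau, config$active_views)
      if (!is.finite(ad_value(loss))) {
        rlang::abort(paste0("Non-finite loss at epoch ", epoch, ", batch ",
                            bi, "; try a smaller learning rate"),
                     class = "massembed_train_error")
      }
      ad_backward(loss)
      grads <- lapply(P, function(nd) nd$grad)
      upd <- adam_step(params, grads, state, train$learning_rate)
      params <- upd$params; state <- upd$state
      losses[bi] <- ad_value(loss)
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       loss = mean(losses))
    if (verbose && (epoch %% max(1L, train$epochs %/% 10L) == 0L)) {
      message(sprintf("epoch %d/%d  loss %.4f", epoch, train$epochs,
                      mean(losses)))
    }
    if (!is.null(validation) && train$validate_every > 0 &&
          epoch %% train$validate_every == 0L) {
      vl <- .validation_loss(validation, params, config, train$tau)
      if (train$select_best && (is.null(best) || vl < best$loss)) {
        best <- list(loss = vl, params = params)
      }
    }
  }
  if (!is.null(best)) params <- best$params
  full_config <- c(config, train[setdiff(names(train), "tau")],
                   list(tau = train$tau))
  new_mvp_model(params = params, config = full_config,
                scaler = dataset$scaler,
                history = dplyr::bind_rows(history))
}

.validation_loss <- function(dataset, params, config, tau) {
  n <- nrow(dataset$molecules)
  batch <- list(molecule_idx = seq_len(n),
                spectrum_idx = match(dataset$molecules$molecule_id,
                                     dataset$annotated$molecule_id))
  views <- .batch_views(dataset, batch, config)
  tape <- ad_tape()
  P <- lapply(params, function(m) ad_const(tape, m))
  emb <- .forward_views(tape, P, views, config, training = FALSE)
  ad_value(total_loss_forward(tape, emb, tau, config$active_views))
}
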