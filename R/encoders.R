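# The four view encoders, all emitting embeddings of the same dimension:
#   mol: 3-layer GCN over the featurized molecular graph, mean pooling,
#        2-layer MLP head
#   fp : 3-layer MLP over the 1024-bit Morgan fingerprint
#   s  : 3-layer peak MLP + 2-layer / 2-head transformer over the peak set,
#        masked mean pooling, linear head (per-sample processing, so peak
#        order and padding cannot affect the output)
#   cs : same architecture as s with an independent parameter collection
# A binned-spectrum variant replaces the two spectral encoders by 3-layer
# MLPs over the fixed binned vector.

#' Encoder configuration
#'
#' @param embed_dim Shared embedding dimension of all views (default 256).
#' @param gcn_hidden Hidden width of the molecular GCN (default 256).
#' @param mlp_hidden Hidden width of the MLPs and the transformer model
#'   dimension (default 256).
#' @param transformer_heads Attention heads in the spectral transformer
#'   (default 2).
#' @param transformer_layers Transformer encoder layers (default 2).
#' @param peak_mlp_layers Layers in the peak MLP (fixed at 3).
#' @param dropout Dropout probability applied to hidden activations during
#'   training (default 0.1).
#' @param active_views Views trained jointly; must contain `"mol"` and
#'   `"s"`.
#' @param spectral Spectral representation: `"formula"` (peak-vector sets,
#'   the default) or `"binned"` (fixed binned vectors).
#' @param fp_nbits,fp_radius Morgan fingerprint parameters (1024 / 5).
#' @param bin_width,max_mz Binning grid of the `"binned"` variant.
#' @return Named list of class `encoder_config`.
#' @export
encoder_config <- function(embed_dim = 256L, gcn_hidden = 256L,
                           mlp_hidden = 256L, transformer_heads = 2L,
                           transformer_layers = 2L, peak_mlp_layers = 3L,
                           dropout = 0.1,
                           active_views = c("mol", "fp", "s", "cs"),
                           spectral = c("formula", "binned"),
                           fp_nbits = 1024L, fp_radius = 5L,
                           bin_width = 0.1, max_mz = 1000) {
  spectral <- match.arg(spectral)
  stopifnot(embed_dim > 0, gcn_hidden > 0, mlp_hidden > 0,
            transformer_heads >= 1, transformer_layers >= 1,
            dropout >= 0, dropout < 1,
            mlp_hidden %% transformer_heads == 0)
  active_views <- match.arg(active_views, c("mol", "fp", "s", "cs"),
                            several.ok = TRUE)
  if (!all(c("mol", "s") %in% active_views)) {
    rlang::abort("active_views must contain at least 'mol' and 's'",
                 class = "massembed_config_error")
  }
  structure(list(
    embed_dim = as.integer(embed_dim), gcn_hidden = as.integer(gcn_hidden),
    mlp_hidden = as.integer(mlp_hidden),
    transformer_heads = as.integer(transformer_heads),
    transformer_layers = as.integer(transformer_layers),
    peak_mlp_layers = 3L, dropout = dropout, active_views = active_views,
    spectral = spectral, fp_nbits = as.integer(fp_nbits),
    fp_radius = as.integer(fp_radius), bin_width = bin_width,
    max_mz = max_mz
  ), class = "encoder_config")
}

# Glorot-uniform initialization of the flat parameter list
.glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

init_params <- function(config) {
  d_node <- graph_feature_dims()$d_node
  h <- config$gcn_hidden; dm <- config$mlp_hidden; d <- config$embed_dim
  P <- list()
  lin <- function(name, nin, nout) {
    P[[paste0(name, "_W")]] <<- .glorot(nin, nout)
    P[[paste0(name, "_b")]] <<- matrix(0, 1, nout)
  }
  # mol: 3 GCN layers + 2-layer head
  lin("mol_gcn1", d_node, h); lin("mol_gcn2", h, h); lin("mol_gcn3", h, h)
  lin("mol_head1", h, h); lin("mol_head2", h, d)
  # fp: 3-layer MLP
  lin("fp_mlp1", config$fp_nbits, dm); lin("fp_mlp2", dm, dm)
  lin("fp_mlp3", dm, d)
  # spectral encoders
  for (v in c("s", "cs")) {
    if (config$spectral == "binned") {
      nbins <- as.integer(round(config$max_mz / config$bin_width))
      lin(paste0(v, "_bin1"), nbins, dm)
      lin(paste0(v, "_bin2"), dm, dm)
      lin(paste0(v, "_bin3"), dm, d)
    } else {
      lin(paste0(v, "_pk1"), 15L, dm); lin(paste0(v, "_pk2"), dm, dm)
      lin(paste0(v, "_pk3"), dm, dm)
      for (l in seq_len(config$transformer_layers)) {
        pre <- paste0(v, "_t", l, "_")
        P[[paste0(pre, "Wq")]] <- .glorot(dm, dm)
        P[[paste0(pre, "Wk")]] <- .glorot(dm, dm)
        P[[paste0(pre, "Wv")]] <- .glorot(dm, dm)
        P[[paste0(pre, "Wo")]] <- .glorot(dm, dm)
        P[[paste0(pre, "ln1_g")]] <- matrix(1, 1, dm)
        P[[paste0(pre, "ln1_b")]] <- matrix(0, 1, dm)
        lin(paste0(pre, "ffn1"), dm, 2L * dm)
        lin(paste0(pre, "ffn2"), 2L * dm, dm)
        P[[paste0(pre, "ln2_g")]] <- matrix(1, 1, dm)
        P[[paste0(pre, "ln2_b")]] <- matrix(0, 1, dm)
      }
      lin(paste0(v, "_out"), dm, d)
    }
  }
  P
}

# parameters owned by each view (for the ablation contract)
view_param_names <- function(params, view) {
  grep(paste0("^", view, "_"), names(params), value = TRUE)
}

.wrap_params <- function(tape, params) {
  lapply(params, function(m) ad_param(tape, m))
}

.maybe_dropout <- function(tape, x, p, training) {
  if (!training || p <= 0) return(x)
  mask <- matrix(stats::rbinom(length(x$val), 1, 1 - p), nrow(x$val),
                 ncol(x$val)) / (1 - p)
  ad_dropout(tape, x, mask)
}

.ad_linear <- function(tape, x, P, name) {
  ad_add_bias(tape, ad_matmul(tape, x, P[[paste0(name, "_W")]]),
              P[[paste0(name, "_b")]])
}

# ---- molecular graph encoder ------------------------------------------------

# block-diagonal symmetric-normalized adjacency (A + I) for a graph batch
.batch_adjacency <- function(graphs) {
  sizes <- vapply(graphs, function(g) length(g$element), integer(1))
  offsets <- c(0L, cumsum(sizes))
  ii <- integer(0); jj <- integer(0)
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]; off <- offsets[k]
    ii <- c(ii, off + seq_len(sizes[k]), off + g$bonds$a, off + g$bonds$b)
    jj <- c(jj, off + seq_len(sizes[k]), off + g$bonds$b, off + g$bonds$a)
  }
  n <- sum(sizes)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  Dinv <- Matrix::Diagonal(x = 1 / sqrt(deg))
  list(A = Dinv %*% A %*% Dinv,
       groups = rep(seq_along(graphs), sizes))
}

encode_mol_forward <- function(tape, P, graphs, config, training = FALSE) {
  if (!length(graphs)) {
    rlang::abort("Empty molecule batch", class = "massembed_encode_error")
  }
  feats <- lapply(graphs, function(g) featurize_graph(g)$node_features)
  X <- ad_const(tape, do.call(rbind, feats))
  adj <- .batch_adjacency(graphs)
  H <- X
  for (l in 1:3) {
    H <- ad_lmult_const(tape, adj$A,
                        .ad_linear(tape, H, P, paste0("mol_gcn", l)))
    H <- ad_relu(tape, H)
    H <- .maybe_dropout(tape, H, config$dropout, training)
  }
  pooled <- ad_segment_mean(tape, H, adj$groups, length(graphs))
  h1 <- ad_relu(tape, .ad_linear(tape, pooled, P, "mol_head1"))
  h1 <- .maybe_dropout(tape, h1, config$dropout, training)
  .ad_linear(tape, h1, P, "mol_head2")
}

# ---- fingerprint encoder ----------------------------------------------------

encode_fp_forward <- function(tape, P, fp_matrix, config, training = FALSE) {
  X <- ad_const(tape, fp_matrix)
  h <- ad_relu(tape, .ad_linear(tape, X, P, "fp_mlp1"))
  h <- .maybe_dropout(tape, h, config$dropout, training)
  h <- ad_relu(tape, .ad_linear(tape, h, P, "fp_mlp2"))
  h <- .maybe_dropout(tape, h, config$dropout, training)
  .ad_linear(tape, h, P, "fp_mlp3")
}

# ---- spectral set encoder ---------------------------------------------------

# `sets` is a list of (n_i x 15) peak-vector matrices; prefix "s" or "cs"
encode_set_forward <- function(tape, P, sets, prefix, config,
                               training = FALSE) {
  if (!length(sets)) {
    rlang::abort("Empty spectrum batch", class = "massembed_encode_error")
  }
  sizes <- vapply(sets, nrow, integer(1))
  if (any(sizes == 0)) {
    rlang::abort("Spectrum with no annotated peaks cannot be encoded",
                 class = "massembed_encode_error")
  }
  X <- ad_const(tape, do.call(rbind, sets))
  h <- ad_relu(tape, .ad_linear(tape, X, P, paste0(prefix, "_pk1")))
  h <- .maybe_dropout(tape, h, config$dropout, training)
  h <- ad_relu(tape, .ad_linear(tape, h, P, paste0(prefix, "_pk2")))
  h <- .maybe_dropout(tape, h, config$dropout, training)
  h <- .ad_linear(tape, h, P, paste0(prefix, "_pk3"))

  dm <- config$mlp_hidden
  nh <- config$transformer_heads
  dh <- dm %/% nh
  offsets <- c(0L, cumsum(sizes))
  pooled <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    x <- ad_rows(tape, h, (offsets[i] + 1L):offsets[i + 1L])
    for (l in seq_len(config$transformer_layers)) {
      pre <- paste0(prefix, "_t", l, "_")
      Q <- ad_matmul(tape, x, P[[paste0(pre, "Wq")]])
      K <- ad_matmul(tape, x, P[[paste0(pre, "Wk")]])
      V <- ad_matmul(tape, x, P[[paste0(pre, "Wv")]])
      heads <- vector("list", nh)
      for (j in seq_len(nh)) {
        idx <- ((j - 1L) * dh + 1L):(j * dh)
        S <- ad_scale(tape,
                      ad_matmul(tape, ad_cols(tape, Q, idx),
                                ad_cols(tape, K, idx), tb = TRUE),
                      1 / sqrt(dh))
        A <- ad_softmax_rows(tape, S)
        heads[[j]] <- ad_matmul(tape, A, ad_cols(tape, V, idx))
      }
      att <- ad_matmul(tape, ad_cbind(tape, heads), P[[paste0(pre, "Wo")]])
      att <- .maybe_dropout(tape, att, config$dropout, training)
      x <- ad_layernorm(tape, ad_add(tape, x, att),
                        P[[paste0(pre, "ln1_g")]], P[[paste0(pre, "ln1_b")]])
      f <- ad_relu(tape, .ad_linear(tape, x, P, paste0(pre, "ffn1")))
      f <- .maybe_dropout(tape, f, config$dropout, training)
      f <- .ad_linear(tape, f, P, paste0(pre, "ffn2"))
      x <- ad_layernorm(tape, ad_add(tape, x, f),
                        P[[paste0(pre, "ln2_g")]], P[[paste0(pre, "ln2_b")]])
    }
    pooled[[i]] <- ad_segment_mean(tape, x, rep(1L, sizes[i]), 1L)
  }
  .ad_linear(tape, ad_rbind(tape, pooled), P, paste0(prefix, "_out"))
}

encode_binned_forward <- function(tape, P, bins, prefix, config,
                                  training = FALSE) {
  nbins <- as.integer(round(config$max_mz / config$bin_width))
  if (ncol(bins) != nbins) {
    rlang::abort(paste0("Binned spectrum width ", ncol(bins),
                        " does not match the configured grid (", nbins, ")"),
                 class = "massembed_encode_error")
  }
  X <- ad_const(tape, bins)
  h <- ad_relu(tape, .ad_linear(tape, X, P, paste0(prefix, "_bin1")))
  h <- .maybe_dropout(tape, h, config$dropout, training)
  h <- ad_relu(tape, .ad_linear(tape, h, P, paste0(prefix, "_bin2")))
  h <- .maybe_dropout(tape, h, config$dropout, training)
  .ad_linear(tape, h, P, paste0(prefix, "_bin3"))
}

# ---- user-facing (evaluation-mode) encoder wrappers -------------------------

.eval_encode <- function(params, fwd) {
  tape <- ad_tape()
  P <- lapply(params, function(m) ad_const(tape, m))
  ad_value(fwd(tape, P))
}

#' Encode molecular graphs into the shared embedding space
#'
#' @param model An `mvp_model` (or any list with `params` and `config`).
#' @param graphs List of `mol_graph` objects, or a molecule tibble from
#'   [parse_molecules()].
#' @return Matrix (n x embed_dim) of `mol`-view embeddings.
#' @export
encode_mol <- function(model, graphs) {
  if (is.data.frame(graphs)) graphs <- graphs$graph
  .eval_encode(model$params, function(tape, P) {
    encode_mol_forward(tape, P, graphs, model$config)
  })
}

#' Encode Morgan fingerprints into the shared embedding space
#'
#' @param model An `mvp_model`.
#' @param fp Fingerprint matrix (n x nbits), or a molecule tibble.
#' @return Matrix (n x embed_dim) of `fp`-view embeddings.
#' @export
encode_fp <- function(model, fp) {
  if (is.data.frame(fp)) {
    fp <- fingerprint_matrix(fp, model$config$fp_nbits,
                             model$config$fp_radius)
  }
  .eval_encode(model$params, function(tape, P) {
    encode_fp_forward(tape, P, fp, model$config)
  })
}

#' Encode spectra (peak-vector sets) into the shared embedding space
#'
#' @param model An `mvp_model`.
#' @param sets List of peak-vector matrices (n_peaks x 15), or an annotated
#'   spectra tibble (the model's scaler is applied).
#' @param view `"s"` for the spectrum encoder or `"cs"` for the consensus
#'   encoder (independent weights).
#' @return Matrix (n x embed_dim) of spectral embeddings.
#' @export
encode_spectrum <- function(model, sets, view = c("s", "cs")) {
  view <- match.arg(view)
  if (is.data.frame(sets)) {
    sets <- lapply(sets$peaks, spectrum_to_matrix, scaler = model$scaler)
  }
  .eval_encode(model$params, function(tape, P) {
    encode_set_forward(tape, P, sets, view, model$config)
  })
}

#' @rdname encode_spectrum
#' @export
encode_consensus <- function(model, sets) encode_spectrum(model, sets, "cs")

#' Encode binned spectra (binned-variant models)
#'
#' @param model An `mvp_model` trained with `spectral = "binned"`.
#' @param bins Matrix (n x nbins) of binned spectra.
#' @inheritParams encode_spectrum
#' @return Matrix (n x embed_dim).
#' @export
encode_binned <- function(model, bins, view = c("s", "cs")) {
  view <- match.arg(view)
  if (model$config$spectral != "binned") {
    rlang::abort("Model was not trained with the binned spectral variant",
                 class = "massembed_encode_error")
  }
  .eval_encode(model$params, function(tape, P) {
    encode_binned_forward(tape, P, bins, view, model$config)
  })
}
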