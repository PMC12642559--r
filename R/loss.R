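# The multiview contrastive objective.
#
# For embeddings of two views aligned by datum index, the directed loss is
# the InfoNCE cross-entropy with in-batch negatives:
#   L(Vp -> Vq) = mean_i -log[ h(vp_i, vq_i) / sum_j h(vp_i, vq_j) ]
# with discriminator h(u, v) = exp(cos(u, v) / tau). Each unordered view
# pair contributes both directions, and the total loss sums over all
# C(|views|, 2) pairs (six pairs, twelve directed terms with four views).

#' Similarity discriminator
#'
#' `h(u, v) = exp(cos(u, v) / tau)`; invariant to positive rescaling of
#' either argument.
#'
#' @param vp,vq Numeric vectors (nonzero).
#' @param tau Temperature (> 0, default 0.05).
#' @return Positive scalar.
#' @export
discriminator_h <- function(vp, vq, tau = 0.05) {
  stopifnot(tau > 0)
  np <- sqrt(sum(vp^2)); nq <- sqrt(sum(vq^2))
  if (np == 0 || nq == 0) {
    rlang::abort("discriminator_h requires nonzero-norm vectors",
                 class = "massembed_loss_error")
  }
  exp(sum(vp * vq) / (np * nq) / tau)
}

.cosine_matrix <- function(A, B) {
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0)) {
    rlang::abort("Zero-norm embedding in batch",
                 class = "massembed_loss_error")
  }
  (A / na) %*% t(B / nb)
}

#' Directed contrastive loss between two aligned embedding batches
#'
#' Anchors are the rows of `anchors`; for anchor `i` the positive is row `i`
#' of `contrasts` and the negatives are its remaining `B - 1` rows.
#'
#' @param anchors,contrasts Matrices (B x d), row `i` of both belonging to
#'   the same datum; `B >= 2`.
#' @param tau Temperature (default 0.05).
#' @return Non-negative scalar.
#' @export
directed_pair_loss <- function(anchors, contrasts, tau = 0.05) {
  anchors <- as.matrix(anchors); contrasts <- as.matrix(contrasts)
  B <- nrow(anchors)
  if (B < 2) {
    rlang::abort("Contrastive loss needs a batch of at least 2 (no negatives)",
                 class = "massembed_loss_error")
  }
  stopifnot(nrow(contrasts) == B, ncol(contrasts) == ncol(anchors), tau > 0)
  Z <- .cosine_matrix(anchors, contrasts) / tau
  m <- apply(Z, 1, max)
  lse <- m + log(rowSums(exp(Z - m)))
  mean(lse - diag(Z))
}

#' Symmetric pairwise contrastive loss
#'
#' `pair_loss(Vp, Vq) = directed_pair_loss(Vp, Vq) +
#' directed_pair_loss(Vq, Vp)`.
#'
#' @inheritParams directed_pair_loss
#' @param Vp,Vq Aligned embedding batches (B x d).
#' @return Non-negative scalar.
#' @export
pair_loss <- function(Vp, Vq, tau = 0.05) {
  directed_pair_loss(Vp, Vq, tau) + directed_pair_loss(Vq, Vp, tau)
}

#' Total multiview contrastive loss
#'
#' Sums [pair_loss()] over every unordered pair of active views (six pairs
#' when all four views are active).
#'
#' @param embeddings Named list of aligned embedding batches; names in
#'   `{"mol", "fp", "s", "cs"}`.
#' @param tau Temperature (default 0.05).
#' @param active_views Views to include (default: all present in
#'   `embeddings`); at least two.
#' @return Non-negative scalar.
#' @export
total_loss <- function(embeddings, tau = 0.05,
                       active_views = names(embeddings)) {
  missing <- setdiff(active_views, names(embeddings))
  if (length(missing)) {
    rlang::abort(paste0("Missing active view embedding(s): ",
                        paste(missing, collapse = ", ")),
                 class = "massembed_loss_error")
  }
  if (length(active_views) < 2) {
    rlang::abort("total_loss needs at least two active views",
                 class = "massembed_loss_error")
  }
  total <- 0
  pairs <- utils::combn(active_views, 2)
  for (k in seq_len(ncol(pairs))) {
    total <- total + pair_loss(embeddings[[pairs[1, k]]],
                               embeddings[[pairs[2, k]]], tau)
  }
  total
}

# autodiff version used inside the training loop: same pair structure,
# returning a scalar node
total_loss_forward <- function(tape, emb_nodes, tau, active_views) {
  pairs <- utils::combn(active_views, 2)
  normed <- lapply(emb_nodes[active_views],
                   function(e) ad_l2normalize_rows(tape, e))
  loss <- NULL
  for (k in seq_len(ncol(pairs))) {
    a <- normed[[pairs[1, k]]]; b <- normed[[pairs[2, k]]]
    S_ab <- ad_matmul(tape, a, b, tb = TRUE)
    S_ba <- ad_matmul(tape, b, a, tb = TRUE)
    term <- ad_add(tape, ad_info_nce(tape, S_ab, tau),
                   ad_info_nce(tape, S_ba, tau))
    loss <- if (is.null(loss)) term else ad_add(tape, loss, term)
  }
  loss
}
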