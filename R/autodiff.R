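# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape records operation nodes in creation order; backward() walks the
# tape in reverse, accumulating gradients. Values are plain base-R matrices
# (a scalar is a 1x1 matrix). This is deliberately small: just the ops the
# four encoders and the contrastive loss need. Gradient correctness is
# checked against central finite differences in the test suite.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

.ad_push <- function(tape, node) {
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    length(tape$nodes) <- 2L * length(tape$nodes)
  }
  tape$nodes[[tape$n]] <- node
  node
}

.ad_new <- function(tape, val, parents = list(), bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$bw <- bw
  nd$leaf <- is.null(bw) && !length(parents)
  nd$requires <- nd$leaf && isTRUE(attr(val, "param")) ||
    any(vapply(parents, function(p) p$requires, logical(1)))
  .ad_push(tape, nd)
}

ad_const <- function(tape, x) .ad_new(tape, as.matrix(x))

ad_param <- function(tape, x) {
  x <- as.matrix(x)
  attr(x, "param") <- TRUE
  nd <- .ad_new(tape, x)
  nd$requires <- TRUE
  nd
}

.ad_accum <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' @keywords internal
ad_backward <- function(node) {
  stopifnot(length(node$val) == 1L)
  node$grad <- matrix(1, 1, 1)
  tape <- node$tape
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

# every op fetches the tape from its first node argument
.op <- function(tape, val, parents, bw) {
  nd <- .ad_new(tape, val, parents, bw)
  nd$tape <- tape
  nd
}

ad_matmul <- function(tape, a, b, ta = FALSE, tb = FALSE) {
  A <- if (ta) t(a$val) else a$val
  B <- if (tb) t(b$val) else b$val
  .op(tape, A %*% B, list(a, b), function(g) {
    if (a$requires) {
      ga <- g %*% (if (tb) b$val else t(b$val))
      .ad_accum(a, if (ta) t(ga) else ga)
    }
    if (b$requires) {
      gb <- (if (ta) a$val else t(a$val)) %*% g
      .ad_accum(b, if (tb) t(gb) else gb)
    }
  })
}

# x (n x d) + bias (1 x d) broadcast over rows
ad_add_bias <- function(tape, x, b) {
  .op(tape, sweep(x$val, 2, as.numeric(b$val), "+"), list(x, b), function(g) {
    .ad_accum(x, g)
    .ad_accum(b, matrix(colSums(g), 1))
  })
}

ad_add <- function(tape, a, b) {
  .op(tape, a$val + b$val, list(a, b), function(g) {
    .ad_accum(a, g); .ad_accum(b, g)
  })
}

ad_scale <- function(tape, a, k) {
  .op(tape, a$val * k, list(a), function(g) .ad_accum(a, g * k))
}

ad_relu <- function(tape, a) {
  mask <- a$val > 0
  .op(tape, a$val * mask, list(a), function(g) .ad_accum(a, g * mask))
}

# inverted dropout; `mask` drawn by the caller so RNG use is explicit
ad_dropout <- function(tape, a, mask) {
  .op(tape, a$val * mask, list(a), function(g) .ad_accum(a, g * mask))
}

ad_softmax_rows <- function(tape, a) {
  m <- a$val - apply(a$val, 1, max)
  e <- exp(m)
  y <- e / rowSums(e)
  .op(tape, y, list(a), function(g) {
    .ad_accum(a, (g - rowSums(g * y)) * y)
  })
}

# row-wise layer normalization with learned gain/bias (1 x d each)
ad_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- ncol(x$val)
  mu <- rowMeans(x$val)
  xc <- x$val - mu
  va <- rowMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  gam <- as.numeric(gamma$val)
  y <- sweep(xhat, 2, gam, "*")
  y <- sweep(y, 2, as.numeric(beta$val), "+")
  .op(tape, y, list(x, gamma, beta), function(g) {
    if (gamma$requires) .ad_accum(gamma, matrix(colSums(g * xhat), 1))
    if (beta$requires) .ad_accum(beta, matrix(colSums(g), 1))
    if (x$requires) {
      gh <- sweep(g, 2, gam, "*")
      gx <- istd * (gh - rowMeans(gh) - xhat * rowMeans(gh * xhat))
      .ad_accum(x, gx)
    }
  })
}

ad_l2normalize_rows <- function(tape, x, eps = 1e-12) {
  nrm <- sqrt(rowSums(x$val^2)) + eps
  y <- x$val / nrm
  .op(tape, y, list(x), function(g) {
    .ad_accum(x, (g - y * rowSums(g * y)) / nrm)
  })
}

# mean over row groups: groups is an integer vector (1..ngroups) per row
ad_segment_mean <- function(tape, x, groups, ngroups) {
  cnt <- tabulate(groups, ngroups)
  M <- rowsum(x$val, groups, reorder = TRUE) / cnt
  .op(tape, M, list(x), function(g) {
    .ad_accum(x, g[groups, , drop = FALSE] / cnt[groups])
  })
}

ad_rows <- function(tape, x, idx) {
  .op(tape, x$val[idx, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(x$val), ncol(x$val))
    for (k in seq_along(idx)) gx[idx[k], ] <- gx[idx[k], ] + g[k, ]
    .ad_accum(x, gx)
  })
}

ad_cols <- function(tape, x, idx) {
  .op(tape, x$val[, idx, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(x$val), ncol(x$val))
    gx[, idx] <- g
    .ad_accum(x, gx)
  })
}

ad_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(n) ncol(n$val), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  .op(tape, do.call(cbind, lapply(nodes, function(n) n$val)), nodes,
      function(g) {
        for (k in seq_along(nodes)) {
          .ad_accum(nodes[[k]], g[, starts[k]:ends[k], drop = FALSE])
        }
      })
}

ad_rbind <- function(tape, nodes) {
  heights <- vapply(nodes, function(n) nrow(n$val), integer(1))
  ends <- cumsum(heights)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  .op(tape, do.call(rbind, lapply(nodes, function(n) n$val)), nodes,
      function(g) {
        for (k in seq_along(nodes)) {
          .ad_accum(nodes[[k]], g[starts[k]:ends[k], , drop = FALSE])
        }
      })
}

# multiply by a fixed (sparse or dense) matrix on the left: A %*% x
ad_lmult_const <- function(tape, A, x) {
  .op(tape, as.matrix(A %*% x$val), list(x), function(g) {
    .ad_accum(x, as.matrix(Matrix::crossprod(A, g)))
  })
}

# InfoNCE cross-entropy over a similarity matrix S (anchors in rows):
# mean_i [ logsumexp_j(S_ij / tau) - S_ii / tau ]
ad_info_nce <- function(tape, S, tau) {
  Z <- S$val / tau
  m <- apply(Z, 1, max)
  lse <- m + log(rowSums(exp(Z - m)))
  val <- mean(lse - diag(Z))
  B <- nrow(Z)
  .op(tape, matrix(val, 1, 1), list(S), function(g) {
    P <- exp(Z - lse)  # row softmax
    G <- (P - diag(B)) / (tau * B)
    .ad_accum(S, as.numeric(g) * G)
  })
}

ad_mean <- function(tape, x) {
  n <- length(x$val)
  .op(tape, matrix(mean(x$val), 1, 1), list(x), function(g) {
    .ad_accum(x, matrix(as.numeric(g) / n, nrow(x$val), ncol(x$val)))
  })
}

ad_value <- function(node) node$val
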