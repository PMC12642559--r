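# Gradient correctness of the autodiff tape against central finite
# differences, through every composition the encoders use.

fd_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

grad_of <- function(build, W0) {
  tape <- massembed:::ad_tape()
  W <- massembed:::ad_param(tape, W0)
  loss <- build(tape, W)
  massembed:::ad_backward(loss)
  W$grad
}

test_that("gradients of MLP, layernorm, softmax-attention match finite differences", {
  set.seed(101)
  X0 <- matrix(rnorm(12), 4, 3)
  W0 <- matrix(rnorm(9), 3, 3)

  cases <- list(
    mlp = function(tape, W, Xc) {
      h <- massembed:::ad_relu(tape, massembed:::ad_matmul(tape, Xc, W))
      massembed:::ad_mean(tape, massembed:::ad_matmul(tape, h, W, tb = TRUE))
    },
    layernorm = function(tape, W, Xc) {
      g <- massembed:::ad_const(tape, matrix(1.5, 1, 3))
      b <- massembed:::ad_const(tape, matrix(-0.2, 1, 3))
      h <- massembed:::ad_layernorm(tape, massembed:::ad_matmul(tape, Xc, W),
                                    g, b)
      massembed:::ad_mean(tape, massembed:::ad_relu(tape, h))
    },
    attention = function(tape, W, Xc) {
      Q <- massembed:::ad_matmul(tape, Xc, W)
      S <- massembed:::ad_scale(tape,
                                massembed:::ad_matmul(tape, Q, Q, tb = TRUE),
                                1 / sqrt(3))
      A <- massembed:::ad_softmax_rows(tape, S)
      massembed:::ad_mean(tape, massembed:::ad_matmul(tape, A, Q))
    },
    l2norm_nce = function(tape, W, Xc) {
      Z <- massembed:::ad_l2normalize_rows(
        tape, massembed:::ad_matmul(tape, Xc, W))
      S <- massembed:::ad_matmul(tape, Z, Z, tb = TRUE)
      massembed:::ad_info_nce(tape, S, 0.1)
    },
    segment_bias = function(tape, W, Xc) {
      b <- massembed:::ad_const(tape, matrix(0.3, 1, 3))
      h <- massembed:::ad_add_bias(tape,
                                   massembed:::ad_matmul(tape, Xc, W), b)
      p <- massembed:::ad_segment_mean(tape, h, c(1L, 1L, 2L, 2L), 2L)
      massembed:::ad_mean(tape, p)
    }
  )
  for (nm in names(cases)) {
    build <- cases[[nm]]
    g_ad <- grad_of(function(tape, W) {
      build(tape, W, massembed:::ad_const(tape, X0))
    }, W0)
    g_fd <- fd_grad(function(w) {
      tape <- massembed:::ad_tape()
      W <- massembed:::ad_const(tape, w)
      massembed:::ad_value(build(tape, W, massembed:::ad_const(tape, X0)))
    }, W0)
    expect_equal(g_ad, g_fd, tolerance = 1e-5, label = nm)
  }
})

test_that("full training-loss gradients match finite differences", {
  prep <- fixture_dataset()$prep
  cfg <- encoder_config(embed_dim = 8, gcn_hidden = 8, mlp_hidden = 8,
                        dropout = 0)
  set.seed(3); params <- massembed:::init_params(cfg)
  batch <- list(molecule_idx = 1:4,
                spectrum_idx = match(prep$molecules$molecule_id[1:4],
                                     prep$annotated$molecule_id))
  views <- massembed:::.batch_views(prep, batch, cfg)
  loss_at <- function(p) {
    tape <- massembed:::ad_tape()
    P <- lapply(p, function(m) massembed:::ad_const(tape, m))
    emb <- massembed:::.forward_views(tape, P, views, cfg, training = FALSE)
    massembed:::ad_value(massembed:::total_loss_forward(
      tape, emb, 0.05, cfg$active_views))
  }
  tape <- massembed:::ad_tape()
  P <- massembed:::.wrap_params(tape, params)
  emb <- massembed:::.forward_views(tape, P, views, cfg, training = FALSE)
  loss <- massembed:::total_loss_forward(tape, emb, 0.05, cfg$active_views)
  massembed:::ad_backward(loss)

  # spot-check a few parameters from each encoder family
  for (nm in c("mol_gcn2_W", "mol_head2_b", "fp_mlp1_W", "s_pk1_W",
               "s_t1_Wq", "s_t2_ln2_g", "cs_out_W")) {
    g_ad <- P[[nm]]$grad
    idx <- seq_len(min(6, length(params[[nm]])))
    eps <- 1e-5
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      g_fd <- as.numeric(loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(g_ad[i], g_fd, tolerance = 1e-4, label = paste(nm, i))
    }
  }
})
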