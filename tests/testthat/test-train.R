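test_that("batches are deterministic, molecule-distinct, and size-checked", {
  prep <- fixture_dataset()$prep
  b1 <- make_batches(prep, 8, seed = 2, epoch = 5)
  b2 <- make_batches(prep, 8, seed = 2, epoch = 5)
  expect_identical(b1, b2)
  b3 <- make_batches(prep, 8, seed = 2, epoch = 6)
  expect_false(identical(b1, b3))
  for (b in b1) {
    expect_equal(anyDuplicated(b$molecule_idx), 0L)
    expect_equal(prep$annotated$molecule_id[b$spectrum_idx],
                 prep$molecules$molecule_id[b$molecule_idx])
  }
  # single batch when batch_size equals the molecule count
  ball <- make_batches(prep, nrow(prep$molecules), seed = 1, epoch = 1)
  expect_length(ball, 1L)
  expect_error(make_batches(prep, 500, seed = 1, epoch = 1),
               class = "massembed_batch_error")
})

test_that("spectrum sampling within batches is uniform across epochs", {
  prep <- fixture_dataset()$prep
  mol <- prep$molecules$molecule_id[1]
  sidx <- which(prep$annotated$molecule_id == mol)
  expect_length(sidx, 3L)
  draws <- integer(0)
  for (epoch in 1:1000) {
    b <- make_batches(prep, nrow(prep$molecules), seed = 77, epoch = epoch)
    pick <- b[[1]]$spectrum_idx[match(1L, b[[1]]$molecule_idx)]
    draws <- c(draws, pick)
  }
  tab <- table(factor(draws, levels = sidx))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("training reduces the loss and is bit-reproducible for a fixed seed", {
  prep <- fixture_dataset()$prep
  cfg <- encoder_config(embed_dim = 16, gcn_hidden = 16, mlp_hidden = 16)
  tc <- train_config(epochs = 6, learning_rate = 1e-3, batch_size = 8,
                     seed = 9)
  m1 <- mvp_train(prep, cfg, tc)
  expect_lt(m1$history$loss[6], m1$history$loss[1])
  m2 <- mvp_train(prep, cfg, tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  # a different seed gives a different trajectory
  m3 <- mvp_train(prep, cfg, train_config(epochs = 6, learning_rate = 1e-3,
                                          batch_size = 8, seed = 10))
  expect_false(identical(m1$params, m3$params))
})

test_that("one optimizer step on a tiny fixed batch strictly decreases the loss", {
  prep <- fixture_dataset()$prep
  cfg <- encoder_config(embed_dim = 8, gcn_hidden = 8, mlp_hidden = 8,
                        dropout = 0)
  set.seed(12)
  params <- massembed:::init_params(cfg)
  batch <- list(molecule_idx = 1:6,
                spectrum_idx = match(prep$molecules$molecule_id[1:6],
                                     prep$annotated$molecule_id))
  views <- massembed:::.batch_views(prep, batch, cfg)
  loss_of <- function(p) {
    tape <- massembed:::ad_tape()
    P <- lapply(p, function(m) massembed:::ad_const(tape, m))
    emb <- massembed:::.forward_views(tape, P, views, cfg, FALSE)
    massembed:::ad_value(massembed:::total_loss_forward(tape, emb, 0.05,
                                                        cfg$active_views))
  }
  tape <- massembed:::ad_tape()
  P <- massembed:::.wrap_params(tape, params)
  emb <- massembed:::.forward_views(tape, P, views, cfg, FALSE)
  loss <- massembed:::total_loss_forward(tape, emb, 0.05, cfg$active_views)
  massembed:::ad_backward(loss)
  l0 <- as.numeric(massembed:::ad_value(loss))
  # plain gradient step with a small learning rate
  stepped <- params
  for (nm in names(params)) {
    g <- P[[nm]]$grad
    if (!is.null(g)) stepped[[nm]] <- stepped[[nm]] - 1e-4 * g
  }
  expect_lt(loss_of(stepped), l0)
})

test_that("ablation training never touches the parameters of inactive views", {
  prep <- fixture_dataset()$prep
  cfg <- encoder_config(embed_dim = 8, gcn_hidden = 8, mlp_hidden = 8,
                        active_views = c("mol", "s"))
  tc <- train_config(epochs = 3, learning_rate = 1e-3, batch_size = 8,
                     seed = 21)
  m <- mvp_train(prep, cfg, tc)
  set.seed(tc$seed %% 2147483647L)
  init <- massembed:::init_params(cfg)
  for (nm in names(init)) {
    if (grepl("^(fp|cs)_", nm)) {
      expect_identical(m$params[[nm]], init[[nm]])
    }
  }
  # and at least some active parameters moved
  expect_false(identical(m$params[["mol_gcn1_W"]], init[["mol_gcn1_W"]]))
  expect_false(identical(m$params[["s_pk1_W"]], init[["s_pk1_W"]]))
})

test_that("validation/test annotation must reuse the training scaler (no leakage)", {
  ds <- fixture_dataset()
  train_prep <- ds$prep
  # pretend the last molecule is test data
  test_mol <- ds$raw$molecules[nrow(ds$raw$molecules), ]
  test_spec <- ds$raw$spectra[
    ds$raw$spectra$molecule_id == test_mol$molecule_id, ]
  test_prep <- suppressWarnings(
    prepare_dataset(test_spec, test_mol, scaler = train_prep$scaler))
  expect_identical(test_prep$scaler, train_prep$scaler)
  refit <- suppressWarnings(prepare_dataset(test_spec, test_mol))
  # refitting on test data would change the vectors; the pipeline must not
  expect_false(identical(as.integer(refit$scaler),
                         as.integer(train_prep$scaler)))
  pk <- test_prep$annotated$peaks[[1]]
  expect_false(isTRUE(all.equal(
    spectrum_to_matrix(pk, train_prep$scaler),
    spectrum_to_matrix(pk, refit$scaler))))
})

test_that("tidy and glance summarize a fitted model", {
  m <- fixture_model()
  td <- tidy(m)
  expect_named(td, c("epoch", "loss"))
  expect_equal(nrow(td), 4L)
  gl <- glance(m)
  expect_equal(gl$embed_dim, 16L)
  expect_equal(gl$views, "mol+fp+s+cs")
  expect_true(is.finite(gl$final_loss))
})
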