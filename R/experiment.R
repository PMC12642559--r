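# A self-contained retrieval experiment on synthetic data: generate,
# annotate, train, embed, rank, and score. This is the package's end-to-end
# check that the loss, encoders and ranking wire together, and the engine
# behind scripts/acceptance.R.

#' Run a synthetic-data retrieval experiment end to end
#'
#' Generates a synthetic library with spectra, annotates and trains the
#' multiview model, then performs held-in retrieval: every library molecule
#' becomes a query with a candidate set of the target plus seeded decoys,
#' ranked under the `mol-s` view (each constituent spectrum) and the
#' `mol-cs` view (the molecule's consensus spectrum).
#'
#' @param synth A [synth_config()]; its `seed` drives data generation and
#'   decoy sampling.
#' @param encoder An [encoder_config()].
#' @param train A [train_config()].
#' @param ks rank@k cutoffs (default 1, 5, 20 capped at the candidate-set
#'   size).
#' @param mces Also compute MCES@1 for both ranking views (default TRUE).
#' @param verbose Passed to [mvp_train()].
#' @return List of class `retrieval_experiment`: `model`, `metrics` (tibble
#'   with `ranking_view`, `k`, `rank_at`, `n_queries`), `mces_at_1` (named
#'   vector or NULL), and the per-query ranking `tables`.
#' @export
run_retrieval_experiment <- function(synth = synth_config(),
                                     encoder = encoder_config(),
                                     train = train_config(),
                                     ks = c(1L, 5L, 20L),
                                     mces = TRUE, verbose = FALSE) {
  ds <- generate_dataset(synth)
  prep <- suppressWarnings(prepare_dataset(ds$spectra, ds$molecules))
  model <- suppressWarnings(mvp_train(prep, encoder, train,
                                      verbose = verbose))

  E_mol <- encode_mol(model, prep$molecules)
  rownames(E_mol) <- prep$molecules$smiles
  E_s <- encode_spectrum(model, prep$annotated, "s")
  E_cs <- encode_spectrum(model, prep$consensus, "cs")

  n <- nrow(prep$molecules)
  n_cand <- min(synth$candidate_set_size, n)
  ks <- ks[ks <= n_cand]
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed((synth$seed + 65537L) %% 2147483647L)

  tab_s <- list(); tgt_s <- character(0)
  tab_cs <- list(); tgt_cs <- character(0)
  for (i in seq_len(n)) {
    decoys <- sample(setdiff(seq_len(n), i), n_cand - 1L)
    cand <- E_mol[c(i, decoys), , drop = FALSE]
    target <- prep$molecules$smiles[i]
    sidx <- which(prep$annotated$molecule_id ==
                    prep$molecules$molecule_id[i])
    for (s in sidx) {
      tab_s[[length(tab_s) + 1L]] <-
        rank_candidates(E_s[s, ], cand, "mol-s",
                        prep$annotated$spectrum_id[s])
      tgt_s <- c(tgt_s, target)
    }
    ci <- match(prep$molecules$molecule_id[i], prep$consensus$molecule_id)
    tab_cs[[length(tab_cs) + 1L]] <-
      rank_candidates(E_cs[ci, ], cand, "mol-cs",
                      prep$consensus$molecule_id[ci])
    tgt_cs <- c(tgt_cs, target)
  }
  ra_s <- rank_at_k(tab_s, tgt_s, ks)
  ra_cs <- rank_at_k(tab_cs, tgt_cs, ks)
  metrics <- dplyr::bind_rows(
    dplyr::mutate(ra_s, ranking_view = "mol-s", .before = 1),
    dplyr::mutate(ra_cs, ranking_view = "mol-cs", .before = 1)
  )
  mces_at_1 <- NULL
  if (mces) {
    top_d <- function(tabs, tgts) {
      mean(mapply(function(tb, tg) {
        top <- tb$candidate_smiles[1]
        mces_distance(prep$molecules$graph[[match(tg,
                                                  prep$molecules$smiles)]],
                      prep$molecules$graph[[match(top,
                                                  prep$molecules$smiles)]],
                      size_cap = 30L)
      }, tabs, tgts))
    }
    mces_at_1 <- c(`mol-s` = top_d(tab_s, tgt_s),
                   `mol-cs` = top_d(tab_cs, tgt_cs))
  }
  structure(list(model = model, metrics = metrics, mces_at_1 = mces_at_1,
                 tables = list(`mol-s` = tab_s, `mol-cs` = tab_cs),
                 targets = list(`mol-s` = tgt_s, `mol-cs` = tgt_cs)),
            class = "retrieval_experiment")
}

#' @export
print.retrieval_experiment <- function(x, ...) {
  cat("<retrieval_experiment>\n")
  print(x$metrics)
  if (!is.null(x$mces_at_1)) {
    cat("MCES@1:", paste(names(x$mces_at_1),
                         sprintf("%.3f", x$mces_at_1), collapse = "  "),
        "\n")
  }
  invisible(x)
}
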