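# Shared fixtures, built in code. Expensive objects (a small trained model,
# a small synthetic dataset) are memoized for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 12 small molecules (<= 8 heavy atoms) for MCES and chemistry tests
fixture_smiles <- c(
  "C", "CC", "CCO", "CCC", "CC=O", "CC(=O)O", "CCN", "C1CCCC1",
  "c1ccccc1", "C1CCOC1", "CC(C)O", "CCS"
)

fixture_molecules <- function() {
  memo("molecules", function() {
    parse_molecules(fixture_smiles, paste0("F", seq_along(fixture_smiles)))
  })
}

# a small annotated synthetic dataset (12 molecules x 3 spectra)
fixture_dataset <- function() {
  memo("dataset", function() {
    ds <- generate_dataset(synth_config(n_molecules = 12, seed = 3))
    prep <- suppressWarnings(prepare_dataset(ds$spectra, ds$molecules))
    list(raw = ds, prep = prep)
  })
}

# a quickly trained small model over all four views
fixture_model <- function() {
  memo("model", function() {
    prep <- fixture_dataset()$prep
    suppressWarnings(mvp_train(
      prep,
      encoder_config(embed_dim = 16, gcn_hidden = 16, mlp_hidden = 16),
      train_config(epochs = 4, learning_rate = 1e-3, batch_size = 8,
                   seed = 42)
    ))
  })
}

# the full learnability experiment (frozen seeds/scale), memoized because
# it trains for 200 epochs
acceptance_experiment <- function() {
  memo("experiment", function() {
    exp <- run_retrieval_experiment(
      synth = synth_config(n_molecules = 50, seed = 101),
      encoder = encoder_config(embed_dim = 64, gcn_hidden = 64,
                               mlp_hidden = 64),
      train = train_config(epochs = 200, learning_rate = 1e-3,
                           batch_size = 32, seed = 101),
      mces = FALSE
    )
    list(
      rank1_mol_s = exp$metrics$rank_at[exp$metrics$ranking_view == "mol-s" &
                                          exp$metrics$k == 1],
      rank1_mol_cs = exp$metrics$rank_at[exp$metrics$ranking_view == "mol-cs" &
                                           exp$metrics$k == 1]
    )
  })
}

# scalar brute-force InfoNCE oracle: explicit loops, no matrix shortcuts
oracle_directed_loss <- function(anchors, contrasts, tau) {
  B <- nrow(anchors)
  h <- function(u, v) {
    exp(sum(u * v) / sqrt(sum(u^2)) / sqrt(sum(v^2)) / tau)
  }
  total <- 0
  for (i in seq_len(B)) {
    denom <- 0
    for (j in seq_len(B)) denom <- denom + h(anchors[i, ], contrasts[j, ])
    total <- total - log(h(anchors[i, ], contrasts[i, ]) / denom)
  }
  total / B
}

# independent MCES oracle: enumerate edge subsets of the smaller graph by
# decreasing size and test labeled (non-induced) subgraph isomorphism with
# igraph VF2
oracle_mces_common <- function(ga, gb) {
  requireNamespace("igraph", quietly = TRUE)
  lab <- function(g) ifelse(g$bonds$aromatic, 4L, pmin(g$bonds$order, 3L))
  build <- function(g, edge_sel) {
    bonds <- g$bonds[edge_sel, , drop = FALSE]
    verts <- sort(unique(c(bonds$a, bonds$b)))
    ig <- igraph::graph_from_edgelist(
      cbind(match(bonds$a, verts), match(bonds$b, verts)), directed = FALSE)
    # vf2 uses vertex/edge attributes named "color" as labels
    igraph::V(ig)$color <- match(g$element[verts], ELEMENTS)
    igraph::E(ig)$color <- lab(g)[edge_sel]
    ig
  }
  if (nrow(ga$bonds) > nrow(gb$bonds)) { tmp <- ga; ga <- gb; gb <- tmp }
  ea <- nrow(ga$bonds)
  target <- build(gb, seq_len(nrow(gb$bonds)))
  for (k in ea:0) {
    if (k == 0) return(0L)
    for (sel in utils::combn(ea, k, simplify = FALSE)) {
      pat <- build(ga, sel)
      if (igraph::subgraph_isomorphic(pat, target, method = "vf2")) {
        return(k)
      }
    }
  }
  0L
}
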