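# Candidate retrieval: filtering, cosine ranking under the four ranking
# views, rank@k / MCES@1 metrics, rank aggregation, and rank variability.
#
# Tie rule, everywhere: tied candidates all receive the worst rank of their
# tie group (never flatters the method).

RANKING_VIEWS <- c("mol-s", "fp-s", "mol-cs", "fp-cs")

#' Filter a candidate library by precursor mass
#'
#' @param target_mass Target monoisotopic mass (Da).
#' @param library Molecule tibble from [parse_molecules()].
#' @param ppm Relative mass window (default 10 ppm).
#' @param cap Maximum number of candidates returned (default 256).
#' @return Subset of `library` (at most `cap` rows, closest masses first).
#' @export
filter_candidates_by_mass <- function(target_mass, library, ppm = 10,
                                      cap = 256L) {
  dev <- abs(library$monoisotopic_mass - target_mass) / target_mass * 1e6
  hits <- library[dev <= ppm, ]
  hits <- hits[order(dev[dev <= ppm]), ]
  utils::head(hits, cap)
}

#' Filter a candidate library by exact molecular formula
#'
#' @param target_formula Formula string or named counts.
#' @param library Molecule tibble.
#' @param cap Maximum number of candidates (default 256).
#' @return Subset of `library` whose formulas match exactly.
#' @export
filter_candidates_by_formula <- function(target_formula, library,
                                         cap = 256L) {
  tf <- format_formula(if (is.character(target_formula))
    parse_formula(target_formula) else target_formula)
  utils::head(library[library$formula == tf, ], cap)
}

# worst-of-tie ranks for scores sorted descending
.worst_tie_rank <- function(scores) {
  scores <- unname(scores)
  vapply(scores, function(s) sum(scores >= s), integer(1))
}

#' Rank candidates by cosine similarity to a query embedding
#'
#' The query must come from a spectral view (`s` or `cs`) and the candidate
#' embeddings from a molecular view (`mol` or `fp`), matching the declared
#' ranking view.
#'
#' @param query_embedding Numeric vector (one query, spectral view).
#' @param candidate_embeddings Matrix (n_candidates x embed_dim) with
#'   rownames giving candidate SMILES.
#' @param ranking_view One of `"mol-s"`, `"fp-s"`, `"mol-cs"`, `"fp-cs"`.
#' @param query_id Optional query identifier stored in the result.
#' @return Tibble `query_id`, `candidate_smiles`, `score`, `rank` (1-based,
#'   descending score, worst-of-tie), sorted by rank. The ranking view is
#'   kept as attribute `ranking_view`.
#' @export
rank_candidates <- function(query_embedding, candidate_embeddings,
                            ranking_view = "mol-s", query_id = "query") {
  if (!ranking_view %in% RANKING_VIEWS) {
    rlang::abort(paste0("Unknown ranking view '", ranking_view,
                        "'; must be one of ",
                        paste(RANKING_VIEWS, collapse = ", ")),
                 class = "massembed_rank_error")
  }
  q <- as.numeric(query_embedding)
  C <- as.matrix(candidate_embeddings)
  if (length(q) != ncol(C)) {
    rlang::abort("Query and candidate embedding dimensions differ",
                 class = "massembed_rank_error")
  }
  qn <- sqrt(sum(q^2)); cn <- sqrt(rowSums(C^2))
  if (qn == 0 || any(cn == 0)) {
    rlang::abort("Zero-norm embedding", class = "massembed_rank_error")
  }
  score <- as.numeric(C %*% q) / (cn * qn)
  rk <- .worst_tie_rank(score)
  out <- tibble::tibble(
    query_id = query_id,
    candidate_smiles = rownames(C) %||% paste0("cand_", seq_along(score)),
    score = score,
    rank = rk
  )
  out <- out[order(out$rank, out$candidate_smiles), ]
  attr(out, "ranking_view") <- ranking_view
  out
}

# the rank of the target candidate within one ranking table
.target_rank <- function(table, target_smiles) {
  i <- match(target_smiles, table$candidate_smiles)
  if (is.na(i)) NA_integer_ else table$rank[i]
}

#' rank@k over a set of ranking tables
#'
#' The percentage of queries whose target molecule is ranked within the top
#' `k` positions.
#'
#' @param tables List of ranking tables (from [rank_candidates()]), each
#'   paired with its target via `targets`.
#' @param targets Character vector of target SMILES, one per table
#'   (canonical form, as in the candidate rows).
#' @param ks Cutoffs (default `c(1, 5, 20)`).
#' @return Tibble `k`, `rank_at` (percent, in `[0, 100]`), plus
#'   `n_queries`.
#' @export
rank_at_k <- function(tables, targets, ks = c(1L, 5L, 20L)) {
  if (!length(tables)) {
    rlang::abort("rank_at_k needs at least one ranking table",
                 class = "massembed_rank_error")
  }
  stopifnot(length(targets) == length(tables))
  rks <- mapply(.target_rank, tables, targets)
  tibble::tibble(
    k = as.integer(ks),
    rank_at = vapply(ks, function(k) {
      100 * mean(!is.na(rks) & rks <= k)
    }, numeric(1)),
    n_queries = length(tables)
  )
}

#' Full retrieval metric report
#'
#' rank@k at the requested cutoffs plus, optionally, MCES@1: the mean exact
#' maximum-common-edge-subgraph distance between each query's target and
#' its top-ranked candidate.
#'
#' @inheritParams rank_at_k
#' @param molecules Optional molecule tibble covering every target and
#'   candidate SMILES (needed for MCES@1).
#' @param mces_size_cap Passed to [mces_distance()].
#' @return List of class `metric_report` with `rank_at` (tibble),
#'   `mces_at_1` (mean or `NA`), `n_queries`.
#' @export
metric_report <- function(tables, targets, ks = c(1L, 5L, 20L),
                          molecules = NULL, mces_size_cap = 20L) {
  ra <- rank_at_k(tables, targets, ks)
  mces <- NA_real_
  if (!is.null(molecules)) {
    ds <- mapply(function(tb, tg) {
      top <- tb$candidate_smiles[tb$rank == min(tb$rank)][1]
      ga <- molecules$graph[[match(tg, molecules$smiles)]]
      gb <- molecules$graph[[match(top, molecules$smiles)]]
      mces_distance(ga, gb, size_cap = mces_size_cap)
    }, tables, targets)
    mces <- mean(ds)
  }
  structure(list(rank_at = ra, mces_at_1 = mces,
                 n_queries = length(tables)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> n =", x$n_queries, "queries\n")
  for (i in seq_len(nrow(x$rank_at))) {
    cat(sprintf("  rank@%-3d %6.2f%%\n", x$rank_at$k[i], x$rank_at$rank_at[i]))
  }
  if (!is.na(x$mces_at_1)) cat(sprintf("  MCES@1   %6.3f\n", x$mces_at_1))
  invisible(x)
}

# ---- rank aggregation (rank-then-aggregate paradigm) ------------------------

.check_same_candidates <- function(tables) {
  base <- sort(tables[[1]]$candidate_smiles)
  for (tb in tables[-1]) {
    if (!identical(sort(tb$candidate_smiles), base)) {
      rlang::abort("Aggregation requires a shared candidate set",
                   class = "massembed_rank_error")
    }
  }
}

#' Aggregate per-spectrum rankings by average rank
#'
#' Candidates are re-ranked by the mean of their ranks across all spectral
#' queries (lower mean rank is better).
#'
#' @param tables List of ranking tables over one shared candidate set.
#' @return Aggregated ranking table (`score` = negative mean rank so that
#'   higher scores are better, `rank` by worst-of-tie).
#' @export
aggregate_average_rank <- function(tables) {
  stopifnot(length(tables) >= 1)
  .check_same_candidates(tables)
  cands <- sort(tables[[1]]$candidate_smiles)
  mean_rank <- vapply(cands, function(cm) {
    mean(vapply(tables, function(tb) {
      tb$rank[match(cm, tb$candidate_smiles)]
    }, numeric(1)))
  }, numeric(1))
  score <- unname(-mean_rank)
  out <- tibble::tibble(
    query_id = tables[[1]]$query_id[1],
    candidate_smiles = cands,
    score = score,
    rank = .worst_tie_rank(score)
  )
  out[order(out$rank, out$candidate_smiles), ]
}

#' Aggregate per-spectrum rankings by summed reciprocal rank
#'
#' Each candidate scores the sum of `1 / rank` over the spectral queries;
#' higher scores rank better.
#'
#' @inheritParams aggregate_average_rank
#' @return Aggregated ranking table.
#' @export
aggregate_reciprocal_rank <- function(tables) {
  stopifnot(length(tables) >= 1)
  .check_same_candidates(tables)
  cands <- sort(tables[[1]]$candidate_smiles)
  score <- vapply(cands, function(cm) {
    sum(vapply(tables, function(tb) {
      1 / tb$rank[match(cm, tb$candidate_smiles)]
    }, numeric(1)))
  }, numeric(1))
  out <- tibble::tibble(
    query_id = tables[[1]]$query_id[1],
    candidate_smiles = cands,
    score = unname(score),
    rank = .worst_tie_rank(unname(score))
  )
  out[order(out$rank, out$candidate_smiles), ]
}

#' Normalized rank difference across spectra of one molecule
#'
#' The range of the target's ranks across the spectra, divided by the
#' number of candidates; 0 for a single spectrum or perfectly stable ranks.
#'
#' @param tables List of ranking tables for one molecule's spectra.
#' @param target_smiles The target molecule's canonical SMILES.
#' @return Scalar in `[0, 1]`.
#' @export
normalized_rank_difference <- function(tables, target_smiles) {
  stopifnot(length(tables) >= 1)
  rks <- vapply(tables, .target_rank, integer(1), target_smiles)
  if (anyNA(rks)) {
    rlang::abort("Target not present in every candidate set",
                 class = "massembed_rank_error")
  }
  n_cand <- nrow(tables[[1]])
  (max(rks) - min(rks)) / n_cand
}
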