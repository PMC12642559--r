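test_that("candidate filtering by mass honors the ppm window and cap", {
  masses <- c(180.063388, 180.063388 * (1 + 11e-6), 180.063388 * (1 + 5e-6),
              200.1)
  lib <- tibble::tibble(
    molecule_id = paste0("m", 1:4), smiles = paste0("s", 1:4),
    formula = c("C6H12O6", "C6H12O6", "C6H12O6", "X"),
    monoisotopic_mass = masses, graph = vector("list", 4)
  )
  hits <- filter_candidates_by_mass(180.063388, lib, ppm = 10)
  expect_setequal(hits$molecule_id, c("m1", "m3"))  # 11 ppm is excluded
  big <- lib[rep(1, 300), ]
  expect_equal(nrow(filter_candidates_by_mass(180.063388, big)), 256L)
})

test_that("candidate filtering by formula is an exact element-count match", {
  mols <- parse_molecules(c("OCC1OC(O)C(O)C(O)C1O", "OCC1OC(O)(CO)C(O)C1O",
                            "OCC1OC(O)C(O)C1O"),
                          c("glucose", "fructose", "pentose"))
  iso <- filter_candidates_by_formula("C6H12O6", mols)
  expect_setequal(iso$molecule_id, c("glucose", "fructose"))
  expect_equal(nrow(filter_candidates_by_formula("C6H12O5", mols[0, ])), 0L)
})

test_that("rank_candidates sorts by cosine with worst-of-tie ranks", {
  q <- c(1, 0, 0)
  C <- rbind(a = c(2, 0, 0),    # cosine 1 (scaled copy)
             b = c(0, 1, 0),    # cosine 0
             c = c(-1, 0, 0))   # cosine -1
  tb <- rank_candidates(q, C, "mol-s", "q")
  expect_equal(tb$candidate_smiles[tb$rank == 1], "a")
  expect_equal(tb$rank, c(1L, 2L, 3L))
  # two identical candidates both get the worst rank of the tie
  C2 <- rbind(a = c(1, 0), b = c(1, 0))
  tb2 <- rank_candidates(c(1, 0), C2, "mol-s")
  expect_equal(tb2$rank, c(2L, 2L))
  # brute-force sort oracle on random scores
  set.seed(44)
  for (rep in 1:20) {
    E <- matrix(rnorm(5 * 3), 5,
                dimnames = list(paste0("c", 1:5), NULL))
    qq <- rnorm(3)
    tb3 <- rank_candidates(qq, E, "fp-cs")
    sc <- sapply(1:5, function(i) {
      sum(qq * E[i, ]) / sqrt(sum(qq^2)) / sqrt(sum(E[i, ]^2))
    })
    oracle_rank <- sapply(sc, function(s) sum(sc >= s))
    expect_equal(tb3$rank[match(paste0("c", 1:5), tb3$candidate_smiles)],
                 as.integer(oracle_rank))
    # invariance to positive rescaling
    tb4 <- rank_candidates(3.7 * qq, E * 0.2, "fp-cs")
    expect_equal(tb4$rank, tb3$rank)
  }
  expect_error(rank_candidates(q, C, "mol-mol"),
               class = "massembed_rank_error")
  expect_error(rank_candidates(c(1, 2), C, "mol-s"),
               class = "massembed_rank_error")
})

test_that("rank@k counts top-k retrievals as percentages", {
  mk <- function(target_rank, n = 25) {
    tibble::tibble(query_id = "q",
                   candidate_smiles = paste0("c", 1:n),
                   score = seq(1, 0, length.out = n),
                   rank = 1:n) -> tb
    list(table = tb, target = paste0("c", target_rank))
  }
  cases <- lapply(c(1, 6, 21), mk)
  tables <- lapply(cases, `[[`, "table")
  targets <- vapply(cases, `[[`, character(1), "target")
  ra <- rank_at_k(tables, targets)
  expect_equal(ra$rank_at, c(100 / 3, 100 / 3, 200 / 3), tolerance = 1e-9)
  # all at rank 1
  all1 <- rank_at_k(lapply(rep(1, 4), function(i) mk(1)$table),
                    rep("c1", 4))
  expect_equal(all1$rank_at, c(100, 100, 100))
  # monotone in k, and rank@n = 100 when the target is present
  expect_true(all(diff(ra$rank_at) >= 0))
  expect_equal(rank_at_k(tables, targets, ks = 25)$rank_at, 100)
  expect_error(rank_at_k(list(), character(0)),
               class = "massembed_rank_error")
})

test_that("rank aggregation matches brute-force oracles and is a fixed point", {
  mk_table <- function(ranks) {
    tibble::tibble(query_id = "q",
                   candidate_smiles = names(ranks),
                   score = -as.numeric(ranks),
                   rank = as.integer(ranks))
  }
  t1 <- mk_table(c(a = 1, b = 3, c = 2, d = 4))
  t2 <- mk_table(c(a = 3, b = 1, c = 2, d = 4))
  t3 <- mk_table(c(a = 2, b = 3, c = 1, d = 4))
  avg <- aggregate_average_rank(list(t1, t2, t3))
  expect_equal(avg$score[match("a", avg$candidate_smiles)], -2)  # mean 2.0
  rec <- aggregate_reciprocal_rank(list(t1, t2, t3))
  expect_equal(rec$score[match("a", rec$candidate_smiles)], 1 + 1 / 3 + 1 / 2)
  # candidate always at rank 1 over m spectra scores m and is top
  always <- aggregate_reciprocal_rank(list(t1, t1, t1))
  expect_equal(always$score[match("a", always$candidate_smiles)], 3)
  expect_equal(always$candidate_smiles[always$rank == 1], "a")
  # fixed point: identical rankings aggregate to themselves
  fp_avg <- aggregate_average_rank(list(t1, t1))
  expect_equal(fp_avg$rank[match(names(c(a = 1, b = 3, c = 2, d = 4)),
                                 fp_avg$candidate_smiles)],
               c(1L, 3L, 2L, 4L))
  # random instances vs explicit oracles
  set.seed(91)
  for (rep in 1:20) {
    ranks <- replicate(3, sample.int(4), simplify = FALSE)
    tabs <- lapply(ranks, function(r) mk_table(stats::setNames(r, letters[1:4])))
    m <- rowMeans(sapply(ranks, identity))
    oracle_avg <- sapply(m, function(x) sum(m <= x))
    got <- aggregate_average_rank(tabs)
    expect_equal(got$rank[match(letters[1:4], got$candidate_smiles)],
                 as.integer(oracle_avg))
    rr <- rowSums(sapply(ranks, function(r) 1 / r))
    oracle_rr <- sapply(rr, function(x) sum(rr >= x))
    got2 <- aggregate_reciprocal_rank(tabs)
    expect_equal(got2$rank[match(letters[1:4], got2$candidate_smiles)],
                 as.integer(oracle_rr))
  }
  # aggregation requires a shared candidate set
  t_bad <- mk_table(c(a = 1, b = 2, x = 3, d = 4))
  expect_error(aggregate_average_rank(list(t1, t_bad)),
               class = "massembed_rank_error")
})

test_that("normalized rank difference is range over candidate count", {
  mk <- function(target_rank, n = 20) {
    tibble::tibble(query_id = "q", candidate_smiles = paste0("c", 1:n),
                   score = -(1:n), rank = 1:n)
  }
  same <- list(mk(5), mk(5), mk(5))
  expect_equal(normalized_rank_difference(same, "c5"), 0)
  two <- list(mk(1), mk(11))
  # target "fixed": ranks of c1 are 1 and 1 here, so craft tables where the
  # target sits at ranks 1 and 11
  tb1 <- mk(1); tb2 <- mk(1)
  tb2$candidate_smiles <- c(paste0("c", 2:11), "c1", paste0("c", 12:20))
  expect_equal(normalized_rank_difference(list(tb1, tb2), "c1"), 10 / 20)
  expect_equal(normalized_rank_difference(list(tb1), "c1"), 0)
})
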