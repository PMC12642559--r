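test_that("library generation is seeded, unique, and size-checked", {
  cfg <- synth_config(n_molecules = 20, seed = 7)
  lib1 <- generate_library(cfg)
  lib2 <- generate_library(cfg)
  expect_identical(lib1$smiles, lib2$smiles)
  expect_equal(anyDuplicated(lib1$smiles), 0L)
  expect_equal(nrow(lib1), 20L)
  expect_true(all(vapply(lib1$graph,
                         function(g) length(g$element), integer(1)) >= 4))
  lib3 <- generate_library(synth_config(n_molecules = 20, seed = 8))
  expect_false(identical(lib1$smiles, lib3$smiles))
  expect_equal(nrow(generate_library(synth_config(n_molecules = 1))), 1L)
  expect_error(generate_library(synth_config(n_molecules = 100000)),
               class = "massembed_synth_error")
})

test_that("noise-free fragmentation yields perfectly annotatable subformula peaks", {
  cfg <- synth_config(n_molecules = 5, noise_peak_rate = 0,
                      mz_error_ppm_sd = 0, seed = 13)
  lib <- generate_library(cfg)
  set.seed(2)
  for (i in seq_len(nrow(lib))) {
    sp <- fragment_molecule(lib[i, ], energy = 20, cfg)
    ann <- annotate_peaks(sp$peaks[[1]], lib$formula[i], cfg$adduct)
    # every generated peak is recovered with essentially zero ppm error
    expect_equal(nrow(ann), nrow(sp$peaks[[1]]))
    expect_true(all(abs(ann$ppm_error) < 1e-6))
    parent <- parse_formula(lib$formula[i])
    for (f in ann$formula) {
      expect_true(all(parse_formula(f) <= parent))
    }
  }
})

test_that("higher pseudo-collision-energy yields smaller fragments on average", {
  cfg <- synth_config(n_molecules = 3, noise_peak_rate = 0,
                      mz_error_ppm_sd = 0, seed = 5)
  lib <- generate_library(cfg)
  mol <- lib[which.max(vapply(lib$graph, function(g) length(g$element),
                              integer(1))), ]
  set.seed(42)
  mean_mz <- function(energy) {
    mean(vapply(1:100, function(i) {
      mean(fragment_molecule(mol, energy, cfg)$peaks[[1]]$mz)
    }, numeric(1)))
  }
  expect_lt(mean_mz(40), mean_mz(10))
})

test_that("fragmentation is reproducible for a fixed RNG state", {
  cfg <- synth_config(n_molecules = 2, seed = 4)
  lib <- generate_library(cfg)
  set.seed(7); s1 <- fragment_molecule(lib[1, ], 20, cfg)
  set.seed(7); s2 <- fragment_molecule(lib[1, ], 20, cfg)
  expect_identical(s1$peaks[[1]], s2$peaks[[1]])
})

test_that("dataset splits are scaffold-disjoint and candidate sets contain the target", {
  ds <- fixture_dataset()$raw
  split_of <- split(ds$molecules$scaffold, ds$molecules$split)
  expect_setequal(names(split_of), c("train", "val", "test"))
  expect_equal(length(intersect(split_of$train, split_of$test)), 0L)
  expect_equal(length(intersect(split_of$train, split_of$val)), 0L)
  expect_equal(length(intersect(split_of$val, split_of$test)), 0L)
  for (mode in c("candidates_by_mass", "candidates_by_formula")) {
    sets <- ds[[mode]]
    for (i in seq_len(nrow(sets))) {
      target <- ds$molecules$smiles[
        match(sets$query_id[i], ds$molecules$molecule_id)]
      expect_equal(sum(sets$candidates[[i]] == target), 1L)
      expect_lte(length(sets$candidates[[i]]), ds$config$candidate_set_size)
    }
  }
  # every spectrum belongs to a library molecule; three per molecule
  expect_true(all(table(ds$spectra$molecule_id) == 3L))
})

test_that("generated datasets exercise the real I/O path", {
  ds <- fixture_dataset()$raw
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_mgf(file.path(dir, "spectra.mgf"))
  expect_equal(nrow(back), nrow(ds$spectra))
  cands <- suppressWarnings(
    read_candidates(file.path(dir, "candidates.json"), validate = FALSE))
  expect_equal(nrow(cands), nrow(ds$candidates_by_mass))
  mols <- utils::read.delim(file.path(dir, "molecules.tsv"))
  expect_equal(nrow(mols), nrow(ds$molecules))
})

test_that("adding noise peaks does not improve downstream annotation purity", {
  # noise peaks either fail annotation (dropped) or dilute true peaks;
  # the count of exactly-recovered true formulas never increases
  lib <- generate_library(synth_config(n_molecules = 3, seed = 9))
  frac_clean <- function(rate) {
    cfg <- synth_config(n_molecules = 3, noise_peak_rate = rate,
                        mz_error_ppm_sd = 0, seed = 9)
    set.seed(31)
    mean(vapply(1:30, function(i) {
      sp <- fragment_molecule(lib[1, ], 20, cfg)
      ann <- suppressWarnings(
        annotate_peaks(sp$peaks[[1]], lib$formula[1], cfg$adduct))
      nrow(ann) / nrow(sp$peaks[[1]])
    }, numeric(1)))
  }
  expect_lte(frac_clean(0.5), frac_clean(0))
})
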