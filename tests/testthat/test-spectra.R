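test_that("annotate_peaks assigns the correct subformula within tolerance", {
  # glucose parent, [M+H]+; C2H4O2 neutral mass 60.021130; ion 61.028406
  pk <- tibble::tibble(mz = 61.028406, intensity = 5)
  ann <- annotate_peaks(pk, "C6H12O6", "[M+H]+")
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$formula, "C2H4O2")
  expect_lt(abs(ann$ppm_error), 0.1)
  expect_equal(ann$intensity, 1)
})

test_that("the ppm boundary is honored (+19 in, +21/+25 out)", {
  ion <- formula_mass("C2H4O2") + adduct_offset("[M+H]+")
  # independent check: no other glucose subformula lies within 20 ppm of
  # the +25 ppm-shifted peak
  parent <- parse_formula("C6H12O6")
  grid <- as.matrix(expand.grid(C = 0:6, H = 0:12, O = 0:6))
  masses <- grid %*% c(formula_mass("C"), formula_mass("H"),
                       formula_mass("O")) + adduct_offset("[M+H]+")
  shifted <- ion * (1 + 25e-6)
  expect_gt(min(abs(shifted - masses) / masses * 1e6), 20)

  for (case in list(list(s = 19e-6, n = 1L), list(s = 21e-6, n = 0L),
                    list(s = 25e-6, n = 0L))) {
    pk <- tibble::tibble(mz = ion * (1 + case$s), intensity = 1)
    ann <- if (case$n == 0) {
      suppressWarnings(annotate_peaks(pk, "C6H12O6", "[M+H]+"))
    } else annotate_peaks(pk, "C6H12O6", "[M+H]+")
    expect_equal(nrow(ann), case$n)
  }
})

test_that("top-60 selection happens before matching and output is canonical", {
  set.seed(7)
  ion <- formula_mass("C2H4O2") + adduct_offset("[M+H]+")
  # 80 peaks: 79 junk at unannotatable m/z, 1 real; real one is the most
  # intense so it survives the top-60 cut
  pk <- tibble::tibble(
    mz = c(ion, runif(79, 400, 500)),
    intensity = c(10, runif(79, 0.1, 5))
  )
  ann <- suppressWarnings(annotate_peaks(pk, "C6H12O6", "[M+H]+"))
  expect_lte(nrow(ann), 60L)
  expect_true("C2H4O2" %in% ann$formula)
  # shuffle invariance
  shuf <- pk[sample.int(nrow(pk)), ]
  expect_equal(suppressWarnings(annotate_peaks(shuf, "C6H12O6", "[M+H]+")),
               ann)
  # a low-intensity real peak beyond the top-60 cut is not annotated
  pk2 <- tibble::tibble(
    mz = c(runif(60, 400, 500), ion),
    intensity = c(rep(5, 60), 0.01)
  )
  ann2 <- suppressWarnings(annotate_peaks(pk2, "C6H12O6", "[M+H]+"))
  expect_false("C2H4O2" %in% ann2$formula)
})

test_that("element scaler records training maxima floored at one", {
  ann <- tibble::tibble(
    molecule_id = c("a", "a"),
    peaks = list(
      tibble::tibble(formula = "C2H4O2", intensity = 1, ppm_error = 0),
      tibble::tibble(formula = "C6H12O6", intensity = 1, ppm_error = 0)
    )
  )
  sc <- suppressWarnings(fit_element_scaler(ann))
  expect_equal(unname(as.integer(sc)[1:3]), c(6L, 12L, 6L))  # C, H, O
  expect_true(all(as.integer(sc)[4:14] == 1L))
  expect_warning(fit_element_scaler(ann), "never observed")

  one <- tibble::tibble(molecule_id = "a",
                        peaks = list(tibble::tibble(
                          formula = "C", intensity = 1, ppm_error = 0)))
  sc1 <- suppressWarnings(fit_element_scaler(one))
  expect_true(all(as.integer(sc1) == 1L))

  empty <- tibble::tibble(molecule_id = character(0), peaks = list())
  expect_error(fit_element_scaler(empty), class = "massembed_scaler_error")
})

test_that("peak vectors follow the fixed 15-entry layout and scaling rule", {
  sc <- structure(c(10L, 20L, 8L, rep(1L, 11)), names = ELEMENTS,
                  class = "element_scaler")
  v <- peak_to_vector("C6H12O6", 1.0, sc)
  expect_equal(v, c(0.6, 0.6, 0.75, rep(0, 11), 1.0))
  expect_equal(peak_to_vector("-", 0.2, sc), c(rep(0, 14), 0.2))
  expect_warning(v2 <- peak_to_vector("C12", 0.5, sc), "not clipped")
  expect_equal(v2[1], 1.2)
  m <- spectrum_to_matrix(tibble::tibble(formula = c("C6H12O6", "CH2"),
                                         intensity = c(1, 0.5)), sc)
  expect_equal(dim(m), c(2L, 15L))
  expect_equal(m[1, ], v)
})

test_that("consensus merging is a max-merge, order-invariant and idempotent", {
  s1 <- tibble::tibble(formula = "CHO2", intensity = 0.5, ppm_error = 0)
  s2 <- tibble::tibble(formula = c("CHO2", "C2H2"),
                       intensity = c(0.9, 0.3), ppm_error = c(0, 0))
  cs <- build_consensus(list(s1, s2))
  expect_equal(cs$formula, c("C2H2", "CHO2"))
  expect_equal(cs$intensity, c(0.3, 0.9))
  # commutative and associative
  expect_equal(build_consensus(list(s2, s1)), cs)
  s3 <- tibble::tibble(formula = "C2H2", intensity = 0.7, ppm_error = 0)
  left <- build_consensus(list(build_consensus(list(s1, s2)), s3))
  right <- build_consensus(list(s1, build_consensus(list(s2, s3))))
  expect_equal(left, right)
  # idempotence / single-spectrum fallback
  self <- build_consensus(list(s2, s2))
  expect_equal(self, build_consensus(list(s2)))
  expect_error(build_consensus(list()), class = "massembed_consensus_error")
  mixed <- tibble::tibble(molecule_id = c("a", "b"), peaks = list(s1, s2))
  expect_error(build_consensus(mixed), class = "massembed_consensus_error")
})

test_that("every constituent spectrum's formula set is a subset of its consensus", {
  prep <- fixture_dataset()$prep
  cons <- prep$consensus
  for (i in seq_len(nrow(prep$annotated))) {
    cf <- cons$peaks[[match(prep$annotated$molecule_id[i],
                            cons$molecule_id)]]$formula
    expect_true(all(prep$annotated$peaks[[i]]$formula %in% cf))
  }
})

test_that("annotated spectra export to a flat TSV", {
  prep <- fixture_dataset()$prep
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotated_tsv(prep$annotated, path)
  tsv <- utils::read.delim(path)
  expect_named(tsv, c("spectrum_id", "formula", "intensity", "ppm_error"))
  expect_equal(nrow(tsv),
               sum(vapply(prep$annotated$peaks, nrow, integer(1))))
})

test_that("binned spectra land in the right bins and are max-normalized", {
  b <- bin_spectrum(tibble::tibble(mz = 100.05, intensity = 1.0))
  expect_length(b, 10000L)
  expect_equal(which(b > 0), 1001L)  # floor(100.05 / 0.1) + 1
  two <- bin_spectrum(tibble::tibble(mz = c(100.01, 100.09, 200.0),
                                     intensity = c(1, 1, 1)))
  expect_equal(max(two), 1)          # same bin summed then renormalized
  expect_equal(two[1001], 1)
  expect_equal(two[2001], 0.5)
  expect_equal(sum(bin_spectrum(tibble::tibble(mz = numeric(0),
                                               intensity = numeric(0)))), 0)
  expect_warning(bin_spectrum(tibble::tibble(mz = 1500, intensity = 1)),
                 "dropped")
})
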