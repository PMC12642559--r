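# Synthetic molecule libraries and in-silico fragmentation spectra.
#
# The generator emulates the statistical structure the framework assumes:
# several noisy spectra per molecule at different pseudo-collision
# energies, with every true peak carrying a subformula of its parent
# (fragments are connected subgraphs of the molecular graph, so spectra
# carry structural signal the graph view can exploit). It makes no claim to
# physically realistic fragmentation chemistry.

#' Synthetic data configuration
#'
#' @param n_molecules Library size.
#' @param spectra_per_molecule Spectra per molecule (default 3, one per
#'   pseudo-collision-energy).
#' @param energies Pseudo-collision-energies; higher energies shift
#'   fragments smaller (default 10/20/40).
#' @param peaks_range Range of true peaks per spectrum (default 8-16).
#' @param noise_peak_rate Expected fraction of noise peaks added at uniform
#'   random m/z (default 0.05).
#' @param intensity_noise_sd Log-normal sd of peak intensities (default
#'   0.5).
#' @param mz_error_ppm_sd Gaussian m/z error in ppm (default 5, comfortably
#'   inside the 20 ppm annotation window).
#' @param candidate_set_size Candidates per query, target included
#'   (default 16).
#' @param adduct Adduct of all generated spectra (default `"[M+H]+"`).
#' @param seed Integer seed; a single RNG stream drives library order,
#'   fragmentation, and noise.
#' @return Named list of class `synth_config`.
#' @export
synth_config <- function(n_molecules = 50L, spectra_per_molecule = 3L,
                         energies = c(10, 20, 40),
                         peaks_range = c(8L, 16L), noise_peak_rate = 0.05,
                         intensity_noise_sd = 0.5, mz_error_ppm_sd = 5,
                         candidate_set_size = 16L, adduct = "[M+H]+",
                         seed = 1L) {
  stopifnot(n_molecules >= 1, spectra_per_molecule >= 1,
            length(energies) >= 1, length(peaks_range) == 2,
            peaks_range[1] >= 1, peaks_range[2] >= peaks_range[1],
            noise_peak_rate >= 0, noise_peak_rate < 1,
            intensity_noise_sd >= 0, mz_error_ppm_sd >= 0,
            candidate_set_size >= 2)
  check_adduct(adduct)
  structure(list(
    n_molecules = as.integer(n_molecules),
    spectra_per_molecule = as.integer(spectra_per_molecule),
    energies = energies, peaks_range = as.integer(peaks_range),
    noise_peak_rate = noise_peak_rate,
    intensity_noise_sd = intensity_noise_sd,
    mz_error_ppm_sd = mz_error_ppm_sd,
    candidate_set_size = as.integer(candidate_set_size),
    adduct = adduct, seed = as.integer(seed)
  ), class = "synth_config")
}

# deterministic combinatorial SMILES grammar over C/H/O/N/S: scaffold
# templates (rings and chains) with up to two substitution points
.SCAFFOLDS <- c(
  "C1CCCC(%s)C1", "c1ccc(%s)cc1", "C1CCOC(%s)C1", "C1CCNC(%s)C1",
  "C1CCSC(%s)C1", "C1CCC(%s)C1", "c1ccnc(%s)c1", "C1COCC(%s)C1",
  "C(%s)CCCC", "C(%s)CCCCC", "C(%s)CCOCC", "C(%s)CCNCC",
  "C1CC(%s)CC(%s)C1", "c1cc(%s)ccc1%s", "C(%s)CCC(%s)C", "C1CC(%s)OC1%s"
)
.SUBSTITUENTS <- c("O", "N", "CO", "CCO", "C(=O)O", "C(C)=O", "S", "C",
                   "CC", "C(N)=O", "OC", "NC")

# full deterministic enumeration of the grammar, in fixed order
.grammar_smiles <- function() {
  out <- character(0)
  for (tpl in .SCAFFOLDS) {
    nslot <- lengths(regmatches(tpl, gregexpr("%s", tpl, fixed = TRUE)))
    if (nslot == 1) {
      for (s1 in .SUBSTITUENTS) out <- c(out, sprintf(tpl, s1))
    } else {
      for (s1 in .SUBSTITUENTS) {
        for (s2 in .SUBSTITUENTS) out <- c(out, sprintf(tpl, s1, s2))
      }
    }
  }
  out
}

#' Generate a deterministic synthetic molecule library
#'
#' Molecules are drawn (in a seeded shuffled order) from a fixed
#' combinatorial SMILES grammar over C/H/O/N/S - ring and chain scaffolds
#' decorated with small substituents - deduplicated by canonical SMILES,
#' each with at least 4 heavy atoms. The scaffold template of each molecule
#' is recorded for scaffold-disjoint splitting.
#'
#' @param config A [synth_config()] (only `n_molecules` and `seed` are
#'   used).
#' @return Molecule tibble ([parse_molecules()] layout) plus a `scaffold`
#'   column.
#' @export
generate_library <- function(config = synth_config()) {
  grammar <- .grammar_smiles()
  scaff_of <- rep(seq_along(.SCAFFOLDS),
                  times = vapply(.SCAFFOLDS, function(tpl) {
                    n <- lengths(regmatches(tpl,
                                            gregexpr("%s", tpl, fixed = TRUE)))
                    as.integer(if (n == 1) length(.SUBSTITUENTS) else
                      length(.SUBSTITUENTS)^2)
                  }, integer(1)))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(config$seed %% 2147483647L)
  ord <- sample.int(length(grammar))
  seen <- character(0)
  rows <- list()
  for (i in ord) {
    rec <- tryCatch(parse_molecules(grammar[i]), error = function(e) NULL)
    if (is.null(rec)) next
    if (rec$smiles %in% seen) next
    if (length(rec$graph[[1]]$element) < 4) next
    seen <- c(seen, rec$smiles)
    rec$molecule_id <- sprintf("M%04d", length(rows) + 1L)
    rec$scaffold <- paste0("scaffold_", scaff_of[i])
    rows[[length(rows) + 1L]] <- rec
    if (length(rows) == config$n_molecules) break
  }
  if (length(rows) < config$n_molecules) {
    rlang::abort(paste0("Grammar yields only ", length(rows),
                        " unique molecules; requested ",
                        config$n_molecules),
                 class = "massembed_synth_error")
  }
  dplyr::bind_rows(rows)
}

# sample one connected fragment subgraph of `size` atoms
.sample_fragment <- function(g, size) {
  n <- length(g$element)
  size <- max(1L, min(size, n))
  cur <- sample.int(n, 1)
  frag <- cur
  while (length(frag) < size) {
    frontier <- unique(c(
      g$bonds$b[g$bonds$a %in% frag], g$bonds$a[g$bonds$b %in% frag]
    ))
    frontier <- setdiff(frontier, frag)
    if (!length(frontier)) break
    frag <- c(frag, frontier[sample.int(length(frontier), 1)])
  }
  frag
}

#' Simulate one fragmentation spectrum of a molecule
#'
#' True peaks are connected-subgraph fragments of the molecular graph
#' (guaranteeing that each peak's formula is a subformula of the parent);
#' higher `energy` shifts fragment sizes smaller. Each true peak's m/z is
#' the fragment's neutral monoisotopic mass plus the adduct offset plus
#' Gaussian ppm error; intensities are log-normal; noise peaks are added at
#' uniform random m/z. Uses the current RNG stream.
#'
#' @param molecule One-row molecule tibble (with `graph`).
#' @param energy Pseudo-collision energy.
#' @param config A [synth_config()].
#' @param spectrum_id Identifier for the generated spectrum.
#' @return One-row spectra tibble in the [read_mgf()] layout.
#' @export
fragment_molecule <- function(molecule, energy, config = synth_config(),
                              spectrum_id = "spec_1") {
  g <- molecule$graph[[1]]
  n <- length(g$element)
  parent <- parse_formula(molecule$formula)
  offset <- adduct_offset(config$adduct)
  n_true <- sample(config$peaks_range[1]:config$peaks_range[2], 1)
  frac <- stats::rbeta(n_true, 2, 2 * energy / 20)
  mz <- numeric(0); inten <- numeric(0)
  for (i in seq_len(n_true)) {
    frag <- .sample_fragment(g, max(1L, round(frac[i] * n)))
    counts <- stats::setNames(integer(length(ELEMENTS)), ELEMENTS)
    for (a in frag) counts[g$element[a]] <- counts[g$element[a]] + 1L
    # hydrogens: those attached to the fragment atoms, plus one per broken
    # bond, capped at the parent's hydrogen count
    broken <- sum((g$bonds$a %in% frag) != (g$bonds$b %in% frag))
    counts["H"] <- min(sum(g$n_h[frag]) + broken, parent["H"])
    m <- sum(counts * ELEMENT_MASS) + offset
    err <- stats::rnorm(1, 0, config$mz_error_ppm_sd) * 1e-6 * m
    mz <- c(mz, m + err)
    inten <- c(inten, stats::rlnorm(1, 0, config$intensity_noise_sd))
  }
  precursor <- molecule$monoisotopic_mass + offset
  n_noise <- stats::rbinom(1, n_true, config$noise_peak_rate)
  if (n_noise > 0) {
    mz <- c(mz, stats::runif(n_noise, 50, precursor))
    inten <- c(inten, stats::rlnorm(n_noise, -1, config$intensity_noise_sd))
  }
  ord <- order(mz)
  tibble::tibble(
    spectrum_id = spectrum_id,
    precursor_mz = precursor,
    adduct = config$adduct,
    molecule_id = molecule$molecule_id,
    smiles = molecule$smiles,
    peaks = list(tibble::tibble(mz = mz[ord], intensity = inten[ord])),
    extra = list(list(ENERGY = as.character(energy)))
  )
}

#' Generate a complete synthetic dataset
#'
#' Builds the library, simulates `spectra_per_molecule` spectra per
#' molecule (one per energy, cycling through `energies`), splits molecules
#' by scaffold so no scaffold crosses the train/validation/test boundary
#' (roughly 70/15/15 by molecule), and constructs by-mass and by-formula
#' candidate sets for every test molecule (target always included; by-mass
#' sets are padded with nearest-mass decoys up to `candidate_set_size`).
#'
#' @param config A [synth_config()].
#' @return List of class `synth_dataset`: `molecules` (with `scaffold` and
#'   `split` columns), `spectra` (raw tibble), `candidates_by_mass`,
#'   `candidates_by_formula` (tibbles `query_id`, `candidates`), `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  library_tbl <- generate_library(config)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed((config$seed + 7919L) %% 2147483647L)

  energies <- rep_len(config$energies, config$spectra_per_molecule)
  specs <- list()
  for (i in seq_len(nrow(library_tbl))) {
    for (j in seq_along(energies)) {
      specs[[length(specs) + 1L]] <- fragment_molecule(
        library_tbl[i, ], energies[j], config,
        spectrum_id = paste0(library_tbl$molecule_id[i], "_e", j)
      )
    }
  }
  spectra <- dplyr::bind_rows(specs)

  scaffs <- unique(library_tbl$scaffold)
  if (length(scaffs) < 3) {
    rlang::abort("Too few scaffolds for a 3-way scaffold-disjoint split",
                 class = "massembed_synth_error")
  }
  scaffs <- scaffs[sample.int(length(scaffs))]
  n_mol_of <- table(library_tbl$scaffold)[scaffs]
  cum <- cumsum(as.integer(n_mol_of)) / nrow(library_tbl)
  split_of <- ifelse(cum <= 0.7, "train", ifelse(cum <= 0.85, "val", "test"))
  # guarantee non-empty val and test
  if (!any(split_of == "val")) split_of[length(split_of) - 1L] <- "val"
  if (!any(split_of == "test")) split_of[length(split_of)] <- "test"
  names(split_of) <- scaffs
  library_tbl$split <- unname(split_of[library_tbl$scaffold])

  test_idx <- which(library_tbl$split == "test")
  mk_sets <- function(mode) {
    rows <- lapply(test_idx, function(i) {
      target <- library_tbl[i, ]
      if (mode == "by_mass") {
        dev <- abs(library_tbl$monoisotopic_mass -
                     target$monoisotopic_mass)
        pool <- library_tbl$smiles[order(dev)]
        cands <- unique(c(target$smiles, pool))
      } else {
        iso <- library_tbl$smiles[library_tbl$formula == target$formula]
        decoys <- setdiff(library_tbl$smiles, iso)
        cands <- unique(c(target$smiles, iso,
                          decoys[sample.int(length(decoys))]))
      }
      tibble::tibble(
        query_id = target$molecule_id,
        candidates = list(utils::head(cands, config$candidate_set_size))
      )
    })
    dplyr::bind_rows(rows)
  }
  structure(list(
    molecules = library_tbl, spectra = spectra,
    candidates_by_mass = mk_sets("by_mass"),
    candidates_by_formula = mk_sets("by_formula"),
    config = config
  ), class = "synth_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits the standard on-disk artifacts - `spectra.mgf`, `candidates.json`
#' (by mass), and `molecules.tsv` - so generated data exercises the real
#' I/O path.
#'
#' @param dataset A `synth_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mgf(dataset$spectra, file.path(dir, "spectra.mgf"))
  cands <- stats::setNames(dataset$candidates_by_mass$candidates,
                           dataset$candidates_by_mass$query_id)
  jsonlite::write_json(cands, file.path(dir, "candidates.json"))
  mols <- dataset$molecules[, c("molecule_id", "smiles", "formula",
                                "monoisotopic_mass", "scaffold", "split")]
  utils::write.table(mols, file.path(dir, "molecules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
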