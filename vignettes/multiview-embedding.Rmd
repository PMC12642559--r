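---
title: "Multiview contrastive embedding of molecules and MS/MS spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiview contrastive embedding of molecules and MS/MS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(massembed)
```

## The annotation problem

Untargeted metabolomics measures tandem mass spectra (MS/MS): lists of
fragment-ion peaks, each an m/z value with an intensity, produced by
fragmenting an ionized metabolite. Assigning a chemical structure to a
measured spectrum — metabolite annotation — is the field's central
bottleneck: spectral libraries cover a small fraction of chemistry, so
practitioners rank *candidate* structures (retrieved by precursor mass or
by assigned molecular formula) by their compatibility with the query
spectrum.

`massembed` learns a joint embedding space over **four views** of a
metabolite datum:

* **mol** — the molecular graph (atoms as nodes, bonds as edges),
* **fp** — a binary Morgan fingerprint (1024 bits, radius 5),
* **s** — an individual MS/MS spectrum, represented as a set of
  formula-annotated peaks,
* **cs** — the consensus spectrum, the formula-keyed union of all spectra
  of one molecule (max intensity per formula), aggregating measurements
  across collision energies.

Matching views of the same molecule are pulled together and non-matching
pairs pushed apart. At inference a query spectrum (or consensus spectrum)
is embedded and candidates are ranked by cosine similarity under one of
four *ranking views*: `mol-s`, `fp-s`, `mol-cs`, `fp-cs`.

## Spectral representation

Peaks are annotated with **subformulas** of the parent formula: the
candidate subformula (element-wise at most the parent over the 14-element
universe C,H,O,N,P,S,Cl,F,Br,I,B,As,Si,Se) whose adduct ion mass falls
within ±20 ppm of the observed m/z, minimizing |ppm error|. Only the 60
most abundant peaks are kept, *before* matching (the alternative —
annotate first, then keep 60 — changes little on clean data but is
ambiguous in general; we freeze selection-then-annotation and document it
here). Unannotated peaks are dropped; intensities are divided by the
maximum surviving intensity. Ties between equally close subformulas break
on the lexicographically smallest formula string, making annotation
deterministic under peak-order shuffles.

Every peak becomes a 15-vector: 14 element counts, each divided by the
highest count of that element observed in the *training* annotations (the
element scaler, floored at 1 and frozen after fitting — validation and
test data reuse it, so no test statistics leak into the representation),
plus the normalized intensity. Counts exceeding a training maximum produce
entries above 1; they are logged, not clipped, because clipping would
silently alias distinct formulas.

Consensus spectra are built per split by max-merging normalized
intensities. Merging normalized (rather than raw) intensities keeps the
consensus in [0, 1] without a second normalization pass; since constituent
spectra are max-normalized, the merge is still a pure union-with-max and
every constituent's formula set is a subset of its consensus.

The comparative *binned* variant (`spectral = "binned"`) replaces the
peak-set representation by a fixed 10,000-bin vector (0.1 Da over 0–1000
m/z, max-normalized) and the spectral encoders by 3-layer MLPs.

## Encoders and objective

All four encoders emit vectors of one shared dimension:

* **mol**: a 3-layer graph convolution (symmetric-normalized adjacency
  with self-loops) over the featurized graph, mean-pooled, then a 2-layer
  MLP head. Node features encode atom type, atomic mass, valence, ring
  membership, formal charge, radical electrons, chirality, degree,
  hydrogen count and aromaticity; bond features (type, ring, conjugation,
  stereo) are produced by the featurizer but, as in classical GCNs, not
  consumed by the convolution.
* **fp**: a 3-layer MLP on the fingerprint bits.
* **s** and **cs**: a 3-layer MLP per peak, then a transformer encoder
  (2 layers, 2 attention heads, no positional encoding — a peak set has no
  order), masked mean pooling, and a linear head. The two spectral
  encoders share the architecture but have independent weights.

Numeric node features are min–max scaled by fixed constants (mass/100,
valence/8, degree/6, H-count/4, charge/3) rather than dataset statistics,
so featurization is dataset-independent and checkpoints are portable.
Exact layer widths are configuration, defaulting to 256 everywhere
(`encoder_config()`); the desk-scale experiments in this package use 64.

The objective is an all-pairs contrastive loss. The discriminator is
`h(u, v) = exp(cos(u, v) / tau)` with temperature `tau = 0.05`; each
directed term is the InfoNCE cross-entropy with in-batch negatives (mean
over anchors), each unordered view pair contributes both directions, and
the total sums the C(4,2) = 6 pairs — 12 directed terms. Batches contain
at most one spectrum per molecule, so in-batch negatives are never
spectra of the anchor's own molecule. Embeddings are not L2-normalized at
encoder output; normalization lives inside the cosine, which is what makes
the loss invariant to positive rescaling of any view.

Training uses Adam (default moments, no weight decay, no schedule); the
full-scale defaults are learning rate 7e-05, 1500 epochs, batch 64.
Last-epoch parameters are kept by default; validation-based selection is
available (`select_best`) but off by default. All randomness — initialization, batch shuffles, spectrum
sampling, dropout — flows from one integer seed, and training is
bit-reproducible for a fixed seed on one platform.

The networks are evaluated and differentiated by a small reverse-mode
autodiff tape on plain matrices, written for this package; gradients are
verified against central finite differences through every encoder in the
test suite.

## Ranking, aggregation, metrics

`rank_candidates()` scores candidates by cosine similarity and assigns
1-based ranks with a **worst-of-tie** rule (tied candidates all get the
worst rank of their group), applied identically in metrics and
aggregation; the rule never flatters the method. With several spectra per
query molecule, two paradigms are supported: *aggregate-then-rank* (build
the consensus spectrum, rank once under `mol-cs`/`fp-cs`) and
*rank-then-aggregate* (rank per spectrum, then fuse by mean rank or by
summed reciprocal rank). With a single spectrum the consensus degenerates
to that spectrum's peak map.

Retrieval quality is reported as rank@k (percentage of queries whose true
molecule ranks in the top k) and MCES@1, the mean maximum-common-edge-
subgraph distance `|E_A| + |E_B| - 2|MCES|` between the target and the
top-ranked candidate. `mces_distance()` is exact: a branch-and-bound over
partial injective vertex maps with atoms matched on element and bonds on
bond type (aromatic is its own type — the strictest chemically meaningful
choice, since the metric's exact label conventions are not standardized).
Exact search is exponential, so molecules above a size cap (default 20
heavy atoms) are refused rather than silently approximated; the test
suite cross-checks the search against an independent igraph/VF2
enumeration oracle on a 12-molecule fixture set.

## The synthetic data generator

Real benchmark corpora require large downloads and GPU-scale training, so
the package ships a first-class generator that reproduces the
*statistical structure* the method assumes, at desk scale:

* a deterministic combinatorial SMILES grammar over C/H/O/N/S (ring and
  chain scaffolds with small substituents), deduplicated by canonical
  SMILES; the scaffold template is recorded and splits are
  scaffold-disjoint — a desk-scale proxy for structure-separated
  benchmark splits;
* three spectra per molecule by default, one per pseudo-collision-energy
  (10/20/40) — mirroring the common three-energy acquisition and the
  evaluation subset where each molecule has exactly three spectra;
* peaks are **connected subgraph fragments** of the molecular graph (plus
  one hydrogen per broken bond, capped at the parent's hydrogen count),
  so every true peak carries a genuine subformula *and* structural signal
  the graph view can exploit — with random subformulas instead, mol–s
  alignment would be unlearnable and end-to-end tests vacuous;
* higher energy shifts fragment sizes smaller (Beta-distributed size
  fraction with mean 1/(1 + energy/20));
* m/z error is Gaussian with 5 ppm sd by default (comfortably inside the
  20 ppm matching window), intensities are log-normal (sd 0.5), and noise
  peaks are added at rate 0.05 at uniform m/z — modest imperfections a
  clean instrument run would show. One RNG stream per dataset, seeded
  from the config, makes every fixture reproducible.

What the generator does **not** emulate: real fragmentation chemistry
(bond energies, rearrangements), isotope patterns, multiply charged
fragments, adduct heterogeneity within a molecule, and library-scale
chemical diversity. Passing tests on synthetic data therefore demonstrate
that the machinery — annotation, encoders, loss, ranking — is wired
correctly and learns when signal exists; they say nothing quantitative
about accuracy on real corpora.

## Desk-scale experiment sizes

The end-to-end experiment used by the tests and by
`scripts/acceptance.R` trains on 50 molecules × 3 spectra with embedding
dimension 64, batch size 32, 200 epochs, learning rate 1e-3 (Adam at this
small scale pairs naturally with a larger step than the full-scale
recipe), and evaluates held-in retrieval against 16-candidate sets
(target + 15 seeded decoys). These sizes were chosen once as the smallest
configuration at which the contrastive signal reliably separates the
library; the qualitative finding it reproduces is that consensus-spectrum
ranking (`mol-cs`) is at least competitive with single-spectrum ranking
(`mol-s`).

## Numerical choices and degenerate inputs

* Subformula enumeration is exact: full enumeration of the parent's
  count grid up to 2e5 combinations, beyond that a per-peak
  meet-in-the-middle split over the element set. Desk-scale parents
  enumerate directly.
* Annotation of a spectrum none of whose peaks match yields an empty
  annotated spectrum with a warning; such spectra are dropped by
  `prepare_dataset()`.
* Spectra with zero annotated peaks cannot be encoded (error), as the
  set encoder has no tokens to attend over.
* A contrastive batch needs at least 2 molecules (no negatives
  otherwise); `make_batches()` refuses datasets smaller than the batch
  size and keeps a trailing partial batch only if it has ≥ 2 molecules.
* Checkpoints are single JSON files with doubles serialized at 17
  significant digits: save → load → save is byte-identical, and a
  version-tag mismatch fails loudly.
* The MGF dialect accepts case-insensitive keys, `PEPMASS` with an
  optional second token, and reads the adduct from `ADDUCT=` or
  `PRECURSOR_TYPE=`; how adducts are encoded in MGF headers is not
  standardized, so this convention is a documented package choice.

## Known limitations

* The exact MCES is exponential and capped at small molecules; the
  approximate relaxations used by large-scale benchmarks are out of
  scope.
* Peak annotation assumes every fragment carries the precursor adduct;
  fragments that lose or exchange the adduct are mis-assigned or
  dropped.
* The encoders run on CPU in plain R; the implementation targets
  desk-scale experiments (tens to hundreds of molecules), not the
  ~200k-spectrum corpora of public benchmarks.
* E/Z bond stereo and tetrahedral chirality are carried as featurizer
  slots but are not perceived from 2-D structure input, so they are
  effectively constant in practice.
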