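# Molecule parsing and the two molecular views (graph, fingerprint).
#
# SMILES handling (canonicalization, atom/bond tables, ring and aromaticity
# perception) is delegated to OpenBabel through ChemmineR/ChemmineOB; on top
# of that the package derives implicit hydrogen counts, formulas restricted
# to the 14-element universe, the featurized graph, and a deterministic
# Morgan (circular) fingerprint.

# SDF V2000 charge codes -> formal charge
.CHARGE_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L,
                  `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)

# allowed valences; implicit H fills up to the smallest allowed valence
.VALENCES <- list(
  C = 4L, H = 1L, O = 2L, N = 3L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  Cl = 1L, F = 1L, Br = 1L, I = 1L, B = 3L, As = c(3L, 5L), Si = 4L,
  Se = c(2L, 4L, 6L)
)

ob_canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (!nzchar(s)) {
      rlang::abort("Empty SMILES string", class = "massembed_smiles_error")
    }
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = s)),
      error = function(e) ""
    )
    out <- strsplit(out, "[ \t\r\n]+")[[1]]
    if (!length(out) || !nzchar(out[1])) {
      rlang::abort(paste0("Unparseable SMILES: '", s, "'"),
                   class = "massembed_smiles_error")
    }
    out[1]
  }, character(1), USE.NAMES = FALSE)
}

#' Test whether SMILES strings are parseable
#'
#' @param smiles Character vector.
#' @return Logical vector, `TRUE` where the SMILES parses and contains only
#'   supported elements.
#' @export
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    ok <- tryCatch({
      parse_molecules(s)
      TRUE
    }, error = function(e) FALSE)
    ok
  }, logical(1), USE.NAMES = FALSE)
}

# degenerate molecules with a single heavy atom (e.g. "C", "[NH4+]") are
# not representable as ChemmineR SDF objects (no bond block); build the
# one-node graph directly from the canonical SMILES atom token
.SINGLE_ATOM_RE <- "^\\[?([A-Z][a-z]?)(H([0-9]*))?([+-][0-9]*)?\\]?$"

.single_atom_graph <- function(canon) {
  el <- sub(.SINGLE_ATOM_RE, "\\1", canon)
  if (!(el %in% ELEMENTS)) {
    rlang::abort(
      paste0("Element ", el, " is not in the supported set {",
             paste(ELEMENTS, collapse = ","), "}"),
      class = "massembed_element_error"
    )
  }
  chg_tok <- sub(.SINGLE_ATOM_RE, "\\4", canon)
  charge <- if (chg_tok == "") 0L else {
    sign <- if (substr(chg_tok, 1, 1) == "+") 1L else -1L
    mag <- substr(chg_tok, 2, nchar(chg_tok))
    sign * (if (mag == "") 1L else as.integer(mag))
  }
  if (grepl("\\[", canon)) {
    h_tok <- sub(.SINGLE_ATOM_RE, "\\2", canon)
    n_h <- if (h_tok == "") 0L else {
      cnt <- sub(.SINGLE_ATOM_RE, "\\3", canon)
      if (cnt == "") 1L else as.integer(cnt)
    }
  } else {
    allowed <- pmax(.VALENCES[[el]] + charge, 0L)
    n_h <- min(allowed)
  }
  structure(list(
    element = el, charge = charge, radical = FALSE, parity = 0L,
    n_h = as.integer(n_h), degree = 0L, bondsum = 0L,
    in_ring = FALSE, aromatic = FALSE,
    bonds = data.frame(a = integer(0), b = integer(0), order = integer(0),
                       in_ring = logical(0), aromatic = logical(0),
                       conjugated = logical(0), stereo = integer(0))
  ), class = "mol_graph")
}

# build the internal graph record for one SDF molecule
.sdf_to_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  n <- length(element)
  bad <- setdiff(unique(element), c(ELEMENTS, "H"))
  if (length(bad)) {
    rlang::abort(
      paste0("Element ", bad[1], " is not in the supported set {",
             paste(ELEMENTS, collapse = ","), "}"),
      class = "massembed_element_error"
    )
  }
  charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charge <- .CHARGE_CODE[as.character(pmin(pmax(charge_code, 0), 7))]
  charge[is.na(charge)] <- 0L
  radical <- charge_code == 4
  parity <- if ("C7" %in% colnames(ab)) as.integer(ab[, "C7"]) else
    integer(n)
  parity[is.na(parity) | parity > 2 | parity < 0] <- 0L

  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(a = as.integer(bb[, "C1"]),
                        b = as.integer(bb[, "C2"]),
                        order = as.integer(bb[, "C3"]))
  }

  # fold explicit hydrogens into their heavy neighbor
  explicit_h <- rep(0L, n)
  if (any(element == "H")) {
    h_idx <- which(element == "H")
    for (h in h_idx) {
      nb <- c(bonds$b[bonds$a == h], bonds$a[bonds$b == h])
      for (x in nb) explicit_h[x] <- explicit_h[x] + 1L
    }
    keep <- setdiff(seq_len(n), h_idx)
    remap <- match(seq_len(n), keep)
    bonds <- bonds[!(bonds$a %in% h_idx | bonds$b %in% h_idx), , drop = FALSE]
    bonds$a <- remap[bonds$a]; bonds$b <- remap[bonds$b]
    element <- element[keep]; charge <- charge[keep]
    radical <- radical[keep]; parity <- parity[keep]
    explicit_h <- explicit_h[keep]
    n <- length(keep)
  }

  # ring perception via ChemmineR; aromaticity decided here with a
  # Huckel-style rule on the kekulized structure (each ring atom must be
  # sp2-capable: an in-ring double bond contributes 1 pi electron, a
  # lone-pair heteroatom with only single ring bonds contributes 2, an
  # exocyclic double bond contributes 0; aromatic iff the count is 4k + 2)
  in_ring_atom <- rep(FALSE, n)
  aromatic_atom <- rep(FALSE, n)
  ring_pairs <- character(0)
  arom_pairs <- character(0)
  if (nrow(bonds) >= n && n >= 3) {  # at least one cycle possible
    rr <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = FALSE)),
      error = function(e) NULL
    )
    if (!is.null(rr)) {
      ring_list <- if (is.list(rr) && !is.null(rr$RINGS)) rr$RINGS else rr
      has_double <- function(a, b = NULL) {
        sel <- (bonds$a == a | bonds$b == a) & bonds$order == 2L
        if (!is.null(b)) {
          sel <- sel & (bonds$a %in% b & bonds$b %in% b)
        }
        any(sel)
      }
      for (k in seq_along(ring_list)) {
        idx <- as.integer(sub("^.*_", "", ring_list[[k]]))
        in_ring_atom[idx] <- TRUE
        m <- length(idx)
        pr <- vapply(seq_len(m), function(i) {
          e <- sort(c(idx[i], idx[if (i == m) 1 else i + 1]))
          paste(e, collapse = "-")
        }, character(1))
        ring_pairs <- c(ring_pairs, pr)
        pi_e <- 0L; ok <- TRUE
        for (a in idx) {
          if (has_double(a, idx)) pi_e <- pi_e + 1L
          else if (element[a] %in% c("N", "O", "S", "P", "Se") &&
                     !has_double(a)) pi_e <- pi_e + 2L
          else if (has_double(a)) pi_e <- pi_e + 0L  # exocyclic double
          else { ok <- FALSE; break }
        }
        if (ok && pi_e %% 4L == 2L) {
          aromatic_atom[idx] <- TRUE
          arom_pairs <- c(arom_pairs, pr)
        }
      }
    }
  }
  bond_key <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b), sep = "-")
  bonds$in_ring <- bond_key %in% ring_pairs
  bonds$aromatic <- bond_key %in% arom_pairs

  # implicit hydrogens from allowed valences (kekulized bond orders)
  bondsum <- rep(0L, n)
  for (i in seq_len(nrow(bonds))) {
    bondsum[bonds$a[i]] <- bondsum[bonds$a[i]] + bonds$order[i]
    bondsum[bonds$b[i]] <- bondsum[bonds$b[i]] + bonds$order[i]
  }
  n_h <- integer(n)
  for (i in seq_len(n)) {
    # cations gain a bonding slot per unit charge, anions lose one
    allowed <- pmax(.VALENCES[[element[i]]] + charge[i], 0L)
    v <- allowed[allowed >= bondsum[i]]
    v <- if (length(v)) min(v) else bondsum[i]
    n_h[i] <- max(0L, v - bondsum[i] - as.integer(radical[i])) +
      explicit_h[i]
  }

  degree <- rep(0L, n)
  for (i in seq_len(nrow(bonds))) {
    degree[bonds$a[i]] <- degree[bonds$a[i]] + 1L
    degree[bonds$b[i]] <- degree[bonds$b[i]] + 1L
  }

  # conjugation: aromatic bonds, multiple bonds touching another multiple
  # bond, and single bonds bridging two unsaturated atoms
  has_multi <- rep(FALSE, n)
  for (i in seq_len(nrow(bonds))) {
    if (bonds$order[i] >= 2 || bonds$aromatic[i]) {
      has_multi[bonds$a[i]] <- TRUE
      has_multi[bonds$b[i]] <- TRUE
    }
  }
  conj <- logical(nrow(bonds))
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a[i]; b <- bonds$b[i]
    conj[i] <- bonds$aromatic[i] ||
      (bonds$order[i] >= 2 && (degree[a] > 1 || degree[b] > 1) &&
         any(has_multi[setdiff(c(
           bonds$b[bonds$a %in% c(a, b)], bonds$a[bonds$b %in% c(a, b)]
         ), c(a, b))])) ||
      (bonds$order[i] == 1 && has_multi[a] && has_multi[b])
  }
  bonds$conjugated <- conj
  # E/Z assignment is not perceived from 2-D SDF; stereo stays "none"
  bonds$stereo <- rep(0L, nrow(bonds))

  structure(list(
    element = element, charge = as.integer(charge), radical = radical,
    parity = parity, n_h = n_h, degree = degree, bondsum = bondsum,
    in_ring = in_ring_atom, aromatic = aromatic_atom, bonds = bonds
  ), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", length(x$element), " heavy atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

graph_formula <- function(g) {
  counts <- stats::setNames(integer(length(ELEMENTS)), ELEMENTS)
  for (e in g$element) counts[e] <- counts[e] + 1L
  counts["H"] <- counts["H"] + sum(g$n_h)
  counts
}

#' Parse SMILES strings into molecule records
#'
#' Canonicalizes each SMILES, builds the heavy-atom graph (implicit
#' hydrogens as a node attribute), and derives the molecular formula over
#' the supported 14-element universe and the monoisotopic mass from the
#' package's internal exact-mass table.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Optional molecule identifiers (defaults to `mol_1`, ...).
#' @return A tibble with one row per molecule: `molecule_id`, `smiles`
#'   (canonical), `formula` (string), `monoisotopic_mass` (Da), and a
#'   `graph` list-column of `mol_graph` objects.
#' @examples
#' \dontrun{
#' parse_molecules(c("OCC1OC(O)C(O)C(O)C1O", "CCO"))
#' }
#' @export
parse_molecules <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (is.null(ids)) ids <- paste0("mol_", seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  canon <- ob_canonical_smiles(smiles)
  single <- grepl(.SINGLE_ATOM_RE, canon)
  sdfs <- if (all(single)) NULL else
    suppressWarnings(ChemmineR::smiles2sdf(canon[!single]))
  sdf_pos <- cumsum(!single)
  graphs <- lapply(seq_along(canon), function(i) {
    if (single[i]) .single_atom_graph(canon[i])
    else .sdf_to_graph(sdfs[[sdf_pos[i]]])
  })
  counts <- lapply(graphs, graph_formula)
  tibble::tibble(
    molecule_id = as.character(ids),
    smiles = canon,
    formula = vapply(counts, format_formula, character(1)),
    monoisotopic_mass = vapply(counts, function(cc) sum(cc * ELEMENT_MASS),
                               numeric(1)),
    graph = graphs
  )
}

#' @rdname parse_molecules
#' @export
parse_molecule <- function(smiles, ids = NULL) parse_molecules(smiles, ids)

# ---- graph featurization ----------------------------------------------------

.ATOM_TYPES <- c(ELEMENTS, "other")

#' Dimensions of the graph featurization
#'
#' The node layout is: atom-type one-hot (15 = 14 elements + other),
#' atomic mass / 100, total valence / 8, ring membership, formal charge / 3,
#' radical flag, chirality one-hot (none/CW/CCW), heavy-atom degree / 6,
#' hydrogen count / 4, aromaticity. The edge layout is: bond-type one-hot
#' (single/double/triple/aromatic), ring membership, conjugation, stereo
#' one-hot (none/Z/E). Numeric features are scaled by fixed constants so the
#' featurization is dataset-independent. Layout version 1.
#'
#' @return Named list with `d_node` and `d_edge`.
#' @export
graph_feature_dims <- function() list(d_node = 26L, d_edge = 9L)

#' Featurize a molecular graph
#'
#' Encodes the ten node properties (atom type, atomic mass, valence, ring
#' membership, formal charge, radical electrons, chirality, degree, number
#' of hydrogens, aromaticity) and four bond properties (bond type, ring
#' membership, conjugation, stereo configuration) documented in
#' [graph_feature_dims()].
#'
#' @param graph A `mol_graph` (from the `graph` column of
#'   [parse_molecules()]).
#' @return List with `node_features` (n_atoms x d_node matrix),
#'   `edge_index` (2 x n_bonds integer matrix, 1-based, undirected), and
#'   `edge_features` (n_bonds x d_edge matrix).
#' @export
featurize_graph <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  n <- length(graph$element)
  if (n == 0) rlang::abort("Graph has zero atoms",
                           class = "massembed_graph_error")
  dims <- graph_feature_dims()
  X <- matrix(0, n, dims$d_node)
  type_idx <- match(graph$element, .ATOM_TYPES)
  type_idx[is.na(type_idx)] <- length(.ATOM_TYPES)
  for (i in seq_len(n)) {
    X[i, type_idx[i]] <- 1
    X[i, 16] <- ELEMENT_MASS[graph$element[i]] / 100
    X[i, 17] <- (graph$bondsum[i] + graph$n_h[i]) / 8
    X[i, 18] <- as.numeric(graph$in_ring[i])
    X[i, 19] <- graph$charge[i] / 3
    X[i, 20] <- as.numeric(graph$radical[i])
    X[i, 21 + min(graph$parity[i], 2)] <- 1   # cols 21:23 chirality one-hot
    X[i, 24] <- graph$degree[i] / 6
    X[i, 25] <- graph$n_h[i] / 4
    X[i, 26] <- as.numeric(graph$aromatic[i])
  }
  m <- nrow(graph$bonds)
  E <- matrix(0, m, dims$d_edge)
  if (m > 0) {
    for (i in seq_len(m)) {
      bt <- if (graph$bonds$aromatic[i]) 4L else min(graph$bonds$order[i], 3L)
      E[i, bt] <- 1
      E[i, 5] <- as.numeric(graph$bonds$in_ring[i])
      E[i, 6] <- as.numeric(graph$bonds$conjugated[i])
      E[i, 7 + min(graph$bonds$stereo[i], 2)] <- 1  # cols 7:9 stereo one-hot
    }
  }
  list(
    node_features = X,
    edge_index = rbind(graph$bonds$a, graph$bonds$b),
    edge_features = E
  )
}

# ---- Morgan fingerprint -----------------------------------------------------

# 32-bit arithmetic on doubles (portable, no integer overflow)
.mul32 <- function(a, b) {
  hi <- ((a %/% 65536) * b) %% 65536
  (hi * 65536 + (a %% 65536) * b) %% 4294967296
}
.xor32 <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  hi * 65536 + lo
}
# FNV-1a over the 4 bytes of each (32-bit coerced) integer in `v`
.hash_ints <- function(v) {
  h <- 2166136261
  for (x in v) {
    x <- x %% 4294967296
    for (s in c(1, 256, 65536, 16777216)) {
      h <- .xor32(h, (x %/% s) %% 256)
      h <- .mul32(h, 16777619)
    }
  }
  h
}

#' Binary Morgan (circular) fingerprint
#'
#' A hashed circular fingerprint: each atom's environment at radii
#' 0..`radius` is summarized by an invariant (element, degree, hydrogen
#' count, charge, aromaticity, ring membership at radius 0; a hash of the
#' sorted labeled neighborhood thereafter) and folded into `nbits` bits.
#' Hashing uses a fixed FNV-1a scheme, so bit patterns are identical across
#' platforms and runs, and depend only on the canonical structure, not on
#' the SMILES spelling.
#'
#' @param graph A `mol_graph`, or a one-row tibble from [parse_molecules()].
#' @param nbits Fingerprint length (default 1024).
#' @param radius Maximum environment radius (default 5).
#' @return Integer vector of 0/1 of length `nbits`.
#' @export
morgan_fingerprint <- function(graph, nbits = 1024L, radius = 5L) {
  if (is.data.frame(graph)) graph <- graph$graph[[1]]
  stopifnot(inherits(graph, "mol_graph"))
  n <- length(graph$element)
  # adjacency with bond labels (aromatic = 4)
  nb <- vector("list", n)
  if (nrow(graph$bonds)) {
    for (i in seq_len(nrow(graph$bonds))) {
      a <- graph$bonds$a[i]; b <- graph$bonds$b[i]
      lab <- if (graph$bonds$aromatic[i]) 4L else graph$bonds$order[i]
      nb[[a]] <- rbind(nb[[a]], c(lab, b))
      nb[[b]] <- rbind(nb[[b]], c(lab, a))
    }
  }
  inv <- vapply(seq_len(n), function(i) {
    .hash_ints(c(match(graph$element[i], .ATOM_TYPES), graph$degree[i],
                 graph$n_h[i], graph$charge[i] + 8L,
                 as.integer(graph$aromatic[i]),
                 as.integer(graph$in_ring[i])))
  }, numeric(1))
  bits <- integer(nbits)
  bits[(inv %% nbits) + 1] <- 1L
  if (radius > 0) {
    for (r in seq_len(radius)) {
      new_inv <- inv
      for (i in seq_len(n)) {
        if (is.null(nb[[i]])) next
        pairs <- cbind(nb[[i]][, 1], inv[nb[[i]][, 2]])
        ord <- order(pairs[, 1], pairs[, 2])
        new_inv[i] <- .hash_ints(c(r, inv[i], t(pairs[ord, , drop = FALSE])))
      }
      inv <- new_inv
      bits[(inv %% nbits) + 1] <- 1L
    }
  }
  bits
}

#' Fingerprint matrix for a molecule table
#'
#' @param molecules Tibble from [parse_molecules()].
#' @inheritParams morgan_fingerprint
#' @return Matrix (n_molecules x nbits) of 0/1, rownames = molecule ids.
#' @export
fingerprint_matrix <- function(molecules, nbits = 1024L, radius = 5L) {
  out <- t(vapply(molecules$graph,
                  function(g) morgan_fingerprint(g, nbits, radius),
                  integer(nbits)))
  rownames(out) <- molecules$molecule_id
  out
}
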