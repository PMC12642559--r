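# Exact maximum common edge subgraph (MCES) distance between two labeled
# molecular graphs:
#
#   d(A, B) = |E_A| + |E_B| - 2 |MCES(A, B)|
#
# where the MCES is the largest graph isomorphic to edge subgraphs of both,
# with atoms matching on element and bonds on bond type (aromatic is its
# own type, distinct from single/double). Computed exactly by
# branch-and-bound over partial injective vertex maps, so it is feasible
# for small molecules only (default cap 20 heavy atoms).

.mces_edge_label <- function(g) {
  if (!nrow(g$bonds)) return(integer(0))
  ifelse(g$bonds$aromatic, 4L, pmin(g$bonds$order, 3L))
}

#' Exact MCES distance between two molecules
#'
#' @param a,b `mol_graph` objects, or one-row tibbles from
#'   [parse_molecules()].
#' @param size_cap Maximum heavy-atom count per molecule (default 20); the
#'   exact search is exponential, so larger molecules are refused.
#' @return Non-negative integer distance; 0 iff the labeled structures are
#'   identical up to isomorphism.
#' @examples
#' \dontrun{
#' mols <- parse_molecules(c("CC", "CCO"))
#' mces_distance(mols$graph[[1]], mols$graph[[2]]) # 1
#' }
#' @export
mces_distance <- function(a, b, size_cap = 20L) {
  if (is.data.frame(a)) a <- a$graph[[1]]
  if (is.data.frame(b)) b <- b$graph[[1]]
  stopifnot(inherits(a, "mol_graph"), inherits(b, "mol_graph"))
  na <- length(a$element); nb <- length(b$element)
  if (na > size_cap || nb > size_cap) {
    rlang::abort(paste0("Molecule exceeds the exact-MCES size cap (",
                        size_cap, " heavy atoms); approximate MCES tooling ",
                        "is out of scope here"),
                 class = "massembed_mces_error")
  }
  # put the smaller graph on the A side
  if (na > nb) { tmp <- a; a <- b; b <- tmp; tmp <- na; na <- nb; nb <- tmp }
  ea <- nrow(a$bonds); eb <- nrow(b$bonds)
  if (ea == 0 || eb == 0) return(ea + eb)
  common <- .mces_search(a, b)
  ea + eb - 2L * common
}

# B&B over assignments of A's vertices (ordered by degree, descending) to
# unused same-element vertices of B, or skipped. The bound counts A edges
# that could still be matched.
.mces_search <- function(a, b) {
  na <- length(a$element)
  lab_a <- .mces_edge_label(a); lab_b <- .mces_edge_label(b)
  # adjacency label lookup for B
  nb <- length(b$element)
  Blab <- matrix(0L, nb, nb)
  for (i in seq_len(nrow(b$bonds))) {
    Blab[b$bonds$a[i], b$bonds$b[i]] <- lab_b[i]
    Blab[b$bonds$b[i], b$bonds$a[i]] <- lab_b[i]
  }
  ord <- order(a$degree, decreasing = TRUE)
  # neighbors of each A vertex among earlier-ordered vertices
  pos <- match(seq_len(na), ord)
  nbrs <- vector("list", na)
  for (i in seq_len(nrow(a$bonds))) {
    u <- a$bonds$a[i]; v <- a$bonds$b[i]; l <- lab_a[i]
    if (pos[u] < pos[v]) nbrs[[v]] <- rbind(nbrs[[v]], c(u, l))
    else nbrs[[u]] <- rbind(nbrs[[u]], c(v, l))
  }
  # upper bound on edges still matchable after step k: edges of A with at
  # least one endpoint at ord position > k
  later_edges <- integer(na + 1L)
  for (k in na:1) {
    cnt <- 0L
    for (i in seq_len(nrow(a$bonds))) {
      if (pos[a$bonds$a[i]] > k || pos[a$bonds$b[i]] > k) cnt <- cnt + 1L
    }
    later_edges[k + 1L] <- cnt
  }
  later_edges[1L] <- nrow(a$bonds)

  best <- 0L
  map <- integer(na)      # 0 = unassigned/skipped
  used <- logical(nb)
  cand_by_el <- split(seq_len(nb), b$element)

  rec <- function(k, matched) {
    if (matched > best) best <<- matched
    if (k > na) return(invisible(NULL))
    if (matched + later_edges[k] <= best) return(invisible(NULL))
    va <- ord[k]
    cands <- cand_by_el[[a$element[va]]]
    if (!is.null(cands)) {
      for (vb in cands) {
        if (used[vb]) next
        gain <- 0L
        nn <- nbrs[[va]]
        if (!is.null(nn)) {
          for (r in seq_len(nrow(nn))) {
            mu <- map[nn[r, 1L]]
            if (mu > 0L && Blab[mu, vb] == nn[r, 2L]) gain <- gain + 1L
          }
        }
        map[va] <<- vb; used[vb] <<- TRUE
        rec(k + 1L, matched + gain)
        map[va] <<- 0L; used[vb] <<- FALSE
      }
    }
    rec(k + 1L, matched)  # skip va
    invisible(NULL)
  }
  rec(1L, 0L)
  best
}
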