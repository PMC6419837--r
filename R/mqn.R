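# Molecular quantum numbers: a 42-dimensional integer descriptor counting
# atom, bond, polarity and topology features. Computed from the molecular
# graph; hydrogens are implicit (heavy-atom counts only, H counts derived
# from default valences).

.MQN_NAMES <- c(
  # atom counts
  "c", "f", "cl", "br", "i", "s", "p", "an", "cn", "ao", "co", "hac",
  # bond counts
  "asb", "adb", "atb", "csb", "cdb", "ctb", "rbc",
  # polarity counts
  "hbam", "hba", "hbdm", "hbd", "neg", "pos",
  # topology counts
  "asv", "adv", "atv", "aqv", "cdv", "ctv", "cqv",
  "r3", "r4", "r5", "r6", "r7", "r8", "r9", "rg10", "afr", "bfr")

# Smallest set of smallest rings. Exact for the molecule sizes this package
# handles (= small graphs): enumerates candidate short cycles per
# non-bridge edge via BFS shortest paths, then greedily selects a set of
# linearly independent cycles (over GF(2) edge space) of minimal total size.
.sssr <- function(g) {
  nb <- nrow(g$bonds)
  ncomp <- igraph::count_components(.graph_igraph(g))
  n_rings <- nb - length(g$elements) + ncomp  # cyclomatic number
  if (n_rings <= 0) return(list())
  ig <- .graph_igraph(g)
  cyc <- .cyclic_bonds(g)
  cands <- list()
  for (b in which(cyc)) {
    u <- g$bonds[b, 1]; v <- g$bonds[b, 2]
    ig2 <- igraph::delete_edges(ig, igraph::get_edge_ids(ig, c(u, v)))
    sp <- suppressWarnings(igraph::shortest_paths(ig2, from = u, to = v)$vpath[[1]])
    if (length(sp) > 1) cands[[length(cands) + 1L]] <- as.integer(sp)
  }
  if (!length(cands)) return(list())
  cands <- cands[order(lengths(cands))]
  # edge incidence vectors over GF(2)
  ekey <- paste(pmin(g$bonds[, 1], g$bonds[, 2]), pmax(g$bonds[, 1], g$bonds[, 2]))
  cycvec <- function(ring) {
    m <- length(ring)
    a <- ring; b <- c(ring[-1], ring[1])
    as.integer(ekey %in% paste(pmin(a, b), pmax(a, b)))
  }
  basis <- NULL
  rings <- list()
  for (cand in cands) {
    v <- cycvec(cand)
    # Gaussian elimination mod 2 against current basis
    w <- v
    if (!is.null(basis)) {
      for (r in seq_len(nrow(basis))) {
        piv <- which(basis[r, ] == 1L)[1]
        if (w[piv] == 1L) w <- (w + basis[r, ]) %% 2L
      }
    }
    if (any(w == 1L)) {
      basis <- rbind(basis, w)
      rings[[length(rings) + 1L]] <- cand
      if (length(rings) == n_rings) break
    }
  }
  rings
}

.mqn_one <- function(g) {
  v <- stats::setNames(integer(42), .MQN_NAMES)
  el <- g$elements
  na <- length(el)
  deg <- .graph_degrees(g)
  orders <- if (nrow(g$bonds)) g$bonds[, "order"] else integer(0)
  cyc_bond <- .cyclic_bonds(g)
  cyc_atom <- logical(na)
  if (any(cyc_bond)) {
    ca <- unique(as.vector(g$bonds[cyc_bond, 1:2]))
    cyc_atom[ca] <- TRUE
  }
  # atom counts
  v["c"] <- sum(el == "C"); v["f"] <- sum(el == "F"); v["cl"] <- sum(el == "Cl")
  v["br"] <- sum(el == "Br"); v["i"] <- sum(el == "I"); v["s"] <- sum(el == "S")
  v["p"] <- sum(el == "P")
  v["an"] <- sum(el == "N" & !cyc_atom); v["cn"] <- sum(el == "N" & cyc_atom)
  v["ao"] <- sum(el == "O" & !cyc_atom); v["co"] <- sum(el == "O" & cyc_atom)
  v["hac"] <- na
  # bond counts
  v["asb"] <- sum(!cyc_bond & orders == 1L); v["adb"] <- sum(!cyc_bond & orders == 2L)
  v["atb"] <- sum(!cyc_bond & orders == 3L)
  v["csb"] <- sum(cyc_bond & orders == 1L); v["cdb"] <- sum(cyc_bond & orders == 2L)
  v["ctb"] <- sum(cyc_bond & orders == 3L)
  if (nrow(g$bonds)) {
    rot <- !cyc_bond & orders == 1L &
      deg[g$bonds[, "a1"]] >= 2L & deg[g$bonds[, "a2"]] >= 2L
    v["rbc"] <- sum(rot)
  }
  # polarity: every N contributes one acceptor site, every O two; donors are
  # N/O carrying implicit hydrogens (implicit H = default valence - bond sum)
  val <- .graph_valences(g)
  defv <- .DEFAULT_VALENCE[el]
  implH <- pmax(0L, defv - val - abs(g$charges))
  isN <- el == "N"; isO <- el == "O"
  v["hbam"] <- sum(isN) + 2L * sum(isO)
  v["hba"] <- sum(isN | isO)
  v["hbdm"] <- sum(implH[isN | isO])
  v["hbd"] <- sum((isN | isO) & implH > 0L)
  v["neg"] <- sum(g$charges < 0L); v["pos"] <- sum(g$charges > 0L)
  # topology
  v["asv"] <- sum(!cyc_atom & deg == 1L); v["adv"] <- sum(!cyc_atom & deg == 2L)
  v["atv"] <- sum(!cyc_atom & deg == 3L); v["aqv"] <- sum(!cyc_atom & deg == 4L)
  v["cdv"] <- sum(cyc_atom & deg == 2L); v["ctv"] <- sum(cyc_atom & deg == 3L)
  v["cqv"] <- sum(cyc_atom & deg == 4L)
  rings <- .sssr(g)
  if (length(rings)) {
    sizes <- lengths(rings)
    for (s in sizes) {
      if (s <= 9) v[paste0("r", s)] <- v[paste0("r", s)] + 1L
      else v["rg10"] <- v["rg10"] + 1L
    }
    atom_ring_count <- integer(na)
    ekey <- paste(pmin(g$bonds[, 1], g$bonds[, 2]), pmax(g$bonds[, 1], g$bonds[, 2]))
    bond_ring_count <- integer(nrow(g$bonds))
    for (r in rings) {
      atom_ring_count[r] <- atom_ring_count[r] + 1L
      a <- r; b <- c(r[-1], r[1])
      bond_ring_count[ekey %in% paste(pmin(a, b), pmax(a, b))] <-
        bond_ring_count[ekey %in% paste(pmin(a, b), pmax(a, b))] + 1L
    }
    v["afr"] <- sum(atom_ring_count >= 2L)
    v["bfr"] <- sum(bond_ring_count >= 2L)
  }
  v
}

#' MQN fingerprints
#'
#' Computes the 42-dimension molecular quantum numbers descriptor for each
#' molecule: atom counts (12), bond counts (7), polarity counts (6) and
#' topology counts (17, including ring-size and fused-ring counts).
#'
#' @param smiles character vector of valid SMILES.
#' @return integer matrix, one row per molecule, 42 named columns.
#' @examples
#' mqn_fingerprint(c("c1ccccc1", "C1CCCCC1"))
#' @export
mqn_fingerprint <- function(smiles) {
  graphs <- parse_molgraph(smiles)
  bad <- vapply(graphs, is.null, TRUE)
  if (any(bad)) stop("invalid molecule(s): ", paste(smiles[bad], collapse = ", "))
  m <- t(vapply(graphs, .mqn_one, stats::setNames(integer(42), .MQN_NAMES)))
  rownames(m) <- smiles
  m
}
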