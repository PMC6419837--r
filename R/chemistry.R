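# Chemistry backend: all parsing, canonicalization and substructure matching
# is delegated to OpenBabel (via ChemmineOB/ChemmineR). Membership tests
# throughout the package compare OpenBabel canonical SMILES only; mixing
# canonical forms from different toolkits is never supported.

OB_OPTS <- data.frame(names = "e", args = "")  # continue past unreadable records

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to the toolkit canonical form. Unparseable strings
#' yield `NA_character_` rather than an error, so corpora can be processed
#' in bulk. The operation is idempotent: `canonicalize(canonicalize(s))`
#' equals `canonicalize(s)`.
#'
#' Because the underlying parser is permissive about valence (it will read
#' `CO=C` as a trivalent neutral oxygen), strings whose neutral C/N/O/...
#' atoms exceed their standard valences are also reported as failures —
#' hypervalent strings emitted by an undertrained model count as invalid,
#' not as novel molecules.
#'
#' @param smiles character vector of SMILES strings.
#' @param check_valence reject molecules with hypervalent neutral atoms
#'   (disable only for strings already known to be valence-legal).
#' @return character vector of the same length; `NA` marks parse failures.
#' @examples
#' canonicalize(c("OCC", "C1CCCCC1", "C1CC"))
#' @export
canonicalize <- function(smiles, check_valence = TRUE) {
  if (length(smiles) == 0) return(character(0))
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  # strings with whitespace or empty strings can never be SMILES and would
  # corrupt the title-based realignment below
  ok <- !is.na(smiles) & nzchar(smiles) & !grepl("[[:space:]]", smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  src <- paste0(smiles[idx], " t", seq_along(idx), "\n", collapse = "")
  res <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", src, options = OB_OPTS))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- regmatches(lines, regexpr("\t", lines), invert = TRUE)
    can <- vapply(parts, `[`, "", 1L)
    tag <- as.integer(sub("^t", "", trimws(vapply(parts, function(p) if (length(p) > 1) p[2] else "", ""))))
    keep <- !is.na(tag) & nzchar(can)
    out[idx[tag[keep]]] <- can[keep]
  }
  if (check_valence && any(!is.na(out))) {
    chk <- which(!is.na(out))
    good <- .standard_valence_ok(out[chk])
    out[chk[!good]] <- NA_character_
  }
  out
}

# TRUE when every neutral atom of a known element respects its standard
# valence (sum of bond orders; implicit hydrogens fill the remainder).
# Charged atoms and unknown elements are not judged.
.standard_valence_ok <- function(smiles) {
  graphs <- parse_molgraph(smiles)
  vapply(graphs, function(g) {
    if (is.null(g)) return(FALSE)
    known <- g$elements %in% names(.DEFAULT_VALENCE) & g$charges == 0L
    v <- .graph_valences(g)
    all(v[known] <= .DEFAULT_VALENCE[g$elements[known]])
  }, TRUE)
}

#' Test SMILES validity
#'
#' A string is valid when the chemistry toolkit can parse it into a molecule.
#' @param smiles character vector.
#' @return logical vector.
#' @export
is_valid_smiles <- function(smiles) !is.na(canonicalize(smiles))

# Parse one V2000 molblock (vector of lines, starting at the title line)
# into a molgraph. The fixed-width format is trivial; ChemmineR's reader is
# not used here because it drops zero-bond (single heavy atom) records.
.parse_molblock <- function(lines) {
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1) return(NULL)
  atoms <- lines[4 + seq_len(na)]
  elements <- trimws(substr(atoms, 32, 34))
  bonds <- if (nb > 0) {
    bl <- lines[4 + na + seq_len(nb)]
    cbind(a1 = as.integer(substr(bl, 1, 3)),
          a2 = as.integer(substr(bl, 4, 6)),
          order = as.integer(substr(bl, 7, 9)))
  } else {
    matrix(integer(0), ncol = 3, dimnames = list(NULL, c("a1", "a2", "order")))
  }
  charges <- integer(na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[[:space:]]+")[[1]])
    npair <- f[1]
    for (p in seq_len(npair)) charges[f[2 * p]] <- f[2 * p + 1]
  }
  g <- list(elements = elements, charges = charges, bonds = bonds)
  class(g) <- "molgraph"
  g
}

# Parse SMILES into light molecular graphs via an SDF round trip.
# Returns a list (same length as input) of molgraph objects:
#   list(elements = chr, charges = int, bonds = matrix[, c("a1","a2","order")])
# or NULL for unparseable entries.
parse_molgraph <- function(smiles) {
  res <- vector("list", length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles) & !grepl("[[:space:]]", smiles)
  if (!any(ok)) return(res)
  idx <- which(ok)
  src <- paste0(smiles[idx], " t", seq_along(idx), "\n", collapse = "")
  sdf <- suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", src, options = OB_OPTS))
  if (!nzchar(sdf)) return(res)
  records <- strsplit(sdf, "\\$\\$\\$\\$\n?")[[1]]
  for (rec in records) {
    lines <- strsplit(rec, "\n", fixed = TRUE)[[1]]
    lines <- lines[cumsum(nzchar(lines)) > 0 | nzchar(lines)]
    # leading blank lines may remain from the record separator; drop them
    while (length(lines) && !nzchar(trimws(lines[1])) ) lines <- lines[-1]
    if (length(lines) < 4) next
    tag <- as.integer(sub("^t", "", trimws(lines[1])))
    if (is.na(tag)) next
    g <- .parse_molblock(lines)
    if (!is.null(g)) res[[idx[tag]]] <- g
  }
  res
}

# Organic-subset symbols that can be written without brackets (neutral atoms).
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

.bond_symbol <- function(order) c("", "=", "#")[order]

# Write a molgraph as a (non-canonical) SMILES string: DFS spanning tree with
# ring-closure digits for the remaining edges. Only used on graphs the package
# itself builds (toy enumeration, carbon skeletons); the result is always
# passed through canonicalize() before use.
graph_to_smiles <- function(g) {
  n <- length(g$elements)
  if (n == 0) stop("empty molecular graph")
  bonds <- g$bonds
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]; o <- bonds[b, 3]
      adj[[i]] <- rbind(adj[[i]], c(j, o))
      adj[[j]] <- rbind(adj[[j]], c(i, o))
    }
  }
  visited <- logical(n)
  ring_bonds <- list()   # key "i-j" -> digit
  ring_at <- vector("list", n)  # atom -> list of c(digit, order)
  next_digit <- 0L
  # first pass: DFS to identify ring-closure edges
  find_rings <- function(i, parent) {
    visited[i] <<- TRUE
    nb <- adj[[i]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        j <- nb[r, 1]; o <- nb[r, 2]
        if (j == parent) { parent <- -1L; next }  # skip tree edge to parent once
        if (visited[j]) {
          key <- paste(min(i, j), max(i, j), sep = "-")
          if (is.null(ring_bonds[[key]])) {
            next_digit <<- next_digit + 1L
            ring_bonds[[key]] <<- next_digit
            ring_at[[i]] <<- c(ring_at[[i]], list(c(next_digit, o)))
            ring_at[[j]] <<- c(ring_at[[j]], list(c(next_digit, o)))
          }
        } else {
          find_rings(j, i)
        }
      }
    }
  }
  roots <- integer(0)
  for (i in seq_len(n)) {
    if (!visited[i]) {
      roots <- c(roots, i)
      find_rings(i, -1L)
    }
  }
  atom_token <- function(i) {
    el <- g$elements[i]
    if (el %in% .ORGANIC_SUBSET && g$charges[i] == 0L) el else paste0("[", el, "]")
  }
  digit_token <- function(d) if (d < 10) as.character(d) else sprintf("%%%02d", d)
  visited2 <- logical(n)
  write_atom <- function(i, parent) {
    visited2[i] <<- TRUE
    s <- atom_token(i)
    for (rc in ring_at[[i]]) s <- paste0(s, .bond_symbol(rc[2]), digit_token(rc[1]))
    nb <- adj[[i]]
    kids <- NULL
    if (!is.null(nb)) {
      skip_parent <- parent
      for (r in seq_len(nrow(nb))) {
        j <- nb[r, 1]
        if (j == skip_parent) { skip_parent <- -1L; next }
        key <- paste(min(i, j), max(i, j), sep = "-")
        if (!is.null(ring_bonds[[key]])) next
        if (!visited2[j]) kids <- rbind(kids, nb[r, , drop = FALSE])
      }
    }
    if (!is.null(kids) && nrow(kids) > 0) {
      for (r in seq_len(nrow(kids))) {
        sub <- paste0(.bond_symbol(kids[r, 2]), write_atom(kids[r, 1], i))
        s <- if (r < nrow(kids)) paste0(s, "(", sub, ")") else paste0(s, sub)
      }
    }
    s
  }
  # disconnected fragments (valid multi-fragment SMILES) are dot-joined
  paste(vapply(roots, write_atom, "", parent = -1L), collapse = ".")
}

#' Carbon skeleton of a molecule
#'
#' Replaces every heavy atom by carbon and sets all bond orders to single,
#' then canonicalizes. The skeleton is invariant under substitution of one
#' heteroatom by another, so it captures the bare graph topology of the
#' molecule, which is how membership of a topology in a reference space is
#' tested.
#'
#' @param smiles character vector of valid SMILES.
#' @return character vector of canonical skeleton SMILES.
#' @examples
#' carbon_skeleton("CCO")       # propane
#' carbon_skeleton("c1ccncc1")  # cyclohexane
#' @export
carbon_skeleton <- function(smiles) {
  graphs <- parse_molgraph(smiles)
  bad <- vapply(graphs, is.null, TRUE)
  if (any(bad)) {
    stop("invalid molecule(s): ", paste(smiles[bad], collapse = ", "))
  }
  raw <- vapply(graphs, function(g) {
    g$elements[] <- "C"
    g$charges[] <- 0L
    if (nrow(g$bonds) > 0) g$bonds[, "order"] <- 1L
    graph_to_smiles(g)
  }, "")
  out <- canonicalize(raw)
  if (anyNA(out)) stop("internal error: skeleton SMILES failed to canonicalize")
  out
}

# Count substructure matches of each SMARTS pattern in each molecule.
# Returns a matrix [molecule x pattern] of match counts.
smarts_match_matrix <- function(smiles, patterns) {
  m <- matrix(0L, nrow = length(smiles), ncol = length(patterns),
              dimnames = list(NULL, names(patterns)))
  if (length(smiles) == 0 || length(patterns) == 0) return(m)
  src <- paste0(smiles, " t", seq_along(smiles), "\n", collapse = "")
  sdf <- suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", src, options = OB_OPTS))
  if (!nzchar(sdf)) return(m)
  sdfstr <- ChemmineR::read.SDFstr(textConnection(sdf))
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(sdfstr))
  # single-atom records are dropped here; they cannot match multi-atom SMARTS
  sdfset <- sdfset[ChemmineR::validSDF(sdfset)]
  if (length(sdfset) == 0) return(m)
  heads <- vapply(ChemmineR::SDFset2SDF(sdfset), function(x) ChemmineR::header(x)[["Molecule_Name"]], "")
  tags <- as.integer(sub("^t", "", heads))
  for (p in seq_along(patterns)) {
    counts <- suppressWarnings(ChemmineR::smartsSearchOB(sdfset, patterns[[p]], uniqueMatches = FALSE))
    m[tags, p] <- as.integer(counts)
  }
  m
}

# Heavy-atom degree of every atom (number of heavy neighbours).
.graph_degrees <- function(g) {
  deg <- integer(length(g$elements))
  if (nrow(g$bonds) > 0) {
    t1 <- tabulate(g$bonds[, "a1"], nbins = length(deg))
    t2 <- tabulate(g$bonds[, "a2"], nbins = length(deg))
    deg <- t1 + t2
  }
  deg
}

# Sum of bond orders at every atom.
.graph_valences <- function(g) {
  v <- integer(length(g$elements))
  if (nrow(g$bonds) > 0) {
    for (b in seq_len(nrow(g$bonds))) {
      v[g$bonds[b, 1]] <- v[g$bonds[b, 1]] + g$bonds[b, 3]
      v[g$bonds[b, 2]] <- v[g$bonds[b, 2]] + g$bonds[b, 3]
    }
  }
  v
}

.DEFAULT_VALENCE <- c(C = 4L, N = 3L, O = 2L, F = 1L, S = 2L, P = 3L,
                      Cl = 1L, Br = 1L, I = 1L, B = 3L)

# igraph view of a molgraph (undirected, all atoms as vertices).
.graph_igraph <- function(g) {
  igraph::make_graph(as.vector(t(g$bonds[, c("a1", "a2"), drop = FALSE])),
                     n = length(g$elements), directed = FALSE)
}

# Logical vector: is each bond part of a ring (i.e. not a bridge)?
.cyclic_bonds <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0) return(logical(0))
  ig <- .graph_igraph(g)
  res <- rep(TRUE, nb)
  br <- igraph::bridges(ig)
  if (length(br)) {
    ends <- igraph::ends(ig, br)
    # match bridge endpoints back to bond rows
    key <- paste(pmin(g$bonds[, 1], g$bonds[, 2]), pmax(g$bonds[, 1], g$bonds[, 2]))
    bkey <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]))
    res[key %in% bkey] <- FALSE
  }
  res
}
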