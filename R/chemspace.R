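# Reference chemical spaces: finite sets of canonical SMILES with the uniform
# per-molecule probability p = 1/n, plus the carbon-skeleton set used for
# topology checks.

#' Build a reference chemical space
#'
#' A reference space is an indexed set of canonical SMILES representing a
#' finite target chemical space, e.g. an exhaustively enumerated database.
#' Inputs are canonicalized, parse failures dropped (and counted), and
#' duplicates removed, so every stored SMILES equals its own
#' re-canonicalization.
#'
#' @param smiles character vector of SMILES strings.
#' @param filters optional [enumeration_filters()] to attach; used by the
#'   violation labeller.
#' @param compute_skeletons compute the carbon-skeleton set (needed for
#'   topology labelling; costs one pass over the molecules).
#' @return object of class `reference_space` with elements `molecules`
#'   (sorted canonical SMILES), `n`, `p = 1/n`, `skeletons`, `filters`, and
#'   counts `parse_failures`, `duplicates_removed`.
#' @export
reference_space <- function(smiles, filters = NULL, compute_skeletons = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) stop("cannot build a reference space from zero molecules")
  can <- canonicalize(smiles)
  failures <- sum(is.na(can))
  if (failures > length(smiles) / 2) {
    stop(sprintf("%d of %d lines failed to parse; this does not look like a SMILES file",
                 failures, length(smiles)))
  }
  can <- can[!is.na(can)]
  if (length(can) == 0) stop("no valid molecules")
  mols <- sort(unique(can))
  dups <- length(can) - length(mols)
  skeletons <- if (compute_skeletons) sort(unique(carbon_skeleton(mols))) else NULL
  structure(list(
    molecules = mols,
    n = length(mols),
    p = 1 / length(mols),
    skeletons = skeletons,
    filters = filters,
    parse_failures = failures,
    duplicates_removed = dups
  ), class = "reference_space")
}

#' @export
print.reference_space <- function(x, ...) {
  cat(sprintf("Reference chemical space: n = %d molecules (p = %.3g each)\n", x$n, x$p))
  if (!is.null(x$skeletons))
    cat(sprintf("  distinct carbon skeletons: %d\n", length(x$skeletons)))
  if (!is.null(x$filters))
    cat("  enumeration filters attached\n")
  if (x$parse_failures || x$duplicates_removed)
    cat(sprintf("  dropped on load: %d parse failures, %d duplicates\n",
                x$parse_failures, x$duplicates_removed))
  invisible(x)
}

#' Membership test against a reference space
#' @param smiles canonical SMILES (canonicalize first if unsure).
#' @param space a `reference_space`.
#' @return logical vector.
#' @export
in_space <- function(smiles, space) {
  stopifnot(inherits(space, "reference_space"))
  smiles %in% space$molecules
}

#' Load a reference space from a SMILES file
#'
#' Reads a line-oriented SMILES file (one molecule per line, optional
#' tab-separated id), canonicalizes, drops failures and duplicates.
#' Errors if the file is empty or more than half the lines fail to parse.
#'
#' @param path file path.
#' @inheritParams reference_space
#' @return a `reference_space`.
#' @export
load_space <- function(path, filters = NULL, compute_skeletons = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty SMILES file: ", path)
  smiles <- vapply(strsplit(lines, "[\t ]+"), `[`, "", 1L)
  reference_space(smiles, filters = filters, compute_skeletons = compute_skeletons)
}

#' Write a reference space to disk
#'
#' Writes the sorted canonical SMILES one per line, plus a JSON sidecar
#' `<path>.json` recording `n`, `parse_failures` and `duplicates_removed`.
#'
#' @param space a `reference_space`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_space <- function(space, path) {
  stopifnot(inherits(space, "reference_space"))
  writeLines(space$molecules, path)
  jsonlite::write_json(
    list(n = space$n, parse_failures = space$parse_failures,
         duplicates_removed = space$duplicates_removed),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Enumeration filters

#' Enumeration filters for a toy GDB-like space
#'
#' The predicates that define which molecules belong to the enumerated
#' space. Each disallowed substructure pattern carries a unique
#' human-readable label, reused verbatim by [check_filters()] and the
#' violation labeller.
#'
#' Bond rules are named predicates on double/triple bond placement; the
#' built-in ones are `"triple_bond_in_ring"` and
#' `"unsaturation_in_3_ring"` (double or triple bonds inside a
#' 3-membered ring).
#'
#' @param max_heavy_atoms maximum number of heavy (non-hydrogen) atoms.
#' @param allowed_elements element symbols allowed.
#' @param max_heteroatom_ratio maximum heteroatoms/carbons ratio; applies
#'   only to carbon-containing molecules (the ratio is undefined without
#'   carbon, so bare N/O single atoms pass).
#' @param disallowed_groups named character vector of SMARTS patterns for
#'   disallowed functional groups.
#' @param disallowed_heteroatom_neighbors character vector of SMARTS
#'   patterns for disallowed heteroatom adjacencies.
#' @param max_bond_order highest bond order the space admits (1-3).
#' @param bond_rules character vector of built-in bond-rule names.
#' @param allowed_skeletons optional character vector of canonical carbon
#'   skeletons; molecules whose skeleton is absent violate
#'   `graph_topology`.
#' @return object of class `enumeration_filters`.
#' @export
enumeration_filters <- function(max_heavy_atoms = 5,
                                allowed_elements = c("C", "N", "O"),
                                max_heteroatom_ratio = 1,
                                disallowed_groups = c(
                                  peroxide = "[#8]~[#8]",
                                  hydrazine = "[#7]~[#7]",
                                  allene = "C=C=C"
                                ),
                                disallowed_heteroatom_neighbors = c("[#7]~[#8]"),
                                max_bond_order = 3,
                                bond_rules = c("triple_bond_in_ring",
                                               "unsaturation_in_3_ring"),
                                allowed_skeletons = NULL) {
  stopifnot(max_heavy_atoms >= 1, length(allowed_elements) >= 1)
  if (length(disallowed_groups) && is.null(names(disallowed_groups)))
    stop("disallowed_groups must be a named vector (labels are reported to users)")
  if (anyDuplicated(names(disallowed_groups)))
    stop("disallowed group labels must be unique")
  structure(list(
    max_heavy_atoms = as.integer(max_heavy_atoms),
    allowed_elements = allowed_elements,
    max_heteroatom_ratio = max_heteroatom_ratio,
    disallowed_groups = disallowed_groups,
    disallowed_heteroatom_neighbors = disallowed_heteroatom_neighbors,
    max_bond_order = as.integer(max_bond_order),
    bond_rules = bond_rules,
    allowed_skeletons = allowed_skeletons
  ), class = "enumeration_filters")
}

#' Default filters for the miniature GDB-like toy space
#'
#' A small, documented stand-in for the functional-group and topology rules
#' of a real GDB enumeration (whose full filter list is not public): no
#' O-O or N-N bonds of any order (peroxides, hydrazines, azo and aromatic
#' analogues), no allenes, no N-O bonds, no triple bonds in rings and no
#' unsaturated 3-membered rings.
#'
#' @param max_heavy_atoms heavy-atom bound of the space (default 4).
#' @param ... passed to [enumeration_filters()].
#' @export
gdb_toy_filters <- function(max_heavy_atoms = 4, ...) {
  enumeration_filters(max_heavy_atoms = max_heavy_atoms, ...)
}

#' @export
print.enumeration_filters <- function(x, ...) {
  cat("Enumeration filters:\n")
  cat(sprintf("  max heavy atoms: %d; elements: {%s}; max het/C ratio: %g\n",
              x$max_heavy_atoms, paste(x$allowed_elements, collapse = ","),
              x$max_heteroatom_ratio))
  if (length(x$disallowed_groups))
    cat("  disallowed groups:", paste(names(x$disallowed_groups), collapse = ", "), "\n")
  if (length(x$disallowed_heteroatom_neighbors))
    cat("  disallowed heteroatom neighbors:",
        paste(x$disallowed_heteroatom_neighbors, collapse = ", "), "\n")
  if (length(x$bond_rules))
    cat("  bond rules:", paste(x$bond_rules, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write filter definitions as JSON
#' @param path JSON file path.
#' @rdname filter_io
#' @export
read_filters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  enumeration_filters(
    max_heavy_atoms = x$max_heavy_atoms,
    allowed_elements = x$allowed_elements,
    max_heteroatom_ratio = x$max_heteroatom_ratio,
    disallowed_groups = unlist(x$disallowed_groups),
    disallowed_heteroatom_neighbors = x$disallowed_heteroatom_neighbors,
    max_bond_order = x$max_bond_order %||% 3,
    bond_rules = x$bond_rules,
    allowed_skeletons = x$allowed_skeletons
  )
}

#' @param filters an `enumeration_filters` object.
#' @rdname filter_io
#' @export
write_filters <- function(filters, path) {
  stopifnot(inherits(filters, "enumeration_filters"))
  jsonlite::write_json(
    list(max_heavy_atoms = filters$max_heavy_atoms,
         allowed_elements = filters$allowed_elements,
         max_heteroatom_ratio = filters$max_heteroatom_ratio,
         disallowed_groups = as.list(filters$disallowed_groups),
         disallowed_heteroatom_neighbors = filters$disallowed_heteroatom_neighbors,
         max_bond_order = filters$max_bond_order,
         bond_rules = filters$bond_rules,
         allowed_skeletons = filters$allowed_skeletons),
    path, auto_unbox = TRUE)
  invisible(path)
}

# Evaluate a named built-in bond rule on a molgraph. TRUE = violated.
.bond_rule_violated <- function(rule, g) {
  if (nrow(g$bonds) == 0) return(FALSE)
  cyc <- .cyclic_bonds(g)
  switch(rule,
    triple_bond_in_ring = any(cyc & g$bonds[, "order"] == 3L),
    unsaturation_in_3_ring = {
      rings <- .sssr(g)
      r3 <- Filter(function(r) length(r) == 3, rings)
      if (!length(r3)) FALSE else {
        any(vapply(r3, function(r) {
          in_ring <- g$bonds[, "a1"] %in% r & g$bonds[, "a2"] %in% r
          any(in_ring & g$bonds[, "order"] > 1L)
        }, TRUE))
      }
    },
    stop("unknown bond rule: ", rule)
  )
}

#' Check a molecule against enumeration filters
#'
#' Returns the labels of every violated filter (possibly none). A molecule
#' inside an enumerated space always returns the empty vector when checked
#' against the filters that built the space.
#'
#' @param smiles a single valid SMILES string.
#' @param filters an [enumeration_filters()] object.
#' @param space optional `reference_space`; when given (or when
#'   `filters$allowed_skeletons` is set), the molecule's carbon skeleton is
#'   checked and `graph_topology` reported if absent.
#' @return character vector of violated filter labels.
#' @export
check_filters <- function(smiles, filters, space = NULL) {
  stopifnot(inherits(filters, "enumeration_filters"), length(smiles) == 1)
  g <- parse_molgraph(smiles)[[1]]
  if (is.null(g)) stop("invalid molecule: ", smiles)
  labels <- character(0)
  if (length(g$elements) > filters$max_heavy_atoms)
    labels <- c(labels, "heavy_atom_count")
  if (!all(g$elements %in% filters$allowed_elements))
    labels <- c(labels, "element_set")
  ncarb <- sum(g$elements == "C")
  nhet <- sum(g$elements != "C")
  # the ratio is only defined for carbon-containing molecules; carbon-free
  # ones (bare N/O at 1 heavy atom) are not excluded by this rule
  if (ncarb > 0 && (nhet / ncarb) > filters$max_heteroatom_ratio)
    labels <- c(labels, "heteroatom_ratio")
  pats <- c(filters$disallowed_groups)
  if (length(pats)) {
    hits <- smarts_match_matrix(smiles, pats)[1, ] > 0
    if (any(hits))
      labels <- c(labels, paste0("functional_group:", names(pats)[hits]))
  }
  if (length(filters$disallowed_heteroatom_neighbors)) {
    pn <- filters$disallowed_heteroatom_neighbors
    names(pn) <- paste0("hn", seq_along(pn))
    if (any(smarts_match_matrix(smiles, pn)[1, ] > 0))
      labels <- c(labels, "heteroatom_neighbors")
  }
  order_bad <- nrow(g$bonds) > 0 && any(g$bonds[, "order"] > filters$max_bond_order)
  if (order_bad) {
    labels <- c(labels, "bond_rule")
  } else {
    for (rule in filters$bond_rules) {
      if (.bond_rule_violated(rule, g)) { labels <- c(labels, "bond_rule"); break }
    }
  }
  skel_ref <- filters$allowed_skeletons
  if (is.null(skel_ref) && !is.null(space)) skel_ref <- space$skeletons
  if (!is.null(skel_ref)) {
    if (!(carbon_skeleton(smiles) %in% skel_ref))
      labels <- c(labels, "graph_topology")
  }
  labels
}

# ---------------------------------------------------------------------------
# Toy-space enumeration

# Exhaustive growth of connected molecular graphs: start from single atoms,
# repeatedly either attach one new atom with a bond of order 1-3 or close one
# ring between non-adjacent atoms, respecting fixed valences (C4/N3/O2/...).
# The frontier is deduplicated by canonical SMILES at every step, so the walk
# visits each distinct molecule once. Filters are applied only at emission:
# non-monotone rules (e.g. the heteroatom ratio, which can be repaired by
# adding carbons) must not prune intermediates.

#' Exhaustively enumerate a miniature chemical space
#'
#' Generates every connected molecule over the allowed elements up to
#' `filters$max_heavy_atoms` heavy atoms (acyclic plus at most `max_rings`
#' ring closures), applies all filters, and returns the survivors as a
#' [reference_space()]. The result is deterministic: two runs with the same
#' filters produce identical spaces.
#'
#' @param filters an [enumeration_filters()] object; its
#'   `allowed_elements` and `max_heavy_atoms` drive the enumeration.
#' @param max_rings maximum number of independent rings (0 or 1).
#' @param max_enumerable guard: refuse `max_heavy_atoms` above this bound,
#'   since the universe grows super-exponentially.
#' @param progress print per-level progress to the console.
#' @return a `reference_space` with `filters` attached.
#' @examples
#' sp <- enumerate_toy_space(enumeration_filters(max_heavy_atoms = 3,
#'   allowed_elements = "C"), max_rings = 0)
#' sp$molecules  # methane, ethane, propane + unsaturated analogues
#' @export
enumerate_toy_space <- function(filters, max_rings = 1, max_enumerable = 6,
                                progress = FALSE) {
  stopifnot(inherits(filters, "enumeration_filters"))
  maxa <- filters$max_heavy_atoms
  if (maxa > max_enumerable) {
    stop(sprintf(paste0("refusing exhaustive enumeration above %d heavy atoms ",
                        "(roughly %.1e candidate graphs at %d atoms)"),
                 max_enumerable, length(filters$allowed_elements)^maxa * 3^maxa,
                 maxa))
  }
  elements <- filters$allowed_elements
  val <- .DEFAULT_VALENCE[elements]
  if (anyNA(val)) stop("no valence rule for element(s): ",
                       paste(elements[is.na(val)], collapse = ","))
  new_graph <- function(el) {
    g <- list(elements = el, charges = 0L,
              bonds = matrix(integer(0), ncol = 3,
                             dimnames = list(NULL, c("a1", "a2", "order"))))
    class(g) <- "molgraph"
    g
  }
  seen <- new.env(parent = emptyenv())   # canonical SMILES -> molgraph
  frontier <- lapply(elements, new_graph)
  can0 <- canonicalize(vapply(frontier, graph_to_smiles, ""), check_valence = FALSE)
  for (i in seq_along(frontier)) assign(can0[i], frontier[[i]], envir = seen)
  frontier <- frontier[!duplicated(can0)]
  n_rings <- function(g) nrow(g$bonds) - length(g$elements) + 1L
  expand <- function(g) {
    out <- list()
    free <- .DEFAULT_VALENCE[g$elements] - .graph_valences(g)
    na <- length(g$elements)
    if (na < maxa) {
      for (i in which(free >= 1L)) {
        for (e in seq_along(elements)) {
          for (o in seq_len(min(filters$max_bond_order, free[i], val[e]))) {
            g2 <- g
            g2$elements <- c(g2$elements, elements[e])
            g2$charges <- c(g2$charges, 0L)
            g2$bonds <- rbind(g2$bonds, c(na + 1L, i, o))
            out[[length(out) + 1L]] <- g2
          }
        }
      }
    }
    if (n_rings(g) < max_rings && na >= 3L) {
      adj <- matrix(FALSE, na, na)
      if (nrow(g$bonds)) adj[g$bonds[, 1:2]] <- adj[g$bonds[, 2:1]] <- TRUE
      for (i in seq_len(na - 1L)) for (j in seq((i + 1L), na)) {
        if (adj[i, j]) next
        for (o in seq_len(min(filters$max_bond_order, free[i], free[j]))) {
          g2 <- g
          g2$bonds <- rbind(g2$bonds, c(i, j, o))
          out[[length(out) + 1L]] <- g2
        }
      }
    }
    out
  }
  level <- 0L
  while (length(frontier) > 0) {
    level <- level + 1L
    cands <- unlist(lapply(frontier, expand), recursive = FALSE)
    if (length(cands) == 0) break
    raw <- vapply(cands, graph_to_smiles, "")
    can <- canonicalize(raw, check_valence = FALSE)  # grown graphs are valence-legal
    if (anyNA(can)) cands <- cands[!is.na(can)]; can <- can[!is.na(can)]
    first <- !duplicated(can)
    cands <- cands[first]; can <- can[first]
    fresh <- !vapply(can, exists, TRUE, envir = seen)
    frontier <- cands[fresh]
    can <- can[fresh]
    for (i in seq_along(frontier)) assign(can[i], frontier[[i]], envir = seen)
    if (progress)
      message(sprintf("level %d: %d new molecules (total %d)",
                      level, length(frontier), length(ls(seen))))
  }
  universe <- sort(ls(seen))
  keep <- vapply(universe, function(s) length(check_filters(s, filters)) == 0, TRUE)
  members <- universe[keep]
  if (length(members) == 0) stop("filters removed every enumerated molecule")
  sp <- reference_space(members, filters = filters)
  sp$universe_size <- length(universe)
  sp
}
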