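# Annotate out-of-space molecules with the enumeration constraints they
# break. Every record gets at least one label: a molecule violating nothing
# but still absent from the space is "miscellaneous" (a space that is not
# perfectly exhaustive, or toolkit dialect differences, produce these).

#' Label an out-of-space molecule with the constraints it violates
#'
#' Applies every filter category: heavy-atom count, element set,
#' heteroatom/carbon ratio, disallowed functional groups (one label per
#' named pattern), disallowed heteroatom neighbourhoods, bond rules, and
#' graph topology (carbon skeleton absent from the space's skeleton set).
#' Tautomer detection is a pluggable hook: when `tautomer_hook` is given it
#' must map a SMILES to a character vector of tautomer canonical SMILES,
#' and a molecule with a tautomer inside the space is labelled
#' `tautomer_of_member`; without a hook the category is not evaluated.
#' All applicable labels are recorded (no priority); a molecule violating
#' nothing is labelled `miscellaneous`.
#'
#' @param smiles a single valid canonical SMILES, not in the space.
#' @param filters [enumeration_filters()]; defaults to the space's own.
#' @param space the [reference_space()] the molecule fell outside of.
#' @param tautomer_hook optional function(smiles) -> character vector.
#' @return object of class `violation_record`: `smiles`, `labels`,
#'   `num_labels`, `tautomers_evaluated`.
#' @export
label_molecule <- function(smiles, filters = NULL, space, tautomer_hook = NULL) {
  stopifnot(inherits(space, "reference_space"), length(smiles) == 1)
  filters <- filters %||% space$filters
  if (is.null(filters)) stop("no filters given and the space carries none")
  can <- canonicalize(smiles)
  if (is.na(can)) stop("invalid molecule: ", smiles)
  if (in_space(can, space))
    stop("molecule is inside the space; labelling is for out-of-space molecules: ", can)
  labels <- check_filters(can, filters)
  if (is.null(space$skeletons))
    stop("space has no skeleton set; rebuild with compute_skeletons = TRUE")
  if (!(carbon_skeleton(can) %in% space$skeletons))
    labels <- c(labels, "graph_topology")
  if (!is.null(tautomer_hook)) {
    tauts <- canonicalize(tautomer_hook(can))
    if (any(!is.na(tauts) & tauts %in% space$molecules))
      labels <- c(labels, "tautomer_of_member")
  }
  labels <- unique(labels)
  if (length(labels) == 0) labels <- "miscellaneous"
  structure(list(smiles = can, labels = labels, num_labels = length(labels),
                 tautomers_evaluated = !is.null(tautomer_hook)),
            class = "violation_record")
}

#' @export
print.violation_record <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$smiles, paste(x$labels, collapse = "; ")))
  invisible(x)
}

#' Label a batch of out-of-space molecules
#'
#' @param smiles character vector of valid SMILES outside the space.
#' @inheritParams label_molecule
#' @return data.frame with columns `smiles`, `labels` (semicolon-joined),
#'   `num_labels`; the individual records in `attr(, "records")`.
#' @export
label_molecules <- function(smiles, filters = NULL, space, tautomer_hook = NULL) {
  records <- lapply(smiles, label_molecule, filters = filters, space = space,
                    tautomer_hook = tautomer_hook)
  out <- data.frame(
    smiles = vapply(records, `[[`, "", "smiles"),
    labels = vapply(records, function(r) paste(r$labels, collapse = ";"), ""),
    num_labels = vapply(records, `[[`, 0L, "num_labels"))
  attr(out, "records") <- records
  out
}

#' Summarize violation records
#'
#' Per-label percentages (which may sum above 100: a molecule can break
#' several constraints) and the histogram of the number of constraints
#' broken per molecule.
#'
#' @param records a list of `violation_record`s or the data.frame from
#'   [label_molecules()].
#' @return object of class `violation_summary`: `percent` (named, per
#'   label), `broken_histogram` (counts indexed by number of labels),
#'   `n_molecules`, `tautomers_evaluated`.
#' @export
violation_summary <- function(records) {
  if (is.data.frame(records)) records <- attr(records, "records")
  if (length(records) == 0) stop("no violation records")
  labels <- lapply(records, `[[`, "labels")
  all_labels <- sort(unique(unlist(labels)))
  n <- length(records)
  percent <- vapply(all_labels, function(l)
    100 * sum(vapply(labels, function(x) l %in% x, TRUE)) / n, 1)
  nlab <- vapply(records, `[[`, 0L, "num_labels")
  stopifnot(all(nlab >= 1))  # the miscellaneous fallback guarantees this
  hist <- stats::setNames(tabulate(nlab, nbins = max(nlab)), seq_len(max(nlab)))
  structure(list(percent = percent, broken_histogram = hist, n_molecules = n,
                 tautomers_evaluated = any(vapply(records, `[[`, TRUE,
                                                  "tautomers_evaluated"))),
            class = "violation_summary")
}

#' @export
print.violation_summary <- function(x, ...) {
  cat(sprintf("Constraint violations across %d out-of-space molecules:\n", x$n_molecules))
  for (l in names(sort(x$percent, decreasing = TRUE)))
    cat(sprintf("  %-28s %5.1f%%\n", l, x$percent[[l]]))
  if (!x$tautomers_evaluated)
    cat("  (tautomer_of_member: not evaluated, no tautomer hook configured)\n")
  cat("  constraints broken per molecule:",
      paste(sprintf("%s:%d", names(x$broken_histogram), x$broken_histogram),
            collapse = "  "), "\n")
  invisible(x)
}
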