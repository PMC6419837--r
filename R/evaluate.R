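# Scoring sampled SMILES multisets against a reference space: the
# valid / canonical-as-generated / in-space / out-of-space partition, unique
# coverage against the ideal bound, multi-model frequency spectra against
# the binomial null, and n-gram composition analysis.

#' Evaluate a sampled SMILES multiset against a reference space
#'
#' Classifies every generated string exactly once: invalid (unparseable or
#' truncated), or valid and then in- or out-of-space by canonical form.
#' "Canonical as generated" counts valid strings whose raw text already
#' equals their canonical form. Unique counts are by canonical molecule
#' (multiset totals count repeats). The unique in-space coverage is
#' compared with the ideal (uniform) model's expected fraction at the same
#' sample size.
#'
#' @param sample character vector of generated SMILES, or a data.frame from
#'   [simulate.smiles_lm()] (whose `truncated` flag marks sequences cut at
#'   the length limit; these are counted as invalid).
#' @param space a [reference_space()].
#' @param k nominal sample size; defaults to `length(sample)` and must
#'   match it.
#' @param chunk_size strings canonicalized per chunk (memory bound, not a
#'   semantic knob).
#' @return object of class `sample_report`: counts `total`, `valid`,
#'   `invalid`, `canonical_as_generated`, `in_space`, `out_of_space`,
#'   `unique_valid`, `unique_in_space`, `unique_out_of_space`,
#'   `coverage_fraction`, `ideal_fraction`, `coverage_gap`, and the vectors
#'   `in_space_molecules` / `out_of_space_molecules` (unique canonical
#'   forms; the latter feed the violation labeller).
#' @export
evaluate_sample <- function(sample, space, k = NULL, chunk_size = 100000L) {
  stopifnot(inherits(space, "reference_space"))
  truncated <- NULL
  if (is.data.frame(sample)) {
    truncated <- sample$truncated %||% logical(nrow(sample))
    sample <- sample$smiles
  }
  if (length(sample) == 0) stop("empty sample")
  truncated <- truncated %||% logical(length(sample))
  k <- k %||% length(sample)
  if (k != length(sample))
    stop("k must equal the multiset size |sample|")
  total <- length(sample)
  valid <- 0L; canonical_as_generated <- 0L; n_in <- 0L; n_out <- 0L
  uniq_in <- new.env(parent = emptyenv())
  uniq_out <- new.env(parent = emptyenv())
  for (start in seq(1, total, by = chunk_size)) {
    sel <- start:min(start + chunk_size - 1L, total)
    raw <- sample[sel]
    can <- canonicalize(raw)
    can[truncated[sel]] <- NA_character_   # truncated sequences count invalid
    ok <- !is.na(can)
    valid <- valid + sum(ok)
    canonical_as_generated <- canonical_as_generated + sum(raw[ok] == can[ok])
    inside <- ok & can %in% space$molecules
    n_in <- n_in + sum(inside)
    n_out <- n_out + sum(ok & !inside)
    for (s in unique(can[inside])) assign(s, TRUE, envir = uniq_in)
    for (s in unique(can[ok & !inside])) assign(s, TRUE, envir = uniq_out)
  }
  unique_in <- length(ls(uniq_in, sorted = FALSE))
  unique_out <- length(ls(uniq_out, sorted = FALSE))
  coverage <- unique_in / space$n
  ideal <- expected_fraction(space$n, k)
  out <- list(total = total, valid = valid, invalid = total - valid,
              canonical_as_generated = canonical_as_generated,
              in_space = n_in, out_of_space = n_out,
              unique_valid = unique_in + unique_out,
              unique_in_space = unique_in, unique_out_of_space = unique_out,
              coverage_fraction = coverage, ideal_fraction = ideal,
              coverage_gap = ideal - coverage,
              n_space = space$n, k = k,
              in_space_molecules = sort(ls(uniq_in)),
              out_of_space_molecules = sort(ls(uniq_out)))
  # partition invariants
  stopifnot(out$valid <= out$total,
            out$canonical_as_generated <= out$valid,
            out$in_space + out$out_of_space == out$valid,
            out$unique_in_space <= space$n)
  class(out) <- "sample_report"
  out
}

#' @export
print.sample_report <- function(x, ...) {
  pct <- function(a) sprintf("%.1f%%", 100 * a / x$total)
  cat(sprintf("Sample report: k = %d draws against a space of n = %d\n", x$k, x$n_space))
  cat(sprintf("  valid SMILES:            %9d (%s)\n", x$valid, pct(x$valid)))
  cat(sprintf("  canonical as generated:  %9d (%s)\n", x$canonical_as_generated,
              pct(x$canonical_as_generated)))
  cat(sprintf("  in space / out of space: %9d / %d\n", x$in_space, x$out_of_space))
  cat(sprintf("  unique in space:         %9d -> coverage %.4f (ideal %.4f, gap %.4f)\n",
              x$unique_in_space, x$coverage_fraction, x$ideal_fraction, x$coverage_gap))
  invisible(x)
}

#' Molecule frequency spectrum across independently trained models
#'
#' For every molecule of the space, counts in how many of the M models'
#' deduplicated samples it occurs (frequency 0..M), and summarizes the
#' spectrum next to the ideal binomial null `Binomial(M, p_cov)` when the
#' per-model sample size `k` is supplied.
#'
#' @param samples_by_model list of M character vectors: each model's unique
#'   in-space canonical molecules (error if any molecule is outside the
#'   space).
#' @param space a [reference_space()].
#' @param k per-model sample size for the binomial null (optional).
#' @return object of class `frequency_spectrum`: `frequency` (named integer
#'   vector over all space molecules), `histogram` (counts over 0..M),
#'   `mean`, `mode`, `never_sampled_count`, `num_models`, and `null`
#'   (from [ideal_frequency_null()], when `k` given).
#' @export
frequency_spectrum <- function(samples_by_model, space, k = NULL) {
  stopifnot(inherits(space, "reference_space"), is.list(samples_by_model),
            length(samples_by_model) >= 1)
  M <- length(samples_by_model)
  f <- stats::setNames(integer(space$n), space$molecules)
  for (i in seq_len(M)) {
    s <- unique(samples_by_model[[i]])
    hit <- s %in% space$molecules
    if (!all(hit))
      stop(sprintf("model %d sample contains %d molecule(s) outside the space",
                   i, sum(!hit)))
    f[s] <- f[s] + 1L
  }
  hist <- stats::setNames(tabulate(f + 1L, nbins = M + 1L), 0:M)
  stopifnot(sum(hist) == space$n)
  emp_mode <- as.integer(names(hist)[which(hist == max(hist))])
  structure(list(frequency = f,
                 histogram = hist,
                 mean = mean(f),
                 mode = emp_mode,
                 never_sampled_count = sum(f == 0L),
                 num_models = M,
                 null = if (!is.null(k)) ideal_frequency_null(M, space$n, k)),
            class = "frequency_spectrum")
}

#' @export
print.frequency_spectrum <- function(x, ...) {
  cat(sprintf("Frequency spectrum over %d models: mean %.2f, mode %s, %d never sampled\n",
              x$num_models, x$mean, paste(x$mode, collapse = "/"),
              x$never_sampled_count))
  if (!is.null(x$null))
    cat(sprintf("  ideal binomial null: mean %.2f, mode %s\n",
                x$null$mean, paste(x$null$mode, collapse = "/")))
  invisible(x)
}

#' Relate molecule frequency to average NLL
#'
#' Stratifies molecules by their multi-model frequency and summarizes the
#' per-stratum NLL distribution, reporting the Spearman rank correlation
#' between frequency and mean NLL (expected strongly negative: molecules
#' the models assign low probability are sampled by few models).
#'
#' @param spectrum a [frequency_spectrum()].
#' @param mean_nll_per_molecule named numeric vector: average NLL per
#'   molecule (names are canonical SMILES; a sample of molecules per
#'   stratum suffices).
#' @return object of class `frequency_nll_summary`: data.frame `strata`
#'   (frequency, n, mean_nll, sd_nll) and `spearman_rho` (NA with a note
#'   when fewer than two strata have data).
#' @export
frequency_vs_nll <- function(spectrum, mean_nll_per_molecule) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  mols <- intersect(names(mean_nll_per_molecule), names(spectrum$frequency))
  if (length(mols) == 0) stop("no molecule in common between spectrum and NLL map")
  f <- spectrum$frequency[mols]
  nll <- mean_nll_per_molecule[mols]
  strata <- lapply(sort(unique(f)), function(fr) {
    v <- nll[f == fr]
    data.frame(frequency = fr, n = length(v), mean_nll = mean(v),
               sd_nll = if (length(v) > 1) stats::sd(v) else NA_real_)
  })
  strata <- do.call(rbind, strata)
  rho <- if (nrow(strata) < 2) NA_real_ else
    suppressWarnings(stats::cor(f, nll, method = "spearman"))
  note <- if (nrow(strata) < 2)
    "only one frequency stratum: correlation undefined" else NULL
  structure(list(strata = strata, spearman_rho = rho, note = note),
            class = "frequency_nll_summary")
}

#' @export
print.frequency_nll_summary <- function(x, ...) {
  cat("NLL by frequency stratum:\n")
  print(x$strata, row.names = FALSE)
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  else cat(sprintf("  Spearman rho(frequency, NLL) = %.3f\n", x$spearman_rho))
  invisible(x)
}

#' n-gram composition of a reference space
#'
#' Token n-grams (order 1 or 2) over the tokenized canonical SMILES of the
#' whole space: per-gram corpus count, percent of all grams, and (when a
#' frequency spectrum is supplied) the mean multi-model frequency of the
#' molecules containing the gram. Begin/end markers are excluded at order
#' 1; at order 2 boundary grams (`^C`, `1$`, ...) are included only when
#' `include_boundary = TRUE`.
#'
#' @param space a [reference_space()].
#' @param spectrum optional [frequency_spectrum()] over the same space.
#' @param order 1 or 2.
#' @param include_boundary include begin/end boundary grams at order 2.
#' @return data.frame of class `ngram_table`, sorted by percent descending:
#'   `gram`, `count`, `percent`, `mean_frequency`.
#' @export
ngram_analysis <- function(space, spectrum = NULL, order = 1,
                           include_boundary = FALSE) {
  stopifnot(inherits(space, "reference_space"))
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  if (!is.null(spectrum)) {
    stopifnot(inherits(spectrum, "frequency_spectrum"))
    if (!setequal(names(spectrum$frequency), space$molecules))
      stop("spectrum was computed over a different space")
  }
  tok <- lapply(space$molecules, tokenize_smiles)
  grams_of <- function(tk) {
    if (order == 1) return(tk)
    full <- if (include_boundary) c(TOKEN_BEGIN, tk, TOKEN_END) else tk
    if (length(full) < 2) return(character(0))
    paste0(full[-length(full)], full[-1])
  }
  per_mol <- lapply(tok, grams_of)
  counts <- table(unlist(per_mol))
  grams <- names(counts)
  mean_freq <- rep(NA_real_, length(grams))
  if (!is.null(spectrum)) {
    f <- spectrum$frequency[space$molecules]
    mean_freq <- vapply(grams, function(g) {
      has <- vapply(per_mol, function(x) g %in% x, TRUE)
      if (!any(has)) return(NA_real_)
      mean(f[has])
    }, 1)
  }
  out <- data.frame(gram = grams,
                    count = as.integer(counts),
                    percent = 100 * as.integer(counts) / sum(counts),
                    mean_frequency = mean_freq)
  out <- out[base::order(-out$percent, out$gram), ]  # `order` arg shadows base
  rownames(out) <- NULL
  class(out) <- c("ngram_table", "data.frame")
  out
}
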