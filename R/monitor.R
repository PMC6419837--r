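# Training-state diagnosis from NLL distributions: per-epoch histograms of
# the training/validation/sampled sets, pairwise Jensen-Shannon divergences
# and mean/variance trajectories. Monitoring is post hoc: it reads the
# checkpoints a fit retained, it never intervenes in training.

#' Shared histogram binning for NLL distributions
#'
#' JSD between continuous NLL samples requires a common discretization. The
#' default grid uses bins of width 0.5 nats from 0 to the uniform-model mean
#' `ln n` plus a padding margin; everything above the last edge falls into
#' an overflow bin.
#'
#' @param n_space reference-space size (sets the uniform mean `ln n`).
#' @param width bin width in nats.
#' @param pad nats added above `ln n`.
#' @return numeric vector of bin edges ending in `Inf`.
#' @export
nll_breaks <- function(n_space, width = 0.5, pad = 20) {
  upper <- log(n_space) + pad
  c(seq(0, upper, by = width), Inf)
}

#' Negative log-likelihood distribution of a SMILES set
#'
#' Scores every sequence under the model and summarizes the resulting NLL
#' sample: mean, variance, and a normalized histogram on a fixed shared
#' binning (so that distributions from different sources and epochs are
#' directly comparable).
#'
#' @param model a fitted [smiles_lm()] (possibly a [checkpoint()]).
#' @param smiles character vector of sequences to score; sequences with
#'   out-of-vocabulary tokens are skipped and counted.
#' @param source one of "training", "validation", "sampled".
#' @param breaks bin edges from [nll_breaks()].
#' @param epoch epoch annotation (defaults to the model's).
#' @return object of class `nll_distribution`: `values`, `mean`,
#'   `variance`, `histogram` (probabilities), `breaks`, `source`, `epoch`,
#'   `n_skipped`.
#' @export
nll_distribution <- function(model, smiles, source = c("training", "validation", "sampled"),
                             breaks, epoch = NULL) {
  source <- match.arg(source)
  stopifnot(length(smiles) >= 1)
  ok <- vapply(smiles, function(s) {
    tryCatch({ encode_smiles(s, model$vocab); TRUE }, error = function(e) FALSE)
  }, TRUE)
  n_skipped <- sum(!ok)
  if (!any(ok)) stop("no sequence could be scored (all tokens out of vocabulary)")
  values <- predict(model, smiles[ok])$nll
  h <- graphics::hist(pmin(values, breaks[length(breaks) - 1]),
                      breaks = breaks, plot = FALSE)
  structure(list(values = values,
                 mean = mean(values),
                 variance = stats::var(values) * (length(values) - 1) / length(values),
                 histogram = h$counts / sum(h$counts),
                 breaks = breaks,
                 source = source,
                 epoch = epoch %||% model$epoch,
                 n_skipped = n_skipped),
            class = "nll_distribution")
}

#' @export
print.nll_distribution <- function(x, ...) {
  cat(sprintf("NLL distribution (%s set, epoch %s): n = %d, mean = %.3f, var = %.3f nats\n",
              x$source, format(x$epoch), length(x$values), x$mean, x$variance))
  invisible(x)
}

#' Jensen-Shannon divergence between two NLL distributions
#'
#' `JSD(A, B) = KL(A || M)/2 + KL(B || M)/2` with `M = (A + B)/2`, computed
#' in natural logs on the shared histogram binning, so its range is
#' `[0, ln 2]`. Symmetric; zero iff the histograms coincide. A smoothing
#' mass of 1e-12 per bin keeps the KL terms finite on disjoint supports.
#'
#' @param dist_a,dist_b `nll_distribution` objects (or bare probability
#'   vectors on identical bins).
#' @return the divergence in nats.
#' @export
jensen_shannon <- function(dist_a, dist_b) {
  pa <- if (inherits(dist_a, "nll_distribution")) dist_a$histogram else dist_a
  pb <- if (inherits(dist_b, "nll_distribution")) dist_b$histogram else dist_b
  if (inherits(dist_a, "nll_distribution") && inherits(dist_b, "nll_distribution") &&
      !isTRUE(all.equal(dist_a$breaks, dist_b$breaks)))
    stop("NLL distributions are binned on different grids")
  if (length(pa) != length(pb)) stop("histograms have different numbers of bins")
  eps <- 1e-12
  pa <- pa + eps; pa <- pa / sum(pa)
  pb <- pb + eps; pb <- pb / sum(pb)
  m <- (pa + pb) / 2
  kl <- function(p, q) sum(p * log(p / q))
  kl(pa, m) / 2 + kl(pb, m) / 2
}

#' Per-epoch training diagnostics
#'
#' For each retained checkpoint: NLL distributions of the training,
#' validation and freshly sampled sets, their means and variances, the three
#' pairwise JSDs, and the percentage of valid SMILES among the sample.
#'
#' @param model a [smiles_lm()] fitted with `keep_checkpoints = TRUE`.
#' @param train,valid the training and validation SMILES sets.
#' @param n_space reference-space size (fixes the shared binning).
#' @param sample_size sequences sampled per epoch (default 10x the
#'   validation-set size).
#' @param epochs which epochs to diagnose (default all).
#' @param seed RNG seed for the per-epoch sampling.
#' @param width histogram bin width in nats.
#' @return data.frame of class `epoch_diagnostics`, one row per epoch:
#'   `epoch`, `jsd_train_valid`, `jsd_train_sampled`, `jsd_valid_sampled`,
#'   `mean_*`, `var_*` for the three sources, `percent_valid`.
#' @export
epoch_diagnostics <- function(model, train, valid, n_space,
                              sample_size = 10 * length(valid),
                              epochs = NULL, seed = 1, width = 0.5) {
  stopifnot(inherits(model, "smiles_lm"))
  if (is.null(model$checkpoints))
    stop("model was fitted without keep_checkpoints = TRUE")
  epochs <- epochs %||% seq_along(model$checkpoints)
  breaks <- nll_breaks(n_space, width = width)
  rows <- vector("list", length(epochs))
  for (i in seq_along(epochs)) {
    e <- epochs[i]
    mdl <- checkpoint(model, e)
    sm <- simulate(mdl, nsim = sample_size, seed = seed + e)
    valid_ok <- !sm$truncated & is_valid_smiles(sm$smiles)
    dt <- nll_distribution(mdl, train, "training", breaks, epoch = e)
    dv <- nll_distribution(mdl, valid, "validation", breaks, epoch = e)
    ds <- nll_distribution(mdl, sm$smiles, "sampled", breaks, epoch = e)
    rows[[i]] <- data.frame(
      epoch = e,
      jsd_train_valid = jensen_shannon(dt, dv),
      jsd_train_sampled = jensen_shannon(dt, ds),
      jsd_valid_sampled = jensen_shannon(dv, ds),
      mean_train = dt$mean, mean_valid = dv$mean, mean_sampled = ds$mean,
      var_train = dt$variance, var_valid = dv$variance, var_sampled = ds$variance,
      percent_valid = 100 * mean(valid_ok))
  }
  out <- do.call(rbind, rows)
  attr(out, "n_space") <- n_space
  attr(out, "breaks") <- breaks
  class(out) <- c("epoch_diagnostics", "data.frame")
  out
}

# Rolling slope of a series over a centered window (simple finite
# differences averaged over the window).
.rolling_slope <- function(y, window = 3) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - window); hi <- min(n, i + window)
    if (hi == lo) return(0)
    stats::coef(stats::lm.fit(cbind(1, lo:hi), y[lo:hi]))[2]
  }, 1)
}

#' Diagnose training phases from per-epoch NLL summaries
#'
#' Labels every diagnosed epoch with a training phase and recommends an
#' epoch window, reading the NLL picture jointly:
#'
#' * `undertrained` — the sampled set is more probable than held-out data
#'   (sampled mean NLL below the training/validation means) while the JSDs
#'   are still far from their minima: the model reproduces a subset of the
#'   training set.
#' * `converged` — all three pairwise JSDs are within `jsd_tol` of their
#'   per-series minima: sampling inside and outside the training set is
#'   about equally likely.
#' * `overtrained` — the sampled set keeps approaching the training set
#'   (falling `jsd_train_sampled`) while departing from validation (rising
#'   `jsd_valid_sampled`).
#' * `transitional` — none of the above.
#'
#' The recommended window intersects the converged-JSD window with the
#' epochs whose validation mean is on its plateau nearest the uniform
#' reference `ln n` (within `mean_tol` of the closest approach) and whose
#' validation variance is within `var_tol` of its minimum (the uniform
#' model has variance 0, so smaller is better). If the intersection is
#' empty, the converged window alone is recommended, and an empty converged
#' window is reported as such.
#'
#' @param diagnostics an [epoch_diagnostics()] data.frame (at least 3 epochs).
#' @param jsd_tol tolerance above each JSD series minimum (nats).
#' @param jsd_abs absolute JSD ceiling for the converged label: a run whose
#'   distributions never actually meet (all JSDs large but flat, e.g. a
#'   monotonically diverging train/validation pair) gets an empty converged
#'   window instead of a spurious one at the argmin.
#' @param mean_tol tolerance around the closest approach of the validation
#'   mean to `ln n` (nats).
#' @param var_tol tolerance above the validation variance minimum (nats^2).
#' @param slope_window half-width (epochs) of the rolling slope used for
#'   trend detection.
#' @return object of class `training_diagnosis`: per-epoch `labels`,
#'   `recommended` epochs (possibly empty), and the component windows.
#' @export
diagnose <- function(diagnostics, jsd_tol = 0.05, jsd_abs = 0.25,
                     mean_tol = 0.5, var_tol = 0.5, slope_window = 2) {
  stopifnot(inherits(diagnostics, "epoch_diagnostics") ||
              is.data.frame(diagnostics))
  d <- as.data.frame(diagnostics)
  if (nrow(d) < 3) stop("need diagnostics for at least 3 epochs")
  n_space <- attr(diagnostics, "n_space")
  if (is.null(n_space)) stop("diagnostics carry no reference-space size")
  mu_ref <- log(n_space)
  near_min <- function(x, tol) x <= min(x) + tol
  conv <- near_min(d$jsd_train_valid, jsd_tol) &
    near_min(d$jsd_train_sampled, jsd_tol) &
    near_min(d$jsd_valid_sampled, jsd_tol) &
    d$jsd_train_valid <= jsd_abs & d$jsd_train_sampled <= jsd_abs &
    d$jsd_valid_sampled <= jsd_abs
  s_vs <- .rolling_slope(d$jsd_valid_sampled, slope_window)
  s_ts <- .rolling_slope(d$jsd_train_sampled, slope_window)
  over <- s_vs > 0 & s_ts <= 0 &
    seq_len(nrow(d)) > which.min(d$jsd_valid_sampled)
  under <- d$mean_sampled < pmin(d$mean_train, d$mean_valid)
  labels <- rep("transitional", nrow(d))
  labels[under] <- "undertrained"
  labels[over] <- "overtrained"
  labels[conv] <- "converged"
  mean_dist <- abs(d$mean_valid - mu_ref)
  mean_win <- mean_dist <= min(mean_dist) + mean_tol
  var_win <- near_min(d$var_valid, var_tol)
  rec <- d$epoch[conv & mean_win & var_win]
  if (length(rec) == 0) rec <- d$epoch[conv]
  structure(list(epochs = d$epoch,
                 labels = labels,
                 recommended = rec,
                 converged_window = d$epoch[conv],
                 mean_plateau_window = d$epoch[mean_win],
                 variance_window = d$epoch[var_win],
                 uniform_mean = mu_ref),
            class = "training_diagnosis")
}

#' @export
print.training_diagnosis <- function(x, ...) {
  cat("Training diagnosis (uniform reference mean =",
      sprintf("%.2f nats)\n", x$uniform_mean))
  tab <- table(factor(x$labels, levels = c("undertrained", "transitional",
                                           "converged", "overtrained")))
  for (nm in names(tab)) if (tab[[nm]] > 0)
    cat(sprintf("  %-12s %d epoch(s)\n", nm, tab[[nm]]))
  if (length(x$recommended))
    cat("  recommended epochs:", paste(range(x$recommended), collapse = "-"), "\n")
  else
    cat("  no converged window found\n")
  invisible(x)
}

#' Plot diagnostic trajectories
#'
#' Three panels: pairwise JSDs, NLL means (with the uniform reference
#' `ln n`), and NLL variances, per epoch.
#' @param x an `epoch_diagnostics` data.frame.
#' @param ... unused.
#' @export
plot.epoch_diagnostics <- function(x, ...) {
  d <- as.data.frame(x)
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(d$epoch, d[, c("jsd_train_valid", "jsd_train_sampled",
                                   "jsd_valid_sampled")],
                    type = "l", lty = 1, xlab = "", ylab = "JSD (nats)")
  graphics::legend("topright", c("train/valid", "train/sampled", "valid/sampled"),
                   col = 1:3, lty = 1, bty = "n", cex = 0.8)
  graphics::matplot(d$epoch, d[, c("mean_train", "mean_valid", "mean_sampled")],
                    type = "l", lty = 1, xlab = "", ylab = "mean NLL")
  graphics::abline(h = log(attr(x, "n_space")), lty = 2)
  graphics::matplot(d$epoch, d[, c("var_train", "var_valid", "var_sampled")],
                    type = "l", lty = 1, xlab = "epoch", ylab = "NLL variance")
  invisible(x)
}
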