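# End-to-end benchmark: build a space, split it, train model(s), monitor
# training, sample at a cadence of epochs, score coverage against the ideal
# bound, aggregate multi-model frequencies, and label the out-of-space
# molecules.

#' Split a reference space into training and validation sets
#'
#' Disjoint random samples of molecules from the space (asserted at split
#' time), the train/validation protocol used for every model fit.
#'
#' @param space a [reference_space()].
#' @param train_size,valid_size set sizes (sum must not exceed `n`).
#' @param seed RNG seed.
#' @return list with `train` and `valid` character vectors.
#' @export
split_space <- function(space, train_size, valid_size, seed = 1) {
  stopifnot(inherits(space, "reference_space"),
            train_size + valid_size <= space$n)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  idx <- sample.int(space$n, train_size + valid_size)
  out <- list(train = space$molecules[idx[seq_len(train_size)]],
              valid = space$molecules[idx[train_size + seq_len(valid_size)]])
  stopifnot(length(intersect(out$train, out$valid)) == 0)
  out
}

#' Benchmark configuration
#'
#' Bundles the study design: the space (or the filters to enumerate one),
#' the split sizes, the per-evaluation sample size `k`, the number of
#' independently trained models `M`, the sampling cadence in epochs, model
#' hyperparameters, and one master seed from which every stage's seed is
#' derived (split: seed+1; model m: seed+100+m; evaluation sampling:
#' seed+1000+epoch; per-model final sampling: seed+2000+m).
#'
#' @param space optional [reference_space()]; enumerated from `filters`
#'   when NULL.
#' @param filters [enumeration_filters()] used when enumerating.
#' @param train_size,valid_size split sizes.
#' @param sample_size evaluation sample size `k`.
#' @param num_models number of independently trained models `M`.
#' @param epochs training epochs.
#' @param sample_every evaluation cadence in epochs.
#' @param model named list of extra [smiles_lm()] arguments.
#' @param seed master seed.
#' @return object of class `benchmark_config`.
#' @export
benchmark_config <- function(space = NULL, filters = gdb_toy_filters(),
                             train_size = 100, valid_size = 50,
                             sample_size = 2000, num_models = 1,
                             epochs = 30, sample_every = 5,
                             model = list(), seed = 1) {
  structure(list(space = space, filters = filters, train_size = train_size,
                 valid_size = valid_size, sample_size = sample_size,
                 num_models = num_models, epochs = epochs,
                 sample_every = sample_every, model = model, seed = seed),
            class = "benchmark_config")
}

#' Run the full coverage benchmark
#'
#' Executes the whole workflow of the package on one configuration and
#' returns a single report: per-model loss logs, a coverage trajectory over
#' the evaluation epochs (each compared to the ideal uniform bound at the
#' same `k`), training diagnostics for the first model, the multi-model
#' frequency spectrum against its binomial null (when `M > 1`), and the
#' violation summary of sampled out-of-space molecules.
#'
#' @param config a [benchmark_config()].
#' @param out_dir optional directory; when given, the report JSON, loss
#'   logs and coverage table are written there.
#' @param verbose print progress.
#' @return object of class `benchmark_report`.
#' @export
run_benchmark <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  space <- config$space
  if (is.null(space)) {
    say("enumerating toy space...")
    space <- enumerate_toy_space(config$filters)
  }
  stopifnot(inherits(space, "reference_space"))
  split <- split_space(space, config$train_size, config$valid_size,
                       seed = config$seed + 1)
  eval_epochs <- unique(c(seq(config$sample_every, config$epochs,
                              by = config$sample_every), config$epochs))
  models <- vector("list", config$num_models)
  for (m in seq_len(config$num_models)) {
    say("training model %d/%d...", m, config$num_models)
    args <- c(list(x = split$train, validation = split$valid,
                   epochs = config$epochs, seed = config$seed + 100 + m,
                   keep_checkpoints = (m == 1)), config$model)
    models[[m]] <- do.call(smiles_lm, args)
  }
  say("evaluating coverage trajectory...")
  traj <- lapply(eval_epochs, function(e) {
    sm <- simulate(checkpoint(models[[1]], e), nsim = config$sample_size,
                   seed = config$seed + 1000 + e)
    rep <- evaluate_sample(sm, space)
    data.frame(epoch = e, coverage = rep$coverage_fraction,
               ideal = rep$ideal_fraction,
               percent_valid = 100 * rep$valid / rep$total,
               percent_in_space = 100 * rep$in_space / rep$total)
  })
  trajectory <- do.call(rbind, traj)
  say("monitoring...")
  diag_epochs <- unique(round(seq(1, config$epochs,
                                  length.out = min(config$epochs, 8))))
  diagnostics <- epoch_diagnostics(models[[1]], split$train, split$valid,
                                   n_space = space$n,
                                   sample_size = min(10 * config$valid_size, 1000),
                                   epochs = diag_epochs, seed = config$seed + 3000)
  diagnosis <- diagnose(diagnostics)
  say("final sampling of all models...")
  final_reports <- lapply(seq_len(config$num_models), function(m) {
    mdl <- if (m == 1) checkpoint(models[[1]], config$epochs) else models[[m]]
    sm <- simulate(mdl, nsim = config$sample_size, seed = config$seed + 2000 + m)
    evaluate_sample(sm, space)
  })
  spectrum <- NULL
  if (config$num_models > 1) {
    say("frequency spectrum across %d models...", config$num_models)
    sets <- lapply(final_reports, `[[`, "in_space_molecules")
    spectrum <- frequency_spectrum(sets, space, k = config$sample_size)
  } else {
    say("single model: frequency stage skipped")
  }
  out_mols <- unique(unlist(lapply(final_reports, `[[`, "out_of_space_molecules")))
  violations <- if (length(out_mols)) {
    say("labelling %d out-of-space molecules...", length(out_mols))
    violation_summary(label_molecules(out_mols, space = space,
                                      filters = config$filters))
  }
  report <- structure(list(
    space_n = space$n,
    config = config,
    trajectory = trajectory,
    diagnosis = diagnosis,
    loss_logs = lapply(models, `[[`, "loss_log"),
    final_reports = final_reports,
    spectrum = spectrum,
    violations = violations,
    models = models
  ), class = "benchmark_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(trajectory, file.path(out_dir, "coverage_trajectory.csv"),
                     row.names = FALSE)
    for (m in seq_along(models))
      utils::write.csv(models[[m]]$loss_log,
                       file.path(out_dir, sprintf("loss_log_model%d.csv", m)),
                       row.names = FALSE)
    jsonlite::write_json(list(
      n = space$n,
      final_coverage = trajectory$coverage[nrow(trajectory)],
      ideal_fraction = trajectory$ideal[1],
      recommended_epochs = diagnosis$recommended,
      frequency_mean = if (!is.null(spectrum)) spectrum$mean,
      frequency_null_mean = if (!is.null(spectrum)) spectrum$null$mean,
      violation_percent = if (!is.null(violations)) as.list(violations$percent)
    ), file.path(out_dir, "benchmark_report.json"), auto_unbox = TRUE,
    digits = NA)
  }
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Coverage benchmark on a space of n = %d\n", x$space_n))
  cat(sprintf("  %d model(s), %d epochs, k = %d per evaluation\n",
              x$config$num_models, x$config$epochs, x$config$sample_size))
  tr <- x$trajectory
  cat(sprintf("  coverage at final epoch: %.4f (ideal bound %.4f)\n",
              tr$coverage[nrow(tr)], tr$ideal[nrow(tr)]))
  if (length(x$diagnosis$recommended))
    cat("  recommended epochs:",
        paste(range(x$diagnosis$recommended), collapse = "-"), "\n")
  if (!is.null(x$spectrum)) print(x$spectrum)
  invisible(x)
}
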