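# The ideal model: an abstract generator that samples molecules uniformly
# from the reference space and nothing else. Its closed-form coverage is the
# yardstick every trained model is compared against.

EULER_GAMMA <- 0.57721566490153286

#' Expected draws to collect a full uniform space
#'
#' Coupon-collector expectation: the mean number of draws with replacement
#' from a uniform distribution over `n` outcomes needed to observe every
#' outcome at least once, `n * H_n`. Computed by the exact harmonic sum for
#' `n <= 1e6` and by the asymptotic `n (ln n + gamma) + 1/2` above (the two
#' agree to better than one part in 1e6 at the crossover).
#'
#' @param n number of distinct outcomes (molecules), `n > 1`.
#' @return expected number of draws (double).
#' @examples
#' expected_draws_full_collection(2)    # 3
#' expected_draws_full_collection(975820187)
#' @export
expected_draws_full_collection <- function(n) {
  stopifnot(length(n) == 1, is.finite(n))
  if (n <= 1) stop("n must be > 1")
  if (n <= 1e6) {
    n * sum(1 / seq_len(n))
  } else {
    n * (log(n) + EULER_GAMMA) + 0.5
  }
}

#' Expected covered fraction of a uniform space
#'
#' The expected fraction of `n` equally likely outcomes observed after `k`
#' draws with replacement: `1 - (1 - 1/n)^k`, evaluated in log space so that
#' `1 - 1/n` is never literally exponentiated for astronomically large `n`.
#' For any non-uniform or incomplete generator this value is an upper bound
#' on achievable coverage at sample size `k`.
#'
#' @param n space size, `n > 2`.
#' @param k sample size, `k > 1`.
#' @return expected fraction in `[0, 1)`.
#' @examples
#' expected_fraction(975820187, 2e9)  # 0.8712
#' @export
expected_fraction <- function(n, k) {
  stopifnot(length(n) == 1, length(k) == 1)
  if (n <= 2) stop("n must be > 2")
  if (k <= 1) stop("k must be > 1")
  -expm1(k * log1p(-1 / n))
}

#' NLL statistics of the ideal (uniform) model
#'
#' Under the ideal model every molecule has probability `1/n`, so every
#' sequence has negative log-likelihood `ln n`: the NLL distribution is a
#' point mass with mean `ln n` and variance 0. A trained model's validation
#' NLL mean and variance are compared against these references.
#'
#' @param n space size, `n > 1`.
#' @return list with `mean` (nats) and `variance` (0).
#' @export
uniform_nll_stats <- function(n) {
  stopifnot(length(n) == 1)
  if (n <= 1) stop("n must be > 1")
  list(mean = log(n), variance = 0)
}

#' Binomial null for multi-model molecule frequencies
#'
#' If `M` independently trained ideal models each draw `k` samples from a
#' uniform space of size `n`, each model covers a given molecule with
#' probability `p_cov = expected_fraction(n, k)` independently, so the
#' number of models generating that molecule follows
#' `Binomial(M, p_cov)`.
#'
#' @param num_models number of independent models `M`.
#' @param n space size.
#' @param k per-model sample size.
#' @return list with `p_cov`, `pmf` (over 0..M), `mean`, and `mode`
#'   (two values when `(M+1) p_cov` is an integer: both modes are reported).
#' @examples
#' ideal_frequency_null(25, 975820187, 2e9)  # mean 21.8, mode 22
#' @export
ideal_frequency_null <- function(num_models, n, k) {
  stopifnot(num_models >= 1)
  p <- expected_fraction(n, k)
  pmf <- stats::dbinom(0:num_models, num_models, p)
  mp <- (num_models + 1) * p
  mode <- if (abs(mp - round(mp)) < 1e-12 && mp >= 1 && mp <= num_models) {
    c(round(mp) - 1, round(mp))
  } else {
    floor(mp)
  }
  list(p_cov = p, pmf = stats::setNames(pmf, 0:num_models),
       mean = num_models * p, mode = mode)
}

#' Coverage of a non-uniform sampler and the uniform upper bound
#'
#' For a generator with molecule probabilities `p_i` (summing to 1 over the
#' space), the expected covered fraction after `k` draws is
#' `mean_i(1 - (1 - p_i)^k)`. By concavity this is maximized by the uniform
#' distribution, so the returned `bound_ok` checks the fraction against
#' `expected_fraction(n, k)` (uniform case) within a tolerance. When any
#' `p_i = 0`, the expected draws to full collection are unbounded, reported
#' via `full_collection = Inf`.
#'
#' @param probabilities non-negative vector summing to 1.
#' @param k sample size.
#' @param tolerance relative tolerance for the normalization and bound
#'   checks.
#' @return list with `fraction`, `bound_ok`, and `full_collection`
#'   (`Inf` if some probability is zero, `NA` otherwise: the exact
#'   non-uniform expectation is not computed).
#' @export
nonuniform_penalty_check <- function(probabilities, k, tolerance = 1e-9) {
  stopifnot(all(probabilities >= 0), k > 1)
  s <- sum(probabilities)
  if (abs(s - 1) > tolerance * length(probabilities))
    stop("probabilities must sum to 1 (got ", format(s), ")")
  n <- length(probabilities)
  covered <- ifelse(probabilities == 0, 0, -expm1(k * log1p(-probabilities)))
  fraction <- mean(covered)
  uniform <- expected_fraction(n, k)
  list(fraction = fraction,
       bound_ok = fraction <= uniform * (1 + tolerance) + tolerance,
       full_collection = if (any(probabilities == 0)) Inf else NA_real_)
}

# ---------------------------------------------------------------------------
# Monte-Carlo oracles: direct simulations used to validate the closed forms.

#' Simulate the coupon-collector problem
#'
#' Draws uniformly with replacement from `1..n` until every outcome has been
#' seen, recording the number of draws, repeated over `trials` independent
#' collections. A direct simulation (no use of the analytic formula), kept
#' as the package's empirical check of the expectation `n * H_n`.
#'
#' @param n number of coupons.
#' @param trials number of independent collections.
#' @param seed RNG seed.
#' @return list with `mean`, `se` (standard error of the mean), and
#'   `draws` (per-trial counts).
#' @export
simulate_coupon_collection <- function(n, trials = 1e4, seed = 1) {
  stopifnot(n > 1, trials >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  block <- as.integer(max(50, ceiling(n * (log(n) + 1) * 4)))
  draws <- vapply(seq_len(trials), function(i) {
    total <- 0L
    seen <- logical(n)
    repeat {
      d <- sample.int(n, block, replace = TRUE)
      for (j in seq_along(d)) {
        if (!seen[d[j]]) {
          seen[d[j]] <- TRUE
          if (all(seen)) return(total + j)
        }
      }
      total <- total + block
    }
  }, 1L)
  list(mean = mean(draws), se = stats::sd(draws) / sqrt(trials), draws = draws)
}

#' Simulate coverage of a uniform sampler
#'
#' Draws `k` samples with replacement from `1..n` and reports the fraction
#' of distinct outcomes observed, repeated over `trials`.
#'
#' @inheritParams simulate_coupon_collection
#' @param k draws per trial.
#' @return list with `mean`, `se`, and `fractions` (per trial).
#' @export
simulate_coverage <- function(n, k, trials = 1000, seed = 1) {
  stopifnot(n > 1, k >= 1, trials >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  fr <- vapply(seq_len(trials), function(i) {
    length(unique(sample.int(n, k, replace = TRUE))) / n
  }, 1)
  list(mean = mean(fr), se = stats::sd(fr) / sqrt(trials), fractions = fr)
}

#' Draw from the ideal model of a reference space
#'
#' Samples `k` molecules uniformly with replacement from the space — the
#' ideal generator made concrete, used to push an exactly-uniform sampler
#' through the same evaluation pipeline as trained models.
#'
#' @param space a [reference_space()].
#' @param k sample size.
#' @param seed RNG seed.
#' @return character vector of `k` canonical SMILES.
#' @export
sample_ideal <- function(space, k, seed = 1) {
  stopifnot(inherits(space, "reference_space"), k >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  space$molecules[sample.int(space$n, k, replace = TRUE)]
}
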