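breaks_for <- function(n) nll_breaks(n)

test_that("NLL distributions summarize a scored set", {
  m <- toy_model()
  br <- breaks_for(toy_space()$n)
  d <- nll_distribution(m, rep("CCO", 20), "validation", br)
  expect_equal(d$variance, 0)           # identical sequences
  expect_equal(sum(d$histogram), 1)
  expect_equal(d$mean, predict(m, "CCO")$nll)
})

test_that("a uniform-random scorer has mean near length x ln V", {
  sp <- toy_space()
  vocab <- build_vocabulary(sp$molecules)
  V <- length(vocab$tokens)
  m0 <- smiles_lm(sp$molecules[1], vocab = vocab, epochs = 1,
                  lr_start = 0, lr_end = 0, seed = 2)
  set <- sp$molecules[1:60]
  br <- breaks_for(sp$n)
  d <- nll_distribution(m0, set, "training", br)
  steps <- vapply(set, function(s) length(tokenize_smiles(s)) + 1L, 1L)
  expect_lt(abs(d$mean - mean(steps) * log(V)) / d$mean, 0.02)
})

test_that("training-set NLL falls as the model converges", {
  m <- toy_model()
  br <- breaks_for(toy_space()$n)
  train <- toy_split()$train
  d2 <- nll_distribution(checkpoint(m, 2), train, "training", br)
  d20 <- nll_distribution(checkpoint(m, 20), train, "training", br)
  expect_lt(d20$mean, d2$mean)
})

test_that("out-of-vocabulary sequences are skipped with a count", {
  m <- toy_model()
  br <- breaks_for(toy_space()$n)
  d <- nll_distribution(m, c("CCO", "CCS"), "sampled", br)  # S not in vocab
  expect_equal(d$n_skipped, 1L)
  expect_length(d$values, 1L)
})

test_that("Jensen-Shannon divergence has its defining properties", {
  m <- toy_model()
  br <- breaks_for(toy_space()$n)
  d <- nll_distribution(m, toy_split()$valid, "validation", br)
  expect_equal(jensen_shannon(d, d), 0)

  # disjoint supports attain the maximum ln 2
  h1 <- c(1, 0, 0, 0); h2 <- c(0, 0, 0, 1)
  expect_equal(jensen_shannon(h1, h2), log(2), tolerance = 1e-6)
  # symmetry and bounds on random histogram pairs
  set.seed(31)
  for (i in 1:20) {
    a <- runif(30); a <- a / sum(a)
    b <- runif(30); b <- b / sum(b)
    j <- jensen_shannon(a, b)
    expect_equal(j, jensen_shannon(b, a))
    expect_gte(j, 0); expect_lte(j, log(2))
  }
  d2 <- nll_distribution(m, toy_split()$valid, "validation",
                         nll_breaks(toy_space()$n, width = 1))
  expect_error(jensen_shannon(d, d2), "different")
})

test_that("binned JSD of two Gaussians matches dense quadrature", {
  # N(10,1) vs N(11,1) (shifted into the NLL range), 1e5 draws, bins of 0.25
  set.seed(77)
  x <- rnorm(1e5, 10, 1); y <- rnorm(1e5, 11, 1)
  br <- c(seq(0, 30, by = 0.25), Inf)
  hx <- hist(x, breaks = br, plot = FALSE)$counts / 1e5
  hy <- hist(y, breaks = br, plot = FALSE)$counts / 1e5
  emp <- jensen_shannon(hx, hy)
  # oracle: exact bin masses by the normal CDF, same JSD formula
  px <- diff(pnorm(br, 10, 1)); py <- diff(pnorm(br, 11, 1))
  ref <- jensen_shannon(px, py)
  expect_lt(abs(emp - ref) / ref, 0.02)
})

test_that("JSD estimates are stable across the candidate bin widths", {
  set.seed(78)
  x <- rnorm(2e4, 10, 1); y <- rnorm(2e4, 11, 1)
  js <- vapply(c(0.25, 0.5, 1), function(w) {
    br <- c(seq(0, 30, by = w), Inf)
    jensen_shannon(hist(x, breaks = br, plot = FALSE)$counts / 2e4,
                   hist(y, breaks = br, plot = FALSE)$counts / 2e4)
  }, 1)
  expect_true(all(js > 0 & js < log(2)))
  expect_lt(max(js) / min(js), 1.5)
})

# Hand-built diagnostics encoding a canonical training narrative:
# early memorized phase, middle agreement, late overfitting.
synthetic_diagnostics <- function() {
  e <- 1:12
  d <- data.frame(
    epoch = e,
    jsd_train_valid   = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50),
    jsd_train_sampled = c(0.45, 0.35, 0.25, 0.10, 0.05, 0.05, 0.05, 0.04, 0.03, 0.02, 0.02, 0.01),
    jsd_valid_sampled = c(0.40, 0.30, 0.22, 0.10, 0.05, 0.05, 0.05, 0.12, 0.25, 0.35, 0.45, 0.55),
    mean_train = c(9, 8, 7, 6.2, 6, 6, 6, 5.4, 4.8, 4.2, 3.6, 3),
    mean_valid = c(9, 8, 7, 6.2, 6, 6, 6, 6.5, 7.2, 8, 9, 10),
    mean_sampled = c(5, 5.5, 6, 6.1, 6, 6, 6, 5.5, 5, 4.4, 3.8, 3.2),
    var_train = rep(1, 12), var_valid = c(4, 3, 2, 1, 0.6, 0.5, 0.5, 1, 2, 3, 4, 5),
    var_sampled = rep(1, 12), percent_valid = rep(90, 12))
  attr(d, "n_space") <- round(exp(6))  # uniform mean ~ 6 nats
  class(d) <- c("epoch_diagnostics", "data.frame")
  d
}

test_that("diagnose reads the canonical narrative correctly", {
  dg <- diagnose(synthetic_diagnostics())
  expect_equal(dg$labels[1], "undertrained")      # sampled mean below others
  expect_true(all(dg$labels[5:7] == "converged"))
  expect_true(all(dg$labels[10:12] == "overtrained"))
  expect_true(all(dg$recommended %in% 4:7))
  # pure function: identical inputs, identical windows
  expect_identical(dg, diagnose(synthetic_diagnostics()))
})

test_that("degenerate diagnostic inputs are handled explicitly", {
  d <- synthetic_diagnostics()
  # constant diagnostics: everything converged, all epochs recommended
  flat <- d
  for (cn in setdiff(names(flat), "epoch")) flat[[cn]] <- rep(flat[[cn]][6], 12)
  dgf <- diagnose(flat)
  expect_true(all(dgf$labels == "converged"))
  expect_equal(dgf$recommended, 1:12)
  # monotonically diverging distributions: empty converged window
  div <- d
  div$jsd_train_valid <- seq(0.3, 0.69, length.out = 12)
  div$jsd_train_sampled <- seq(0.35, 0.69, length.out = 12)
  div$jsd_valid_sampled <- seq(0.3, 0.68, length.out = 12)
  dgd <- diagnose(div)
  expect_length(dgd$converged_window, 0)
  expect_length(dgd$recommended, 0)
  expect_error(diagnose(d[1:2, ]), "3 epochs")
})

test_that("the monitor flags an overfit-by-construction run as overtrained", {
  m <- overfit_model()
  spl <- overfit_split()
  d <- epoch_diagnostics(m, spl$train, spl$valid, n_space = toy_space()$n,
                         sample_size = 400, epochs = seq(2, 40, by = 2),
                         seed = 2)
  expect_true(all(d$var_valid >= 0))
  dg <- diagnose(d)
  expect_gt(sum(dg$labels == "overtrained"), 5)
  # the late phase of the run is dominated by the overtrained label
  expect_gt(mean(dg$labels[dg$epochs >= 20] == "overtrained"), 0.5)
})
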