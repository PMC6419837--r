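# The sequence model: initialization, scoring, teacher-forced training,
# sampling, and the consistency contracts between them.

test_that("fits are bit-reproducible given the seed", {
  a <- smiles_lm(c("CC", "CCO", "CCC"), epochs = 3, seed = 4)
  b <- smiles_lm(c("CC", "CCO", "CCC"), epochs = 3, seed = 4)
  expect_identical(a$loss_log, b$loss_log)
  expect_identical(a$params, b$params)
})

test_that("an untrained model scores every sequence near uniform", {
  vocab <- build_vocabulary(c("CC", "CO", "CN", "CCC"))
  V <- length(vocab$tokens)
  m0 <- smiles_lm("CC", vocab = vocab, epochs = 1, lr_start = 0, lr_end = 0,
                  seed = 9)
  # L = 4 steps after "^" (C, C, C, $): NLL ~ 4 ln V at random init
  nll <- predict(m0, "CCC")$nll
  expect_lt(abs(nll - 4 * log(V)) / (4 * log(V)), 0.01)
  expect_gt(nll, 0)
})

test_that("per-step outputs are probability distributions", {
  m <- toy_model()
  probs <- token_probabilities(m, toy_split()$train[1])
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-12)
})

test_that("one-pass NLL equals the chain-rule sum of stepwise conditionals", {
  m <- toy_model()
  for (s in toy_split()$valid[1:5]) {
    probs <- token_probabilities(m, s)
    targets <- attr(probs, "targets")
    stepwise <- -sum(log(probs[cbind(seq_len(nrow(probs)),
                                     match(targets, colnames(probs)))]))
    expect_equal(predict(m, s)$nll, stepwise, tolerance = 1e-10)
  }
})

test_that("validation NLL decreases over the early epochs of a toy fit", {
  ll <- toy_model()$loss_log
  expect_lt(ll$mean_valid_nll[5], ll$mean_valid_nll[1])
  expect_lt(ll$mean_valid_nll[20], ll$mean_valid_nll[5])
  expect_lt(ll$mean_valid_nll[40], ll$mean_valid_nll[10])
})

test_that("the learning rate decays geometrically between the endpoints", {
  ll <- toy_model()$loss_log
  expect_equal(ll$lr[1], 5e-3)
  expect_equal(ll$lr[nrow(ll)], 5e-4, tolerance = 1e-12)
  ratios <- ll$lr[-1] / ll$lr[-nrow(ll)]
  expect_equal(ratios, rep(ratios[1], length(ratios)), tolerance = 1e-10)
})

test_that("a model overfitted on one molecule reproduces it on sampling", {
  m <- smiles_lm(rep("CC", 64), epochs = 60, seed = 5, batch_size = 64,
                 lr_start = 5e-3, lr_end = 5e-3)
  s <- simulate(m, nsim = 1000, seed = 7)
  expect_gte(mean(s$smiles == "CC"), 0.99)
})

test_that("empirical sampling frequencies match exp(-NLL)", {
  m <- smiles_lm(c(rep("CC", 40), rep("CO", 24)), epochs = 60, seed = 6,
                 batch_size = 32, lr_start = 5e-3, lr_end = 5e-3)
  nsim <- 4000
  s <- simulate(m, nsim = nsim, seed = 8)
  tab <- sort(table(s$smiles), decreasing = TRUE)[1:5]
  p_model <- exp(-predict(m, names(tab))$nll)
  for (i in seq_along(tab)) {
    se <- sqrt(nsim * p_model[i] * (1 - p_model[i]))
    expect_lt(abs(as.integer(tab[i]) - nsim * p_model[i]), 3 * se + 1)
  }
})

test_that("sampling is reproducible and respects the truncation limit", {
  m <- toy_model()
  a <- simulate(m, nsim = 100, seed = 3)
  b <- simulate(m, nsim = 100, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$nll >= 0))
  short <- simulate(m, nsim = 200, seed = 3, max_length = 2)
  expect_true(any(short$truncated))
  expect_true(all(nchar(short$smiles) <= 2 * max(nchar(m$vocab$tokens))))
})

test_that("input contracts are enforced", {
  expect_error(smiles_lm(c("CC", "CO"), validation = c("CO", "CN")), "disjoint")
  m <- smiles_lm(c("CC", "CO"), epochs = 2, seed = 1)
  expect_error(predict(m, "CF"), "F")
  expect_error(smiles_lm(c("CC"), epochs = 2, lr_start = 1e-5, lr_end = 1e-3))
})

test_that("checkpoints reproduce the epoch they were taken at", {
  m <- toy_model()
  ck <- checkpoint(m, 10)
  expect_equal(ck$epoch, 10)
  expect_identical(ck$params, m$checkpoints[[10]])
  expect_error(checkpoint(ck, 5), "keep_checkpoints")
  expect_error(checkpoint(m, 999), "no checkpoint")
  # weights at different epochs genuinely differ
  expect_false(identical(checkpoint(m, 1)$params, checkpoint(m, 40)$params))
})
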