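test_that("the space sampled once each, canonically, gives full coverage", {
  sp <- toy_space()
  rep <- evaluate_sample(sp$molecules, sp)
  expect_equal(rep$total, sp$n)
  expect_equal(rep$valid, sp$n)
  expect_equal(rep$canonical_as_generated, sp$n)
  expect_equal(rep$in_space, sp$n)
  expect_equal(rep$out_of_space, 0L)
  expect_equal(rep$coverage_fraction, 1)
})

test_that("uniform sampling coverage matches the closed form within 3 SE", {
  sp <- toy_space()
  k <- 500
  rep <- evaluate_sample(sample_ideal(sp, k, seed = 4), sp)
  f <- expected_fraction(sp$n, k)
  se <- sqrt(f * (1 - f) / sp$n)
  expect_lt(abs(rep$coverage_fraction - f), 3 * se)
  expect_equal(rep$ideal_fraction, f)
})

test_that("invalid and truncated strings are classified as invalid", {
  sp <- toy_space()
  rep <- evaluate_sample(c("C1CC", "QXZ", "CCO"), sp)
  expect_equal(rep$invalid, 2L)
  expect_equal(rep$valid, 1L)
  df <- data.frame(smiles = c("CCO", "CCO"), truncated = c(FALSE, TRUE))
  rep2 <- evaluate_sample(df, sp)
  expect_equal(rep2$valid, 1L)
  expect_equal(rep2$invalid, 1L)
})

test_that("the partition identity holds on arbitrary mixed samples", {
  sp <- toy_space()
  set.seed(9)
  mixed <- c(sample(sp$molecules, 200, replace = TRUE),
             rep(c("CCCCCC", "CCOO", "xx", "C1CC"), 25),
             simulate(toy_model(), nsim = 300, seed = 1)$smiles)
  rep <- evaluate_sample(mixed, sp)
  expect_equal(rep$in_space + rep$out_of_space, rep$valid)
  expect_equal(rep$valid + rep$invalid, rep$total)
  expect_equal(rep$unique_in_space + rep$unique_out_of_space, rep$unique_valid)
  expect_lte(rep$unique_in_space, sp$n)
  expect_equal(length(rep$out_of_space_molecules), rep$unique_out_of_space)
})

test_that("sample preconditions are enforced", {
  sp <- toy_space()
  expect_error(evaluate_sample(character(0), sp), "empty")
  expect_error(evaluate_sample(c("CC", "CO"), sp, k = 5), "multiset")
})

test_that("chunked evaluation agrees with single-pass evaluation", {
  sp <- toy_space()
  s <- sample_ideal(sp, 400, seed = 12)
  a <- evaluate_sample(s, sp)
  b <- evaluate_sample(s, sp, chunk_size = 37L)
  a$out_of_space_molecules <- b$out_of_space_molecules <- NULL
  expect_equal(a[c("valid", "in_space", "unique_in_space", "coverage_fraction")],
               b[c("valid", "in_space", "unique_in_space", "coverage_fraction")])
})

test_that("identical model samples give an all-or-nothing spectrum", {
  sp <- toy_space()
  half <- sp$molecules[seq_len(sp$n %/% 2)]
  fs <- frequency_spectrum(rep(list(half), 4), sp)
  expect_setequal(unique(fs$frequency), c(0L, 4L))
  expect_equal(fs$mean, 4 * length(half) / sp$n)
  expect_equal(sum(fs$histogram), sp$n)
  expect_equal(fs$never_sampled_count, sp$n - length(half))
})

test_that("independent uniform samplers reproduce the binomial null", {
  sp <- toy_space()
  M <- 5; k <- 400
  sets <- lapply(1:M, function(i) unique(sample_ideal(sp, k, seed = 100 + i)))
  fs <- frequency_spectrum(sets, sp, k = k)
  expect_equal(sum(fs$histogram), sp$n)
  probs <- fs$null$pmf
  # pool cells with small expectation before the chi-square
  expected <- probs * sp$n
  pool <- cumsum(expected) < 5
  obs <- c(sum(fs$histogram[pool]), fs$histogram[!pool])
  p <- c(sum(probs[pool]), probs[!pool])
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("spectra reject molecules outside the space", {
  sp <- toy_space()
  expect_error(frequency_spectrum(list(c(sp$molecules[1], "CCCCCC")), sp),
               "outside")
})

test_that("frequency correlates perfectly with NLL by construction", {
  sp <- toy_space()
  M <- 5
  set.seed(21)
  f <- sample(0:M, sp$n, replace = TRUE)
  sets <- lapply(1:M, function(m) sp$molecules[f >= m])
  fs <- frequency_spectrum(sets, sp)
  # NLL = -ln(f/M) for sampled molecules, a large value for f = 0
  nll <- ifelse(f == 0, 20, -log(f / M))
  names(nll) <- sp$molecules
  res <- frequency_vs_nll(fs, nll)
  expect_equal(res$spearman_rho, -1)
  expect_equal(nrow(res$strata), M + 1)
  expect_true(all(diff(res$strata$mean_nll) < 0))
})

test_that("a single stratum reports an undefined correlation", {
  sp <- toy_space()
  fs <- frequency_spectrum(list(sp$molecules), sp)  # every molecule f = 1
  nll <- stats::setNames(rep(1, sp$n), sp$molecules)
  res <- frequency_vs_nll(fs, nll)
  expect_true(is.na(res$spearman_rho))
  expect_match(res$note, "stratum")
})

test_that("1-gram percentages count tokens exactly", {
  sp2 <- reference_space(c("CC", "CO"), compute_skeletons = FALSE)
  tab <- ngram_analysis(sp2, order = 1)
  expect_equal(tab$gram, c("C", "O"))
  expect_equal(tab$percent, c(75, 25))
  expect_equal(sum(tab$percent), 100)
  expect_error(ngram_analysis(sp2, order = 3), "order")
})

test_that("2-grams include boundary markers only on request", {
  sp2 <- reference_space(c("CC", "CO"), compute_skeletons = FALSE)
  plain <- ngram_analysis(sp2, order = 2)
  expect_setequal(plain$gram, c("CC", "CO"))
  with_b <- ngram_analysis(sp2, order = 2, include_boundary = TRUE)
  expect_true(all(c("^C", "C$", "O$") %in% with_b$gram))
})

test_that("gram frequency averages come from the containing molecules", {
  sp <- toy_space()
  # molecules containing nitrogen never sampled; everything else sampled once
  no_n <- sp$molecules[!grepl("[Nn]", sp$molecules)]
  fs <- frequency_spectrum(list(no_n), sp)
  tab <- ngram_analysis(sp, spectrum = fs, order = 1)
  expect_equal(tab$mean_frequency[tab$gram == "N"], 0)
  if ("n" %in% tab$gram)
    expect_equal(tab$mean_frequency[tab$gram == "n"], 0)
  expect_gt(tab$mean_frequency[tab$gram == "C"], 0)
  expect_equal(sum(tab$percent), 100, tolerance = 1e-9)
})
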