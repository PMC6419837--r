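# Expected MQN vectors below were frozen from an independent cheminformatics
# toolkit's implementation of the descriptor on molecules where the
# published MQN definitions are unambiguous.

.mqn_ref <- list(
  "C"        = c(1,0,0,0,0,0,0,0,0,0,0,1, 0,0,0,0,0,0,0, 0,0,0,0,0,0, 0,0,0,0,0,0,0, 0,0,0,0,0,0,0,0,0,0),
  "CCO"      = c(2,0,0,0,0,0,0,0,0,1,0,3, 2,0,0,0,0,0,0, 2,1,1,1,0,0, 2,1,0,0,0,0,0, 0,0,0,0,0,0,0,0,0,0),
  "c1ccncc1" = c(5,0,0,0,0,0,0,0,1,0,0,6, 0,0,0,3,3,0,0, 1,1,0,0,0,0, 0,0,0,0,6,0,0, 0,0,0,1,0,0,0,0,0,0),
  "C1CCCCC1" = c(6,0,0,0,0,0,0,0,0,0,0,6, 0,0,0,6,0,0,0, 0,0,0,0,0,0, 0,0,0,0,6,0,0, 0,0,0,1,0,0,0,0,0,0),
  "CC(=O)N"  = c(2,0,0,0,0,0,0,1,0,1,0,4, 2,1,0,0,0,0,0, 3,2,2,1,0,0, 3,0,1,0,0,0,0, 0,0,0,0,0,0,0,0,0,0),
  "C#N"      = c(1,0,0,0,0,0,0,1,0,0,0,2, 0,0,1,0,0,0,0, 1,1,0,0,0,0, 2,0,0,0,0,0,0, 0,0,0,0,0,0,0,0,0,0),
  "C1CC1"    = c(3,0,0,0,0,0,0,0,0,0,0,3, 0,0,0,3,0,0,0, 0,0,0,0,0,0, 0,0,0,0,3,0,0, 1,0,0,0,0,0,0,0,0,0),
  "O=C1CCO1" = c(3,0,0,0,0,0,0,0,0,1,1,5, 0,1,0,4,0,0,0, 4,2,0,0,0,0, 1,0,0,0,3,1,0, 0,1,0,0,0,0,0,0,0,0),
  "CC(C)=O"  = c(3,0,0,0,0,0,0,0,0,1,0,4, 2,1,0,0,0,0,0, 2,1,0,0,0,0, 3,0,1,0,0,0,0, 0,0,0,0,0,0,0,0,0,0),
  "NCC=O"    = c(2,0,0,0,0,0,0,1,0,1,0,4, 2,1,0,0,0,0,1, 3,2,2,1,0,0, 2,2,0,0,0,0,0, 0,0,0,0,0,0,0,0,0,0))

test_that("MQN fingerprints match the independent reference vectors", {
  got <- mqn_fingerprint(names(.mqn_ref))
  for (s in names(.mqn_ref)) {
    expect_equal(unname(got[s, ]), .mqn_ref[[s]], info = s)
  }
})

test_that("aromatic and saturated rings differ only where they should", {
  fp <- mqn_fingerprint(c("c1ccccc1", "C1CCCCC1"))
  expect_equal(unname(fp[1, "r6"]), unname(fp[2, "r6"]))     # same ring size
  expect_equal(unname(fp[1, "hac"]), unname(fp[2, "hac"]))
  expect_false(fp[1, "cdb"] == fp[2, "cdb"])                 # bond types differ
})

test_that("fingerprints are deterministic and reject invalid input", {
  a <- mqn_fingerprint(c("CCO", "CCO"))
  expect_equal(a[1, ], a[2, ])
  expect_error(mqn_fingerprint("C1CC"), "invalid")
})

test_that("separable clusters land on opposite sides of the map", {
  smiles <- c("C", "C", "C", "CCCCCCCCCC", "CCCCCCCCCC", "CCCCCCCCCC")
  map <- build_mqn_map(smiles, descriptor = "carbons", w = 2, h = 2)
  b <- map$buckets
  expect_equal(nrow(b), 2)
  expect_equal(sum(b$count), 6)
  expect_equal(abs(diff(b$x)), 1)  # opposite ends of PC1
})

test_that("maps conserve molecules and are input-order invariant", {
  sp <- toy_space()
  set.seed(5)
  mols <- sample(sp$molecules, 120)
  m1 <- build_mqn_map(mols, "cyclic_bonds", w = 8, h = 8)
  expect_equal(sum(m1$buckets$count), 120)
  perm <- sample(seq_along(mols))
  m2 <- build_mqn_map(mols[perm], "cyclic_bonds", w = 8, h = 8)
  o1 <- m1$buckets[order(m1$buckets$x, m1$buckets$y), ]
  o2 <- m2$buckets[order(m2$buckets$x, m2$buckets$y), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  expect_equal(m1$loadings, m2$loadings)
  # sign convention: dominant loading of each component is positive
  for (j in 1:2) expect_gt(max(m1$loadings[, j]), 0)
})

test_that("constant descriptors give a single hue", {
  smiles <- c("C", "CC", "CCC", "CCO", "CN")
  map <- build_mqn_map(smiles, descriptor = rep(3, 5), w = 4, h = 4)
  expect_true(all(map$buckets$descriptor_norm == 0.5))
})

test_that("identical fingerprints make the PCA degenerate", {
  expect_error(build_mqn_map(c("CCO", "CCO", "CCO"), rep(1, 3)), "degenerate")
})

test_that("pixel value is monotone in count, empty pixels stay black", {
  counts <- sort(runif(50))
  vals <- default_value_rule(counts)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0.25 & vals <= 1))
  expect_equal(default_value_rule(1), 1)  # fullest pixel at full value

  sp <- toy_space()
  map <- build_mqn_map(sp$molecules, "carbons", w = 8, h = 8)
  path <- withr::local_tempfile(fileext = ".png")
  render_map(map, path)
  img <- png::readPNG(path)
  expect_equal(dim(img), c(8, 8, 3))
  occupied <- matrix(FALSE, 8, 8)
  b <- map$buckets
  occupied[cbind(8 - b$y, b$x + 1)] <- TRUE
  # empty pixels are black
  expect_true(all(img[cbind(which(!occupied, arr.ind = TRUE), 1)] == 0))
  # the fullest pixel reaches full value (max RGB channel = 1)
  top <- b[which.max(b$count), ]
  expect_equal(max(img[8 - top$y, top$x + 1, ]), 1)
})
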