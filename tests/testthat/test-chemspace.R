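test_that("canonicalization handles valid, non-canonical and broken input", {
  expect_equal(canonicalize("C1CCCCC1"), "C1CCCCC1")
  # ethanol written backwards maps to the same canonical form as "CCO"
  expect_equal(canonicalize("OCC"), canonicalize("CCO"))
  expect_true(is.na(canonicalize("C1CC")))     # unclosed ring
  expect_true(is.na(canonicalize("QXZ")))
  # strings the permissive parser reads as hypervalent atoms are failures
  expect_true(is.na(canonicalize("CO=C")))     # trivalent neutral oxygen
  expect_true(is.na(canonicalize("C=N=C")))    # tetravalent neutral nitrogen
  expect_true(is.na(canonicalize("CC(#N)C")))  # pentavalent carbon
  expect_true(is.na(canonicalize("")))
  expect_equal(canonicalize(character(0)), character(0))
})

test_that("canonicalization is idempotent over a whole corpus", {
  corpus <- toy_space()$molecules
  expect_equal(canonicalize(corpus), corpus)
  mixed <- c("OCC", "C(C)(C)C", "N(C)C", "c1ccncc1")
  once <- canonicalize(mixed)
  expect_equal(canonicalize(once), once)
})

test_that("spaces load from SMILES files with dedup and failure accounting", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "OCC", "C1CC"), f)
  sp <- load_space(f, compute_skeletons = FALSE)
  expect_equal(sp$n, 1L)
  expect_equal(sp$molecules, canonicalize("CCO"))
  expect_equal(sp$parse_failures, 1L)
  expect_equal(sp$duplicates_removed, 1L)

  f2 <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("C", "CC", "CCC", "CCCC", "CO", "CN", "CCO", "CCN", "N", "O"), f2)
  sp2 <- load_space(f2, compute_skeletons = FALSE)
  expect_equal(sp2$n, 10L)
  expect_equal(sp2$p, 0.1)
  expect_equal(sp2$p * sp2$n, 1)

  f3 <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(0), f3)
  expect_error(load_space(f3), "empty")

  f4 <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "xx1", "yy2", "zz3"), f4)
  expect_error(load_space(f4), "parse")
})

test_that("written spaces round-trip with a JSON sidecar", {
  sp <- reference_space(c("CCO", "CC", "C"), compute_skeletons = FALSE)
  f <- withr::local_tempfile(fileext = ".smi")
  write_space(sp, f)
  sp2 <- load_space(f, compute_skeletons = FALSE)
  expect_equal(sp2$molecules, sp$molecules)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$n, 3L)
})

test_that("carbon skeletons strip heteroatoms and bond orders", {
  expect_equal(carbon_skeleton("CCO"), canonicalize("CCC"))
  expect_equal(carbon_skeleton("c1ccncc1"), canonicalize("C1CCCCC1"))
  expect_equal(carbon_skeleton("CCC"), canonicalize("CCC"))
  expect_equal(carbon_skeleton("CC=O"), canonicalize("CCC"))
  expect_error(carbon_skeleton("C1CC"), "invalid")
})

test_that("skeletons are invariant under heteroatom substitution", {
  groups <- list(c("CCO", "CCN", "CCC"),
                 c("C1CCO1", "C1CCN1", "C1CCC1"),
                 c("c1ccncc1", "c1ccccc1"),
                 c("CC(=O)N", "CC(=O)O", "CC(C)C"))
  for (g in groups) {
    sk <- carbon_skeleton(g)
    expect_length(unique(sk), 1L)
  }
})

test_that("micro-enumeration matches hand-enumerable sets", {
  sp <- enumerate_toy_space(
    enumeration_filters(max_heavy_atoms = 3, allowed_elements = "C",
                        max_bond_order = 1),
    max_rings = 0)
  expect_setequal(sp$molecules, canonicalize(c("C", "CC", "CCC")))
  expect_equal(sp$n, 3L)

  sp1 <- enumerate_toy_space(enumeration_filters(max_heavy_atoms = 1))
  expect_setequal(sp1$molecules, c("C", "N", "O"))
})

test_that("enumeration is exhaustive against an independent brute force", {
  # Oracle: enumerate every labeled multigraph on <= 3 atoms directly
  # (paths/stars with explicit bond orders), keep the valence-legal ones,
  # and reduce to canonical forms. The toolkit path grows graphs
  # incrementally instead, so agreement checks completeness.
  val <- c(C = 4, N = 3, O = 2)
  els <- names(val)
  bond <- c("-", "=", "#")
  cand <- as.character(els)
  for (a in els) for (b in els) for (o in 1:3) {
    if (o <= min(val[a], val[b]))
      cand <- c(cand, paste0(a, bond[o], b))
  }
  for (a in els) for (b in els) for (c in els) {
    for (o1 in 1:3) for (o2 in 1:3) {
      # path a - b - c with b in the middle
      if (o1 <= val[a] && o2 <= val[c] && o1 + o2 <= val[b])
        cand <- c(cand, paste0(a, bond[o1], b, bond[o2], c))
    }
  }
  cand <- gsub("-", "", cand, fixed = TRUE)
  oracle <- sort(unique(canonicalize(cand)))
  sp <- enumerate_toy_space(
    enumeration_filters(max_heavy_atoms = 3,
                        max_heteroatom_ratio = Inf,
                        disallowed_groups = c(),
                        disallowed_heteroatom_neighbors = character(0),
                        bond_rules = character(0)),
    max_rings = 0)
  expect_setequal(sp$molecules, oracle)
})

test_that("enumeration is deterministic and refuses unbounded sizes", {
  f <- enumeration_filters(max_heavy_atoms = 2)
  a <- enumerate_toy_space(f)
  b <- enumerate_toy_space(f)
  expect_identical(a$molecules, b$molecules)
  expect_error(enumerate_toy_space(enumeration_filters(max_heavy_atoms = 9)),
               "refusing")
})

test_that("every enumerated molecule passes the filters that built it", {
  sp <- toy_space()
  for (s in sp$molecules) {
    expect_identical(check_filters(s, sp$filters), character(0))
  }
})

test_that("check_filters reports the precise violated labels", {
  f <- toy_space()$filters
  expect_true("heavy_atom_count" %in% check_filters("CCCCC", f))
  # peroxide motif and nothing else (4 atoms, ratio 1, no N-O)
  expect_identical(check_filters("CCOO", f), "functional_group:peroxide")
  expect_true("heteroatom_neighbors" %in% check_filters("CNO", f))
  expect_true("element_set" %in% check_filters("CCS", f))
  expect_true("heteroatom_ratio" %in% check_filters("OCO", f))
  expect_error(check_filters("C1CC", f), "invalid")
})

test_that("filter definitions survive a JSON round trip", {
  f <- gdb_toy_filters()
  p <- withr::local_tempfile(fileext = ".json")
  write_filters(f, p)
  f2 <- read_filters(p)
  expect_equal(f2$max_heavy_atoms, f$max_heavy_atoms)
  expect_equal(f2$disallowed_groups, f$disallowed_groups)
  expect_equal(f2$bond_rules, f$bond_rules)
})
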