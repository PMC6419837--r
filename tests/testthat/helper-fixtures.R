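# Shared fixtures, built once per test run and memoized. All fixtures are
# generated in code (the toy space by exhaustive enumeration, models by
# fitting) — nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# The default miniature GDB-like space: every molecule over {C,N,O} up to 4
# heavy atoms, acyclic plus one ring, passing the default filters (n = 191).
toy_space <- function() {
  fixture("toy_space", function() enumerate_toy_space(gdb_toy_filters()))
}

toy_split <- function() {
  fixture("toy_split", function() split_space(toy_space(), 100, 50, seed = 2))
}

# Desk-scale training profile: small learning-rate window chosen for corpora
# where an epoch is only a handful of gradient steps.
toy_model <- function() {
  fixture("toy_model", function() {
    spl <- toy_split()
    smiles_lm(spl$train, spl$valid, epochs = 40, batch_size = 16,
              lr_start = 5e-3, lr_end = 5e-4, seed = 11,
              keep_checkpoints = TRUE)
  })
}

# Overfit-by-construction run: 10 training molecules recycled within each
# epoch so the model memorizes them, against a 40-molecule validation set.
overfit_split <- function() {
  fixture("overfit_split", function() split_space(toy_space(), 10, 40, seed = 3))
}

overfit_model <- function() {
  fixture("overfit_model", function() {
    spl <- overfit_split()
    smiles_lm(rep(spl$train, 16), spl$valid, epochs = 40, batch_size = 16,
              lr_start = 5e-3, lr_end = 5e-3, seed = 21,
              keep_checkpoints = TRUE)
  })
}
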