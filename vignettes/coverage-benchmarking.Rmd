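---
title: "Benchmarking generative SMILES models against an enumerated chemical space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking generative SMILES models against an enumerated chemical space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A SMILES language model is trained on a small random sample of a *finite*,
exhaustively enumerated chemical space (a GDB-style database) and then
sampled. Because the target space is finite and known, two questions become
quantitative: how *much* of the space can the model generate
(completeness), and how *evenly* does it spread its probability mass over
the space (uniformness)?

The yardstick is the **ideal model**: an abstract generator that emits each
of the `n` molecules of the space with probability `p = 1/n` and nothing
else. Its behaviour is closed-form:

* Drawing with replacement until every molecule is seen is the classical
  coupon-collector problem: the expected number of draws is `n * H_n`,
  with `H_n` the n-th harmonic number, asymptotically
  `n (ln n + gamma) + 1/2` (`gamma` the Euler–Mascheroni constant).
  `expected_draws_full_collection()` uses the exact harmonic sum up to
  `n = 1e6` and the asymptotic form above it; the two agree to better than
  one part in 1e6 at the crossover.
* After `k` draws the expected covered fraction is `1 - (1 - 1/n)^k`
  (`expected_fraction()`), evaluated as `-expm1(k * log1p(-1/n))` because
  at database scale `1 - 1/n` must never be exponentiated literally.
* Every sequence has probability `1/n`, so the ideal negative
  log-likelihood (NLL) distribution is a point mass: mean `ln n`, variance
  zero (`uniform_nll_stats()`).
* If `M` independent ideal models each draw `k` samples, the number of
  models generating a given molecule is `Binomial(M, p_cov)` with
  `p_cov = expected_fraction(n, k)` (`ideal_frequency_null()`).

By Jensen's inequality the uniform distribution maximizes expected
coverage, so the ideal fraction is an upper bound for any trained
generator: a model that is non-uniform or incomplete covers strictly less
(`nonuniform_penalty_check()` verifies this empirically for arbitrary
probability vectors). Coverage of a real model at sample size `k`,
measured by `evaluate_sample()`, therefore reads directly as "how close to
ideal is this architecture on this space".

## The sequence model

`smiles_lm()` fits the generator: token embedding, stacked GRU layers, a
linear layer and a softmax over the vocabulary. Sequences are tokenized
with begin/end markers (`^`/`$`), multi-character atoms (`Cl`, `Br`) and
bracket expressions are single tokens. Training is teacher forcing on the
sequence NLL (natural logs throughout; the loss never depends on sampled
tokens), with ADAM (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`) and a
learning rate multiplied by a constant each epoch so that it decays
geometrically between the configured endpoints. Sampling is multinomial
from the per-step softmax, token by token, until `$` or the length limit
(truncated sequences are flagged and counted as invalid downstream).

The network is implemented directly in base R matrix algebra, with
backpropagation through time and a global gradient-norm clip of 5. The
implementation is validated in the test suite by numerical oracles:
stepwise chain-rule consistency of the NLL, near-uniform scores
(`L * ln V`) at random initialization, an overfit-to-one-molecule
reproduction check, and agreement of empirical sample frequencies with
`exp(-NLL)`.

Two hyperparameter profiles ship with the package. The full-scale
reference profile (embedding 256, hidden 512, 3 GRU layers, batch 128,
learning rate 1e-3 to 1e-5, 140-token limit; `lm_reference_profile()`) is
the configuration appropriate for spaces of 1e9 molecules and 1e6-sequence
training sets. The desk-scale defaults used in the examples and tests are
embedding 32, hidden 64, one layer, 50-token limit, and — because a toy
corpus of 100 sequences gives only a handful of gradient steps per
epoch — a higher learning-rate window (5e-3 to 5e-4 over 40 epochs, batch
16). With the full-scale window a toy fit would terminate essentially
untrained; the desk-scale window was fixed once from that observation, not
tuned against any benchmark outcome.

## The toy reference space

A coverage benchmark needs a finite space that is exhaustively enumerable
on a laptop. `enumerate_toy_space()` grows connected molecular graphs
atom by atom over the allowed elements (default C, N, O with valences
4/3/2, hydrogens implicit), closing at most one ring, deduplicating by
canonical SMILES at every step, and finally applies the filters. Filters
are applied only at emission because the heteroatom-ratio rule is not
monotone under atom addition. The default `gdb_toy_filters()` space caps
molecules at 4 heavy atoms and excludes O–O and N–N bonds of any order,
N–O bonds, allenes, triple bonds in rings and unsaturated 3-membered
rings, yielding **n = 173** molecules — small enough that every test can
re-derive facts about it, large enough that a sampled model covers it
gradually. The heteroatom/carbon ratio rule (default max 1) applies only
to carbon-containing molecules, so the single atoms C, N, O are all
members.

Canonicalization, validity and SMARTS matching are delegated to OpenBabel;
the space's canonical form is whatever the pinned toolkit produces, and
all membership tests compare canonical strings only. One consequence,
surfaced while testing: strings such as `(CC)C`, which stricter toolkits
reject, are parsed by OpenBabel as disconnected fragments. The package
treats them as valid multi-fragment molecules; they can never be in-space
(every space member is connected) and their carbon skeletons are
dot-joined fragment skeletons.

What the toy space does *not* emulate about a real enumerated database:
molecules are tiny (so SMILES are short and easy to learn), the filter
list is illustrative rather than the database's real one, there is no
stereochemistry, and the enumeration is genuinely exhaustive (a real
database's hierarchical filtering is not, which is one source of its
"miscellaneous" out-of-space category). Passing the toy benchmark
therefore shows that the *machinery* — training, scoring, coverage
accounting, diagnostics — is correct, not that a given architecture will
reach any particular coverage at database scale.

## Training diagnostics

`epoch_diagnostics()` scores the training, validation and freshly sampled
sets after each retained epoch and `diagnose()` reads the three NLL
distributions jointly:

* sampled set more probable than held-out data with large JSDs:
  **undertrained** (the model parrots a subset of the training set);
* all three pairwise Jensen–Shannon divergences near their minima:
  **converged** — sampling inside and outside the training set is about
  equally likely, which is when coverage peaks;
* sampled set approaching the training set while departing from
  validation: **overtrained**.

The recommended epoch window intersects the converged-JSD window with the
epochs whose validation mean NLL is closest to the uniform reference
`ln n` and whose validation variance (ideal: 0) is near its minimum.

JSD needs a common discretization; the package uses shared fixed bins of
0.5 nats spanning `[0, ln n + 20]` with an overflow bin and 1e-12
smoothing mass so KL terms stay finite. The bin width is a documented
choice, not a reproduction of any particular published script; a test
checks that widths 0.25/0.5/1.0 give estimates within 50% of each other
on a known case, and a quadrature oracle pins the 0.25-nat binning to
within 2% of the exact JSD of two Gaussians. Two guards make the labels
robust on degenerate inputs: the converged label additionally requires
all JSDs below an absolute ceiling (0.25 nats, several times the
converged-phase values observed in healthy toy runs) so that a
monotonically diverging run reports an *empty* converged window, and
trend detection uses rolling least-squares slopes over +/-2 epochs.

## Out-of-space labelling and maps

Every valid sampled molecule outside the space is annotated with all the
constraints it breaks (`label_molecule()`): heavy-atom count, element set,
heteroatom ratio, named functional-group patterns, heteroatom
neighbourhoods, bond rules, and graph topology — the latter by checking
the molecule's carbon skeleton (all atoms to carbon, all bonds single)
against the space's precomputed skeleton set. Labels have no priority
order; a molecule violating nothing is labelled `miscellaneous`. Tautomer
detection is a pluggable hook because tautomer enumeration is a separate
algorithmic problem; without a hook the category is reported as "not
evaluated". On the toy space miscellaneous should be near zero (the
enumeration is exhaustive and a single toolkit defines canonical forms);
this is an expectation, not an assertion.

`build_mqn_map()` draws chemical-space maps: 42-dimension MQN
fingerprints (implemented in-package from the molecular graph, frozen
against an independent implementation on unambiguous molecules), PCA on
the raw unscaled fingerprint matrix (centered — PCA is on the covariance —
but never standardized), the first two components bucketed into a pixel
grid, and HSV colouring with hue = normalized mean descriptor and
value driven by occupancy. The literal published value rule
`min(0.25, log10(count_norm))` is degenerate (the log of a normalized
count is never positive, so the `min` is constant); the package implements
`clip(max(0.25, 1 + log10(count_norm)), 0, 1)`, which realizes the stated
intent — sparse pixels fade toward the black background, the fullest pixel
reaches full value — and exposes the rule as a pluggable function.
Component signs follow the convention that each component's largest
loading is positive, making maps order- and platform-stable.

## Numerical and design notes

* All NLLs and divergences are in nats.
* Probabilities of the form `(1 - p)^k` are always computed via
  `expm1`/`log1p`.
* The binomial mode is `floor((M + 1) p)`, with the exact-integer tie
  reported as two modes.
* Batch padding uses the `$` token id with padded positions masked out of
  the loss; gradients flowing through padded steps are provably zero, so
  no extra masking of the recurrence is needed.
* Determinism: fits, samples, splits and enumerations are reproducible
  given their seeds; the benchmark driver derives every stage seed from
  one master seed.
* Problem sizes in the tests and examples (n = 173 space, 100/50 splits,
  k = 2000 evaluation samples, 40 epochs, 1e5-trial Monte-Carlo oracles)
  were chosen so the whole suite re-derives its expectations from scratch
  in well under a minute per module.

## Known limitations

* The evaluation pipeline chunks its input but keeps the unique-molecule
  sets in memory; billion-string samples would need an external unique
  store.
* The toy enumerator is exhaustive only up to 6 heavy atoms and one ring
  closure by design (it refuses more).
* MQN hydrogen-bond counts use the simple N/O lone-pair and N-H/O-H rules;
  exotic valence states outside the toy element set are not modelled.
* Monitoring is post hoc, by design: `diagnose()` recommends epochs after
  training; it does not implement early stopping.
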