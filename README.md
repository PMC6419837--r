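# smilesbench

Coverage benchmarks for SMILES generative models on exhaustively
enumerated chemical spaces.

When a generative language model is trained on a random sample of a
*finite* chemical database (a GDB-style exhaustive enumeration), the
obvious questions become measurable: what fraction of the database can the
model generate, and how uniformly does it sample it? `smilesbench` answers
both by comparing the trained model against the **ideal model** — the
abstract generator that emits each of the `n` database molecules with
probability `1/n` and nothing else. The package is aimed at people
developing or evaluating molecular generative models who want a
closed-form yardstick instead of heuristic similarity metrics.

The ideal model's behaviour is classical probability:

- Expected draws to collect the whole space (coupon-collector):
  `E[T] = n·H_n ≈ n(ln n + γ) + 1/2`.
- Expected fraction covered by `k` draws: `f = 1 − (1 − 1/n)^k`.
  By Jensen's inequality this is an **upper bound** for any non-uniform or
  incomplete generator, which is what makes it a benchmark.
- Ideal negative log-likelihood distribution: point mass at `ln n`
  (variance 0).
- Frequency of a molecule across `M` independently trained models:
  `Binomial(M, f)`.

Around that core the package provides the full working pipeline at desk
scale: a toy exhaustive enumerator with explicit chemical filters, a
SMILES tokenizer, a GRU language model fitted by teacher forcing
(`smiles_lm()`, a classed model with `predict`/`simulate`/`plot` methods),
NLL-histogram training diagnostics with Jensen–Shannon divergences
(`epoch_diagnostics()`, `diagnose()`), sample partition and coverage
reports (`evaluate_sample()`), multi-model frequency spectra
(`frequency_spectrum()`), constraint labelling of out-of-space molecules
(`label_molecule()`), and MQN/PCA chemical-space maps (`build_mqn_map()`).

## Worked example

Enumerate a miniature reference space, train a model on 100 of its
molecules, and score a 2000-draw sample:

```r
library(smilesbench)

space <- enumerate_toy_space(gdb_toy_filters())
space
#> Reference chemical space: n = 173 molecules (p = 0.00578 each)
#>   distinct carbon skeletons: 8
#>   enumeration filters attached

split <- split_space(space, train_size = 100, valid_size = 50, seed = 2)
fit <- smiles_lm(split$train, split$valid, epochs = 40, batch_size = 16,
                 lr_start = 5e-3, lr_end = 5e-4, seed = 11,
                 keep_checkpoints = TRUE)
fit
#> SMILES GRU language model (epoch 40)
#>   vocabulary: 10 tokens; embedding 32; 1 x GRU(64)
#>   trained on 100 sequences (50 validation), batch 16, lr 5.0e-03 -> 5.0e-04
#>   final mean NLL: train 6.987, valid 7.675 nats

sample <- simulate(fit, nsim = 2000, seed = 33)
evaluate_sample(sample, space)
#> Sample report: k = 2000 draws against a space of n = 173
#>   valid SMILES:                 1142 (57.1%)
#>   canonical as generated:        812 (40.6%)
#>   in space / out of space:       955 / 187
#>   unique in space:               144 -> coverage 0.8324 (ideal 1.0000, gap 0.1676)
```

Reading the report: 57% of generated strings are chemically valid, 41%
were emitted directly in canonical form, and the model has reproduced 144
of the 173 database molecules — coverage 0.83 against the ideal bound of
~1.0 at this sample size, so this small model is still visibly short of a
uniform generator.

Training-state diagnosis from the per-epoch NLL distributions:

```r
d <- epoch_diagnostics(fit, split$train, split$valid, n_space = space$n,
                       sample_size = 500, epochs = seq(2, 40, by = 2), seed = 1)
diagnose(d)
#> Training diagnosis (uniform reference mean = 5.15 nats)
#>   undertrained 3 epoch(s)
#>   transitional 3 epoch(s)
#>   converged    14 epoch(s)
#>   recommended epochs: 30-40
```

And the constraint taxonomy of what the model generates *outside* the
space:

```r
rep <- evaluate_sample(sample, space)
violation_summary(label_molecules(rep$out_of_space_molecules, space = space))
#> Constraint violations across 110 out-of-space molecules:
#>   heteroatom_ratio              43.6%
#>   graph_topology                29.1%
#>   heavy_atom_count              29.1%
#>   heteroatom_neighbors          22.7%
#>   functional_group:hydrazine    19.1%
#>   bond_rule                     12.7%
#>   functional_group:allene        5.5%
#>   functional_group:peroxide      3.6%
#>   (tautomer_of_member: not evaluated, no tautomer hook configured)
#>   constraints broken per molecule: 1:56  2:41  3:8  4:5
```

At full database scale the ideal-model arithmetic runs in microseconds:

```r
expected_draws_full_collection(975820187)   # 20,761,554,747 draws
100 * expected_fraction(975820187, 2e9)     # 87.12 % coverage at 2e9 draws
ideal_frequency_null(25, 975820187, 2e9)    # Binomial null: mean 21.8, mode 22
```

`run_benchmark(benchmark_config(...))` wires all stages (enumerate, split,
train M models, monitor, sample, evaluate, frequency spectrum, labelling)
into one report. The methods vignette
(`vignettes/coverage-benchmarking.Rmd`) documents the model, the filter
set, every tunable default and the package's design decisions.

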