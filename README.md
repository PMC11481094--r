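# momcts

Pareto multiobjective Monte Carlo tree search for de novo molecular
generation in R.

Drug candidates must satisfy several properties at once — bind the
target, look drug-like, avoid toxicity — and these goals conflict.
Collapsing them into one weighted score bakes the trade-off in before the
search starts.  `momcts` instead searches the space of SMILES strings for
the whole *Pareto front* of trade-offs in a single run:

* **The tree is the string.**  Each node holds one SMILES token; a
  root-to-node path is a molecule prefix.  A recurrent (GRU) language
  model trained on known molecules — or a transparent n-gram model —
  proposes continuations and completes prefixes into whole molecules.
* **Vector rewards, hypervolume selection.**  Each completed molecule is
  scored on all objectives at once, shaped into `[0,1]^d` (docking
  affinity via a saturating improvement-over-baseline map, QED
  drug-likeness, one-minus-toxicity-probability), behind a hard
  synthetic-accessibility gate (SAscore ≤ 3.5).  Children are ranked by
  the exact hypervolume their optimistic (component-wise UCB) reward
  vector would add to the current nondominated archive, with a
  projection-distance penalty for dominated vectors — so the search is
  pulled toward every unexplored part of the front, not a single corner.
* **Chemistry is real.**  Validity means surviving RDKit sanitization
  (via a persistent Python subprocess); duplicates are detected on
  canonical SMILES and evaluated once; metrics (validity, uniqueness,
  novelty, internal diversity over Morgan fingerprints) follow the
  standard definitions for generative models.

The methods vignette (`vignette("momcts-methods")`) derives the node
value, proves that adding a constant objective of 1 degenerates the
machinery exactly to scalar UCB1, and records all defaults and
limitations.

## Requirements

* R ≥ 4.1 with `jsonlite` and `yaml` (plus `testthat`/`withr` to run the
  tests).
* Python ≥ 3.8 with RDKit on the `PATH` (override the interpreter with
  the `MOMCTS_PYTHON` environment variable).  `chem_available()` reports
  whether the backend is reachable.
* Optional, only for real docking objectives: AutoDock Vina and Open
  Babel binaries.

```r
# from the package directory
R CMD INSTALL .
```

## A worked example

Fully offline: a synthetic training corpus, a small GRU policy (20
epochs, ~2 s), mock docking/toxicity plus real QED, 400 search
iterations (~6 s).

```r
library(momcts)

corpus <- generate_fixture_corpus(100, seed = 1)
policy <- train_policy(corpus,
  policy_config(embedding_dim = 24, hidden_dim = 96,
                num_recurrent_layers = 1, epochs = 20,
                batch_size = 16, max_length = 40, seed = 1))

objectives <- objective_set(
  list(objective_mock_docking(), objective_qed(), objective_mock_toxicity()),
  validity = "chem", sa = "mock")

run <- run_search(search_config(max_iterations = 400, max_length = 40, seed = 1),
                  policy, objectives)
run
#> <momcts run: 400 iterations, 59 unique molecules, front size 11, hypervolume 0.4534>

run$front
#> <Pareto front: 11 points, d = 3>
#>            [,1]      [,2]      [,3]
#>  [1,] 0.7021797 0.4444408 0.8320184
#>  [2,] 0.8130304 0.4426284 0.8205385
#>  [3,] 0.7347820 0.5340885 0.7508842
#>  ...

head(run$front$members, 3)
#> [[1]] "CCC(C)C"
#> [[2]] "c1ccccc1"
#> [[3]] "CC(C)CCO"

compute_metrics(run, training_corpus = corpus)
#> generated: 400   valid: 138   unique: 59
#> validity            0.3450
#> uniqueness          0.4275
#> duplication ratio   0.5725
#> novelty             0.7288
#> internal diversity  0.9278
```

The columns of `run$records` (one row per iteration: SMILES, canonical
form, validity/filter flags, raw objective values, shaped rewards, front
membership) are what `write_generation_log()` exports as tidy CSV.

### Declarative runs and the CLI

The same experiment can be described in YAML — see
`system.file("extdata", "example_run.yaml", package = "momcts")` — and
executed with `run_from_config("run.yaml")`, which writes the generation
log, Pareto front, metrics and a run manifest.  A thin command-line
interface wraps the same entry points:

```sh
cli=$(Rscript -e 'cat(system.file("cli/momcts", package = "momcts"))')
Rscript "$cli" fixtures --n 100 --seed 1 --out corpus.smi
Rscript "$cli" train --corpus corpus.smi --kind ngram --out policy.rds
Rscript "$cli" run --config run.yaml
Rscript "$cli" metrics --log momcts_run/generation_log.csv --corpus corpus.smi
Rscript "$cli" front --log momcts_run/generation_log.csv --out front.csv
```

Exit codes: 0 success, 2 usage/configuration error, 3 runtime failure.

## Correctness

The test suite checks the numerical core against independent oracles:

* Pareto fronts against an all-pairs dominance scan; the incremental
  archive against batch recomputation under random insertion orders.
* Exact hypervolume against inclusion–exclusion (small sets) and
  Monte-Carlo box sampling (10⁶ points, 3-σ bound); monotonicity under
  insertion.
* The hand-written GRU backward pass against central finite differences.
* The full search loop against an exhaustively enumerable toy space
  (3-letter alphabet, length ≤ 6, anti-correlated objectives): 2,000
  iterations recover all 13 points of the analytic Pareto front with no
  spurious points, and checkpoint hypervolumes are non-decreasing.
* Byte-identical outputs for repeated runs under a fixed seed.

One acceptance block encodes full-scale targets (validity 0.735,
uniqueness 0.976, internal diversity 0.886, each within three standard
deviations over five runs, and a −9.4 kcal/mol cocrystal-ligand
re-docking check).  It requires a ~250k-molecule training corpus, a
receptor structure, a docking engine and multi-day compute, none of which
ship with the package, so it fails with a clear message on a desktop
setup — by design, not by accident.

## Package layout

```
R/                 core: tokenizer, policies (GRU + n-gram), Pareto/hypervolume,
                   search loop, objectives/QED, metrics, YAML config, fixtures
inst/python/       RDKit worker subprocess (line-JSON over FIFOs)
inst/cli/momcts    command-line interface
inst/extdata/      shipped fixture corpus and example run config
tests/testthat/    unit, property and acceptance tests with built-in oracles
scripts/           acceptance report generator
vignettes/         methods vignette
```

## License

MIT — see `LICENSE`.
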