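Package: momcts
Title: Pareto Multiobjective Monte Carlo Tree Search for De Novo Molecular Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates small molecules optimized simultaneously for several
    objectives (predicted binding affinity, drug-likeness, low toxicity) by
    Monte Carlo tree search over SMILES strings.  Tree nodes hold single
    SMILES vocabulary tokens; rollouts are completed by a recurrent (GRU)
    language model trained on a SMILES corpus, or by a deterministic n-gram
    policy for fully offline use.  Node selection scalarizes vector rewards
    through the hypervolume indicator of the current Pareto front with a
    projection-distance penalty for dominated candidates.  Includes an exact
    hypervolume computation (staircase in 2-D, dimension sweep in higher
    dimensions), an incremental nondominated archive, reward shaping for
    docking/QED/toxicity objectives with a synthetic-accessibility filter,
    generation-quality metrics (validity, uniqueness, novelty, internal
    diversity), and fully offline fixtures with enumerable toy search spaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
SystemRequirements: Python (>= 3.8) with RDKit (chemistry backend);
    AutoDock Vina and Open Babel (optional, docking adapter only)
Config/testthat/edition: 3
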