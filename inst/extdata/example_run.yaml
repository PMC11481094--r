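# Example offline run configuration.
#
# Uses the shipped synthetic training corpus, an n-gram rollout policy and
# the deterministic mock objectives, so it runs with no docking engine and
# finishes in seconds.  Replace `corpus` with a real training set and the
# mock components with `kind: docking` (plus receptor/box) for a real
# campaign.  Relative paths are resolved against the working directory;
# point `corpus` at `system.file("extdata", "fixture_corpus.smi",
# package = "momcts")` or copy the file next to this config.
seed: 1
policy:
  kind: ngram        # or: recurrent (trains the GRU; slower)
  corpus: fixture_corpus.smi
  order: 3
  alpha: 0.5         # additive smoothing; keeps rollouts exploratory
search:
  c: 1.0             # exploration constant per reward component
  max_iterations: 500
  max_length: 40     # tokens, sentinels included
  expansion_prob_floor: 0.001
  checkpoint_schedule: [50, 100, 200]
objectives:
  components:
    - kind: mock_docking   # deterministic stand-in for a docking engine
      baseline: 0.0
    - kind: qed
    - kind: mock_toxicity
  validity: chem     # sanitize via the chemistry backend
  sa: chem           # synthetic-accessibility filter
  sa_threshold: 3.5
output:
  dir: momcts_run
  log: generation_log.csv
  front: pareto_front.csv
  metrics: metrics.json
  manifest: manifest.json
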