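test_that("docking reward is the shaped, clipped improvement over baseline", {
  expect_equal(reward_docking(-9.4, baseline = 0), 9.4 / 10.4, tolerance = 1e-12)
  expect_equal(reward_docking(0), 0)
  expect_equal(reward_docking(3.2), 0)         # worse than baseline clips to 0
  expect_equal(reward_docking(-5, baseline = -6), 0)
  ds <- seq(-15, 0, by = 0.5)
  r <- reward_docking(ds)
  expect_true(all(diff(r) <= 0))               # better (lower) score, higher reward
  expect_true(all(r >= 0 & r < 1))
  expect_error(reward_docking(NaN), class = "momcts_domain_error")
})

test_that("QED and toxicity rewards are shaped into [0, 1]", {
  expect_equal(reward_qed(0.67), 0.67)
  expect_equal(reward_qed(1.2), 1)
  expect_equal(reward_qed(-0.1), 0)
  expect_equal(reward_toxicity(0.25), 0.75)
  expect_error(reward_toxicity(1.5), class = "momcts_domain_error")
  expect_error(reward_toxicity(-0.1), class = "momcts_domain_error")
})

test_that("the synthetic-accessibility filter is inclusive at the threshold", {
  expect_true(sa_filter(3.5))
  expect_false(sa_filter(3.500001))
  expect_true(sa_filter(1))
  expect_false(sa_filter(10))
  expect_error(sa_filter(0.5), class = "momcts_domain_error")
  expect_error(sa_filter(11), class = "momcts_domain_error")
})

test_that("docking output parsing reads both result formats", {
  pdbqt <- c("MODEL 1", "REMARK VINA RESULT:    -9.4      0.000      0.000",
             "ATOM ...")
  expect_equal(parse_vina_affinity(pdbqt), -9.4)
  table_out <- c("mode |   affinity | dist from best mode",
                 "-----+------------+---------------------",
                 "   1       -7.2          0.000      0.000",
                 "   2       -6.9          1.873      2.441")
  expect_equal(parse_vina_affinity(table_out), -7.2)
})

test_that("mock objectives are deterministic and bounded", {
  for (s in c("CCO", "c1ccccc1", "CC(=O)OC", "CCCCCCCCCC")) {
    expect_identical(mock_docking_score(s), mock_docking_score(s))
    expect_lt(mock_docking_score(s), 0)
    p <- mock_toxicity_probability(s)
    expect_gte(p, 0); expect_lte(p, 1)
    sa <- mock_sa_score(s)
    expect_gte(sa, 1); expect_lte(sa, 10)
  }
  # more heavy atoms and rings bind better in the mock
  expect_lt(mock_docking_score("c1ccccc1CCCC"), mock_docking_score("CC"))
})

test_that("objective sets validate their specifications", {
  expect_error(objective_set(list()), class = "momcts_domain_error")
  expect_error(objective_set(list(objective_qed(), "not an objective")),
               class = "momcts_domain_error")
  expect_error(objective_set(list(objective_qed("x"), objective_mock_docking(name = "x"))),
               class = "momcts_domain_error")
  os <- objective_set(list(objective_mock_docking(), objective_qed()),
                      validity = "all", sa = "mock")
  expect_s3_class(os, "momcts_objective_set")
  expect_equal(os$sa_threshold, 3.5)
})

test_that("evaluating objectives returns named raw values and unit-box rewards", {
  os <- objective_set(list(objective_mock_docking(), objective_qed(),
                           objective_mock_toxicity()),
                      validity = "chem", sa = "mock")
  ev <- evaluate_objectives("CCO", os)
  expect_named(ev$raw, c("docking", "qed", "toxicity"))
  expect_true(all(ev$reward >= 0 & ev$reward <= 1))
  expect_false(isTRUE(ev$failed))
  # docking reward consistent with its transform
  expect_equal(unname(ev$reward["docking"]),
               reward_docking(mock_docking_score("CCO")), tolerance = 1e-12)
})

test_that("a missing docking engine falls back to the mock with a warning", {
  cfg <- docking_config(receptor = "r.pdbqt", center = c(0, 0, 0),
                        size = c(20, 20, 20), vina = "", obabel = "")
  expect_warning(obj <- objective_docking(cfg), "mock")
  expect_equal(obj$kind, "mock")
})

test_that("docking configuration validates the search box", {
  expect_error(docking_config("r", center = c(0, 0), size = c(1, 1, 1)),
               class = "momcts_domain_error")
  expect_error(docking_config("r", center = c(0, 0, 0), size = c(0, 1, 1)),
               class = "momcts_domain_error")
  expect_error(docking_config("r", c(0, 0, 0), c(1, 1, 1), exhaustiveness = 0),
               class = "momcts_domain_error")
})

test_that("native QED agrees with the chemistry backend's own value", {
  for (s in c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "c1ccccc1",
              "CC(C)Cc1ccc(cc1)C(C)C(=O)O")) {
    props <- qed_properties(s)
    ours <- qed_from_properties(props)
    backend <- momcts:::chem_call(list(op = "qed", smiles = list(s)), "qed")[[1]]
    expect_equal(ours, backend, tolerance = 1e-6)
    expect_equal(qed_score(s), ours)
  }
})

test_that("QED handles missing descriptors and invalid molecules", {
  props <- qed_properties("CCO")
  props$MW <- NA_real_
  expect_true(is.na(qed_from_properties(props)))
  expect_error(qed_from_properties(data.frame(MW = 100)),
               class = "momcts_domain_error")
  expect_true(is.na(qed_score("CC(")))
})
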