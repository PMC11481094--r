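test_that("the fixture corpus is deterministic under its seed", {
  a <- generate_fixture_corpus(50, seed = 1)
  b <- generate_fixture_corpus(50, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_fixture_corpus(50, seed = 2)))
  expect_length(a, 50L)
  expect_error(generate_fixture_corpus(0), class = "momcts_domain_error")
})

test_that("every fixture molecule is sanitizable and tokenizable", {
  corpus <- fixture_corpus()
  expect_true(all(check_validity(corpus)$valid))
  v <- default_vocabulary()
  for (s in corpus) expect_identical(detokenize(tokenize(s, v)), s)
})

test_that("toy spaces validate their definition", {
  expect_error(toy_space(alphabet = character(0)), class = "momcts_domain_error")
  expect_error(toy_space(alphabet = c("C", "C")), class = "momcts_domain_error")
  expect_error(toy_space(max_length = 0), class = "momcts_domain_error")
  expect_error(toy_space(objectives = list(function(s) 0)),
               class = "momcts_domain_error")
})

test_that("enumeration is exact and refuses oversized spaces", {
  sp <- toy_space(alphabet = c("C", "N", "O"), max_length = 4L)
  res <- enumerate_toy_pareto(sp)
  expect_equal(nrow(res$table), sum(3^(1:4)))
  # front from the table must agree with the all-pairs dominance oracle
  pts <- as.matrix(res$table[, names(sp$objectives)])
  oracle <- unique(pts[oracle_front_indices(pts), , drop = FALSE])
  expect_equal(nrow(res$front$points), nrow(oracle))
  expect_error(enumerate_toy_pareto(toy_space(max_length = 20L)),
               class = "momcts_space_too_large_error")
})

test_that("anti-correlated objectives put every achievable point on the front", {
  sp <- toy_space(max_length = 6L)
  res <- enumerate_toy_pareto(sp)
  achievable <- unique(res$table[, names(sp$objectives)])
  expect_equal(nrow(res$front$points), nrow(achievable))
  expect_equal(nrow(res$front$points), 13L)  # Farey fractions with denominator <= 6
})

test_that("constant objectives collapse the front to a single point", {
  sp <- toy_space(max_length = 3L,
                  objectives = list(u = function(s) 0.5, v = function(s) 0.5))
  res <- enumerate_toy_pareto(sp)
  expect_equal(nrow(res$front$points), 1L)
  expect_equal(unname(res$front$points[1, ]), c(0.5, 0.5))
})

test_that("the toy objective set accepts only strings inside the universe", {
  sp <- toy_space(max_length = 3L)
  os <- toy_objective_set(sp)
  expect_true(momcts:::obj_validity(os, "CNO")$valid)
  expect_false(momcts:::obj_validity(os, "CNOC")$valid)   # too long
  expect_false(momcts:::obj_validity(os, "CX")$valid)     # foreign token
  ev <- evaluate_objectives("CCN", os)
  expect_equal(unname(ev$reward), c(2 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("the toy policy can reach the whole universe", {
  sp <- toy_space()
  pol <- toy_policy(sp)
  p <- next_token_distribution(pol, c("&", "C", "N"))
  nonstart <- p[!names(p) %in% "&"]
  expect_true(all(nonstart > 0))
  expect_equal(sum(p), 1)
})
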