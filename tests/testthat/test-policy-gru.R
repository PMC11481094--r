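# The recurrent model is hand-written, so its backward pass is checked
# against central finite differences on a small instance.

test_that("analytic gradients match finite differences", {
  corpus <- c("CCO", "CC(C)O", "OCC", "C=CC")
  vocab <- vocabulary_from_corpus(corpus)
  V <- length(vocab$tokens)
  params <- momcts:::gru_init_params(V, 5L, 7L, 2L, seed = 3)
  seqs <- lapply(corpus, function(s)
    encode(c("&", tokenize(s, vocab)$tokens, "\n"), vocab))
  lens <- vapply(seqs, length, 1L) - 1L
  Tm <- max(lens)
  end_id <- encode("\n", vocab)
  ids <- matrix(end_id, length(seqs), Tm + 1L)
  for (b in seq_along(seqs)) ids[b, seq_along(seqs[[b]])] <- seqs[[b]]

  loss_at <- function(p) momcts:::gru_forward(p, ids, lens, keep_cache = FALSE)$loss
  fw <- momcts:::gru_forward(params, ids, lens, keep_cache = TRUE)
  grad <- momcts:::gru_backward(params, ids, fw)

  eps <- 1e-5
  set.seed(11)
  check_slot <- function(get, set, g) {
    w <- get(params)
    for (k in sample(length(w), min(4L, length(w)))) {
      p_hi <- set(params, k, w[k] + eps)
      p_lo <- set(params, k, w[k] - eps)
      num <- (loss_at(p_hi) - loss_at(p_lo)) / (2 * eps)
      expect_equal(g[k], num, tolerance = 1e-4)
    }
  }
  check_slot(function(p) p$E,
             function(p, k, v) { p$E[k] <- v; p }, grad$E)
  check_slot(function(p) p$Wout,
             function(p, k, v) { p$Wout[k] <- v; p }, grad$Wout)
  check_slot(function(p) p$bout,
             function(p, k, v) { p$bout[k] <- v; p }, grad$bout)
  for (l in 1:2) {
    for (nm in c("Wr", "Wz", "Wn", "Ur", "Uz", "Un", "br", "bz", "bn")) {
      check_slot(function(p) p$layers[[l]][[nm]],
                 function(p, k, v) { p$layers[[l]][[nm]][k] <- v; p },
                 grad$layers[[l]][[nm]])
    }
  }
})

test_that("training reduces the cross-entropy loss", {
  corpus <- fixture_corpus()[1:40]
  pol <- train_policy(corpus, policy_config(embedding_dim = 12, hidden_dim = 24,
                                            num_recurrent_layers = 1,
                                            epochs = 8, batch_size = 8,
                                            max_length = 40, seed = 2))
  lh <- pol$loss_history
  expect_length(lh, 8L)
  expect_lt(lh[8], lh[1])
  expect_true(all(is.finite(lh)))
})

test_that("training and rollouts are deterministic under the seed", {
  corpus <- fixture_corpus()[1:20]
  cfg <- policy_config(embedding_dim = 8, hidden_dim = 12,
                       num_recurrent_layers = 1, epochs = 2, batch_size = 8,
                       max_length = 40, seed = 5)
  p1 <- train_policy(corpus, cfg)
  p2 <- train_policy(corpus, cfg)
  expect_identical(p1$params, p2$params)
  set.seed(9); r1 <- rollout(p1)
  set.seed(9); r2 <- rollout(p2)
  expect_identical(r1$tokens, r2$tokens)
})

test_that("next-token distributions are proper probabilities", {
  pol <- fixture_gru_policy()
  p <- next_token_distribution(pol, c("&", "C", "C"))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_named(p, pol$vocabulary$tokens)
})

test_that("checkpoints round-trip and reject mismatched vocabularies", {
  pol <- fixture_gru_policy()
  path <- withr::local_tempfile(fileext = ".rds")
  save_policy(pol, path)
  pol2 <- load_policy(path)
  expect_identical(pol2$params, pol$params)
  p1 <- next_token_distribution(pol, c("&", "C"))
  p2 <- next_token_distribution(pol2, c("&", "C"))
  expect_identical(p1, p2)
  other <- vocabulary(c("C", "O"))
  expect_error(load_policy(path, vocab = other), class = "momcts_checkpoint_error")
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1, 2), bad)
  expect_error(load_policy(bad), class = "momcts_checkpoint_error")
})

test_that("scaled-down training yields mostly valid rollouts", {
  pol <- fixture_gru_policy()
  set.seed(7)
  sm <- replicate(50, tokens_to_smiles(rollout(pol, max_length = 40)))
  expect_gt(mean(check_validity(sm)$valid), 0.6)
})
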