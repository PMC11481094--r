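# Independent oracles used across the suite.  Each reimplements a quantity
# by the most naive correct method available so that the package's optimized
# paths can be checked against them.

# All-pairs dominance front: keep x iff no other point dominates it.
oracle_front_indices <- function(pts) {
  n <- nrow(pts)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j == i) next
      if (all(pts[j, ] >= pts[i, ]) && any(pts[j, ] > pts[i, ])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  which(keep)
}

# Hypervolume by inclusion-exclusion over box unions (exact, exponential in n).
oracle_hv_incl_excl <- function(pts, z) {
  n <- nrow(pts)
  total <- 0
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    corner <- apply(pts[idx, , drop = FALSE], 2, min)
    vol <- prod(pmax(0, corner - z))
    total <- total + (-1)^(length(idx) + 1L) * vol
  }
  total
}

# Hypervolume by Monte-Carlo box sampling; returns estimate and standard error.
oracle_hv_monte_carlo <- function(pts, z, upper, n_samples = 1e6) {
  d <- ncol(pts)
  samples <- matrix(stats::runif(n_samples * d), n_samples, d)
  samples <- sweep(samples, 2, upper - z, "*")
  samples <- sweep(samples, 2, z, "+")
  inside <- rep(FALSE, n_samples)
  for (i in seq_len(nrow(pts))) {
    inside <- inside | rowSums(sweep(samples, 2, pts[i, ], "<=")) == d
  }
  p <- mean(inside)
  box <- prod(upper - z)
  list(estimate = p * box, se = sqrt(p * (1 - p) / n_samples) * box)
}

# Brute-force n-gram conditional probability from raw string counts.
oracle_ngram_prob <- function(corpus, context_tokens, next_token, vocab_tokens,
                              alpha = 0) {
  hits <- 0L; ctx <- 0L
  k <- length(context_tokens)
  for (s in corpus) {
    toks <- c("&", strsplit(s, "", fixed = TRUE)[[1]], "\n")
    if (length(toks) < k + 1L) next
    for (pos in seq_len(length(toks) - k)) {
      if (identical(toks[pos:(pos + k - 1L)], context_tokens)) {
        ctx <- ctx + 1L
        if (toks[pos + k] == next_token) hits <- hits + 1L
      }
    }
  }
  # additive smoothing over the vocabulary minus the start sentinel
  v <- sum(vocab_tokens != "&")
  (hits + alpha) / (ctx + alpha * v)
}

# Internal diversity directly from a full pairwise similarity matrix.
oracle_internal_diversity <- function(smiles) {
  smiles <- unique(smiles)
  fps <- morgan_fingerprints(smiles)
  fps <- fps[!vapply(fps, is.null, TRUE)]
  m <- length(fps)
  if (m < 2L) return(0)
  sims <- c()
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      a <- fps[[i]]; b <- fps[[j]]
      sims <- c(sims, length(intersect(a, b)) / length(union(a, b)))
    }
  }
  1 - mean(sims)
}

# Shared fixture corpus (built once per test session).
fixture_corpus <- local({
  corpus <- NULL
  function() {
    if (is.null(corpus)) corpus <<- generate_fixture_corpus(100, seed = 1)
    corpus
  }
})

# Scaled-down recurrent policy on the fixture corpus (cached across tests).
fixture_gru_policy <- local({
  pol <- NULL
  function() {
    if (is.null(pol)) {
      pol <<- train_policy(fixture_corpus(),
                           policy_config(embedding_dim = 24, hidden_dim = 96,
                                         num_recurrent_layers = 1,
                                         epochs = 20, batch_size = 16,
                                         learning_rate = 0.01,
                                         max_length = 40, seed = 1))
    }
    pol
  }
})

tokens_to_smiles <- function(seq) momcts:::detokenize_chr(seq$tokens)
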