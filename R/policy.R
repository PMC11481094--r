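#' Configuration for the recurrent rollout policy
#'
#' Defaults follow the reference training setup for the SMILES language
#' model: an 81-dimensional token embedding, two 256-unit GRU layers with
#' tanh candidate activation, Adam with learning rate 0.01, batch size 256,
#' 100 epochs.  `max_length` caps rollouts (in tokens, sentinels included).
#'
#' @param embedding_dim embedding dimension.
#' @param hidden_dim GRU hidden units per layer.
#' @param num_recurrent_layers number of stacked GRU layers.
#' @param learning_rate Adam learning rate.
#' @param batch_size sequences per gradient step.
#' @param epochs passes over the corpus.
#' @param max_length maximum rollout length in tokens.
#' @param seed seed for initialization and batch shuffling.
#' @return a list of class `momcts_policy_config`.
#' @export
policy_config <- function(embedding_dim = 81L, hidden_dim = 256L,
                          num_recurrent_layers = 2L, learning_rate = 0.01,
                          batch_size = 256L, epochs = 100L,
                          max_length = 100L, seed = 1L) {
  for (v in c(embedding_dim, hidden_dim, num_recurrent_layers, batch_size, epochs)) {
    if (!is_count(v)) momcts_error("policy dimensions must be positive integers",
                                   "momcts_domain_error")
  }
  if (!is_count(max_length) || max_length < 2) {
    momcts_error("max_length must be an integer >= 2", "momcts_domain_error")
  }
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    momcts_error("learning_rate must be positive", "momcts_domain_error")
  }
  structure(list(embedding_dim = as.integer(embedding_dim),
                 hidden_dim = as.integer(hidden_dim),
                 num_recurrent_layers = as.integer(num_recurrent_layers),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 max_length = as.integer(max_length),
                 seed = as.integer(seed)),
            class = "momcts_policy_config")
}

#' Train the recurrent SMILES language model
#'
#' Minimizes next-token cross-entropy on start-prefixed, end-terminated token
#' sequences.  The trained model is frozen: search never updates it.
#'
#' @param corpus character vector of SMILES strings, or a path to a SMILES
#'   line file (one molecule per line, optional tab-separated id).
#' @param cfg a [policy_config()].
#' @param vocab optional [vocabulary()]; by default rebuilt from the corpus.
#' @param verbose print per-epoch loss.
#' @return a policy of class `c("momcts_gru_policy", "momcts_policy")` with a
#'   `loss_history` attribute (mean training loss per epoch).
#' @export
train_policy <- function(corpus, cfg = policy_config(), vocab = NULL,
                         verbose = FALSE) {
  if (length(corpus) == 1L && !grepl("[&\n]", corpus) && file.exists(corpus)) {
    corpus <- read_smiles_file(corpus)
  }
  if (!length(corpus)) momcts_error("empty corpus", "momcts_empty_corpus_error")
  if (is.null(vocab)) vocab <- vocabulary_from_corpus(corpus)
  seqs <- vector("list", length(corpus))
  for (li in seq_along(corpus)) {
    seqs[[li]] <- tryCatch(
      encode(c(START_TOKEN, tokenize(corpus[[li]], vocab)$tokens, END_TOKEN), vocab),
      error = function(e) momcts_error(sprintf("line %d: %s", li, conditionMessage(e)),
                                       "momcts_unknown_token_error", line = li))
  }
  V <- length(vocab$tokens)
  end_id <- encode(END_TOKEN, vocab)
  params <- gru_init_params(V, cfg$embedding_dim, cfg$hidden_dim,
                            cfg$num_recurrent_layers, cfg$seed)
  opt <- adam_init(params)
  n <- length(seqs)
  loss_history <- numeric(cfg$epochs)
  set.seed(cfg$seed)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_tok <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      batch <- seqs[idx]
      lens <- vapply(batch, length, 1L) - 1L  # prediction targets per row
      Tm <- max(lens)
      ids <- matrix(end_id, length(batch), Tm + 1L)
      for (b in seq_along(batch)) ids[b, seq_along(batch[[b]])] <- batch[[b]]
      fw <- gru_forward(params, ids, lens, keep_cache = TRUE)
      grad <- gru_backward(params, ids, fw)
      st <- adam_step(params, grad, opt, cfg$learning_rate)
      params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + fw$loss * sum(lens)
      ep_tok <- ep_tok + sum(lens)
    }
    loss_history[ep] <- ep_loss / ep_tok
    if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, loss_history[ep]))
  }
  structure(list(kind = "recurrent", vocabulary = vocab, config = cfg,
                 params = params, loss_history = loss_history),
            class = c("momcts_gru_policy", "momcts_policy"))
}

#' @export
print.momcts_gru_policy <- function(x, ...) {
  cat(sprintf("<GRU policy: %d-dim embedding, %d x %d GRU, |V| = %d, final loss %.4f>\n",
              x$config$embedding_dim, x$config$num_recurrent_layers,
              x$config$hidden_dim, length(x$vocabulary$tokens),
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Next-token distribution of a policy
#'
#' @param policy a trained policy (`momcts_gru_policy` or
#'   `momcts_ngram_policy`).
#' @param prefix a `momcts_token_sequence`, character vector of tokens, or
#'   integer vector of vocabulary indices.  Must begin with the start token
#'   and contain no terminator.
#' @return a probability vector over the full vocabulary (sums to 1).
#' @export
next_token_distribution <- function(policy, prefix) {
  UseMethod("next_token_distribution")
}

prefix_ids <- function(policy, prefix) {
  vocab <- policy$vocabulary
  ids <- if (is.numeric(prefix)) as.integer(prefix)
         else encode(if (inherits(prefix, "momcts_token_sequence")) prefix$tokens
                     else as.character(prefix), vocab)
  if (!length(ids) || ids[1L] != encode(START_TOKEN, vocab)) {
    momcts_error("prefix must begin with the start token", "momcts_domain_error")
  }
  if (encode(END_TOKEN, vocab) %in% ids) {
    momcts_error("prefix already contains the terminator",
                 "momcts_prefix_terminated_error")
  }
  ids
}

#' @export
next_token_distribution.momcts_ngram_policy <- function(policy, prefix) {
  p <- ngram_distribution(policy, prefix_ids(policy, prefix))
  names(p) <- policy$vocabulary$tokens
  p
}

#' @export
next_token_distribution.momcts_gru_policy <- function(policy, prefix) {
  ids <- prefix_ids(policy, prefix)
  hidden <- gru_init_hidden(policy$params)
  for (id in ids) {
    st <- gru_step(policy$params, id, hidden)
    hidden <- st$hidden
  }
  p <- st$probs
  names(p) <- policy$vocabulary$tokens
  p
}

#' Complete a prefix by sampling from the policy
#'
#' Tokens are sampled autoregressively (multinomial at temperature 1) until
#' the terminator appears or `max_length` tokens are reached.  Sampling draws
#' from R's global random number stream, so a preceding `set.seed()` makes
#' the rollout reproducible.
#'
#' @param policy a trained policy.
#' @param prefix prefix tokens (defaults to the bare start token).
#' @param max_length hard cap on total sequence length in tokens.
#' @return a `momcts_token_sequence` extending the prefix, with attribute
#'   `truncated` set to `TRUE` when the cap was hit before the terminator.
#' @export
rollout <- function(policy, prefix = START_TOKEN,
                    max_length = policy$config$max_length %||% 100L) {
  vocab <- policy$vocabulary
  ids <- prefix_ids(policy, prefix)
  if (length(ids) >= max_length) {
    momcts_error("prefix length must be below max_length", "momcts_domain_error")
  }
  end_id <- encode(END_TOKEN, vocab)
  if (inherits(policy, "momcts_gru_policy")) {
    hidden <- gru_init_hidden(policy$params)
    for (id in ids) {
      st <- gru_step(policy$params, id, hidden)
      hidden <- st$hidden
    }
    while (length(ids) < max_length) {
      nxt <- sample.int(length(st$probs), 1L, prob = st$probs)
      ids <- c(ids, nxt)
      if (nxt == end_id) break
      st <- gru_step(policy$params, nxt, hidden)
      hidden <- st$hidden
    }
  } else {
    while (length(ids) < max_length) {
      p <- ngram_distribution(policy, ids)
      nxt <- sample.int(length(p), 1L, prob = p)
      ids <- c(ids, nxt)
      if (nxt == end_id) break
    }
  }
  out <- token_sequence(vocab$tokens[ids])
  attr(out, "truncated") <- ids[length(ids)] != end_id
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a policy checkpoint
#'
#' The checkpoint is a single file bundling the weights (or count tables),
#' the vocabulary and the configuration.  Loading against an explicitly
#' supplied vocabulary that differs from the stored one is an error, since
#' integer indices would no longer line up with the embedding rows.
#'
#' @param policy a policy object.
#' @param path checkpoint file path.
#' @param vocab optional vocabulary the checkpoint is required to match.
#' @export
save_policy <- function(policy, path) {
  saveRDS(policy, path)
  invisible(path)
}

#' @rdname save_policy
#' @export
load_policy <- function(path, vocab = NULL) {
  policy <- readRDS(path)
  if (!inherits(policy, "momcts_policy")) {
    momcts_error("file does not contain a policy checkpoint", "momcts_checkpoint_error")
  }
  if (!is.null(vocab) && !identical(vocab$tokens, policy$vocabulary$tokens)) {
    momcts_error("checkpoint vocabulary does not match the supplied vocabulary",
                 "momcts_checkpoint_error")
  }
  policy
}
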