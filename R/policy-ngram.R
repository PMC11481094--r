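#' Count-based n-gram rollout policy
#'
#' A deterministic, fully inspectable language model over token sequences:
#' the next-token distribution given a prefix is the conditional frequency of
#' the last `order - 1` tokens in the training corpus, optionally with
#' additive (Laplace) smoothing, and uniform over the vocabulary on contexts
#' never seen in training.  It exists so that the tree search is exercisable
#' and oracle-checkable without training a recurrent model.
#'
#' @param corpus character vector of SMILES strings, or a path to a SMILES
#'   line file.
#' @param vocab a [vocabulary()]; defaults to one built from the corpus.
#' @param order n-gram order (context length is `order - 1` tokens).
#' @param alpha additive smoothing pseudo-count.  The default `0` uses raw
#'   conditional frequencies on seen contexts (so a single-sequence corpus
#'   makes rollouts deterministic); `alpha = 1` gives add-one smoothing.
#' @return a policy object of class `c("momcts_ngram_policy", "momcts_policy")`.
#' @export
ngram_policy <- function(corpus, vocab = NULL, order = 3L, alpha = 0) {
  if (length(corpus) == 1L && !grepl("[&\n]", corpus) && file.exists(corpus)) {
    corpus <- read_smiles_file(corpus)
  }
  if (!length(corpus)) momcts_error("empty corpus", "momcts_empty_corpus_error")
  if (!is_count(order) || order < 2L) momcts_error("order must be >= 2", "momcts_domain_error")
  if (is.null(vocab)) vocab <- vocabulary_from_corpus(corpus)
  counts <- new.env(parent = emptyenv())
  V <- length(vocab$tokens)
  for (li in seq_along(corpus)) {
    toks <- tryCatch(tokenize(corpus[[li]], vocab)$tokens, error = function(e) {
      momcts_error(sprintf("line %d: %s", li, conditionMessage(e)),
                   "momcts_unknown_token_error", line = li)
    })
    seqt <- c(START_TOKEN, toks, END_TOKEN)
    ids <- encode(seqt, vocab)
    for (pos in 2:length(ids)) {
      lo <- max(1L, pos - (order - 1L))
      key <- paste(ids[lo:(pos - 1L)], collapse = ",")
      tab <- if (exists(key, envir = counts, inherits = FALSE)) get(key, envir = counts) else integer(V)
      tab[ids[pos]] <- tab[ids[pos]] + 1L
      assign(key, tab, envir = counts)
    }
  }
  structure(list(kind = "ngram", vocabulary = vocab, order = as.integer(order),
                 alpha = alpha, counts = counts),
            class = c("momcts_ngram_policy", "momcts_policy"))
}

#' @export
print.momcts_ngram_policy <- function(x, ...) {
  cat(sprintf("<n-gram policy: order %d, alpha %g, %d contexts, |V| = %d>\n",
              x$order, x$alpha, length(ls(x$counts)), length(x$vocabulary$tokens)))
  invisible(x)
}

ngram_distribution <- function(policy, prefix_ids) {
  V <- length(policy$vocabulary$tokens)
  start_id <- get(START_TOKEN, envir = policy$vocabulary$index_of)
  k <- policy$order - 1L
  lo <- max(1L, length(prefix_ids) - k + 1L)
  key <- paste(prefix_ids[lo:length(prefix_ids)], collapse = ",")
  seen <- exists(key, envir = policy$counts, inherits = FALSE)
  p <- if (seen) get(key, envir = policy$counts) + policy$alpha else numeric(V)
  # the start sentinel can never follow anything
  p[start_id] <- 0
  tot <- sum(p)
  if (tot == 0) {
    p <- rep(1 / (V - 1L), V)
    p[start_id] <- 0
    return(p)
  }
  p / tot
}
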