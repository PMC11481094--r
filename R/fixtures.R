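#' Offline fixtures: synthetic corpora and enumerable toy search spaces
#'
#' The fixture corpus emulates a small drug-like SMILES training set
#' (alkyl chains, ethers, amines, alcohols, single carbocycles and
#' aromatics) built from templated scaffolds, so every module is exercisable
#' without the real ~250k-molecule training corpus.  Toy spaces are small
#' enough to enumerate exhaustively, giving the search an analytically known
#' Pareto front to recover.
#'
#' @name fixtures
NULL

#' Generate a synthetic SMILES training corpus
#'
#' Deterministic under the seed; every line is a valid, sanitizable
#' molecule whose tokens are drawn from the default vocabulary (atoms,
#' bonds, branch parentheses and ring digits).
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @return character vector of `n` SMILES strings (duplicates possible for
#'   large `n`, as in real corpora).
#' @export
generate_fixture_corpus <- function(n = 100L, seed = 1L) {
  if (!is_count(n)) momcts_error("n must be a positive integer", "momcts_domain_error")
  set.seed(seed)
  chain <- function(k) paste(rep("C", k), collapse = "")
  out <- character(n)
  for (i in seq_len(n)) {
    kind <- sample(6L, 1L)
    out[i] <- switch(kind,
      # plain and branched alkanes
      {
        k <- sample(2:8, 1L)
        s <- chain(k)
        if (k >= 4 && stats::runif(1) < 0.5) {
          s <- paste0(chain(k - 2L), "(C)", chain(1L))
        }
        s
      },
      # ethers and alcohols
      {
        k <- sample(1:4, 1L); m <- sample(1:4, 1L)
        if (stats::runif(1) < 0.5) paste0(chain(k), "O", chain(m))
        else paste0(chain(k), "O")
      },
      # amines and nitriles
      {
        k <- sample(1:5, 1L)
        if (stats::runif(1) < 0.6) paste0(chain(k), "N")
        else paste0(chain(k), "C#N")
      },
      # carbonyls: ketones, acids, esters
      {
        k <- sample(1:3, 1L); m <- sample(1:3, 1L)
        pick <- sample(3L, 1L)
        if (pick == 1L) paste0(chain(k), "C(=O)", chain(m))
        else if (pick == 2L) paste0(chain(k), "C(=O)O")
        else paste0(chain(k), "C(=O)O", chain(m))
      },
      # benzene ring with 0-2 substituents
      {
        subs <- sample(0:2, 1L)
        s <- "c1ccccc1"
        if (subs >= 1L) s <- paste0(sample(c("C", "CC", "O", "N", "CO"), 1L), s)
        if (subs == 2L) s <- paste0(s, sample(c("C", "O", "N"), 1L))
        s
      },
      # saturated rings
      {
        k <- sample(c(5L, 6L), 1L)
        s <- paste0("C1", paste(rep("C", k - 1L), collapse = ""), "1")
        if (stats::runif(1) < 0.4) s <- paste0(s, sample(c("C", "O", "N"), 1L))
        s
      })
  }
  out
}

#' Enumerable toy search space
#'
#' A tiny SMILES-like string universe: all non-empty strings over `alphabet`
#' of length at most `max_length`, with deterministic objective functions
#' mapping each string to `[0, 1]^d`.  Small enough that the exact Pareto
#' front is computable by exhaustive enumeration, which makes it an oracle
#' for the tree search.
#'
#' @param alphabet character vector of single tokens (terminator excluded).
#' @param max_length maximum string length in tokens.
#' @param objectives named list of functions, each mapping a string to a
#'   value in `[0, 1]`.
#' @return an object of class `momcts_toy_space`.
#' @export
toy_space <- function(alphabet = c("C", "N", "O"), max_length = 6L,
                      objectives = toy_objectives_anticorrelated()) {
  if (!length(alphabet) || anyDuplicated(alphabet)) {
    momcts_error("alphabet must be distinct tokens", "momcts_domain_error")
  }
  if (!is_count(max_length)) momcts_error("max_length must be >= 1", "momcts_domain_error")
  if (is.null(names(objectives)) || any(!nzchar(names(objectives)))) {
    momcts_error("objectives must be a named list", "momcts_domain_error")
  }
  structure(list(alphabet = alphabet, max_length = as.integer(max_length),
                 objectives = objectives),
            class = "momcts_toy_space")
}

#' Anti-correlated toy objective pair
#'
#' `f` is the fraction of `"C"` tokens in the string; the second objective is
#' `1 - f`.  Every achievable point lies on the Pareto front, which makes
#' front-recovery rates easy to interpret.
#'
#' @param token the token whose fraction defines `f`.
#' @return named list of two functions.
#' @export
toy_objectives_anticorrelated <- function(token = "C") {
  frac <- function(s) {
    toks <- strsplit(s, "", fixed = TRUE)[[1]]
    if (!length(toks)) return(0)
    mean(toks == token)
  }
  list(f = frac, g = function(s) 1 - frac(s))
}

#' Exact Pareto front of a toy space by exhaustive enumeration
#'
#' @param space a [toy_space()].
#' @param max_points enumeration cap on `|alphabet|^max_length`.
#' @return a list with `front` (a `momcts_pareto_front` whose members are
#'   the achieving strings), and `table` (data.frame of every string and its
#'   objective values).
#' @export
enumerate_toy_pareto <- function(space, max_points = 1e6) {
  total <- sum(length(space$alphabet)^seq_len(space$max_length))
  if (total > max_points) {
    momcts_error(sprintf("toy space has %.0f strings, above the enumeration cap %g",
                         total, max_points), "momcts_space_too_large_error")
  }
  strings <- character(0)
  level <- ""
  for (len in seq_len(space$max_length)) {
    level <- as.vector(outer(level, space$alphabet, paste0))
    strings <- c(strings, level)
  }
  vals <- vapply(space$objectives,
                 function(f) vapply(strings, f, 0, USE.NAMES = FALSE),
                 numeric(length(strings)))
  vals <- matrix(vals, nrow = length(strings))
  colnames(vals) <- names(space$objectives)
  front <- pareto_front(vals, ids = strings)
  tab <- data.frame(string = strings, vals, stringsAsFactors = FALSE)
  list(front = front, table = tab)
}

#' Objective set over a toy space
#'
#' Strings inside the universe (non-empty, length at most the space's
#' `max_length`, alphabet tokens only) are "valid" and are their own
#' canonical form; anything else - notably rollouts truncated beyond the
#' universe - is invalid.  No synthetic filter; the toy objective functions
#' are the rewards.
#'
#' @param space a [toy_space()].
#' @return a [objective_set()].
#' @export
toy_objective_set <- function(space) {
  specs <- lapply(names(space$objectives), function(nm) {
    f <- space$objectives[[nm]]
    new_objective(nm, "mock", compute = function(smiles) f(smiles),
                  transform = function(x) x)
  })
  in_universe <- function(s) {
    toks <- strsplit(s, "", fixed = TRUE)[[1]]
    ok <- length(toks) >= 1L && length(toks) <= space$max_length &&
      all(toks %in% space$alphabet)
    if (ok) s else NA_character_
  }
  objective_set(specs, validity = in_universe, sa = "none")
}

#' Rollout policy for a toy space
#'
#' An add-one-smoothed n-gram policy trained on the deterministic corpus of
#' every length-1 and length-2 alphabet string ([toy_corpus()]).  The
#' smoothing guarantees positive probability for every alphabet token and
#' the terminator in every context, so rollouts cover the whole enumerable
#' space and every token clears the expansion probability floor.
#'
#' @param space a [toy_space()].
#' @return an n-gram policy.
#' @export
toy_policy <- function(space) {
  ngram_policy(toy_corpus(space), alpha = 1)
}

#' @rdname toy_policy
#' @export
toy_corpus <- function(space) {
  a <- space$alphabet
  c(a, as.vector(outer(a, a, paste0)))
}
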