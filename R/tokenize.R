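#' Tokenize a SMILES string
#'
#' Greedy left-to-right longest match against the vocabulary: bracket atoms
#' `[...]` are consumed as single tokens, two-letter elements (`Br`, `Cl`)
#' match before their one-letter prefixes, and `%nn` ring closures are single
#' tokens.  The concatenation of the returned tokens reproduces the input
#' exactly.
#'
#' @param s a single non-empty SMILES string (without sentinels).
#' @param vocab a [vocabulary()]; defaults to [default_vocabulary()].
#' @return an object of class `momcts_token_sequence`: a list with `tokens`
#'   (character vector) and `source` (the input string).
#' @examples
#' tokenize("CC(=O)O")$tokens
#' tokenize("C[C@@@@H]N")$tokens  # bracket atom kept whole
#' @export
tokenize <- function(s, vocab = default_vocabulary()) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s)) {
    momcts_error("s must be a single non-empty string", "momcts_domain_error")
  }
  by_len <- order(nchar(vocab$tokens), decreasing = TRUE)
  cand <- vocab$tokens[by_len]
  toks <- character(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    hit <- NA_character_
    if (ch == "[") {
      j <- i
      while (j <= n && substr(s, j, j) != "]") j <- j + 1L
      sub <- substr(s, i, j)
      if (j > n || !exists(sub, envir = vocab$index_of, inherits = FALSE)) {
        momcts_error(sprintf("unknown token '%s' at position %d of '%s'",
                             sub, i, s),
                     "momcts_unknown_token_error", substring = sub, position = i)
      }
      hit <- sub
    } else {
      # longest match first among non-bracket tokens
      for (tok in cand) {
        w <- nchar(tok)
        if (i + w - 1L <= n && substr(s, i, i + w - 1L) == tok) { hit <- tok; break }
      }
      if (is.na(hit)) {
        momcts_error(sprintf("unknown token '%s' at position %d of '%s'",
                             ch, i, s),
                     "momcts_unknown_token_error", substring = ch, position = i)
      }
    }
    toks <- c(toks, hit)
    i <- i + nchar(hit)
  }
  token_sequence(toks, source = s)
}

#' @keywords internal
#' @noRd
token_sequence <- function(tokens, source = NULL) {
  endpos <- which(tokens == END_TOKEN)
  if (length(endpos) > 1L || (length(endpos) == 1L && endpos != length(tokens))) {
    momcts_error("end token may occur at most once, and only in final position",
                 "momcts_token_sequence_error")
  }
  if (is.null(source)) source <- detokenize_chr(tokens)
  structure(list(tokens = tokens, source = source),
            class = "momcts_token_sequence")
}

#' @export
print.momcts_token_sequence <- function(x, ...) {
  shown <- vapply(x$tokens, function(t) {
    if (t == "\n") "\\n" else t
  }, "")
  cat("<token sequence> ", paste(shown, collapse = " "), "\n", sep = "")
  invisible(x)
}

detokenize_chr <- function(tokens) {
  paste(tokens[!tokens %in% c(START_TOKEN, END_TOKEN)], collapse = "")
}

#' Reassemble a SMILES string from tokens
#'
#' Concatenates the tokens with the start/end sentinels stripped, so that
#' `detokenize(tokenize(s))` is `s` for every tokenizable string.
#'
#' @param t a `momcts_token_sequence` or a character vector of tokens.
#' @return a single SMILES string.
#' @export
detokenize <- function(t) {
  toks <- if (inherits(t, "momcts_token_sequence")) t$tokens else as.character(t)
  detokenize_chr(toks)
}

#' Map tokens to integer indices and back
#'
#' `encode()` maps each token to its 1-based index in the vocabulary;
#' `decode()` inverts it.  `decode(encode(t))` is the identity.
#'
#' @param t a `momcts_token_sequence` or character vector of tokens.
#' @param idx integer vector of 1-based vocabulary indices.
#' @param vocab a [vocabulary()].
#' @return `encode()`: an integer vector; `decode()`: a
#'   `momcts_token_sequence`.
#' @export
encode <- function(t, vocab = default_vocabulary()) {
  toks <- if (inherits(t, "momcts_token_sequence")) t$tokens else as.character(t)
  vapply(toks, function(tok) {
    if (!exists(tok, envir = vocab$index_of, inherits = FALSE)) {
      momcts_error(sprintf("unknown token '%s'", if (tok == "\n") "\\n" else tok),
                   "momcts_unknown_token_error", substring = tok)
    }
    get(tok, envir = vocab$index_of)
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname encode
#' @export
decode <- function(idx, vocab = default_vocabulary()) {
  idx <- as.integer(idx)
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(vocab$tokens))) {
    momcts_error("indices out of vocabulary range", "momcts_unknown_token_error")
  }
  token_sequence(vocab$tokens[idx])
}

#' Read a SMILES line file
#'
#' One molecule per line; an optional tab-separated identifier column after
#' the SMILES is dropped.  Blank lines are skipped.
#'
#' @param path file path.
#' @return character vector of SMILES strings.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
}

#' @rdname read_smiles_file
#' @param smiles character vector to write, one per line.
#' @export
write_smiles_file <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}
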