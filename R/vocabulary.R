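#' SMILES vocabularies
#'
#' A vocabulary is an ordered set of distinct SMILES tokens together with the
#' start sentinel `"&"` and the terminator `"\n"`.  Single atoms and bond
#' symbols are one- or two-character tokens; bracket atoms such as `"[C@@H]"`
#' are kept as single multi-character tokens; ring-closure digits `1`..`9`
#' and two-digit `%nn` closures are their own tokens.
#'
#' @name vocabulary
NULL

START_TOKEN <- "&"
END_TOKEN <- "\n"

#' Construct a vocabulary
#'
#' @param tokens character vector of distinct tokens.  The start and end
#'   sentinels are appended if absent.
#' @return an object of class `momcts_vocabulary` with fields `tokens`,
#'   `start_token`, `end_token` and an `index_of` environment mapping each
#'   token to its 1-based integer index.
#' @export
vocabulary <- function(tokens) {
  tokens <- as.character(tokens)
  if (anyNA(tokens) || any(!nzchar(tokens))) {
    momcts_error("vocabulary tokens must be non-empty strings", "momcts_vocab_error")
  }
  tokens <- unique(tokens)
  if (!START_TOKEN %in% tokens) tokens <- c(START_TOKEN, tokens)
  if (!END_TOKEN %in% tokens) tokens <- c(tokens, END_TOKEN)
  multi <- tokens[nchar(tokens) > 1L & !tokens %in% c(START_TOKEN, END_TOKEN)]
  bad <- multi[!(startsWith(multi, "[") & endsWith(multi, "]")) &
                 !multi %in% c("Br", "Cl") & !grepl("^%[0-9]{2}$", multi)]
  if (length(bad)) {
    momcts_error(paste0("multi-character tokens must be bracket atoms [..], ",
                        "two-letter elements (Br, Cl) or %nn ring closures: ",
                        paste(bad, collapse = " ")), "momcts_vocab_error")
  }
  index_of <- new.env(parent = emptyenv())
  for (i in seq_along(tokens)) assign(tokens[i], i, envir = index_of)
  structure(list(tokens = tokens, start_token = START_TOKEN,
                 end_token = END_TOKEN, index_of = index_of),
            class = "momcts_vocabulary")
}

#' @export
print.momcts_vocabulary <- function(x, ...) {
  shown <- vapply(x$tokens, function(t) if (t == "\n") "\\n" else t, "")
  cat(sprintf("<momcts_vocabulary: %d tokens>\n", length(x$tokens)))
  cat(strwrap(paste(shown, collapse = " "), width = 72), sep = "\n")
  invisible(x)
}

#' @export
length.momcts_vocabulary <- function(x) length(x$tokens)

#' Default SMILES vocabulary
#'
#' The atom, bond and bracket-atom token inventory used for drug-like ZINC
#' molecules, extended with the structural auxiliaries any SMILES corpus
#' requires: branch parentheses, ring-closure digits and the start/end
#' sentinels.
#'
#' @return a `momcts_vocabulary`.
#' @export
default_vocabulary <- function() {
  atoms <- c("C", "c", "o", "O", "N", "F", "n", "S", "s", "Br", "I", "P")
  bonds <- c("-", "=", "#", "$", ":", "/", "\\")
  brackets <- c("[C@@H]", "[O-]", "[C@H]", "[NH+]", "[C@]", "[nH]",
                "[NH2+]", "[C@@]", "[N+]", "[nH+]", "[S@]", "[N-]",
                "[n-]", "[OH+]", "[NH-]", "[P@@H]", "[P@@]", "[PH2]",
                "[o+]", "[CH2-]", "[CH-]", "[SH+]", "[O+]",
                "[S-]", "[S+]", "[S@@+]", "[NH3+]", "[n+]",
                "[S@@]", "[P@]", "[P+]", "[PH]", "[s+]", "[PH+]")
  structural <- c("(", ")", as.character(1:9))
  vocabulary(c(START_TOKEN, atoms, bonds, brackets, structural, END_TOKEN))
}

#' Build a vocabulary from a SMILES corpus
#'
#' Scans every line and collects the tokens that occur, so that rare bracket
#' atoms or `%nn` ring closures present in the data are representable.
#'
#' @param smiles character vector of SMILES strings (one molecule each).
#' @return a `momcts_vocabulary` whose token order is: start token, observed
#'   tokens in order of first appearance, end token.
#' @export
vocabulary_from_corpus <- function(smiles) {
  if (!length(smiles)) momcts_error("empty corpus", "momcts_empty_corpus_error")
  seen <- character(0)
  for (s in smiles) {
    for (tok in scan_smiles_tokens(s)) {
      if (!tok %in% seen) seen <- c(seen, tok)
    }
  }
  vocabulary(c(START_TOKEN, seen, END_TOKEN))
}

# Lexical scan used when *building* a vocabulary: splits a SMILES string into
# candidate tokens without requiring a pre-existing vocabulary.
scan_smiles_tokens <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) momcts_error(sprintf("unclosed bracket atom at position %d in '%s'", i, s),
                              "momcts_unknown_token_error", position = i, substring = "[")
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n) momcts_error(sprintf("truncated %%nn ring closure at position %d in '%s'", i, s),
                                   "momcts_unknown_token_error", position = i, substring = "%")
      out <- c(out, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch %in% c("B", "C") && i < n && ((ch == "B" && chars[i + 1L] == "r") ||
                                                (ch == "C" && chars[i + 1L] == "l"))) {
      out <- c(out, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

#' Persist / restore a vocabulary as JSON
#'
#' The token list is stored as an ordered JSON array so that integer indices
#' survive a round trip (a policy checkpoint depends on them).
#'
#' @param vocab a `momcts_vocabulary`.
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(vocab$tokens, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  vocabulary(jsonlite::fromJSON(path))
}
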