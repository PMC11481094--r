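test_that("tokenization round-trips and splits known strings correctly", {
  expect_equal(tokenize("CC(=O)O")$tokens, c("C", "C", "(", "=", "O", ")", "O"))
  expect_equal(tokenize("c1ccccc1")$tokens,
               c("c", "1", "c", "c", "c", "c", "c", "1"))
  for (s in c("CCO", "CC(=O)OC", "c1ccccc1N", "C[C@@H]N", "O=C([O-])C",
              "BrC(Br)C", "C/C=C\\C", "C[NH3+]")) {
    expect_identical(detokenize(tokenize(s)), s)
  }
})

test_that("bracket atoms are single tokens", {
  toks <- tokenize("C[C@@H]N")$tokens
  expect_equal(toks, c("C", "[C@@H]", "N"))
  expect_equal(tokenize("[NH3+]")$tokens, "[NH3+]")
})

test_that("two-letter elements match before one-letter prefixes", {
  expect_equal(tokenize("BrCBr")$tokens, c("Br", "C", "Br"))
})

test_that("unknown substrings raise a typed error with a position", {
  err <- expect_error(tokenize("CXC"), class = "momcts_unknown_token_error")
  expect_equal(err$position, 2L)
  expect_equal(err$substring, "X")
  expect_error(tokenize("C[Zn]C"), class = "momcts_unknown_token_error")
  expect_error(tokenize("C[unterminated"), class = "momcts_unknown_token_error")
  expect_error(tokenize(""), class = "momcts_domain_error")
})

test_that("encode/decode are inverse and validate their inputs", {
  v <- default_vocabulary()
  seq <- tokenize("CC(=O)O", v)
  ids <- encode(seq, v)
  expect_type(ids, "integer")
  expect_identical(decode(ids, v)$tokens, seq$tokens)
  expect_error(encode("Zz", v), class = "momcts_unknown_token_error")
  expect_error(decode(c(1L, 10000L), v), class = "momcts_unknown_token_error")
  expect_error(decode(0L, v), class = "momcts_unknown_token_error")
})

test_that("the end token may only appear in final position", {
  v <- default_vocabulary()
  end_id <- encode("\n", v)
  c_id <- encode("C", v)
  expect_error(decode(c(c_id, end_id, c_id), v),
               class = "momcts_token_sequence_error")
  expect_silent(decode(c(c_id, c_id, end_id), v))
})

test_that("vocabulary construction deduplicates and adds sentinels", {
  v <- vocabulary(c("C", "C", "O"))
  expect_equal(v$tokens, c("&", "C", "O", "\n"))
  expect_equal(length(v), 4L)
  expect_error(vocabulary(c("C", "CCO")), class = "momcts_vocab_error")
  expect_error(vocabulary(c("C", "")), class = "momcts_vocab_error")
  expect_silent(vocabulary(c("C", "Cl", "Br", "[C@@H]", "%10")))
})

test_that("corpus-derived vocabulary keeps first-appearance order and rare tokens", {
  v <- vocabulary_from_corpus(c("OC", "C%12CC%12C", "[Se]"))
  expect_equal(v$tokens[2:3], c("O", "C"))
  expect_true("%12" %in% v$tokens)
  expect_true("[Se]" %in% v$tokens)
  expect_identical(detokenize(tokenize("C%12CC%12C", v)), "C%12CC%12C")
})

test_that("vocabulary JSON round trip preserves token order", {
  v <- vocabulary_from_corpus(generate_fixture_corpus(20, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_vocabulary(v, path)
  v2 <- read_vocabulary(path)
  expect_identical(v2$tokens, v$tokens)
  expect_identical(encode("C", v2), encode("C", v))
})

test_that("SMILES line files drop tab-separated ids and blank lines", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO\tmol1", "", "c1ccccc1\tmol2", "CC"), path)
  expect_equal(read_smiles_file(path), c("CCO", "c1ccccc1", "CC"))
  write_smiles_file(c("CCO", "CC"), path)
  expect_equal(read_smiles_file(path), c("CCO", "CC"))
})
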