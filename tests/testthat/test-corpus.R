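test_that("tokenizer handles multi-character tokens and round-trips", {
  expect_equal(tokenize_smiles("CCO")[[1]], c("C", "C", "O"))
  expect_equal(tokenize_smiles("CC(Cl)Br")[[1]],
               c("C", "C", "(", "Cl", ")", "Br"))
  expect_equal(tokenize_smiles("c1cc[nH]c1")[[1]],
               c("c", "1", "c", "c", "[nH]", "c", "1"))
  expect_equal(tokenize_smiles("C%12CC%12")[[1]],
               c("C", "%12", "C", "C", "%12"))
  for (s in toy_smiles) {
    expect_identical(detokenize(tokenize_smiles(s)[[1]]), s)
  }
})

test_that("untokenizable characters are reported with their offset", {
  expect_error(tokenize_smiles("CC?O"), "offset 3")
  expect_error(tokenize_smiles("CCe"), "offset 3")
})

test_that("canonicalization is idempotent and flags invalid input", {
  expect_identical(canonicalize("OCC"), canonicalize("CCO"))
  expect_true(is.na(canonicalize("C1CC")))
  benz <- canonicalize("C1=CC=CC=C1")
  expect_identical(benz, canonicalize("c1ccccc1"))
  expect_identical(canonicalize(benz), benz)
  expect_equal(is_valid_smiles(c("CCO", "xyz", "c1ccccc1")),
               c(TRUE, FALSE, TRUE))
})

test_that("Bemis-Murcko scaffolds keep frameworks and drop side chains", {
  expect_identical(extract_scaffold("c1ccccc1"), canonicalize("c1ccccc1"))
  expect_identical(extract_scaffold("CCO"), "")
  aspirin <- canonicalize("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(extract_scaffold(aspirin), canonicalize("c1ccccc1"))
  expect_error(extract_scaffold("C1CC"), "invalid")
})

test_that("scaffold extraction is idempotent on fixture molecules", {
  corp <- generate_fixture_corpus(50, seed = 4)
  sc <- unique(corp$scaffold[nzchar(corp$scaffold)])
  expect_identical(extract_scaffold(sc), sc)
})

test_that("corpus construction canonicalizes and drops invalid entries", {
  expect_message(corp <- make_corpus(c("OCC", "C1CC", "CCO")), "dropped 1")
  expect_equal(nrow(corp), 2L)
  expect_identical(corp$smiles[1], corp$smiles[2])
  expect_equal(attr(corp, "n_dropped"), 1L)
  expect_identical(detokenize(corp$tokens[[1]]), corp$smiles[1])
})

test_that("vocabulary contains specials, dense indices, first-token counts", {
  vocab <- toy_vocab()
  expect_true(all(c("<pad>", "<eos>", "<unk>", "<cond>") %in% vocab$tokens))
  expect_equal(unname(vocab$token_to_index),
               seq_along(vocab$tokens) - 1L)
  expect_true(all(names(vocab$first_token_weights) %in% vocab$tokens))
  expect_true(all(vocab$first_token_weights >= 1L))

  corp2 <- make_corpus(c("CCO", "OCC"))
  v2 <- build_vocabulary(corp2)
  expect_length(v2$first_token_weights, 1L)
  expect_equal(unname(v2$first_token_weights), 2L)

  corp3 <- make_corpus(c("CCO", "c1ccccc1", "NC"))
  v3 <- build_vocabulary(corp3)
  firsts <- vapply(corp3$tokens, `[`, character(1), 1L)
  expect_equal(sort(names(v3$first_token_weights)), sort(unique(firsts)))
  expect_equal(sum(v3$first_token_weights), 3L)
  expect_error(build_vocabulary(toy_corpus()[0, ]), "empty")
})

test_that("vocabulary JSON round-trips", {
  f <- tempfile(fileext = ".json")
  write_vocabulary(toy_vocab(), f)
  v <- read_vocabulary(f)
  expect_identical(v$tokens, toy_vocab()$tokens)
  expect_identical(v$first_token_weights, toy_vocab()$first_token_weights)
})

test_that("corpus splitting is 9:1, disjoint, seed-reproducible", {
  corp <- generate_fixture_corpus(100, seed = 2)
  sp <- split_corpus(corp, seed = 0L)
  expect_equal(nrow(sp$train), 90L)
  expect_equal(nrow(sp$test), 10L)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  sp2 <- split_corpus(corp, seed = 0L)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_corpus(corp, seed = 1L)
  expect_false(identical(sp$train_idx, sp3$train_idx))

  sp10 <- split_corpus(toy_corpus())
  expect_equal(nrow(sp10$train), 9L)
  expect_equal(nrow(sp10$test), 1L)
  expect_error(split_corpus(toy_corpus()[1:5, ]), "at least 10")
})

test_that("fixture corpora are valid, deterministic and lead-like", {
  corp <- generate_fixture_corpus(100, seed = 1)
  expect_equal(nrow(corp), 100L)
  expect_equal(attr(corp, "n_dropped"), 0L)
  corp_b <- generate_fixture_corpus(100, seed = 1)
  expect_identical(corp$smiles, corp_b$smiles)
  expect_false(identical(corp$smiles,
                         generate_fixture_corpus(100, seed = 2)$smiles))

  props <- mol_properties(generate_fixture_corpus(300, seed = 3)$smiles)
  expect_gte(mean(props$MW >= 250 & props$MW <= 350), 0.8)
})

test_that("fixture actives share one Bemis-Murcko scaffold", {
  act <- generate_fixture_actives(30, seed = 5)
  expect_equal(attr(act, "n_dropped"), 0L)
  expect_identical(unique(act$scaffold),
                   canonicalize("O=C(Nc1ccccc1)c1ccccc1"))
  expect_identical(top_scaffold(act), unique(act$scaffold))
})

test_that("SMILES files round-trip as plain text and CSV", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("CCO", "c1ccccc1"), f)
  expect_equal(read_smiles_file(f), c("CCO", "c1ccccc1"))

  fc <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(SMILES = c("CCO", "CCN"), act = 1:2), fc,
                   row.names = FALSE)
  expect_equal(read_smiles_file(fc, smiles_col = "SMILES"), c("CCO", "CCN"))
  expect_error(read_smiles_file(fc, smiles_col = "smi"), "not found")

  fo <- tempfile(fileext = ".csv")
  write_corpus(toy_corpus(), fo)
  df <- utils::read.csv(fo)
  expect_equal(df$smiles, toy_corpus()$smiles)
})
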