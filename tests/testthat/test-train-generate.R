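test_that("zero learning rate and zero epochs leave the model unchanged", {
  model <- tiny_gpt(embed_dim = 8L, n_heads = 2L)
  corp <- toy_corpus()

  m0 <- train_generator(model, corp,
                        train_config(epochs = 0L, seed = 1L))
  expect_identical(m0$params, model$params)
  expect_length(m0$loss_trace, 0L)

  mlr0 <- train_generator(model, corp,
                          train_config(learning_rate = 0, epochs = 3L,
                                       batch_size = 5L, seed = 1L))
  expect_equal(diff(range(mlr0$loss_trace)), 0, tolerance = 1e-12)
  expect_equal(mlr0$params, model$params, tolerance = 1e-12)
})

test_that("training is reproducible and reduces the loss early", {
  corp <- generate_fixture_corpus(30, seed = 8)
  vocab <- build_vocabulary(corp)
  run <- function(seed) {
    m <- tiny_gpt(vocab, n_layers = 1L, n_heads = 2L, embed_dim = 16L,
                  max_len = 80L)
    train_generator(m, corp, train_config(learning_rate = 1e-3,
                                          epochs = 2L, batch_size = 10L,
                                          seed = seed))
  }
  m1 <- run(1L)
  m2 <- run(1L)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss_trace, m2$loss_trace)

  improved <- vapply(1:8, function(s) {
    m <- run(s)
    m$loss_trace[2] < m$loss_trace[1]
  }, logical(1))
  expect_gte(mean(improved), 0.95)
})

test_that("a vocabulary mismatch is rejected at training time", {
  corp_big <- generate_fixture_corpus(20, seed = 3)
  model <- tiny_gpt()   # vocabulary from the 10 toy molecules
  expect_error(train_generator(model, corp_big, train_config(epochs = 1L)),
               "vocabulary mismatch")
})

test_that("finetuning requires a pretrained checkpoint", {
  model <- tiny_gpt()
  prot <- encode_protein(fixture_protein(), encoding_config())
  expect_error(finetune(model, toy_corpus(), prot), "pretrained")
})

test_that("checkpoints round-trip and refuse mismatched vocabularies", {
  model <- tiny_gpt(embed_dim = 8L, n_heads = 2L)
  model <- train_generator(model, toy_corpus(),
                           train_config(epochs = 1L, batch_size = 5L,
                                        seed = 2L))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f, vocab = model$vocab)
  expect_equal(back$params, model$params)
  expect_equal(back$loss_trace, model$loss_trace)

  other <- build_vocabulary(make_corpus(c("CCBr", "CCI", "CCCl", "CCF")))
  expect_error(load_checkpoint(f, vocab = other), "does not match")
})

test_that("start tokens are drawn by first-position frequency", {
  vocab <- toy_vocab()
  vocab$first_token_weights <- c(C = 2L, O = 1L)
  draws <- with_seed_test(31L, pick_start_token(vocab, 30000L))
  freq <- table(draws) / 30000
  expect_equal(unname(freq[["C"]]), 2 / 3, tolerance = 0.01)
  expect_equal(unname(freq[["O"]]), 1 / 3, tolerance = 0.01)

  vocab$first_token_weights <- c(C = 5L)
  expect_identical(unique(with_seed_test(1L, pick_start_token(vocab, 50L))),
                   "C")

  vocab$first_token_weights <- c(C = 3L, c = 3L, O = 3L, N = 3L)
  d4 <- with_seed_test(7L, pick_start_token(vocab, 30000L))
  expect_true(all(abs(table(d4) / 30000 - 0.25) < 0.01))

  vocab$first_token_weights <- integer(0)
  expect_error(pick_start_token(vocab), "empty")
})

test_that("sampling is seed-deterministic and respects the vocabulary", {
  model <- tiny_gpt(embed_dim = 8L, n_heads = 2L, max_len = 30L)
  model <- train_generator(model, toy_corpus(),
                           train_config(epochs = 1L, batch_size = 5L,
                                        seed = 1L))
  s1 <- sample_molecules(model, 5L, seed = 11L, max_len = 20L)
  s2 <- sample_molecules(model, 5L, seed = 11L, max_len = 20L)
  expect_identical(s1, s2)
  s3 <- sample_molecules(model, 5L, seed = 12L, max_len = 20L)
  expect_false(identical(s1, s3))

  expect_error(sample_molecules(model, 2L, scaffold = "C%99C"),
               "outside the vocabulary")
})

test_that("greedy decoding from an overfit model reproduces training data", {
  # four molecules with pairwise-distinct (scaffold, start token) prefixes,
  # so greedy decoding can in principle reproduce each of them
  corp <- toy_corpus()[c(1L, 3L, 9L, 6L), ]
  vocab <- toy_vocab()
  model <- tiny_gpt(vocab, n_layers = 2L, n_heads = 2L, embed_dim = 32L,
                    max_len = 40L)
  model <- train_generator(model, corp,
                           train_config(learning_rate = 2e-3, epochs = 120L,
                                        batch_size = 4L, seed = 1L))
  expect_lt(model$loss_trace[length(model$loss_trace)], 0.1)
  dec <- vapply(seq_len(nrow(corp)), function(i) {
    sample_molecules(model, 1L, scaffold = corp$scaffold[i],
                     temperature = 0,
                     start_tokens = corp$tokens[[i]][1])
  }, character(1))
  expect_gte(sum(dec == corp$smiles), 3L)
})
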