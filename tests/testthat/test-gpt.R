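test_that("attention reduces to hand-computable cases", {
  # single position: softmax over one element is 1, output = V row
  V1 <- matrix(c(1.5, -2, 0.25), 1)
  expect_equal(attention(matrix(rnorm(3), 1), matrix(rnorm(3), 1), V1), V1)

  # queries orthogonal to all keys: zero logits, uniform weights 1/L
  Q <- matrix(c(1, 0, 0, 0), 1)
  K <- rbind(c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  V <- rbind(c(1, 0), c(0, 1), c(2, 2))
  expect_equal(attention(Q, K, V), matrix(c(1, 1), 1), tolerance = 1e-12)

  # 2x2 hand-computed values at d_k = 1
  Q2 <- matrix(c(1, 2), 2, 1)
  K2 <- matrix(c(1, -1), 2, 1)
  V2 <- matrix(c(10, 20, 30, 40), 2, 2)
  w1 <- exp(1) / (exp(1) + exp(-1))
  w2 <- exp(2) / (exp(2) + exp(-2))
  hand <- rbind(c(w1 * 10 + (1 - w1) * 20, w1 * 30 + (1 - w1) * 40),
                c(w2 * 10 + (1 - w2) * 20, w2 * 30 + (1 - w2) * 40))
  expect_equal(attention(Q2, K2, V2), hand, tolerance = 1e-6)

  # causal mask: first row ignores later positions
  m <- ligandgen:::causal_mask(2L)
  out <- attention(Q2, K2, V2, mask = m)
  expect_equal(out[1, ], V2[1, ])
  expect_error(attention(matrix(0, 1, 3), K2, V2), "key dimension")
})

test_that("input embeddings are additive in token/position/segment", {
  model <- tiny_gpt()
  toks <- tokenize_smiles("CCO")[[1]]
  h <- embed_inputs(model, toks, rep("smiles", 3))
  expect_equal(dim(h), c(4L, 4L))

  # zero parameters give a zero embedding matrix
  m0 <- model
  for (nm in c("wte", "wpe", "wse", "wcond")) m0$params[[nm]][] <- 0
  expect_equal(embed_inputs(m0, toks, rep("smiles", 3)),
               matrix(0, 4, 4))

  # swapping a segment label shifts that row by the segment-row difference
  h_scaf <- embed_inputs(model, toks, c("scaffold", "smiles", "smiles"))
  delta <- model$params$wse[1, ] - model$params$wse[2, ]
  expect_equal(h_scaf[2, ] - h[2, ], delta)
  expect_equal(h_scaf[3:4, ], h[3:4, ])

  # lookup-and-add oracle for a 3-token input
  idx <- match(toks, model$vocab$tokens)
  cond_row <- as.numeric(t(model$params$wcond) %*% numeric(8))
  oracle <- rbind(
    cond_row + model$params$wpe[1, ] + model$params$wse[1, ],
    model$params$wte[idx[1], ] + model$params$wpe[2, ] +
      model$params$wse[2, ],
    model$params$wte[idx[2], ] + model$params$wpe[3, ] +
      model$params$wse[2, ],
    model$params$wte[idx[3], ] + model$params$wpe[4, ] +
      model$params$wse[2, ])
  expect_equal(unname(h), unname(oracle))

  expect_error(embed_inputs(model, c("C", "Zz"), rep("smiles", 2)),
               "outside the vocabulary")
})

test_that("forward output rows are distributions and causally masked", {
  model <- tiny_gpt(embed_dim = 8L, n_heads = 2L)
  p <- predict(model, smiles = "CCO", scaffold = "c1ccccc1")
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)
  expect_true(all(p >= 0))

  # appending a token never changes earlier distributions
  p2 <- predict(model, smiles = "CCOC", scaffold = "c1ccccc1")
  expect_equal(p2[seq_len(nrow(p)), ], p, tolerance = 1e-10)

  # perturbing a later token leaves earlier rows untouched
  p3 <- predict(model, smiles = "CCN")
  p4 <- predict(model, smiles = "CCO")
  expect_equal(p3[1:3, ], p4[1:3, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(p3[4, ], p4[4, ])))
})

test_that("a 1-layer 1-head model matches a dependency-free re-computation", {
  model <- tiny_gpt()
  cfg <- model$config
  pm <- model$params
  enc <- ligandgen:::encode_sequence(model$vocab, "", "CCO")
  set.seed(8)
  cond <- rnorm(8)
  got <- ligandgen:::seq_forward(pm, cfg, enc$idx, enc$seg, cond)$logits

  # straight-line recomputation: embeddings, LN, single-head attention,
  # GELU FFN, final LN, tied head
  L <- length(enc$idx)
  X <- pm$wte[enc$idx, ]
  X[1, ] <- as.numeric(t(pm$wcond) %*% cond)
  X <- X + pm$wpe[1:L, ] + pm$wse[enc$seg, ]
  ln <- function(x, g, b) {
    t(apply(x, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5) * g + b
    }))
  }
  Y <- ln(X, pm$`L1.ln1_g`, pm$`L1.ln1_b`)
  q <- Y %*% pm$`L1.Wq`
  k <- Y %*% pm$`L1.Wk`
  v <- Y %*% pm$`L1.Wv`
  S <- q %*% t(k) / sqrt(4)
  A <- matrix(0, L, L)
  for (i in 1:L) {
    w <- exp(S[i, 1:i] - max(S[i, 1:i]))
    A[i, 1:i] <- w / sum(w)
  }
  X1 <- X + (A %*% v) %*% pm$`L1.Wo`
  Y2 <- ln(X1, pm$`L1.ln2_g`, pm$`L1.ln2_b`)
  a <- Y2 %*% pm$`L1.W1`
  H <- a * pnorm(a)
  X2 <- X1 + H %*% pm$`L1.W2`
  logits_oracle <- ln(X2, pm$lnf_g, pm$lnf_b) %*% t(pm$wte)
  expect_equal(got, logits_oracle, tolerance = 1e-5)
})

test_that("analytic gradients agree with finite differences", {
  model <- tiny_gpt(n_layers = 2L, n_heads = 2L, embed_dim = 8L)
  cfg <- model$config
  enc <- ligandgen:::encode_sequence(model$vocab, "c1ccccc1", "CCO")
  set.seed(5)
  cond <- rnorm(8)
  loss_of <- function(params) {
    fwd <- ligandgen:::seq_forward(params, cfg, enc$idx, enc$seg, cond)
    sl <- ligandgen:::seq_loss(fwd$logits, enc$idx, enc$seg)
    sl$loss_sum / sl$n
  }
  fwd <- ligandgen:::seq_forward(model$params, cfg, enc$idx, enc$seg, cond,
                                 keep_cache = TRUE)
  sl <- ligandgen:::seq_loss(fwd$logits, enc$idx, enc$seg)
  gr <- ligandgen:::seq_backward(model$params, cfg, enc$idx, enc$seg, cond,
                                 fwd, dlogit_scale = 1 / sl$n)
  set.seed(9)
  for (nm in names(gr)) {
    p <- model$params[[nm]]
    for (rep in 1:2) {
      j <- sample(length(p), 1)
      eps <- 1e-5
      pp <- model$params
      pp[[nm]][j] <- pp[[nm]][j] + eps
      pmn <- model$params
      pmn[[nm]][j] <- pmn[[nm]][j] - eps
      num <- (loss_of(pp) - loss_of(pmn)) / (2 * eps)
      expect_equal(gr[[nm]][j], num, tolerance = 1e-3,
                   label = paste("grad", nm))
    }
  }
})

test_that("parameter counts follow the closed-form breakdown", {
  model <- tiny_gpt(n_layers = 0L)
  br <- attr(count_parameters(model), "breakdown")
  V <- length(model$vocab$tokens)
  expect_equal(unname(br[["wte"]]), V * 4L)
  expect_equal(unname(br[["wpe"]]), 40L * 4L)
  expect_equal(unname(br[["wse"]]), 2L * 4L)
  expect_equal(unname(br[["wcond"]]), 8L * 4L)

  n1 <- as.integer(count_parameters(tiny_gpt(n_layers = 1L)))
  n2 <- as.integer(count_parameters(tiny_gpt(n_layers = 2L)))
  n4 <- as.integer(count_parameters(tiny_gpt(n_layers = 4L)))
  per_block <- n2 - n1
  d <- 4L
  h <- 16L
  # per block: 4 d^2 projections + 2 d h FFN weights + 9 d bias/LN + h bias
  expect_equal(per_block, 4L * d^2 + 2L * d * h + 9L * d + h)
  expect_equal(n4, n2 + 2L * per_block)
})

test_that("the default architecture lands in the documented size class", {
  corp <- toy_corpus()
  model <- smiles_gpt(generator_config(), build_vocabulary(corp))
  n <- as.integer(count_parameters(model))
  expect_gt(n, 1e6)
  expect_lt(n, 1e7)
})

test_that("embed_dim must be divisible by n_heads", {
  expect_error(generator_config(embed_dim = 10L, n_heads = 4L),
               "divisible")
})

test_that("sequences beyond max_len are rejected", {
  model <- tiny_gpt(max_len = 6L)
  expect_error(predict(model, smiles = "CCCCCCCCCC"), "max_len")
})
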