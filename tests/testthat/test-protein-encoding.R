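test_that("sequence sanitization enforces the residue policy", {
  s <- sanitize_sequence("acdef")
  expect_equal(s$residues, "ACDEF")
  expect_equal(s$length, 5L)

  expect_equal(sanitize_sequence("AC*DE")$residues, "ACDE")
  expect_equal(sanitize_sequence("MKBZUOJ")$residues, "MKNQCKL")
  expect_error(sanitize_sequence("MKX"), "shorter than 3")
  expect_error(sanitize_sequence("  "), "empty")
  expect_error(sanitize_sequence("AC1DE?"), "unrecognized")

  fa <- ">sp|P001| test\nMKV\nLLA"
  s2 <- sanitize_sequence(fa)
  expect_equal(s2$id, "sp|P001| test")
  expect_equal(s2$residues, "MKVLLA")
})

test_that("FASTA records round-trip through Biostrings", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">p1 kinase", "MKVLLAGCDEF", ">p2", "ACDEFGHIKLMNP"), f)
  seqs <- read_protein_fasta(f)
  expect_length(seqs, 2L)
  expect_equal(seqs[[1]]$id, "p1")
  expect_equal(seqs[[2]]$residues, "ACDEFGHIKLMNP")
})

test_that("PseAAC matches a direct-formula oracle and is a distribution", {
  v <- pseaac("ACDEFGHIKL", epsilon = 2L, alpha = 0.05)
  expect_equal(as.numeric(v), pseaac_oracle("ACDEFGHIKL", 2L, 0.05),
               tolerance = 1e-10)
  for (seed in 1:100) {
    len <- 10L + (seed %% 41L)
    res <- random_protein(len, seed)
    eps <- seed %% min(8L, len - 1L)
    x <- pseaac(res, epsilon = eps, alpha = 0.05)
    expect_equal(unname(as.numeric(x)), pseaac_oracle(res, eps, 0.05),
                 tolerance = 1e-10)
    expect_length(x, 20L + eps)
    expect_true(all(x >= 0))
    expect_equal(sum(x), 1, tolerance = 1e-9)
  }
})

test_that("PseAAC homopolymer puts all mass on one residue", {
  x <- pseaac("AAAAAAAAAA", epsilon = 3L, alpha = 0.05)
  expect_length(x, 23L)
  expect_equal(unname(x[["A"]]), 1)
  expect_equal(sum(abs(x[names(x) != "A"])), 0)
})

test_that("PseAAC honours the epsilon < S constraint and width contract", {
  expect_error(pseaac("ACDEF", epsilon = 5L), "smaller than")
  expect_length(pseaac(random_protein(40, 1), epsilon = 30L), 50L)
})

test_that("conjoint triad matches a triple-loop oracle on random 12-mers", {
  for (seed in 1:25) {
    res <- random_protein(12, 100 + seed)
    d <- conjoint_triad(res)
    expect_equal(unname(d), ct_oracle(res), tolerance = 1e-12)
    expect_length(d, 343L)
    expect_true(all(d >= 0 & d <= 1))
    expect_identical(min(d), 0)
  }
})

test_that("poly-glycine concentrates the conjoint triad on one type", {
  d <- conjoint_triad(strrep("G", 10))
  expect_equal(sum(d == 1), 1L)
  expect_equal(sum(d == 0), 342L)
  expect_error(conjoint_triad("AC"), "3")
})

test_that("permuting class labels permutes but preserves CT values", {
  res <- random_protein(30, 9)
  perm <- c(3L, 1L, 2L, 5L, 4L, 7L, 6L)
  remap <- stats::setNames(perm[CT_CLASSES], names(CT_CLASSES))
  d1 <- conjoint_triad(res)
  d2 <- conjoint_triad(res, class_map = remap)
  expect_equal(unname(sort(d1)), unname(sort(d2)))
})

test_that("autocorrelation matches a double-loop oracle", {
  one_prop <- AD_PROPERTIES[1, , drop = FALSE]
  for (seed in 1:10) {
    res <- random_protein(10, 300 + seed)
    v <- autocorrelation(res, properties = one_prop, max_lag = 3L)
    expect_equal(unname(v), ad_oracle(res, one_prop, 3L), tolerance = 1e-10)
  }
  res <- random_protein(50, 5)
  v8 <- autocorrelation(res, max_lag = 30L)
  expect_length(v8, 240L)
  expect_equal(unname(v8), ad_oracle(res, AD_PROPERTIES, 30L),
               tolerance = 1e-10)
})

test_that("constant sequences give the constant-signal autocorrelation", {
  v <- autocorrelation(strrep("W", 12), max_lag = 4L)
  z <- apply(AD_PROPERTIES, 1, function(p) {
    ((p - mean(p)) / sqrt(mean((p - mean(p))^2)))[["W"]]
  })
  expect_equal(unname(v), unname(rep(z^2, each = 4L)), tolerance = 1e-12)
  expect_error(autocorrelation("ACD", max_lag = 3L), "smaller than")
})

test_that("the fused encoding is 512-long, deterministic, length-stable", {
  p1 <- encode_protein(random_protein(60, 21))
  p2 <- encode_protein(random_protein(60, 21))
  p3 <- encode_protein(random_protein(200, 22))
  expect_length(p1$values, 512L)
  expect_identical(p1$values, p2$values)
  expect_length(p3$values, 512L)
  expect_equal(unname(p1$source_dims), c(50L, 240L, 343L))
  expect_equal(sum(p1$source_dims), 633L)

  cfg <- encoding_config(epsilon = 5L, max_lag = 10L)
  p4 <- encode_protein(random_protein(60, 21), cfg)
  expect_length(p4$values, 512L)
  expect_equal(unname(p4$source_dims), c(25L, 80L, 343L))
})

test_that("encoder errors propagate through the fused encoding", {
  expect_error(encode_protein(sanitize_sequence("ACDEFGHIK")), "smaller")
})
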