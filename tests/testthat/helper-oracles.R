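# Independent brute-force oracles: straight-line transcriptions of the
# descriptor formulas, kept deliberately separate from the package
# implementations they check.

random_protein <- function(len, seed) {
  with_seed_test(seed, paste(sample(ligandgen::AA_LETTERS, len,
                                    replace = TRUE), collapse = ""))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  force(code)
}

# population z-score of one property scale over the 20 amino acids
zscore20 <- function(p) {
  m <- sum(p) / 20
  s <- sqrt(sum((p - m)^2) / 20)
  (p - m) / s
}

# direct transcription of the PseAAC formula: frequencies plus
# alpha-weighted sequence-order correlation factors, all over the shared
# denominator
pseaac_oracle <- function(residues, epsilon, alpha,
                          props = ligandgen::PSEAAC_PROPERTIES) {
  chars <- strsplit(residues, "")[[1]]
  S <- length(chars)
  f <- numeric(20)
  names(f) <- ligandgen::AA_LETTERS
  for (ch in chars) f[ch] <- f[ch] + 1
  f <- f / S
  Z <- t(apply(props, 1, zscore20))
  theta <- numeric(epsilon)
  if (epsilon > 0) {
    for (j in seq_len(epsilon)) {
      acc <- 0
      for (i in 1:(S - j)) {
        a <- chars[i]
        b <- chars[i + j]
        acc <- acc + mean((Z[, b] - Z[, a])^2)
      }
      theta[j] <- acc / (S - j)
    }
  }
  denom <- sum(f) + alpha * sum(theta)
  unname(c(f / denom, alpha * theta / denom))
}

# triple-loop conjoint-triad oracle over all 3-residue windows
ct_oracle <- function(residues, classes = ligandgen::CT_CLASSES) {
  chars <- strsplit(residues, "")[[1]]
  S <- length(chars)
  f <- numeric(343)
  for (i in 1:(S - 2)) {
    c1 <- classes[[chars[i]]]
    c2 <- classes[[chars[i + 1]]]
    c3 <- classes[[chars[i + 2]]]
    id <- (c1 - 1) * 49 + (c2 - 1) * 7 + c3
    f[id] <- f[id] + 1
  }
  (f - min(f)) / max(f)
}

# double-loop Moreau-Broto autocorrelation oracle
ad_oracle <- function(residues, props, max_lag) {
  chars <- strsplit(residues, "")[[1]]
  S <- length(chars)
  out <- numeric(0)
  for (r in seq_len(nrow(props))) {
    z <- zscore20(props[r, ])
    for (d in seq_len(max_lag)) {
      acc <- 0
      for (i in 1:(S - d)) acc <- acc + z[[chars[i]]] * z[[chars[i + d]]]
      out <- c(out, acc / (S - d))
    }
  }
  out
}

# 1-D Wasserstein-1 oracle for equal-sized samples: mean |sorted a - sorted b|
w1_equal_oracle <- function(a, b) mean(abs(sort(a) - sort(b)))
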