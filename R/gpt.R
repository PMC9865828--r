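# Decoder-only transformer over SMILES tokens, conditioned on a protein
# encoding and a Bemis-Murcko scaffold. Written in plain R matrix algebra,
# with analytic gradients for every layer (checked against finite
# differences in the test suite). Layout of one training sequence:
#
#   position 1        : conditioning slot (projected protein encoding)
#   positions 2..s+1  : scaffold tokens  (segment 1)
#   remaining         : SMILES tokens + <eos>  (segment 2)
#
# The cross-entropy loss is taken only at positions predicting tokens of
# the SMILES region (scaffold and condition are context, not targets).

#' Generator hyperparameters
#'
#' Defaults follow the mini-GPT recipe this generator is modelled on:
#' 8 decoder blocks with 8 attention heads, 256-wide token/position/segment
#' embeddings, a 1024-wide GELU feed-forward inner layer, and a 512-wide
#' protein-conditioning input projected to the embedding width.
#'
#' @param vocab_size Number of tokens (set automatically by
#'   [smiles_gpt()]).
#' @param n_layers Number of decoder blocks.
#' @param n_heads Attention heads; must divide `embed_dim`.
#' @param embed_dim Embedding width.
#' @param ff_hidden Feed-forward inner width (default `4 * embed_dim`).
#' @param max_len Maximum total sequence length (condition slot + scaffold
#'   + SMILES + end token).
#' @param condition_dim Width of the protein encoding (default 512).
#' @param dropout Dropout rate used during training (default 0.1).
#' @param seed Parameter-initialization seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(vocab_size = NULL, n_layers = 8L, n_heads = 8L,
                             embed_dim = 256L, ff_hidden = 4L * embed_dim,
                             max_len = 128L, condition_dim = 512L,
                             dropout = 0.1, seed = 1L) {
  embed_dim <- as.integer(embed_dim)
  n_heads <- as.integer(n_heads)
  if (embed_dim %% n_heads != 0L) {
    stop("'embed_dim' must be divisible by 'n_heads'", call. = FALSE)
  }
  structure(list(vocab_size = if (is.null(vocab_size)) NULL
                 else as.integer(vocab_size),
                 n_layers = as.integer(n_layers), n_heads = n_heads,
                 embed_dim = embed_dim, ff_hidden = as.integer(ff_hidden),
                 max_len = as.integer(max_len),
                 condition_dim = as.integer(condition_dim),
                 dropout = dropout, seed = as.integer(seed)),
            class = "generator_config")
}

init_matrix <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

#' Build an untrained SMILES generator
#'
#' Initializes all parameters from `config$seed` (Gaussian, sd 0.02; unit
#' layer-norm gains). The output head is weight-tied to the token
#' embedding matrix, so it adds no parameters.
#'
#' @param config A [generator_config()]; `vocab_size` is filled from
#'   `vocab`.
#' @param vocab A [build_vocabulary()] result.
#' @return Object of class `smiles_gpt`: list with `config`, `vocab`,
#'   `params` (named list of matrices/vectors), `trained`, `loss_trace`.
#' @export
smiles_gpt <- function(config = generator_config(), vocab) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  config$vocab_size <- length(vocab$tokens)
  d <- config$embed_dim
  h <- config$ff_hidden
  params <- with_seed(config$seed, {
    p <- list(
      wte = init_matrix(config$vocab_size, d),
      wpe = init_matrix(config$max_len, d),
      wse = init_matrix(2L, d),
      wcond = init_matrix(config$condition_dim, d)
    )
    for (l in seq_len(config$n_layers)) {
      pre <- paste0("L", l, ".")
      p[[paste0(pre, "ln1_g")]] <- rep(1, d)
      p[[paste0(pre, "ln1_b")]] <- rep(0, d)
      p[[paste0(pre, "Wq")]] <- init_matrix(d, d)
      p[[paste0(pre, "Wk")]] <- init_matrix(d, d)
      p[[paste0(pre, "Wv")]] <- init_matrix(d, d)
      p[[paste0(pre, "Wo")]] <- init_matrix(d, d)
      p[[paste0(pre, "bq")]] <- rep(0, d)
      p[[paste0(pre, "bk")]] <- rep(0, d)
      p[[paste0(pre, "bv")]] <- rep(0, d)
      p[[paste0(pre, "bo")]] <- rep(0, d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d)
      p[[paste0(pre, "ln2_b")]] <- rep(0, d)
      p[[paste0(pre, "W1")]] <- init_matrix(d, h)
      p[[paste0(pre, "b1")]] <- rep(0, h)
      p[[paste0(pre, "W2")]] <- init_matrix(h, d)
      p[[paste0(pre, "b2")]] <- rep(0, d)
    }
    p$lnf_g <- rep(1, d)
    p$lnf_b <- rep(0, d)
    p
  })
  structure(list(config = config, vocab = vocab, params = params,
                 trained = FALSE, phase = "init", loss_trace = NULL,
                 vocab_hash = vocab_hash(vocab)),
            class = "smiles_gpt")
}

vocab_hash <- function(vocab) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(vocab$tokens, f)
  unname(tools::md5sum(f))
}

#' Count trainable parameters
#'
#' @param model A `smiles_gpt`.
#' @return Integer total, with a per-tensor breakdown in attribute
#'   `breakdown`.
#' @export
count_parameters <- function(model) {
  sizes <- vapply(model$params, length, integer(1))
  structure(sum(sizes), breakdown = sizes)
}

# -- primitive layers --------------------------------------------------------

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k) + mask) V`: each query row attends over the
#' key rows, with an optional additive mask (`-Inf` blocks a position, as
#' in causal masking).
#'
#' @param Q,K,V Matrices; `Q` and `K` share the key width `d_k`, `K` and
#'   `V` share their number of rows.
#' @param mask Optional additive mask matrix, `nrow(Q) x nrow(K)`.
#' @return `nrow(Q) x ncol(V)` matrix; attention weights over unmasked
#'   positions sum to 1 per row.
#' @export
attention <- function(Q, K, V, mask = NULL) {
  if (ncol(Q) != ncol(K)) stop("Q and K must share the key dimension",
                               call. = FALSE)
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows",
                               call. = FALSE)
  scores <- Q %*% t(K) / sqrt(ncol(K))
  if (!is.null(mask)) {
    if (!all(dim(mask) == c(nrow(Q), nrow(K)))) {
      stop("mask must be nrow(Q) x nrow(K)", call. = FALSE)
    }
    scores <- scores + mask
  }
  softmax_rows(scores) %*% V
}

causal_mask <- function(L) {
  m <- matrix(0, L, L)
  m[upper.tri(m)] <- -Inf
  m
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# row-wise layer norm; returns y plus the quantities needed for backprop
layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  invstd <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * invstd
  list(y = t(t(xhat) * g + b), xhat = xhat, invstd = invstd)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- t(t(dy) * g)
  dx <- cache$invstd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

add_rows <- function(x, b) t(t(x) + b)

# -- input embedding ---------------------------------------------------------

#' Assemble the input embedding matrix
#'
#' `h0 = token embedding + position embedding + segment embedding` per
#' position; the projected protein-encoding vector occupies the first row
#' (the conditioning slot).
#'
#' @param model A `smiles_gpt`.
#' @param tokens Character vector of scaffold-then-SMILES tokens.
#' @param segments Character (or integer) vector parallel to `tokens`,
#'   with values `"scaffold"`/`"smiles"` (or 1/2).
#' @param condition A `protein_encoding`, or `NULL` for the zero (no
#'   target) condition.
#' @return `(length(tokens) + 1) x embed_dim` matrix.
#' @export
embed_inputs <- function(model, tokens, segments, condition = NULL) {
  if (is.character(segments)) {
    segments <- match(segments, c("scaffold", "smiles"))
  }
  if (length(segments) != length(tokens) || anyNA(segments)) {
    stop("'segments' must label every token as scaffold or smiles",
         call. = FALSE)
  }
  idx <- match(tokens, model$vocab$tokens)
  if (anyNA(idx)) {
    stop("token(s) outside the vocabulary: ",
         paste(unique(tokens[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  seq_embed(model$params, model$config,
            idx = c(vocab_special(model$vocab, "COND"), idx),
            seg = c(1L, as.integer(segments)),
            cond = condition_values(condition, model$config))
}

condition_values <- function(condition, config) {
  if (is.null(condition)) return(numeric(config$condition_dim))
  v <- if (inherits(condition, "protein_encoding")) condition$values
       else as.numeric(condition)
  if (length(v) != config$condition_dim) {
    stop(sprintf("condition has length %d, expected %d", length(v),
                 config$condition_dim), call. = FALSE)
  }
  v
}

seq_embed <- function(params, config, idx, seg, cond) {
  L <- length(idx)
  if (L > config$max_len) {
    stop(sprintf("sequence length %d exceeds max_len %d", L, config$max_len),
         call. = FALSE)
  }
  E <- params$wte[idx, , drop = FALSE]
  E[1, ] <- drop(crossprod(params$wcond, cond))
  E + params$wpe[seq_len(L), , drop = FALSE] +
    params$wse[seg, , drop = FALSE]
}

# -- forward pass ------------------------------------------------------------

# Full forward over one sequence. Returns logits and (optionally) all
# intermediates needed by seq_backward.
seq_forward <- function(params, config, idx, seg, cond, keep_cache = FALSE,
                        drop_masks = NULL) {
  L <- length(idx)
  nh <- config$n_heads
  dh <- config$embed_dim / nh
  mask <- causal_mask(L)
  x <- seq_embed(params, config, idx, seg, cond)
  if (!is.null(drop_masks)) x <- x * drop_masks$embed
  cache <- if (keep_cache) list(h0 = x, layers = vector("list",
                                                        config$n_layers))
  for (l in seq_len(config$n_layers)) {
    pre <- paste0("L", l, ".")
    lc <- list(x_in = x)
    ln1 <- layernorm_fwd(x, params[[paste0(pre, "ln1_g")]],
                         params[[paste0(pre, "ln1_b")]])
    q <- add_rows(ln1$y %*% params[[paste0(pre, "Wq")]],
                  params[[paste0(pre, "bq")]])
    k <- add_rows(ln1$y %*% params[[paste0(pre, "Wk")]],
                  params[[paste0(pre, "bk")]])
    v <- add_rows(ln1$y %*% params[[paste0(pre, "Wv")]],
                  params[[paste0(pre, "bv")]])
    O <- matrix(0, L, config$embed_dim)
    A <- vector("list", nh)
    for (hh in seq_len(nh)) {
      cols <- ((hh - 1) * dh + 1):(hh * dh)
      s <- q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE]) /
        sqrt(dh) + mask
      A[[hh]] <- softmax_rows(s)
      O[, cols] <- A[[hh]] %*% v[, cols, drop = FALSE]
    }
    ao <- add_rows(O %*% params[[paste0(pre, "Wo")]],
                   params[[paste0(pre, "bo")]])
    if (!is.null(drop_masks)) ao <- ao * drop_masks$attn[[l]]
    x1 <- x + ao
    ln2 <- layernorm_fwd(x1, params[[paste0(pre, "ln2_g")]],
                         params[[paste0(pre, "ln2_b")]])
    a <- add_rows(ln2$y %*% params[[paste0(pre, "W1")]],
                  params[[paste0(pre, "b1")]])
    h1 <- gelu(a)
    ff <- add_rows(h1 %*% params[[paste0(pre, "W2")]],
                   params[[paste0(pre, "b2")]])
    if (!is.null(drop_masks)) ff <- ff * drop_masks$ffn[[l]]
    x2 <- x1 + ff
    if (keep_cache) {
      lc$ln1 <- ln1; lc$q <- q; lc$k <- k; lc$v <- v; lc$A <- A; lc$O <- O
      lc$x1 <- x1; lc$ln2 <- ln2; lc$a <- a; lc$h1 <- h1
      cache$layers[[l]] <- lc
    }
    x <- x2
  }
  lnf <- layernorm_fwd(x, params$lnf_g, params$lnf_b)
  logits <- lnf$y %*% t(params$wte)
  if (keep_cache) {
    cache$x_final <- x
    cache$lnf <- lnf
    cache$logits <- logits
  }
  list(logits = logits, cache = cache)
}

# Cross-entropy over the SMILES-region targets of one sequence.
# Positions i with seg[i + 1] == 2 predict token idx[i + 1].
loss_positions <- function(seg) which(seg[-1] == 2L)

seq_loss <- function(logits, idx, seg) {
  pos <- loss_positions(seg)
  p <- softmax_rows(logits[pos, , drop = FALSE])
  tgt <- idx[pos + 1L]
  nll <- -log(pmax(p[cbind(seq_along(pos), tgt)], 1e-12))
  list(loss_sum = sum(nll), n = length(pos))
}

# Analytic gradients for one sequence; `dlogit_scale` multiplies the raw
# (sum over targets) gradient, letting the caller average over a batch.
seq_backward <- function(params, config, idx, seg, cond, fwd,
                         drop_masks = NULL, dlogit_scale = 1) {
  cache <- fwd$cache
  L <- length(idx)
  nh <- config$n_heads
  dh <- config$embed_dim / nh
  grads <- list()
  gadd <- function(name, val) {
    grads[[name]] <<- if (is.null(grads[[name]])) val else grads[[name]] + val
  }

  pos <- loss_positions(seg)
  P <- softmax_rows(cache$logits[pos, , drop = FALSE])
  tgt <- idx[pos + 1L]
  P[cbind(seq_along(pos), tgt)] <- P[cbind(seq_along(pos), tgt)] - 1
  dlogits <- matrix(0, L, config$vocab_size)
  dlogits[pos, ] <- P * dlogit_scale

  gadd("wte", t(dlogits) %*% cache$lnf$y)      # tied output head
  dhf <- dlogits %*% params$wte
  lb <- layernorm_bwd(dhf, cache$lnf, params$lnf_g)
  gadd("lnf_g", lb$dg); gadd("lnf_b", lb$db)
  dx <- lb$dx

  for (l in rev(seq_len(config$n_layers))) {
    pre <- paste0("L", l, ".")
    lc <- cache$layers[[l]]
    # feed-forward branch
    dff <- if (is.null(drop_masks)) dx else dx * drop_masks$ffn[[l]]
    gadd(paste0(pre, "W2"), t(lc$h1) %*% dff)
    gadd(paste0(pre, "b2"), colSums(dff))
    dh1 <- dff %*% t(params[[paste0(pre, "W2")]])
    da <- dh1 * gelu_grad(lc$a)
    gadd(paste0(pre, "W1"), t(lc$ln2$y) %*% da)
    gadd(paste0(pre, "b1"), colSums(da))
    dln2y <- da %*% t(params[[paste0(pre, "W1")]])
    lb2 <- layernorm_bwd(dln2y, lc$ln2, params[[paste0(pre, "ln2_g")]])
    gadd(paste0(pre, "ln2_g"), lb2$dg)
    gadd(paste0(pre, "ln2_b"), lb2$db)
    dx1 <- dx + lb2$dx
    # attention branch
    dao <- if (is.null(drop_masks)) dx1 else dx1 * drop_masks$attn[[l]]
    gadd(paste0(pre, "Wo"), t(lc$O) %*% dao)
    gadd(paste0(pre, "bo"), colSums(dao))
    dO <- dao %*% t(params[[paste0(pre, "Wo")]])
    dq <- matrix(0, L, config$embed_dim)
    dk <- matrix(0, L, config$embed_dim)
    dv <- matrix(0, L, config$embed_dim)
    for (hh in seq_len(nh)) {
      cols <- ((hh - 1) * dh + 1):(hh * dh)
      A <- lc$A[[hh]]
      dOh <- dO[, cols, drop = FALSE]
      vh <- lc$v[, cols, drop = FALSE]
      dA <- dOh %*% t(vh)
      dv[, cols] <- t(A) %*% dOh
      dS <- A * (dA - rowSums(dA * A))
      dq[, cols] <- dS %*% lc$k[, cols, drop = FALSE] / sqrt(dh)
      dk[, cols] <- t(dS) %*% lc$q[, cols, drop = FALSE] / sqrt(dh)
    }
    gadd(paste0(pre, "Wq"), t(lc$ln1$y) %*% dq)
    gadd(paste0(pre, "bq"), colSums(dq))
    gadd(paste0(pre, "Wk"), t(lc$ln1$y) %*% dk)
    gadd(paste0(pre, "bk"), colSums(dk))
    gadd(paste0(pre, "Wv"), t(lc$ln1$y) %*% dv)
    gadd(paste0(pre, "bv"), colSums(dv))
    dln1y <- dq %*% t(params[[paste0(pre, "Wq")]]) +
      dk %*% t(params[[paste0(pre, "Wk")]]) +
      dv %*% t(params[[paste0(pre, "Wv")]])
    lb1 <- layernorm_bwd(dln1y, lc$ln1, params[[paste0(pre, "ln1_g")]])
    gadd(paste0(pre, "ln1_g"), lb1$dg)
    gadd(paste0(pre, "ln1_b"), lb1$db)
    dx <- dx1 + lb1$dx
  }

  dh0 <- if (is.null(drop_masks)) dx else dx * drop_masks$embed
  # token embeddings (positions >= 2; position 1 holds the condition)
  dwte <- matrix(0, config$vocab_size, config$embed_dim)
  for (i in 2:L) dwte[idx[i], ] <- dwte[idx[i], ] + dh0[i, ]
  gadd("wte", dwte)
  dwpe <- matrix(0, config$max_len, config$embed_dim)
  dwpe[seq_len(L), ] <- dh0
  gadd("wpe", dwpe)
  dwse <- matrix(0, 2L, config$embed_dim)
  for (s in 1:2) {
    rows <- which(seg == s)
    if (length(rows)) dwse[s, ] <- colSums(dh0[rows, , drop = FALSE])
  }
  gadd("wse", dwse)
  gadd("wcond", cond %o% dh0[1, ])
  grads
}

make_drop_masks <- function(config, L, p) {
  if (p <= 0) return(NULL)
  keep <- function(nr, nc) {
    matrix(stats::rbinom(nr * nc, 1L, 1 - p) / (1 - p), nr, nc)
  }
  list(embed = keep(L, config$embed_dim),
       attn = lapply(seq_len(config$n_layers),
                     function(l) keep(L, config$embed_dim)),
       ffn = lapply(seq_len(config$n_layers),
                    function(l) keep(L, config$embed_dim)))
}

# -- public forward ----------------------------------------------------------

#' Next-token distributions for a prefix
#'
#' Runs the full decoder stack and returns the softmax distribution over
#' the vocabulary at every position (each row sums to 1). Position `i`
#' holds the model's distribution for the token *following* position `i`.
#'
#' @param object A `smiles_gpt`.
#' @param smiles SMILES prefix (tokenized internally); may be `""`.
#' @param scaffold Scaffold SMILES conditioning string (default none).
#' @param condition A `protein_encoding` or `NULL`.
#' @param ... Unused.
#' @return `L x vocab_size` matrix of row-stochastic distributions, where
#'   `L` counts the condition slot, scaffold tokens and SMILES tokens.
#' @export
predict.smiles_gpt <- function(object, smiles = "", scaffold = "",
                               condition = NULL, ...) {
  enc <- encode_sequence(object$vocab, scaffold, smiles,
                         add_eos = FALSE)
  out <- seq_forward(object$params, object$config, enc$idx, enc$seg,
                     condition_values(condition, object$config))
  p <- softmax_rows(out$logits)
  colnames(p) <- object$vocab$tokens
  p
}

# Token/segment encoding of scaffold + SMILES (+ optional EOS).
encode_sequence <- function(vocab, scaffold, smiles, add_eos = TRUE,
                            smiles_tokens = NULL) {
  sc <- if (nzchar(scaffold)) tokenize_smiles(scaffold)[[1]] else character(0)
  sm <- smiles_tokens %||%
    (if (nzchar(smiles)) tokenize_smiles(smiles)[[1]] else character(0))
  idx <- c(vocab_special(vocab, "COND"),
           vocab_index(vocab, sc), vocab_index(vocab, sm),
           if (add_eos) vocab_special(vocab, "EOS"))
  seg <- c(1L, rep(1L, length(sc)),
           rep(2L, length(sm) + as.integer(add_eos)))
  list(idx = idx, seg = seg, n_scaffold = length(sc))
}
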