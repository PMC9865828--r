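# Training (pretraining and transfer-learning finetuning) of the SMILES
# generator: Adam on token-level cross-entropy over the SMILES region.

#' Training configuration
#'
#' Defaults follow the published recipe for this family of generators:
#' Adam with learning rate `6e-4` for 10 epochs.
#'
#' @param learning_rate Adam step size.
#' @param epochs Number of passes over the corpus.
#' @param batch_size Sequences per Adam step.
#' @param seed Seed controlling shuffling and dropout; a fixed seed with a
#'   fixed corpus order reproduces losses exactly.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param verbose Print the per-epoch mean loss.
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 6e-4, epochs = 10L, batch_size = 64L,
                         seed = 1L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         verbose = FALSE) {
  stopifnot_scalar_number(learning_rate, "learning_rate")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps, verbose = verbose),
            class = "train_config")
}

# Convert a corpus (+ optional fixed condition) into training examples.
prepare_examples <- function(model, corpus, condition = NULL) {
  vocab <- model$vocab
  unk <- vocab_special(vocab, "UNK")
  cond <- condition_values(condition, model$config)
  lapply(seq_len(nrow(corpus)), function(i) {
    enc <- encode_sequence(vocab, corpus$scaffold[i], corpus$smiles[i],
                           smiles_tokens = corpus$tokens[[i]])
    if (any(enc$idx == unk &
              seq_along(enc$idx) > 1L)) {
      stop("corpus contains tokens outside the model vocabulary ",
           "(vocabulary mismatch): ", corpus$smiles[i], call. = FALSE)
    }
    list(idx = enc$idx, seg = enc$seg, cond = cond)
  })
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  corr1 <- 1 - cfg$beta1^state$t
  corr2 <- 1 - cfg$beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    params[[nm]] <- params[[nm]] - cfg$learning_rate *
      (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + cfg$eps)
  }
  list(params = params, state = state)
}

#' Train the generator on a corpus
#'
#' One fitting routine serves both phases: generic pretraining (no
#' condition, or a null encoding) and transfer-learning finetuning (a
#' fixed protein encoding attached to every example; see [finetune()]).
#' Records the mean per-token training loss for every epoch.
#'
#' @param model A `smiles_gpt`.
#' @param corpus A `mol_corpus` tokenized with the model's vocabulary.
#' @param config A [train_config()].
#' @param condition Optional `protein_encoding` attached to every example.
#' @return The updated `smiles_gpt` (parameters, `loss_trace`, `trained`).
#' @export
train_generator <- function(model, corpus, config = train_config(),
                            condition = NULL) {
  examples <- prepare_examples(model, corpus, condition)
  n <- length(examples)
  params <- model$params
  trace <- numeric(0)
  if (config$epochs > 0L) {
    state <- adam_init(params)
    gcfg <- model$config
    with_seed(derive_seed(config$seed, 1L), {
      for (ep in seq_len(config$epochs)) {
        ord <- sample.int(n)
        ep_loss <- 0
        ep_tok <- 0L
        for (start in seq(1L, n, by = config$batch_size)) {
          batch <- examples[ord[start:min(start + config$batch_size - 1L, n)]]
          ntok <- sum(vapply(batch, function(e) length(loss_positions(e$seg)),
                             integer(1)))
          grads <- NULL
          for (e in batch) {
            dm <- make_drop_masks(gcfg, length(e$idx), gcfg$dropout)
            fwd <- seq_forward(params, gcfg, e$idx, e$seg, e$cond,
                               keep_cache = TRUE, drop_masks = dm)
            sl <- seq_loss(fwd$logits, e$idx, e$seg)
            ep_loss <- ep_loss + sl$loss_sum
            ep_tok <- ep_tok + sl$n
            g <- seq_backward(params, gcfg, e$idx, e$seg, e$cond, fwd,
                              drop_masks = dm, dlogit_scale = 1 / ntok)
            grads <- if (is.null(grads)) g else {
              for (nm in names(g)) grads[[nm]] <- grads[[nm]] + g[[nm]]
              grads
            }
          }
          upd <- adam_step(params, grads, state, config)
          params <- upd$params
          state <- upd$state
        }
        trace <- c(trace, ep_loss / ep_tok)
        if (config$verbose) {
          message(sprintf("epoch %d: mean token loss %.4f", ep,
                          trace[length(trace)]))
        }
      }
    })
  }
  model$params <- params
  model$trained <- TRUE
  model$phase <- if (is.null(condition)) "pretrain" else "finetune"
  model$loss_trace <- c(model$loss_trace, trace)
  model
}

#' Transfer-learning finetuning on known actives
#'
#' Continues training a pretrained checkpoint on a (small) set of active
#' compounds, with the target protein's encoding attached to every
#' example. Training settings default to the pretraining recipe.
#'
#' @param model A pretrained `smiles_gpt` (error if untrained).
#' @param actives A `mol_corpus` of known actives.
#' @param protein A `protein_encoding` of the target.
#' @param config A [train_config()].
#' @return The finetuned `smiles_gpt`.
#' @export
finetune <- function(model, actives, protein, config = train_config()) {
  if (!isTRUE(model$trained)) {
    stop("finetune requires a pretrained checkpoint; train the model first",
         call. = FALSE)
  }
  stopifnot(inherits(protein, "protein_encoding"))
  train_generator(model, actives, config, condition = protein)
}

#' Mean per-token negative log-likelihood of a corpus
#'
#' @param model A `smiles_gpt`.
#' @param corpus A `mol_corpus`.
#' @param condition Optional `protein_encoding`.
#' @return Mean cross-entropy per predicted token (nats).
#' @export
per_token_nll <- function(model, corpus, condition = NULL) {
  examples <- prepare_examples(model, corpus, condition)
  tot <- 0
  n <- 0L
  for (e in examples) {
    fwd <- seq_forward(model$params, model$config, e$idx, e$seg, e$cond)
    sl <- seq_loss(fwd$logits, e$idx, e$seg)
    tot <- tot + sl$loss_sum
    n <- n + sl$n
  }
  tot / n
}

# -- S3 methods --------------------------------------------------------------

#' @export
print.smiles_gpt <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<smiles_gpt> %d layers x %d heads, embed %d, ",
                     "ffn %d, vocab %d (%s)\n"),
              cfg$n_layers, cfg$n_heads, cfg$embed_dim, cfg$ff_hidden,
              cfg$vocab_size, x$phase))
  cat(sprintf("  parameters: %s\n",
              format(as.integer(count_parameters(x)), big.mark = ",")))
  if (!is.null(x$loss_trace)) {
    cat(sprintf("  final training loss: %.4f (%d epochs)\n",
                x$loss_trace[length(x$loss_trace)], length(x$loss_trace)))
  }
  invisible(x)
}

#' @export
summary.smiles_gpt <- function(object, ...) {
  print(object)
  br <- attr(count_parameters(object), "breakdown")
  cat("  parameter breakdown (top components):\n")
  top <- sort(br, decreasing = TRUE)
  top <- utils::head(top, 8)
  for (nm in names(top)) cat(sprintf("    %-12s %d\n", nm, top[[nm]]))
  invisible(object)
}

#' @export
coef.smiles_gpt <- function(object, ...) object$params

#' @export
plot.smiles_gpt <- function(x, ...) {
  if (is.null(x$loss_trace)) stop("model has no training trace",
                                  call. = FALSE)
  plot(seq_along(x$loss_trace), x$loss_trace, type = "b",
       xlab = "epoch", ylab = "mean token loss",
       main = "training loss", ...)
  invisible(x)
}

#' @export
logLik.smiles_gpt <- function(object, corpus, condition = NULL, ...) {
  examples <- prepare_examples(object, corpus, condition)
  tot <- 0
  n <- 0L
  for (e in examples) {
    fwd <- seq_forward(object$params, object$config, e$idx, e$seg, e$cond)
    sl <- seq_loss(fwd$logits, e$idx, e$seg)
    tot <- tot - sl$loss_sum
    n <- n + sl$n
  }
  structure(tot, nobs = n, df = as.integer(count_parameters(object)),
            class = "logLik")
}

# -- checkpoints -------------------------------------------------------------

#' Save / load a generator checkpoint
#'
#' A checkpoint is a single-file archive of the configuration, all
#' parameter tensors, the vocabulary and its hash, and the loss trace.
#' Loading verifies the stored parameters against the stored vocabulary
#' hash, and against `vocab` if one is supplied; a mismatch is an error
#' (a model is meaningless under a different token ordering).
#'
#' @param model A `smiles_gpt`.
#' @param path File path (.rds).
#' @param vocab Optional `smiles_vocabulary` the checkpoint must match.
#' @return `load_checkpoint` returns the `smiles_gpt`; `save_checkpoint`
#'   the path, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, params = model$params,
               vocab = model$vocab, vocab_hash = model$vocab_hash,
               trained = model$trained, phase = model$phase,
               loss_trace = model$loss_trace), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, vocab = NULL) {
  x <- readRDS(path)
  if (!identical(x$vocab_hash, vocab_hash(x$vocab))) {
    stop("checkpoint is corrupt: vocabulary hash mismatch", call. = FALSE)
  }
  if (!is.null(vocab) && !identical(vocab_hash(vocab), x$vocab_hash)) {
    stop("checkpoint vocabulary does not match the supplied vocabulary",
         call. = FALSE)
  }
  structure(list(config = x$config, vocab = x$vocab, params = x$params,
                 trained = x$trained, phase = x$phase,
                 loss_trace = x$loss_trace, vocab_hash = x$vocab_hash),
            class = "smiles_gpt")
}
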