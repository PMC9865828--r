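# Conditional autoregressive sampling, with the weighted start-token rule:
# generation begins from a token drawn in proportion to how often each
# token opened a training SMILES string.

#' Draw start tokens by first-position frequency
#'
#' Samples from the vocabulary's `first_token_weights` table, i.e. the
#' tokens observed at position 1 of the training SMILES, each weighted by
#' its frequency there. Uses the current RNG stream.
#'
#' @param vocab A `smiles_vocabulary`.
#' @param n Number of draws.
#' @return Character vector of tokens.
#' @export
pick_start_token <- function(vocab, n = 1L) {
  w <- vocab$first_token_weights
  if (is.null(w) || length(w) == 0L) {
    stop("vocabulary has an empty first-token weight table", call. = FALSE)
  }
  names(w)[sample.int(length(w), n, replace = TRUE, prob = w)]
}

#' Sample molecules from the generator
#'
#' Autoregressive sampling: the prefix (conditioning slot, scaffold
#' tokens, start token) is extended one token at a time by drawing from
#' the temperature-scaled next-token distribution until the end token or
#' `max_len`. `temperature = 0` decodes greedily. Returned strings are
#' raw model output; validity is assessed downstream by the evaluation
#' battery.
#'
#' @param model A trained `smiles_gpt`.
#' @param n Number of molecules.
#' @param condition A `protein_encoding` or `NULL`.
#' @param scaffold Scaffold SMILES ("" = unconditioned on scaffold); its
#'   tokens must be in the vocabulary.
#' @param temperature Softmax temperature (> 0), or 0 for greedy.
#' @param max_len Maximum SMILES length in tokens.
#' @param seed Optional seed for reproducible sampling; the
#'   (checkpoint, seed, request) triple fully determines the output.
#' @param start_tokens Optional character vector overriding the weighted
#'   start-token draw (recycled to length `n`).
#' @return Character vector of `n` SMILES strings.
#' @export
sample_molecules <- function(model, n, condition = NULL, scaffold = "",
                             temperature = 1.0, max_len = NULL, seed = NULL,
                             start_tokens = NULL) {
  stopifnot(n >= 1L)
  if (temperature < 0) stop("'temperature' must be >= 0", call. = FALSE)
  vocab <- model$vocab
  if (nzchar(scaffold)) {
    sc <- tokenize_smiles(scaffold)[[1]]
    if (anyNA(match(sc, vocab$tokens))) {
      stop("scaffold contains tokens outside the vocabulary", call. = FALSE)
    }
  }
  max_len <- max_len %||% model$config$max_len
  runner <- function() {
    vapply(seq_len(n), function(i) {
      start <- if (is.null(start_tokens)) pick_start_token(vocab)
               else start_tokens[((i - 1L) %% length(start_tokens)) + 1L]
      sample_one(model, condition, scaffold, start, temperature, max_len)
    }, character(1))
  }
  if (is.null(seed)) runner() else with_seed(seed, runner())
}

sample_one <- function(model, condition, scaffold, start_token, temperature,
                       max_len) {
  vocab <- model$vocab
  cfg <- model$config
  cond <- condition_values(condition, cfg)
  enc <- encode_sequence(vocab, scaffold, "", add_eos = FALSE,
                         smiles_tokens = start_token)
  idx <- enc$idx
  seg <- enc$seg
  eos <- vocab_special(vocab, "EOS")
  banned <- vapply(c("PAD", "UNK", "COND"), function(s)
    vocab_special(vocab, s), integer(1))
  out <- start_token
  while (length(out) < max_len && length(idx) < cfg$max_len) {
    logits <- seq_forward(model$params, cfg, idx, seg,
                          cond)$logits[length(idx), ]
    logits[banned] <- -Inf
    nxt <- if (temperature == 0) {
      which.max(logits)
    } else {
      p <- exp((logits - max(logits)) / temperature)
      sample.int(length(p), 1L, prob = p / sum(p))
    }
    if (nxt == eos) break
    idx <- c(idx, nxt)
    seg <- c(seg, 2L)
    out <- c(out, vocab$tokens[nxt])
  }
  detokenize(out)
}

#' Simulate molecules from a fitted generator
#'
#' `simulate()` interface to [sample_molecules()].
#'
#' @param object A trained `smiles_gpt`.
#' @param nsim Number of molecules.
#' @param seed RNG seed (passed to [sample_molecules()]).
#' @param ... Further arguments to [sample_molecules()] (`condition`,
#'   `scaffold`, `temperature`, ...).
#' @return Character vector of SMILES.
#' @export
simulate.smiles_gpt <- function(object, nsim = 1, seed = NULL, ...) {
  sample_molecules(object, n = nsim, seed = seed, ...)
}

#' Most frequent scaffold of a corpus
#'
#' The default generation scaffold for a target: the most common
#' Bemis-Murcko scaffold among its known actives (ties broken
#' alphabetically; the empty scaffold is ignored).
#'
#' @param corpus A `mol_corpus`.
#' @return Scaffold SMILES (possibly "" when all molecules are acyclic).
#' @export
top_scaffold <- function(corpus) {
  sc <- corpus$scaffold[nzchar(corpus$scaffold)]
  if (length(sc) == 0L) return("")
  tab <- sort(table(sc), decreasing = TRUE)
  names(tab)[1]
}
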