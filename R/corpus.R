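# SMILES corpus handling: tokenization, canonical corpus construction,
# vocabulary with first-token statistics, and reproducible 9:1 splits.

# Standard SMILES token pattern: bracket atoms as single tokens, %nn ring
# closures, the two-letter halogens, then any single SMILES character.
SMILES_TOKEN_REGEX <- paste0(
  "\\[[^\\]]+\\]",          # bracket atoms, e.g. [nH], [O-]
  "|%[0-9]{2}",             # two-digit ring closures
  "|Cl|Br",                 # two-letter organic-subset atoms
  "|[BCNOPSFIbcnops0-9]",   # organic-subset atoms and ring digits
  "|[=#$:~@*+/\\\\().-]"    # bonds, branches, charges, stereo marks
)

#' Tokenize SMILES strings
#'
#' Splits each string into chemically meaningful tokens: bracket atoms
#' (`[nH]`) and `%nn` ring closures stay single tokens, `Cl`/`Br` are not
#' split, everything else is one character. Concatenating the tokens
#' reproduces the input exactly.
#'
#' @param smiles Character vector of SMILES strings.
#' @return List of character vectors (one per input string), like
#'   [strsplit()].
#' @examples \dontrun{tokenize_smiles("CC(Cl)Br")[[1]]}
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  lapply(smiles, function(s) {
    if (!nzchar(s)) return(character(0))
    m <- gregexpr(SMILES_TOKEN_REGEX, s, perl = TRUE)[[1]]
    toks <- regmatches(s, list(m))[[1]]
    covered <- sum(attr(m, "match.length"))
    if (m[1] == -1L || covered != nchar(s)) {
      # locate the first character not covered by any token
      pos <- rep(FALSE, nchar(s))
      if (m[1] != -1L) {
        for (i in seq_along(m)) {
          pos[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
        }
      }
      off <- which(!pos)[1]
      stop(sprintf("untokenizable character '%s' at offset %d in \"%s\"",
                   substr(s, off, off), off, s), call. = FALSE)
    }
    toks
  })
}

#' Join tokens back into a SMILES string
#' @param tokens Character vector of tokens.
#' @return Character scalar.
#' @export
detokenize <- function(tokens) paste(tokens, collapse = "")

#' Build a canonical molecule corpus
#'
#' Canonicalizes the input SMILES, drops unparseable entries (with a
#' message reporting the count), tokenizes, and extracts Bemis-Murcko
#' scaffolds. Optionally attaches drug-likeness properties.
#'
#' @param smiles Character vector of raw SMILES.
#' @param properties If `TRUE`, attach MW/LogP/QED/SA columns.
#' @return `data.frame` of class `mol_corpus` with columns `smiles_raw`,
#'   `smiles` (canonical), `scaffold`, and a list-column `tokens`; the
#'   number of dropped invalid entries is in attribute `n_dropped`.
#' @export
make_corpus <- function(smiles, properties = FALSE) {
  stopifnot(is.character(smiles), length(smiles) > 0L)
  canon <- canonicalize(smiles)
  keep <- !is.na(canon)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("dropped %d invalid SMILES during ingestion", n_dropped))
  }
  if (!any(keep)) stop("no valid SMILES in input", call. = FALSE)
  df <- data.frame(smiles_raw = smiles[keep], smiles = canon[keep],
                   scaffold = extract_scaffold(canon[keep]),
                   stringsAsFactors = FALSE)
  df$tokens <- tokenize_smiles(df$smiles)
  if (properties) {
    df <- cbind(df, mol_properties(df$smiles)[, c("MW", "LogP", "QED",
                                                  "SA", "SA_norm")])
  }
  attr(df, "n_dropped") <- n_dropped
  class(df) <- c("mol_corpus", "data.frame")
  df
}

# Special tokens. There is no BOS: generation starts from a sampled first
# token (see pick_start_token), so only PAD/EOS/UNK/CONDITION are reserved.
SPECIAL_TOKENS <- c(PAD = "<pad>", EOS = "<eos>", UNK = "<unk>",
                    COND = "<cond>")

#' Build a token vocabulary from a corpus
#'
#' The token set is the union of all tokens appearing in the canonical
#' SMILES and their scaffolds, plus the four special tokens (padding,
#' end-of-sequence, unknown, and the conditioning slot). Also records, for
#' every token observed at position 1 of a SMILES string, how often it
#' occurs there: these counts drive weighted start-token sampling at
#' generation time.
#'
#' @param corpus A `mol_corpus` (see [make_corpus()]).
#' @return Object of class `smiles_vocabulary`: list with `tokens`
#'   (specials first, then sorted corpus tokens), `token_to_index` (dense
#'   0-based map, exported as-is to JSON) and `first_token_weights`.
#' @export
build_vocabulary <- function(corpus) {
  if (is.null(corpus) || nrow(corpus) == 0L) {
    stop("cannot build a vocabulary from an empty corpus", call. = FALSE)
  }
  scaffold_tokens <- tokenize_smiles(corpus$scaffold[nzchar(corpus$scaffold)])
  toks <- sort(unique(c(unlist(corpus$tokens), unlist(scaffold_tokens))))
  tokens <- c(unname(SPECIAL_TOKENS), toks)
  firsts <- vapply(corpus$tokens, `[`, character(1), 1L)
  ft <- table(firsts)
  structure(list(tokens = tokens,
                 token_to_index = stats::setNames(seq_along(tokens) - 1L,
                                                  tokens),
                 first_token_weights = stats::setNames(as.integer(ft),
                                                       names(ft))),
            class = "smiles_vocabulary")
}

#' @export
print.smiles_vocabulary <- function(x, ...) {
  cat(sprintf("<smiles_vocabulary> %d tokens (%d special), %d start tokens\n",
              length(x$tokens), length(SPECIAL_TOKENS),
              length(x$first_token_weights)))
  invisible(x)
}

# 1-based positions of tokens in the vocabulary; unknown tokens map to UNK.
vocab_index <- function(vocab, tokens) {
  i <- match(tokens, vocab$tokens)
  i[is.na(i)] <- match(SPECIAL_TOKENS[["UNK"]], vocab$tokens)
  i
}

vocab_special <- function(vocab, which) {
  match(SPECIAL_TOKENS[[which]], vocab$tokens)
}

#' Write / read a vocabulary as JSON
#'
#' @param vocab A `smiles_vocabulary`.
#' @param path Output (or input) JSON file.
#' @return `read_vocabulary` returns a `smiles_vocabulary`;
#'   `write_vocabulary` the path, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(list(tokens = vocab$tokens,
                            token_to_index = as.list(vocab$token_to_index),
                            first_token_weights =
                              as.list(vocab$first_token_weights)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(list(tokens = x$tokens,
                 token_to_index = stats::setNames(
                   as.integer(unlist(x$token_to_index)),
                   names(x$token_to_index)),
                 first_token_weights = stats::setNames(
                   as.integer(unlist(x$first_token_weights)),
                   names(x$first_token_weights))),
            class = "smiles_vocabulary")
}

#' Split a corpus into training and test sets
#'
#' Seeded shuffle followed by a 9:1 partition (the split used both for
#' generic pretraining corpora and for per-target active sets).
#'
#' @param corpus A `mol_corpus` with at least 10 records.
#' @param ratio Training fraction (default 0.9).
#' @param seed Shuffle seed (default 42); the same seed always reproduces
#'   the identical split.
#' @return Object of class `corpus_split`: list with `train`, `test`
#'   (both `mol_corpus`), `ratio`, `seed` and the shuffled `train_idx` /
#'   `test_idx` index vectors.
#' @export
split_corpus <- function(corpus, ratio = 0.9, seed = 42L) {
  n <- nrow(corpus)
  if (is.null(n) || n < 10L) {
    stop("corpus must contain at least 10 records to split", call. = FALSE)
  }
  stopifnot(ratio > 0, ratio < 1)
  perm <- with_seed(seed, sample.int(n))
  n_train <- floor(ratio * n)
  train_idx <- sort(perm[seq_len(n_train)])
  test_idx <- sort(perm[(n_train + 1):n])
  structure(list(train = corpus[train_idx, , drop = FALSE],
                 test = corpus[test_idx, , drop = FALSE],
                 ratio = ratio, seed = as.integer(seed),
                 train_idx = train_idx, test_idx = test_idx),
            class = "corpus_split")
}

#' @export
print.corpus_split <- function(x, ...) {
  cat(sprintf("<corpus_split> %d train / %d test (ratio %.2f, seed %d)\n",
              nrow(x$train), nrow(x$test), x$ratio, x$seed))
  invisible(x)
}

#' Read SMILES from a plain-text or CSV file
#'
#' @param path One-SMILES-per-line text file, or a CSV.
#' @param smiles_col For CSV input, the name of the SMILES column; `NULL`
#'   (default) treats the file as plain text.
#' @return Character vector of SMILES.
#' @export
read_smiles_file <- function(path, smiles_col = NULL) {
  if (is.null(smiles_col)) {
    out <- trimws(readLines(path, warn = FALSE))
    out[nzchar(out)]
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!smiles_col %in% names(df)) {
      stop("column '", smiles_col, "' not found in ", path, call. = FALSE)
    }
    df[[smiles_col]]
  }
}

#' Write a canonical corpus to CSV
#'
#' Columns: canonical smiles, scaffold, tokens joined by spaces.
#' @param corpus A `mol_corpus`.
#' @param path Output CSV path.
#' @export
write_corpus <- function(corpus, path) {
  utils::write.csv(
    data.frame(smiles = corpus$smiles, scaffold = corpus$scaffold,
               tokens = vapply(corpus$tokens, paste, character(1),
                               collapse = " "),
               stringsAsFactors = FALSE),
    path, row.names = FALSE)
  invisible(path)
}
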