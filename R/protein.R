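# Protein sequence handling and the three sequence encoders (PseAAC,
# autocorrelation descriptors, conjoint triad), fused into the fixed-width
# conditioning vector consumed by the generator.

#' Sanitize a raw amino-acid sequence
#'
#' Uppercases, strips whitespace, digits and stop characters (`*`), and
#' resolves non-standard letters by the usual convention: B->N, Z->Q, U->C,
#' O->K, J->L; `X` (unknown) is dropped. The policy is overridable through
#' `substitutions`, a named character vector mapping letters to replacement
#' letters ("" drops the residue).
#'
#' @param raw A character scalar: the residue string, possibly with a FASTA
#'   header line (anything after `>` up to the first newline is used as id).
#' @param id Optional record id; defaults to the FASTA header or `"seq"`.
#' @param substitutions Named character vector overriding the default
#'   non-standard-residue policy.
#' @return An object of class `protein_sequence`: list with `id`,
#'   `residues` and `length`.
#' @export
sanitize_sequence <- function(raw, id = NULL,
                              substitutions = c(B = "N", Z = "Q", U = "C",
                                                O = "K", J = "L", X = "")) {
  if (!is.character(raw) || length(raw) != 1L) {
    stop("'raw' must be a single character string", call. = FALSE)
  }
  if (startsWith(trimws(raw), ">")) {
    lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
    if (is.null(id)) id <- sub("^>\\s*", "", trimws(lines[1]))
    raw <- paste(lines[-1], collapse = "")
  }
  s <- toupper(gsub("[[:space:][:digit:]*]", "", raw))
  if (!nzchar(s)) stop("empty protein sequence", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (from in names(substitutions)) {
    chars[chars == from] <- substitutions[[from]]
  }
  chars <- chars[nzchar(chars)]
  bad <- setdiff(unique(chars), AA_LETTERS)
  if (length(bad) > 0L) {
    stop("unrecognized residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(chars) < 3L) {
    stop("sequence shorter than 3 residues after sanitization", call. = FALSE)
  }
  structure(list(id = id %||% "seq",
                 residues = paste(chars, collapse = ""),
                 length = length(chars)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s: %d residues\n", x$id, x$length))
  cat(" ", if (x$length > 60) paste0(substr(x$residues, 1, 60), "...")
      else x$residues, "\n")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a single- or multi-record FASTA file.
#' @return List of `protein_sequence` objects.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path,
                              call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    sanitize_sequence(as.character(set[[i]]), id = ids[i])
  })
}

as_protein_sequence <- function(seq) {
  if (inherits(seq, "protein_sequence")) seq else sanitize_sequence(seq)
}

# z-score each row of a property table over the 20 residues (population SD,
# the convention used for pseudo amino acid composition).
standardize_properties <- function(table) {
  t(apply(table, 1, function(p) {
    (p - mean(p)) / sqrt(mean((p - mean(p))^2))
  }))
}

#' Pseudo amino acid composition
#'
#' The 20 amino-acid frequencies augmented with `epsilon` sequence-order
#' correlation factors. Writing `f_u` for residue frequencies and `theta_j`
#' for the rank-`j` correlation factor, the vector is
#' `x_u = f_u / (sum f + alpha * sum theta)` for the first 20 entries and
#' `x_{20+j} = alpha * theta_j / (sum f + alpha * sum theta)` for the rest,
#' so all components are non-negative and sum to one. `theta_j` is the mean
#' over positions of the squared standardized property differences between
#' residues `j` apart (hydrophobicity, hydrophilicity and side-chain mass
#' averaged).
#'
#' @param seq A `protein_sequence` (or raw string, sanitized on the fly).
#' @param epsilon Number of correlation factors; must satisfy
#'   `0 <= epsilon < S`.
#' @param alpha Non-negative weight of the correlation part (default 0.05).
#' @param properties Property table, rows standardized internally
#'   (default [PSEAAC_PROPERTIES]).
#' @return Object of class `pseaac`: numeric vector of length
#'   `20 + epsilon` with attributes `epsilon` and `alpha`.
#' @export
pseaac <- function(seq, epsilon = 30L, alpha = 0.05,
                   properties = PSEAAC_PROPERTIES) {
  seq <- as_protein_sequence(seq)
  S <- seq$length
  epsilon <- as.integer(epsilon)
  if (epsilon < 0L) stop("'epsilon' must be non-negative", call. = FALSE)
  if (epsilon >= S) {
    stop(sprintf("'epsilon' (%d) must be smaller than the sequence length (%d)",
                 epsilon, S), call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha < 0) {
    stop("'alpha' must be a non-negative number", call. = FALSE)
  }
  chars <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
  f <- as.numeric(table(factor(chars, levels = AA_LETTERS))) / S
  P <- standardize_properties(properties)[, chars, drop = FALSE]
  theta <- numeric(epsilon)
  if (epsilon > 0L) {
    for (j in seq_len(epsilon)) {
      d <- P[, (1 + j):S, drop = FALSE] - P[, 1:(S - j), drop = FALSE]
      theta[j] <- mean(colMeans(d^2))
    }
  }
  denom <- sum(f) + alpha * sum(theta)
  x <- c(f, alpha * theta) / denom
  names(x) <- c(AA_LETTERS,
                if (epsilon > 0L) paste0("theta", seq_len(epsilon)))
  structure(x, epsilon = epsilon, alpha = alpha, class = "pseaac")
}

#' Conjoint triad descriptor
#'
#' Maps residues to 7 physicochemical classes, counts every overlapping
#' window of three consecutive residues among the `7^3 = 343` triad types,
#' and scales the counts as `d_i = (f_i - min f) / max f`.
#'
#' @param seq A `protein_sequence` (or raw string); at least 3 residues.
#' @param class_map Named integer vector mapping the 20 residues to classes
#'   1..7 (default [CT_CLASSES]).
#' @return Numeric vector of length 343 in `[0, 1]`, named
#'   `c<i>.<j>.<k>` by class triple; its minimum is exactly 0.
#' @export
conjoint_triad <- function(seq, class_map = CT_CLASSES) {
  seq <- as_protein_sequence(seq)
  if (seq$length < 3L) stop("conjoint triad needs at least 3 residues",
                            call. = FALSE)
  n_class <- max(class_map)
  if (!setequal(names(class_map), AA_LETTERS)) {
    stop("'class_map' must cover exactly the 20 standard residues",
         call. = FALSE)
  }
  cls <- unname(class_map[strsplit(seq$residues, "", fixed = TRUE)[[1]]])
  S <- length(cls)
  idx <- (cls[1:(S - 2)] - 1L) * n_class^2 +
    (cls[2:(S - 1)] - 1L) * n_class + cls[3:S]
  f <- tabulate(idx, nbins = n_class^3)
  d <- (f - min(f)) / max(f)
  grid <- expand.grid(k = 1:n_class, j = 1:n_class, i = 1:n_class)
  names(d) <- paste0("c", grid$i, ".", grid$j, ".", grid$k)
  d
}

#' Normalized Moreau-Broto autocorrelation descriptors
#'
#' For each physicochemical scale `p` (z-scored over the 20 residues) and
#' each lag `d` in `1..max_lag`, computes
#' `AC(p, d) = (1 / (S - d)) * sum_i P_i * P_{i+d}`, the average product of
#' standardized property values `d` positions apart.
#'
#' @param seq A `protein_sequence` (or raw string).
#' @param properties Property table (rows = scales, columns = the 20
#'   residues; default [AD_PROPERTIES]).
#' @param max_lag Largest lag; must be smaller than the sequence length.
#' @return Numeric vector of length `nrow(properties) * max_lag`, named
#'   `<scale>.lag<d>`.
#' @export
autocorrelation <- function(seq, properties = AD_PROPERTIES, max_lag = 30L) {
  seq <- as_protein_sequence(seq)
  S <- seq$length
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L) stop("'max_lag' must be at least 1", call. = FALSE)
  if (max_lag >= S) {
    stop(sprintf("'max_lag' (%d) must be smaller than the sequence length (%d)",
                 max_lag, S), call. = FALSE)
  }
  P <- standardize_properties(properties)[, strsplit(seq$residues, "",
                                                     fixed = TRUE)[[1]],
                                          drop = FALSE]
  out <- matrix(0, nrow(properties), max_lag)
  for (d in seq_len(max_lag)) {
    out[, d] <- rowSums(P[, 1:(S - d), drop = FALSE] *
                          P[, (1 + d):S, drop = FALSE]) / (S - d)
  }
  v <- as.numeric(t(out))
  names(v) <- as.vector(t(outer(rownames(properties), seq_len(max_lag),
                                function(p, d) paste0(p, ".lag", d))))
  v
}

#' Configuration for the fused protein encoding
#'
#' @param epsilon,alpha PseAAC parameters (see [pseaac()]).
#' @param max_lag,properties Autocorrelation parameters (see
#'   [autocorrelation()]).
#' @param pseaac_properties Property table for the PseAAC correlation
#'   factors.
#' @param class_map Conjoint-triad class map.
#' @param dim Width of the fused encoding (default 512).
#' @param projection_seed Seed of the deterministic random projection that
#'   maps the concatenated descriptors to `dim` values.
#' @return List of class `encoding_config`.
#' @export
encoding_config <- function(epsilon = 30L, alpha = 0.05, max_lag = 30L,
                            properties = AD_PROPERTIES,
                            pseaac_properties = PSEAAC_PROPERTIES,
                            class_map = CT_CLASSES,
                            dim = 512L, projection_seed = 7L) {
  structure(list(epsilon = as.integer(epsilon), alpha = alpha,
                 max_lag = as.integer(max_lag), properties = properties,
                 pseaac_properties = pseaac_properties,
                 class_map = class_map, dim = as.integer(dim),
                 projection_seed = as.integer(projection_seed)),
            class = "encoding_config")
}

# Deterministic Gaussian random projection matrix (dim x d_in), scaled so
# the projection roughly preserves vector norms.
projection_matrix <- function(d_in, d_out, seed) {
  with_seed(seed, matrix(stats::rnorm(d_out * d_in, sd = 1 / sqrt(d_in)),
                         d_out, d_in))
}

#' Encode a protein sequence as a fixed 512-length conditioning vector
#'
#' Concatenates the PseAAC vector, the autocorrelation descriptors and the
#' conjoint triad descriptor (633 values under the defaults) and applies a
#' deterministic seeded Gaussian projection to exactly `config$dim`
#' dimensions. The same sequence and configuration always yield the
#' identical vector.
#'
#' @param seq A `protein_sequence`, raw residue string, or path handled by
#'   [sanitize_sequence()].
#' @param config An [encoding_config()].
#' @return Object of class `protein_encoding`: list with `id`, `values`
#'   (length `config$dim`) and `source_dims` (the three pre-projection
#'   lengths).
#' @export
encode_protein <- function(seq, config = encoding_config()) {
  seq <- as_protein_sequence(seq)
  ps <- pseaac(seq, epsilon = config$epsilon, alpha = config$alpha,
               properties = config$pseaac_properties)
  ad <- autocorrelation(seq, properties = config$properties,
                        max_lag = config$max_lag)
  ct <- conjoint_triad(seq, class_map = config$class_map)
  raw <- c(as.numeric(ps), as.numeric(ad), as.numeric(ct))
  proj <- projection_matrix(length(raw), config$dim, config$projection_seed)
  structure(list(id = seq$id,
                 values = as.numeric(proj %*% raw),
                 source_dims = c(pseaac = length(ps), ad = length(ad),
                                 ct = length(ct))),
            class = "protein_encoding")
}

#' @export
print.protein_encoding <- function(x, ...) {
  cat(sprintf("<protein_encoding> %s: %d values (PseAAC %d + AD %d + CT %d)\n",
              x$id, length(x$values), x$source_dims[["pseaac"]],
              x$source_dims[["ad"]], x$source_dims[["ct"]]))
  invisible(x)
}

#' A zero conditioning vector (no target)
#'
#' Used during generic pretraining, where no protein target is attached.
#' @param dim Encoding width (default 512).
#' @return A `protein_encoding` with all-zero values.
#' @export
null_encoding <- function(dim = 512L) {
  structure(list(id = "<none>", values = numeric(dim),
                 source_dims = c(pseaac = 0L, ad = 0L, ct = 0L)),
            class = "protein_encoding")
}
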