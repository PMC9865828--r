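# Evaluation battery for generated molecules: validity / novelty /
# uniqueness ratios, drug-likeness property summaries, Wasserstein-1
# property shifts against a reference set, and nearest-active Tanimoto
# similarity over Morgan fingerprints.

#' Validity, novelty and uniqueness ratios
#'
#' * valid: fraction of generated strings that parse;
#' * unique: distinct canonical molecules among the valid ones, divided by
#'   the number of valid strings;
#' * novel: fraction of the distinct canonical valid molecules that are
#'   absent from the reference (training) set.
#'
#' Novelty and uniqueness are computed on canonical SMILES of the valid
#' subset, the convention of the standard generation benchmarks.
#'
#' @param generated Character vector of generated SMILES (non-empty).
#' @param reference Character vector of reference SMILES (canonicalized
#'   internally); may be empty.
#' @return Named numeric vector `c(valid=, unique=, novel=)`.
#' @export
eval_ratios <- function(generated, reference = character(0)) {
  if (length(generated) == 0L) {
    stop("cannot evaluate an empty set of generated molecules",
         call. = FALSE)
  }
  canon <- canonicalize(generated)
  valid <- canon[!is.na(canon)]
  ratio_valid <- length(valid) / length(generated)
  if (length(valid) == 0L) {
    return(c(valid = 0, unique = NA_real_, novel = NA_real_))
  }
  distinct <- unique(valid)
  ref <- unique(canonicalize(reference))
  ref <- ref[!is.na(ref)]
  c(valid = ratio_valid,
    unique = length(distinct) / length(valid),
    novel = mean(!distinct %in% ref))
}

#' Empirical Wasserstein-1 distance between two samples
#'
#' The earth-mover distance between the empirical distributions,
#' `integral |F_a - F_b| dx`; for equally sized samples this equals the
#' mean absolute difference of the sorted values. Symmetric, nonnegative,
#' and exactly `|c|` when one sample is the other shifted by `c`.
#'
#' @param a,b Non-empty numeric vectors.
#' @return Nonnegative scalar.
#' @export
wasserstein1 <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  pts <- sort(unique(c(a, b)))
  if (length(pts) == 1L) return(0)
  Fa <- stats::ecdf(a)(pts)
  Fb <- stats::ecdf(b)(pts)
  k <- length(pts)
  sum(abs(Fa[-k] - Fb[-k]) * diff(pts))
}

# Tanimoto over two on-bit index sets.
tanimoto_bits <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Nearest-active Tanimoto similarity
#'
#' For each generated molecule, the maximum Tanimoto similarity
#' `|A n B| / |A u B|` of its Morgan fingerprint bit set against all
#' active compounds. Monotone non-decreasing as actives are added.
#'
#' @param generated Character vector of valid SMILES.
#' @param actives Non-empty character vector of valid SMILES.
#' @param radius,n_bits Morgan fingerprint parameters (default 2 / 2048).
#' @return Numeric vector in `[0, 1]`, one value per generated molecule.
#' @export
tanimoto_nearest <- function(generated, actives, radius = 2L,
                             n_bits = 2048L) {
  if (length(actives) == 0L) stop("'actives' must be non-empty",
                                  call. = FALSE)
  fg <- morgan_bits(generated, radius, n_bits)
  fa <- morgan_bits(actives, radius, n_bits)
  vapply(fg, function(g) max(vapply(fa, function(a) tanimoto_bits(g, a),
                                    numeric(1))), numeric(1))
}

#' Evaluate a generated set against references
#'
#' Assembles the full report: ratios, per-molecule properties with
#' mean +/- sd summaries, Wasserstein-1 distances per property against
#' the actives (and optionally a decoy set), and the nearest-active
#' similarity distribution.
#'
#' @param generated Character vector of generated SMILES.
#' @param actives Character vector of reference actives (the transfer
#'   learning set); also the novelty reference unless `reference_train`
#'   is given.
#' @param decoys Optional second reference set.
#' @param reference_train Optional explicit novelty reference.
#' @param radius,n_bits Morgan fingerprint parameters.
#' @return Object of class `eval_report`: list with `ratios`,
#'   `properties` (per valid molecule), `property_summary`, `w1`,
#'   `similarity`, `n_generated`.
#' @export
summarize_generation <- function(generated, actives, decoys = NULL,
                                 reference_train = NULL, radius = 2L,
                                 n_bits = 2048L) {
  if (length(generated) == 0L || length(actives) == 0L) {
    stop("'generated' and 'actives' must be non-empty", call. = FALSE)
  }
  ratios <- eval_ratios(generated, reference_train %||% actives)
  canon <- canonicalize(generated)
  valid <- canon[!is.na(canon)]
  act <- canonicalize(actives)
  act <- act[!is.na(act)]
  props <- mol_properties(valid)
  props_act <- mol_properties(act)
  prop_names <- c("MW", "LogP", "QED", "SA")
  summ <- t(vapply(prop_names, function(p) {
    c(mean = mean(props[[p]]), sd = stats::sd(props[[p]]))
  }, numeric(2)))
  w1 <- vapply(prop_names, function(p) {
    wasserstein1(props[[p]], props_act[[p]])
  }, numeric(1))
  w1 <- list(actives = w1)
  if (!is.null(decoys)) {
    dec <- canonicalize(decoys)
    dec <- dec[!is.na(dec)]
    props_dec <- mol_properties(dec)
    w1$decoys <- vapply(prop_names, function(p) {
      wasserstein1(props[[p]], props_dec[[p]])
    }, numeric(1))
  }
  structure(list(ratios = ratios, properties = props,
                 property_summary = summ, w1 = w1,
                 similarity = tanimoto_nearest(valid, act, radius, n_bits),
                 n_generated = length(generated)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  %d generated: valid %.3f, unique %.3f, novel %.3f\n",
              x$n_generated, x$ratios[["valid"]], x$ratios[["unique"]],
              x$ratios[["novel"]]))
  for (p in rownames(x$property_summary)) {
    cat(sprintf("  %-5s %8.3f +/- %.3f   (W1 vs actives %.3f)\n", p,
                x$property_summary[p, "mean"], x$property_summary[p, "sd"],
                x$w1$actives[[p]]))
  }
  cat(sprintf("  nearest-active Tanimoto: mean %.3f, max %.3f\n",
              mean(x$similarity), max(x$similarity)))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes `report.json` (ratios, summaries, W1 table) and
#' `per_molecule.csv` (canonical SMILES, properties, nearest-active
#' similarity).
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(ratios = as.list(report$ratios),
         property_summary = apply(report$property_summary, 1, as.list),
         w1 = lapply(report$w1, as.list),
         similarity_mean = mean(report$similarity),
         n_generated = report$n_generated),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  per_mol <- report$properties
  per_mol$nearest_active_tanimoto <- report$similarity
  utils::write.csv(per_mol, file.path(dir, "per_molecule.csv"),
                   row.names = FALSE)
  invisible(dir)
}
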