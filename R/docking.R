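# File-level adapter for AutoDock-Vina-family docking: writes grid
# configs, ligand files and job manifests, and parses result logs. It
# never runs or re-implements docking; receptor preparation (hydrogens,
# Gasteiger charges, pdbqt conversion) stays with the external tools the
# manifest names.

#' Define a docking grid box
#'
#' @param size_x,size_y,size_z Box edge lengths in Angstrom (all > 0).
#' @param center_x,center_y,center_z Box center coordinates in Angstrom.
#' @return List of class `grid_box`.
#' @export
grid_box <- function(size_x, size_y, size_z, center_x, center_y, center_z) {
  sizes <- c(size_x = size_x, size_y = size_y, size_z = size_z)
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    stop("all grid box sizes must be positive", call. = FALSE)
  }
  structure(list(size_x = size_x, size_y = size_y, size_z = size_z,
                 center_x = center_x, center_y = center_y,
                 center_z = center_z),
            class = "grid_box")
}

#' Built-in grid presets for the three study targets
#'
#' Grid boxes used for the kinase EGFR (PDB 2RGP), the sphingosine-1-
#' phosphate receptor S1PR1 (7VIH) and the serotonin receptor HTR1A
#' (7E2X). `"EGFR_alt"` is the alternative EGFR center reported from
#' blind-docking analysis (centers 23/38/87); both EGFR variants are
#' shipped without reconciling them.
#'
#' @param target One of `"EGFR"`, `"S1PR1"`, `"HTR1A"`, `"EGFR_alt"`.
#' @return A [grid_box()].
#' @export
grid_preset <- function(target = c("EGFR", "S1PR1", "HTR1A", "EGFR_alt")) {
  switch(match.arg(target),
    EGFR = grid_box(44, 49, 57, 19.496, 35.001, 89.270),
    S1PR1 = grid_box(75, 75, 75, 120.713, 118.886, 131.755),
    HTR1A = grid_box(75, 75, 75, 93.496, 92.635, 76.821),
    EGFR_alt = grid_box(44, 49, 57, 23, 38, 87))
}

format_grid_value <- function(x) {
  if (x == round(x)) as.character(as.integer(x))
  else format(x, trim = TRUE, scientific = FALSE, nsmall = 3)
}

#' Write a docking job: config, ligand list and manifest
#'
#' Emits, under `out_dir`:
#' * `conf.txt` — grid keys in the Vina dialect (`receptor=`, `size_x=`,
#'   `center_x=`, ...);
#' * `ligands.smi` — one SMILES per line;
#' * `manifest.json` — the external conversion (openbabel) and docking
#'   commands to run, one docking invocation per replicate.
#'
#' Nothing is executed; identical inputs produce byte-identical files.
#'
#' @param ligand_smiles Character vector of ligand SMILES.
#' @param receptor_path Path to the receptor PDB/PDBQT file (must exist).
#' @param grid A [grid_box()].
#' @param out_dir Output directory.
#' @param replicates Number of docking replicates per ligand (default 3;
#'   scores are later aggregated by their minimum).
#' @param exhaustiveness Optional Vina exhaustiveness setting.
#' @return The manifest, invisibly.
#' @export
write_docking_job <- function(ligand_smiles, receptor_path, grid, out_dir,
                              replicates = 3L, exhaustiveness = NULL) {
  if (!file.exists(receptor_path)) {
    stop("receptor file not found: ", receptor_path, call. = FALSE)
  }
  stopifnot(inherits(grid, "grid_box"), length(ligand_smiles) >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conf <- c(
    paste0("receptor = ", basename(receptor_path), "qt"),
    vapply(c("size_x", "size_y", "size_z", "center_x", "center_y",
             "center_z"),
           function(k) paste0(k, " = ", format_grid_value(grid[[k]])),
           character(1)),
    if (!is.null(exhaustiveness)) {
      paste0("exhaustiveness = ", format_grid_value(exhaustiveness))
    }
  )
  writeLines(conf, file.path(out_dir, "conf.txt"))
  writeLines(ligand_smiles, file.path(out_dir, "ligands.smi"))
  ids <- sprintf("ligand_%04d", seq_along(ligand_smiles))
  manifest <- list(
    receptor = receptor_path,
    grid = unclass(grid),
    replicates = as.integer(replicates),
    prepare_receptor = paste0(
      "# prepare receptor with AutoDockTools (add hydrogens, Gasteiger ",
      "charges, merge non-polar hydrogens), then convert to pdbqt"),
    ligands = lapply(seq_along(ligand_smiles), function(i) {
      pdbqt <- paste0(ids[i], ".pdbqt")
      list(id = ids[i], smiles = ligand_smiles[i],
           convert = sprintf(
             "obabel -:%s -O %s -h --gen3d", ligand_smiles[i], pdbqt),
           dock = vapply(seq_len(replicates), function(r) {
             sprintf(
               "vina --config conf.txt --ligand %s --out %s_rep%d_out.pdbqt > %s_rep%d.log",
               pdbqt, ids[i], r, ids[i], r)
           }, character(1)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Parse Vina-family docking logs
#'
#' Reads the result table (`mode | affinity | rmsd ...`) of one or more
#' Vina-style logs and extracts the best (lowest) affinity per table.
#' Tables may be preceded by a `Ligand: <id>` line; unnamed tables are
#' numbered in order.
#'
#' @param text Character vector of log lines (or a single string with
#'   newlines).
#' @return `data.frame` with columns `ligand_id` and `score` (kcal/mol,
#'   best mode per table).
#' @export
parse_vina_scores <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  res <- list()
  current_id <- NULL
  in_table <- FALSE
  best <- NULL
  n_tab <- 0L
  flush <- function() {
    if (!is.null(best)) {
      res[[length(res) + 1L]] <<- data.frame(
        ligand_id = current_id %||% sprintf("table_%d", n_tab),
        score = best, stringsAsFactors = FALSE)
    }
    best <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*Ligand:\\s*\\S", ln)) {
      flush()
      current_id <- sub("^\\s*Ligand:\\s*", "", trimws(ln))
      next
    }
    if (grepl("^-+\\+-+", ln)) {
      flush()
      n_tab <- n_tab + 1L
      in_table <- TRUE
      next
    }
    if (in_table) {
      if (grepl("^\\s*\\d+\\s+-?\\d", ln)) {
        f <- strsplit(trimws(ln), "\\s+")[[1]]
        aff <- suppressWarnings(as.numeric(f[2]))
        if (is.na(aff)) {
          stop(sprintf("unparseable affinity on line %d: \"%s\"", i, ln),
               call. = FALSE)
        }
        best <- if (is.null(best)) aff else min(best, aff)
      } else if (nzchar(trimws(ln))) {
        in_table <- FALSE
      }
    }
  }
  flush()
  if (length(res) == 0L) {
    stop("no Vina result table found in log text", call. = FALSE)
  }
  do.call(rbind, res)
}

#' Aggregate replicate docking scores
#'
#' Each ligand is docked several times (three in the study protocol) and
#' the optimal -- i.e. minimum, most negative -- score is kept.
#'
#' @param ligand_id Ligand identifier.
#' @param replicate_scores Numeric vector of per-replicate scores.
#' @return Object of class `docking_result`: list with `ligand_id`,
#'   `score = min(replicate_scores)` and `replicate_scores`.
#' @export
docking_result <- function(ligand_id, replicate_scores) {
  if (length(replicate_scores) == 0L || any(!is.finite(replicate_scores))) {
    stop("'replicate_scores' must be non-empty and finite", call. = FALSE)
  }
  structure(list(ligand_id = ligand_id, score = min(replicate_scores),
                 replicate_scores = replicate_scores),
            class = "docking_result")
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf("<docking_result> %s: %.2f kcal/mol (best of %d replicates)\n",
              x$ligand_id, x$score, length(x$replicate_scores)))
  invisible(x)
}
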