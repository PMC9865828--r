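# Bridge to RDKit for the standard cheminformatics steps: parsing and
# canonicalization, Bemis-Murcko scaffolds, drug-likeness descriptors and
# Morgan fingerprints. Calls are batched (one interpreter launch per vector
# of molecules) and memoized per session.

.chem_cache <- new.env(parent = emptyenv())

#' Locate the python interpreter used for RDKit operations
#'
#' Resolution order: option `ligandgen.python`, environment variable
#' `LIGANDGEN_PYTHON`, then `python` / `python3` on the `PATH`.
#'
#' @return Path to the interpreter.
#' @export
chem_python <- function() {
  p <- getOption("ligandgen.python", "")
  if (!nzchar(p)) p <- Sys.getenv("LIGANDGEN_PYTHON", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) {
    stop("no python interpreter found; set options(ligandgen.python=...)",
         call. = FALSE)
  }
  unname(p)
}

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "ligandgen")
  if (!nzchar(path)) {
    # during development (pkgload), inst/ is on the source path
    path <- file.path("inst", "python", "chem_backend.py")
  }
  if (!file.exists(path)) stop("chem_backend.py not found", call. = FALSE)
  path
}

# Run one batched backend op; returns the parsed JSON payload (a list or
# character vector parallel to `smiles`).
chem_backend <- function(op, smiles, args = character()) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(list())
  key_head <- paste(c(op, args), collapse = "/")
  keys <- paste0(key_head, "\r", smiles)
  hit <- vapply(keys, function(k) !is.null(.chem_cache[[k]]), logical(1))
  if (!all(hit)) {
    todo <- unique(smiles[!hit])
    fin <- tempfile(fileext = ".smi")
    fout <- tempfile(fileext = ".json")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    writeLines(todo, fin)
    status <- system2(chem_python(),
                      c(shQuote(backend_script()), op, shQuote(fin),
                        shQuote(fout), args),
                      stdout = TRUE, stderr = TRUE)
    if (!file.exists(fout)) {
      stop("chem backend failed: ", paste(status, collapse = "\n"),
           call. = FALSE)
    }
    res <- jsonlite::fromJSON(fout, simplifyVector = FALSE)
    for (i in seq_along(todo)) {
      .chem_cache[[paste0(key_head, "\r", todo[i])]] <- res[[i]] %||% NA
    }
  }
  lapply(keys, function(k) .chem_cache[[k]])
}

#' Canonicalize SMILES strings
#'
#' Parses each string with RDKit and returns its canonical SMILES form.
#' Unparseable strings yield `NA_character_` (invalid input is an ordinary
#' value here, not an error, so corpus ingestion can count and drop it).
#' The operation is idempotent: canonical output canonicalizes to itself.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where invalid.
#' @examples \dontrun{canonicalize(c("OCC", "CCO", "C1CC"))}
#' @export
canonicalize <- function(smiles) {
  out <- unlist(chem_backend("canon", smiles), use.names = FALSE)
  out[!nzchar(out) | is.na(out)] <- NA_character_
  out
}

#' Test whether SMILES strings parse
#'
#' @param smiles Character vector.
#' @return Logical vector: `TRUE` where RDKit parses the string.
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(canonicalize(smiles))
}

#' Extract Bemis-Murcko scaffolds
#'
#' Returns the molecular framework (ring systems plus the linkers between
#' them, all side chains removed) as canonical SMILES. Acyclic molecules
#' have no framework and map to the empty string; the generator conditions
#' on a "no scaffold" state in that case.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Character vector of scaffold SMILES ("" for acyclic molecules).
#' @export
extract_scaffold <- function(smiles) {
  out <- unlist(chem_backend("scaffold", smiles), use.names = FALSE)
  if (any(bad <- out == "!")) {
    stop("invalid SMILES passed to extract_scaffold: ",
         paste(utils::head(smiles[bad], 3), collapse = ", "), call. = FALSE)
  }
  out
}

#' Compute drug-likeness properties
#'
#' Molecular weight (Da), Crippen LogP, the quantitative estimate of
#' drug-likeness QED (in \[0, 1\]) and the synthetic accessibility score on
#' its native 1 (easy) to 10 (hard) scale, plus `SA_norm = (10 - SA) / 9`
#' rescaled so that higher means easier to synthesize.
#'
#' @param smiles Character vector of valid SMILES.
#' @return `data.frame` with columns smiles, MW, LogP, QED, SA, SA_norm.
#' @export
mol_properties <- function(smiles) {
  res <- chem_backend("props", smiles)
  bad <- vapply(res, function(x) !is.list(x), logical(1))
  if (any(bad)) {
    stop("invalid SMILES passed to mol_properties: ",
         paste(utils::head(smiles[bad], 3), collapse = ", "), call. = FALSE)
  }
  num <- function(f) vapply(res, function(x) as.numeric(x[[f]]), numeric(1))
  sa <- num("SA")
  data.frame(smiles = smiles, MW = num("MW"), LogP = num("LogP"),
             QED = num("QED"), SA = sa, SA_norm = (10 - sa) / 9,
             stringsAsFactors = FALSE)
}

#' Morgan fingerprint on-bits
#'
#' @param smiles Character vector of valid SMILES.
#' @param radius Morgan radius (default 2, i.e. ECFP4-like).
#' @param n_bits Folded fingerprint width (default 2048).
#' @return List of sorted 0-based on-bit integer vectors, one per molecule.
#' @export
morgan_bits <- function(smiles, radius = 2L, n_bits = 2048L) {
  res <- chem_backend("morgan", smiles,
                      args = c(as.integer(radius), as.integer(n_bits)))
  bad <- vapply(res, function(x) length(x) == 1L && all(is.na(x[[1]])),
                logical(1))
  if (any(bad)) {
    stop("invalid SMILES passed to morgan_bits: ",
         paste(utils::head(smiles[bad], 3), collapse = ", "), call. = FALSE)
  }
  lapply(res, function(x) as.integer(unlist(x)))
}
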