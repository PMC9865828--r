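# Synthetic SMILES fixture generator. Assembles lead-like molecules from a
# small template grammar (substituted aryl/heteroaryl rings joined by short
# linkers), emulating the molecular-weight window (250-350 Da) of the
# lead-like corpora the generator is normally pretrained on. Every emitted
# string is valid by construction; tests and examples therefore need no
# external download.

fixture_grammar <- function() {
  list(
    # prefix substituents (attach to the ring atom that follows them)
    prefix = c("", "C", "CC", "CO", "F", "Cl", "N#C", "CC(C)",
               "FC(F)(F)", "CS(=O)(=O)", "CCO"),
    prefix_w = c(1, 2, 2, 3, 1, 2, 1, 2, 3, 2, 2),
    # substituents placed inside a ring branch, e.g. c2ccc(<sub>)cc2
    sub = c("F", "Cl", "C", "OC", "N", "O", "C#N", "C(F)(F)F", "CC",
            "N(C)C", "OCC", "S(C)(=O)=O", "C(C)C", "C(N)=O"),
    sub_w = c(2, 3, 2, 3, 1, 1, 2, 3, 2, 2, 2, 2, 2, 2),
    # linkers between the two ring systems
    linker = c("C(=O)N", "NC(=O)", "CN", "C(=O)", "S(=O)(=O)N", "OC",
               "CC", "C(=O)OC", "NC(=O)C", "CNC(=O)", "CCN"),
    linker_w = c(3, 3, 2, 2, 2, 2, 2, 1, 1, 1, 1)
  )
}

pick <- function(values, weights) {
  values[sample.int(length(values), 1L, prob = weights)]
}

# one assembled molecule; ring-closure digits 1..3 are allotted per level
fixture_molecule <- function(g) {
  sub_b <- pick(g$sub, g$sub_w)
  ring_b <- switch(pick(c("benzene", "pyridine", "piperidine", "naphthalene",
                          "plain"), c(5, 3, 2, 1, 1)),
    benzene = paste0("c2ccc(", sub_b, ")cc2"),
    pyridine = paste0("c2ccc(", sub_b, ")nc2"),
    piperidine = "C2CCN(C(C)=O)CC2",
    naphthalene = "c2ccc3ccccc3c2",
    plain = "c2ccccc2")
  link <- pick(g$linker, g$linker_w)
  if (stats::runif(1) < 0.5) {
    # doubly substituted first ring, balanced by a light prefix so the
    # molecular weight stays inside the lead-like window
    paste0(pick(c("", "C", "F", "CO"), c(3, 2, 1, 1)),
           "c1cc(", pick(g$sub, g$sub_w), ")cc(", link, ring_b, ")c1")
  } else {
    # singly substituted first ring always carries a substantive prefix
    paste0(pick(c("CO", "CC", "FC(F)(F)", "CS(=O)(=O)", "CC(C)", "CCO",
                  "Cl", "N#C"), c(3, 2, 3, 2, 2, 2, 2, 1)),
           "c1ccc(", link, ring_b, ")cc1")
  }
}

#' Generate a synthetic lead-like SMILES corpus
#'
#' Deterministic per seed; all strings are valid SMILES by construction
#' and most fall in the 250-350 Da lead-like molecular-weight window.
#' Stands in for large public corpora in tests, examples and the
#' acceptance pipeline.
#'
#' @param n Number of molecules (duplicates possible but rare).
#' @param seed RNG seed.
#' @param properties Passed to [make_corpus()].
#' @return A `mol_corpus` (see [make_corpus()]).
#' @export
generate_fixture_corpus <- function(n, seed = 1L, properties = FALSE) {
  stopifnot(n >= 1L)
  g <- fixture_grammar()
  smiles <- with_seed(seed, vapply(seq_len(n), function(i) fixture_molecule(g),
                                   character(1)))
  make_corpus(smiles, properties = properties)
}

#' Generate a synthetic "known actives" set sharing one scaffold
#'
#' Emits diaryl-amide molecules that all share the Bemis-Murcko scaffold
#' `O=C(Nc1ccccc1)c1ccccc1`, with varying peripheral substituents -- a toy
#' stand-in for a per-target active-compound set used to exercise the
#' transfer-learning path (finetuning should pull generated molecules
#' toward this scaffold).
#'
#' @param n Number of molecules.
#' @param seed RNG seed.
#' @param properties Passed to [make_corpus()].
#' @return A `mol_corpus`.
#' @export
generate_fixture_actives <- function(n, seed = 1L, properties = FALSE) {
  stopifnot(n >= 1L)
  g <- fixture_grammar()
  smiles <- with_seed(seed, vapply(seq_len(n), function(i) {
    paste0(pick(g$prefix, g$prefix_w), "c1ccc(C(=O)Nc2ccc(",
           pick(g$sub, g$sub_w), ")cc2)cc1")
  }, character(1)))
  make_corpus(smiles, properties = properties)
}

#' A small synthetic kinase-like protein sequence for examples and tests
#'
#' A deterministic pseudo-random 120-residue sequence (fixed seed), long
#' enough for all three encoders under default settings. Synthetic: it is
#' not a real protein.
#'
#' @param length Number of residues.
#' @param seed RNG seed.
#' @return A `protein_sequence`.
#' @export
fixture_protein <- function(length = 120L, seed = 11L) {
  stopifnot(length >= 3L)
  res <- with_seed(seed, paste(sample(AA_LETTERS, length, replace = TRUE),
                               collapse = ""))
  sanitize_sequence(res, id = sprintf("synthetic_%d", seed))
}
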