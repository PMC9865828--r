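---
title: "Target-conditioned SMILES generation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-conditioned SMILES generation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Given a protein target known only by its amino-acid sequence and a small
set of known active compounds, propose new candidate ligands. The package
treats this as conditional language modelling over SMILES strings: a small
decoder-only transformer learns the distribution of drug-like molecules
from a large generic corpus, and transfer learning on the target's actives
shifts that distribution toward chemistry that binds the target. Two
conditioning signals steer generation: a fixed-length numeric encoding of
the protein sequence, and a Bemis–Murcko scaffold that the generated
molecule should elaborate.

# Protein encoding

Three classical sequence descriptors are fused into one vector.

**Pseudo amino acid composition** (`pseaac()`). The 20 residue frequencies
$f_u$ are augmented with $\varepsilon$ sequence-order correlation factors
$\theta_j$, giving

$$x_u = \frac{f_u}{\sum_i f_i + \alpha\sum_j \theta_j},\qquad
  x_{20+j} = \frac{\alpha\,\theta_j}{\sum_i f_i + \alpha\sum_j \theta_j},$$

so the vector is a probability distribution (non-negative, sums to one).
$\theta_j$ is the classic sequence-order correlation: the average, over
positions $i$, of the mean squared difference of standardized
hydrophobicity, hydrophilicity and side-chain mass between residues $i$
and $i+j$. Property scales are standardized over the 20 amino acids with
the population standard deviation. Defaults $\alpha = 0.05$ and
$\varepsilon = 30$ are the long-standing defaults for this descriptor
family; $\varepsilon$ must stay below the sequence length, which every
realistic target satisfies.

**Autocorrelation descriptors** (`autocorrelation()`). Normalized
Moreau–Broto autocorrelation of eight standard physicochemical scales
(Kyte–Doolittle hydropathy, Hopp–Woods hydrophilicity, side-chain mass,
isoelectric point, residue volume, Grantham polarity, average flexibility,
Zimmerman bulkiness), each z-scored over the 20 residues:
$AC(p, d) = \frac{1}{S-d}\sum_i P_i P_{i+d}$ for lags $d = 1..30$,
giving $8 \times 30 = 240$ values. The descriptor literature offers
several autocorrelation variants; normalized Moreau–Broto is the most
common, and both the property table and the maximum lag are configurable.

**Conjoint triad** (`conjoint_triad()`). Residues are mapped to the seven
standard dipole/side-chain-volume classes
$\{AGV\},\{ILFP\},\{YMTS\},\{HNQW\},\{RK\},\{DE\},\{C\}$; every
overlapping window of three consecutive residues is counted among the
$7^3 = 343$ triad types, and counts are scaled as
$d_i = (f_i - \min f)/\max f$. Note the denominator is $\max f$ alone,
so the minimum entry is exactly 0 and all entries lie in $[0, 1]$.

**Fusion** (`encode_protein()`). The concatenation (633 values under the
defaults: $20{+}30$ PseAAC, 240 AD, 343 CT) is mapped to exactly 512
dimensions. The target width is fixed by the generator contract; the map
itself was an open choice. We use a seeded Gaussian random projection —
deterministic, approximately norm-preserving, and reproducible from the
`projection_seed` in `encoding_config()` — and the generator additionally
learns its own linear $512 \to 256$ map, so a learned end-to-end
projection and a precomputed standalone one are both supported.

# The generator

`smiles_gpt()` builds a pre-norm decoder-only transformer in the mini-GPT
mould: token, position and segment embeddings of width 256, eight decoder
blocks of eight-head masked self-attention
($\mathrm{softmax}(QK^\top/\sqrt{d_k})V$) and a GELU feed-forward layer
with hidden width 1024, and an output head weight-tied to the token
embedding matrix. Layer and head counts are not dictated by the
architecture constants alone; eight/eight keeps the default model at
roughly $6\times10^6$ parameters with a typical SMILES vocabulary, the
size class this family of generators targets, and both are configurable.

One training sequence is laid out as

```
[condition] [scaffold tokens...] [SMILES tokens...] [<eos>]
```

The protein encoding enters through a learned $512 \to 256$ projection
occupying the first position — minimal-assumption conditioning in the
style of prefix tokens. Segment embeddings (scaffold vs. SMILES region)
let the model distinguish context from target. Cross-entropy is taken
only at positions predicting SMILES-region tokens: the model is trained
to predict molecules, never to re-predict its conditioning.

All forward and backward passes are plain R matrix algebra; every
analytic gradient is checked against central finite differences in the
test suite. Optimization is Adam at learning rate $6\times10^{-4}$ for 10
epochs by default, the published recipe for this model family; dropout
(default 0.1) applies to the embedding and both residual branches.

# Tokenization, corpora, sampling

The SMILES tokenizer is the standard regex scheme: bracket atoms and
`%nn` ring closures are single tokens, `Cl`/`Br` stay whole, everything
else is one character; concatenating tokens reproduces the string
exactly, and untokenizable characters are an error naming the offset.
Corpora are canonicalized on ingestion (unparseable entries are dropped
with a count); whether to train on raw or canonical strings was open, and
we canonicalize so that duplicates, novelty and uniqueness are
well-defined. Scaffolds are Bemis–Murcko frameworks; acyclic molecules
have the empty scaffold and are conditioned on an empty scaffold region.
Splits are a seeded shuffle and 9:1 partition, the ratio used for both
the generic corpus and the per-target actives.

Generation starts from a token drawn in proportion to its frequency at
the first position of the training SMILES (`pick_start_token()`), then
proceeds by temperature-scaled multinomial sampling until the end token
or a 100-token cap; temperature 0 is greedy. The default scaffold for a
target is the most frequent Bemis–Murcko scaffold among its actives,
overridable per request. Because every training sequence carries its
scaffold, sampling is intended to be scaffold-conditioned; sampling with
an empty scaffold when training never saw one is out-of-distribution and
yields visibly degraded validity.

# Standard cheminformatics steps

Parsing/canonicalization, scaffold extraction, MW/LogP/QED/SA and Morgan
fingerprints are delegated to RDKit through a batched subprocess helper
(`inst/python/chem_backend.py`), the same toolkit this line of work uses.
The SA score is reported on its native 1 (easy) to 10 (hard) scale, with
a normalized $(10-\mathrm{SA})/9$ column alongside, because the two
conventions coexist in the literature and the raw scale is the one the
underlying estimator defines. Morgan fingerprints default to radius 2 and
2048 bits, the de-facto standard.

# Evaluation battery

`eval_ratios()` computes validity (parseable fraction), uniqueness
(distinct canonical molecules over valid ones) and novelty (distinct
valid molecules absent from the reference set), all on canonical SMILES
of the valid subset, matching the conventions of the common generation
benchmarks. `wasserstein1()` is the exact empirical earth-mover distance
$\int |F_a - F_b|\,dx$ over the pooled support (no binning).
`tanimoto_nearest()` reports each generated molecule's maximum Tanimoto
similarity to the actives over Morgan bit sets. `summarize_generation()`
assembles ratios, per-property mean ± sd, W1 shifts and the similarity
distribution into one report.

# Docking adapter

Docking itself needs external software and receptor structures, so the
adapter stays at the file contract: `write_docking_job()` emits a
Vina-dialect grid config, a ligand list and a manifest of the conversion
and docking commands (three replicates by default), and
`parse_vina_scores()` reads result tables back; replicate scores
aggregate by their minimum (the best pose). Grid presets for the three
study targets are built in; two different published EGFR centers exist
and both are shipped (`"EGFR"`, `"EGFR_alt"`) rather than silently
reconciled.

# The synthetic fixture generator

`generate_fixture_corpus()` assembles molecules from a small template
grammar — substituted aryl/heteroaryl rings joined by short linkers —
chosen to emulate the lead-like corpora used for pretraining: every
string is valid by construction and the bulk of the distribution sits in
the 250–350 Da window. `generate_fixture_actives()` emits diaryl-amide
variants sharing one Bemis–Murcko scaffold, a toy stand-in for a
per-target active set. What the fixtures do *not* emulate: the chemical
diversity, stereochemistry, charged species and ring-system variety of
real corpora, or any actual binding relationship between the synthetic
"actives" and the synthetic protein sequence. Passing tests therefore
demonstrate that the machinery (encodings, training, transfer, metrics)
behaves as specified, not that the model generates potent ligands for
real targets — that claim would require the full-scale corpora and
docking validation, which the configuration supports but the test suite
deliberately does not depend on.

# Problem sizes and numerical choices

The shipped tests and the acceptance pipeline run desk-scale versions of
every stage, sized so the whole suite completes in minutes on one CPU:
2-layer/64-wide models, fixture corpora of a few hundred molecules,
actives sets of 50–60, and generation batches of a few hundred. These
sizes are the package's own validation choices; the full-size defaults
(8 × 256 architecture, 10-epoch Adam recipe) remain the configuration
users would scale up to. The desk-scale pipeline trains with dropout 0
and more epochs than the full-size recipe: with a few hundred training
molecules the goal is a tight fit to the fixture grammar, not
regularization, and sampling validity tracks how far the per-token loss
has been driven down. Transfer-learning finetuning keeps the recipe's
10 epochs; more finetuning raises scaffold fidelity and validity but
narrows uniqueness, the expected behaviour when a generic distribution
is pulled onto a one-scaffold active set. Other numerical details: layer norm uses
$\epsilon = 10^{-5}$; softmax subtracts the row maximum; log-likelihoods
clamp probabilities at $10^{-12}$; the overfit and determinism checks run
with dropout 0, since stochastic regularization would make them
meaningless; training shuffles and sampling draws all derive from
explicit seeds, so a (checkpoint, seed, request) triple fully determines
output.

# Known limitations

* The transformer is pure R: perfectly adequate for the tested sizes,
  but pretraining on millions of molecules would need a compiled or
  GPU-backed reimplementation of the same contracts.
* The protein encoding is sequence-only by design; no structural or
  evolutionary features.
* Sampling quality is scaffold-conditional (see above); unconditional
  sampling from a scaffold-trained checkpoint is unsupported usage.
* The docking adapter writes and parses files only; scores come from
  whatever Vina-family engine the user runs.
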