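---
title: "Elastic networks of learned maintained contacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic networks of learned maintained contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmcenm)
```

## The model

An anisotropic network model (ANM) replaces a protein by one point mass
per residue (its C&alpha; atom) and a harmonic spring between every pair
of residues in *contact*. Contact is binary: residues $i \ne j$ are
connected when their C&alpha; distance $d_{ij}$ is at most a cutoff
$r_c$ (we use an inclusive boundary, $d_{ij} \le r_c$, and a default
$r_c = 10$ Å). The network potential is

$$V = \sum_{\text{edges}} \tfrac{k_{ij}}{2}\,(d_{ij} - d^0_{ij})^2,$$

and normal mode analysis (NMA) of its $3N \times 3N$ Hessian yields
$3N - 6$ internal modes after the six zero-frequency rigid-body motions.
Low-frequency modes are the energetically cheapest collective
deformations and, for many proteins, align with the functional
transition between an unbound (start) and a ligand-bound (end)
conformation.

The catch is that the spring topology is frozen at the start
conformation. Collective domain motions barely disturb it, but localized
transitions change the contact topology substantially; contacts that
break during the motion act as extraneous constraints that stiffen the
network in exactly the directions the protein actually moves. This
package implements the remedy: identify the breaking contacts and remove
them.

Three surgically modified networks are supported:

* **mcENM** — remove the *observed* breaking contacts (requires both
  conformations; the theoretical upper bound),
* **lmcENM** — remove the breaking contacts *predicted* by a classifier
  from the start conformation alone (the method of interest),
* **mfcENM** — additionally add the observed forming contacts (included
  because it is instructive that it does not help).

## Contact transitions and the strain threshold

Given a residue correspondence between two conformations (global
sequence alignment: match +1, mismatch −1, linear gap −2) and a
least-squares superposition, every start contact is labeled by its
strain
$e_{ij} = |d^S_{ij} - d^E_{ij}| / d^S_{ij}$:
*maintained* when $e_{ij} \le e_c$, *breaking* otherwise; pairs in
contact only at the end are *forming*. Stretch and compression count
equally (the absolute value), and a stretched contact whose end distance
exceeds $r_c$ but whose strain is small remains maintained — the strain
rule is authoritative. The default threshold $e_c = 0.09$ (9 % of the
initial distance) is the data-set optimum of the method this package
implements; it is exposed as a parameter.

Network surgery is restricted to contacts at least four sequence
positions apart and never drops a node below degree four — removing
shorter-range contacts destabilizes the network (more than six zero
modes) without measurably improving accuracy.

## Spring schemes

Four stiffness parameterizations are available through
`spring_scheme()`:

* `uniform_cutoff` — $k = \gamma$ within $r_c$ (the classical ANM; the
  baseline everywhere in this package is the 10 Å cutoff network
  stabilized to minimum degree 4),
* `hca` — cutoff-free, $k = a d - b$ below 4 Å and $c\,d^{-6}$ beyond,
  with $a = 205.5$, $b = 571.2$, $c = 3.059 \times 10^5$ in
  kcal mol⁻¹ Å units (the linear branch is clamped at zero below
  $b/a \approx 2.78$ Å, a distance real C&alpha; pairs do not reach),
* `edenm` — bonded ladder $k = 60 / s^2$ for sequence separation
  $s \le 3$, $(6/d)^6$ within the size-dependent cutoff
  $r_c(N) = 2.9 \ln N - 2.9$, zero beyond,
* `ofc` — cutoff network with a secondary-structure stiffness multiplier
  table. The published parameterization lives in an external package's
  defaults; we ship a documented stand-in (3× for helix–helix pairs
  within four sequence positions, 2× for strand–strand, 1× otherwise)
  and accept a user table.

Stabilization connects under-constrained nodes to their nearest
not-yet-connected sequence neighbors (ties toward the lower index) until
every node has degree ≥ 4; stabilizer edges carry $k = \gamma$ and are
exempt from surgery. Masses are uniform, so eigenvalues are on a
$\gamma$/mass scale and mode variances are taken as $1/\lambda$; all
reported quantities are fractions, overlaps or correlations in which the
absolute scale cancels.

## Predicting breaking contacts

Every long-range contact is described by a 170-entry feature vector in
seven blocks (pairwise 63, graph topology 10, graph spectrum 5, single
node 12, node label statistics 57, edge label statistics 13, whole
protein 10). The graph blocks summarize the contact's *immediate
neighborhood graph* — the contact residues, their sequence neighbors,
everything in contact with either, plus the $i \pm 4$ helix-turn
neighbors for helical residues — via centralities, eccentricities,
clustering and the adjacency spectrum. A secondary-structure-element
graph (segments of minimum length three; edges between segments sharing
a contact) supplies the segment-level context.

Features whose source requires external annotation (conservation and
mutual information from alignments, pocket descriptors, residue depth,
symmetry, side-chain contacts) are carried behind an availability mask:
absent annotations contribute the neutral standardized value 0 rather
than an imputation. Hydrogen bonds, solvent accessibility and half-sphere
exposure have internal C&alpha;-level geometric surrogates, computed from
distance patterns and neighbor counts, so they are always available.

The classifier is a support vector machine with an RBF kernel
($c = 100$, $\gamma = 10^{-5}$, the published optimum; a
leave-one-protein-out tuner over a small grid is included). Breaking
contacts are rare (a few percent of contacts), so training undersamples
maintained contacts at 3:1 per protein and weights classes inversely to
their frequency; probabilities come from Platt scaling as implemented by
libsvm's internal cross-validation. Standardization statistics are fit
on the training corpus only and serialized with the model. Contacts are
ranked by decreasing probability, and the removal subset is chosen by
one of three strategies: constant count (top $n$, default 60), relative
(top fraction of scored contacts, default 16 %, the package default),
or score threshold (strictly above 0.4). Counts truncate strictly —
score ties at a boundary are not pulled in — so removal counts are
reproducible. The "relative" percentage is interpreted as a fraction of
the scored contacts (the alternative reading, a fraction of an inferred
breaking-contact count, is not computable from a single conformation).

## Evaluation measures

For a pair with displacement field $\Delta r_i = r_i^S - r_i^E$ (after
superposition; overlap is frame-dependent, so the convention is fixed
here):

* per-mode overlap $O_j$ (absolute cosine), cumulative overlap
  $CO(k) = (\sum_{j \le k} O_j^2)^{1/2}$ — $CO(10)$ is the headline
  accuracy measure,
* variance fractions $\propto 1/\lambda_j$ and their cumulative sum
  $CFV(k)$,
* degree of collectivity
  $\kappa = \exp(-\sum_i u_i^2 \log u_i^2)/N \in [1/N, 1]$,
* the best single mode (maximum overlap, 0-based rank, collectivity,
  variance fraction) and the number of modes to reach 70/80/90 % of the
  transition (infinite when never reached),
* Pearson correlations between predicted mean-square fluctuations and
  squared displacements or B-factors (after least-squares scaling),
* subspace similarity RMSIP($k{=}10$) and eigenvalue-weighted RWSIP
  against, e.g., the principal components of a conformational ensemble
  (`ensemble_pca()`; population covariance, so total variance equals the
  mean squared deviation). RWSIP weights follow the convention that both
  mode sets are ordered by decreasing variance; ENM weights are
  $1/\lambda$.

Degenerate eigenvalues make individual modes convention-dependent;
per-mode quantities are therefore only asserted on non-degenerate
fixtures, while subspace measures (CO over a block, RMSIP, RWSIP) are
invariant and used everywhere else.

## Synthetic benchmark

Because the method's original benchmark corpus requires bulk structure
retrieval, the package ships generators that produce test conditions
with *known* ground truth:

* `make_globule(n, seed)` — a self-avoiding compact C&alpha; chain
  (bonds 3.8 ± 0.1 Å, non-bonded separation ≥ 4 Å, radius of gyration
  near $3 n^{1/3}$ Å),
* `make_hinge_pair()` — two packed domains joined by a 5-residue linker;
  the end conformation rotates one domain rigidly about the
  inter-domain axis (default 45°, total length 75 residues so pairs
  clear the 70-residue curation filter). Intra-domain distances are
  preserved exactly, so breaking contacts concentrate at the interface —
  a caricature of a collective domain motion,
* `make_loop_pair()` — a globule whose most surface-exposed span
  (default 8 residues) is displaced radially outward (default 6 Å) with
  a smooth sinusoidal taper — a caricature of a localized transition,
* `random_removal_control()` — removes the same *number* of randomly
  chosen long-range contacts, separating "removing the right contacts"
  from "removing any contacts".

All randomness flows from one integer seed through `with_seed()`, so
every fixture replays exactly. The default sizes (75/72 residues, 20
pairs in `make_corpus()`) keep a full recovery experiment — feature
extraction, 20 train/test splits, NMA of every variant — comfortably
inside a normal test run while leaving dozens of breaking contacts per
pair.

These toys test machinery, not biology: they have no side chains, no
real secondary-structure packing, poly-random sequences, and their
"domains" are spherical blobs. Passing the recovery experiments shows
that the pipeline identifies and exploits contact-topology change when
it is present; it does not certify accuracy on real proteins, for which
the curation filters (RMSD > 1 Å, ≥ 70 aligned residues, resolution
≤ 2.5 Å, no chain breaks at 4.2 Å, advisory bound-peptide and
extended-structure flags) and the full pipeline apply unchanged.

What the tests demonstrate on this corpus, each re-derived at run time:
removing observed breaking contacts never hurts and helps most for
localized motions; matched random removal is a null operation; and a
classifier trained on 15 synthetic proteins selects removal sets on the
held-out 5 whose precision beats the breaking-contact prevalence in
nearly every split.

## Numerical choices

* Eigen-decomposition uses the symmetric solver of base R; eigenvalues
  below $10^{-8} \times \lambda_{\max}$ count as zero. A stabilized
  network is accepted only with exactly six zero modes (five for
  intentionally degenerate collinear toys).
* Mode ranks are reported 0-based (rank 0 = first internal mode).
* Alternate PDB locations resolve to the highest occupancy, ties by
  altloc letter; residues without a C&alpha; atom are dropped with a
  message.
* The alignment-length filter counts matched (non-gap) positions, not
  identities.
* The geometric secondary-structure fallback labels a window helical
  when $d_{i,i+3} \in [4.4, 6.2]$ Å and $d_{i,i+4} \in [4.8, 6.8]$ Å,
  extended when $d_{i,i+3} \ge 9$ Å, and relabels runs shorter than 3 to
  coil. An external per-residue assignment (e.g. DSSP output collapsed
  to three states) takes precedence when supplied.
* Removal lists are processed in ranking order; a removal that would
  violate the degree-4 floor is skipped with a warning rather than
  aborting, because a stable network with one extra contact is more
  useful than no network.

## Worked example

```{r example, eval = FALSE}
library(lmcenm)

# a localized synthetic transition with known ground truth
lp <- make_loop_pair(seed = 1)
curate_pair(lp$pair)

# how much of the motion do ten modes explain, per network variant?
analyze_pair(lp$pair, variants = c("enm", "hca", "edenm", "mcenm"))

# train a breaking-contact classifier on a synthetic corpus and build
# the network of learned maintained contacts for a new protein
corpus <- make_corpus(n_pairs = 10, seed = 7)
model <- train_breaking_classifier(
  build_training_set(corpus, ratio = 3, seed = 7))
new_protein <- make_loop_pair(seed = 99)
got <- predict_and_build(new_protein$pair$start, model)
normal_modes(got$network)$n_zero   # stays 6: surgery preserved stability
```

## Limitations

* Single chains at C&alpha; resolution only; no mmCIF, no complexes.
* The shipped ofc stiffness table is a stand-in, not the published
  NMR-derived constants.
* Several feature blocks are inert without external annotation tables;
  the mask makes this explicit rather than silently imputing.
* The harmonic approximation degrades far from the start conformation;
  overlap measures compare directions, not magnitudes.
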