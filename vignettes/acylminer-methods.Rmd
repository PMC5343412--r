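---
title: "Models and methods behind acylminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind acylminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acylminer)
```

# The problem

Acyltransferase superfamilies — DGAT1 within the MBOAT/SOAT clan, the
DGAT2/DAGAT family, soluble DGAT3, and PDAT inside the LCAT superfamily —
are annotated across divergent proteomes by iterative profile-HMM
searching: a seed alignment of trusted members is turned into a
position-specific probabilistic model, the model is searched against the
proteomes, confident hits are folded back into the alignment, and the
cycle repeats until no new members appear.  Two bookkeeping problems
dominate in practice: predicted proteomes carry *redundant* gene models
(byte-identical re-predictions of one locus) and *truncated* gene models
(fragments that break multiple alignments but still belong to the
family).  `acylminer` implements the complete workflow with an emphasis on
determinism — every stochastic stage takes an explicit seed — and on
testability: a protein-superfamily simulator with known labels stands in
for real proteome collections, so sensitivity, precision and clade
assignment can be scored exactly.

# Profile HMMs

`build_profile()` estimates a Plan-7-like architecture: alignment columns
with gap fraction below `match_threshold` (default 0.5, the usual
rule of thumb) become match states in order; each node has the seven
Plan-7 transitions M→M/I/D, I→M/I, D→M/D.  Match emissions are observed
counts plus a background-proportional pseudocount
(`pseudocount_weight`, default 1.0; the background is the WAG stationary
distribution so that the scorer and the simulator share one model).
This additive pseudocount scheme is deliberately simpler than the
Dirichlet-mixture priors of production HMM suites; at the alignment
depths this package targets (tens of sequences) the difference is minor
and the simpler estimator is fully specified and exactly testable.
Transition probabilities are counted from each row's implied
match/insert/delete path plus a pseudocount of 1 on every structurally
allowed transition; the two transitions Plan-7 cannot represent (I→D,
D→I) are counted on the nearest allowed transition (M→D, M→I).

## Uni-local scoring

`forward_bits()` returns `log2 P(seq | model) / P(seq | background)`
summed over alignments that are **local in the sequence** (residues
outside the matched region are emitted by the background and score zero)
and **local in the model**: the begin state enters any of the `K` match
states with probability `t(B→M)/K`, and every pre-terminal match state
exits with probability `1/K` (its remaining transitions scaled by
`1 − 1/K`).  One hit per sequence; there is no multi-hit (J-state)
machinery.  Model-locality matters for exactly the sequences this
pipeline cares about: a gene model missing 60% of a 300-residue protein
pays ~`log2 K` ≈ 8 bits to enter mid-model, instead of a delete-chain
penalty proportional to the missing length, which would push genuine
fragments below any sensible inclusion threshold.  For `K = 1` the
scheme reduces to the glocal model, which keeps the one analytically
forced case (a single match state emitting one residue against a uniform
null scores exactly `log2 20` bits) exact.

The forward and Viterbi recursions run in C++; the forward pass works in
scaled linear space (per-row rescaling with an accumulated log scale),
which is finite for sequences beyond 10,000 residues and roughly two
orders of magnitude faster than cell-wise log-sum-exp.  `X` residues are
emitted with probability 1 under both the model and the null, so they are
score-neutral — needed because real gene models contain runs of
unidentified amino acids.  Correctness is pinned by an exhaustive
path-enumeration oracle on all models with up to 4 match states and
sequences up to 6 residues (the test grid has over 200 cases, agreement
to 1e-9 bits), plus the `forward ≥ Viterbi` inequality on random pairs.

## E-value calibration

`calibrate_evalue()` scores the model against 200 i.i.d. background
sequences of the database's mean length and fits a Gumbel distribution to
the bit scores by maximum likelihood.  The bulk of uni-local forward
scores is narrower than a Gumbel while the right tail — the only part an
E-value reads — is heavier, so the fit censors the lowest 75% of the
sample (a left-censored ML fit, `gumbel_ml(x, censor = 0.75)`).  E-values
are `db_size * (1 - exp(-exp(-lambda (s - mu))))`, computed via
`-expm1(-x)` so they remain strictly positive and strictly decreasing in
the score.  Calibration is reseeded deterministically every mining
iteration because the model changes.

# The mining loop

`mine_to_convergence()` iterates: build profile → calibrate → search →
retrieve hits at the inclusion threshold (default E = 0.01; a stricter
1e-8 field is provided for searches against prokaryotic reference sets,
where only highly confident homologs should enter a eukaryote-seeded
analysis) → collapse 100%-identical sequences to their first occurrence
(substrings are *not* duplicates) → quarantine sequences failing the
hallmark screen → realign the accepted set to the profile → repeat.
Convergence is declared when the accepted id set equals the previous
iteration's — the strictest testable reading of "no new information";
`max_iterations` (default 20) bounds the loop, returning
`converged = FALSE` with a warning rather than an error.

Scrutiny replaces the manual alignment curation a human would do:
a `motif_screen` lists required hallmark motifs, and any retrieved
sequence missing one is quarantined — *not* deleted — so it can later be
placed by score.  Scrutiny also serves a second, less obvious purpose:
iterative profiling is vulnerable to drift, where one borderline
background hit slips over the threshold, is absorbed into the alignment,
and then scores arbitrarily well against the model built from it.  A
required hallmark makes that absorption step essentially impossible for
background sequences.  `consensus_screen()` +
`find_anchor_windows()` derive such screens from conserved gap-free
windows of a trusted alignment, which is also how the test fixtures
build screens whose amino- and carboxy-terminal anchors truncated gene
models necessarily lack.

`group_specific_mining()` re-runs the loop per taxon group, seeding from
the globally accepted members of that group, and reports the union — by
construction it never removes a globally accepted id.

# Alignment trimming

`trim_alignment()` performs entropy/gap/block trimming in five steps:
(1) drop columns whose smoothed entropy exceeds `entropy_cutoff`
(default 0.7); (2) drop columns with gap fraction above
`column_gap_cutoff` (0.2); (3) drop kept runs shorter than `min_block`
(3); (4) remove sequences whose gap proportion over the kept columns
exceeds `sequence_gap_cutoff` (0.4); (5) if step 4 removed anything,
re-run steps 1–4 once on the reduced row set (a single re-pass, not a
fixpoint loop, for bounded and deterministic runtime).  Entropy is
applied before the gap rules; the order is fixed and documented here.

The entropy estimator is spectral: the min-shifted similarity matrix
(BLOSUM30 by default, bundled as plain text) is normalized to similarity
coefficients `M[a,b] = s[a,b]/sqrt(s[a,a] s[b,b])`, and a column with
residue frequencies `p` is scored by the von Neumann entropy of
`rho = sqrt(p) M sqrt(p)` (trace 1), scaled by `log 20`.  A perfectly
conserved column scores 0 under any matrix; a uniform column under the
identity matrix scores 1; mixtures of biochemically similar residues
score lower than mixtures of dissimilar ones.  We note for the record
that the more obvious construction — smearing `p` through the
row-normalized shifted matrix and taking the Shannon entropy — fails
outright with a low-identity matrix like BLOSUM30: every column,
conserved or random, lands in a narrow band around 0.9–1.0 and the 0.7
cutoff removes everything.  The spectral form is the construction the
established block-trimming estimators use, and it makes the cutoff
meaningful.  The trimmer is validated against an independently coded
brute-force transcription of the five steps on 100 random alignments.

# Clade classification

`classify()` scores a sequence against every model of a clade panel and
assigns the argmax, with ties broken lexicographically and flagged
ambiguous; assignments with a winning margin below `margin_threshold`
(default 2 bits — the literature reports "very similar scores" for
genuinely ambiguous clades without quantifying them, so the threshold is
exposed and the raw scores are always reported) are flagged ambiguous
with both clade names.  A sequence that is not significant against *any*
panel model (per-model Gumbel P-value above 0.01) is flagged
`low_score`: probably not a superfamily member at all.  The sign of the
bit score cannot serve that purpose under local scoring, where the null
distribution sits a few bits above zero.  `classify_quarantined()`
applies this to a mining state's quarantined (typically truncated)
sequences — the score-based placement used for fragments excluded from
tree building.

# Sequence features

* `scan_motifs()` matches ordered position groups with optional
  spacer ranges (enumerated exhaustively) and *tolerated* substitutions,
  which are accepted but annotated.  The bundled YAML library encodes the
  DGAT2 conserved V-P-F-G block (tolerating the F→Y replacement present
  in biochemically active homologs, plus the P→C and F→I/M variants seen
  in individual gene models), the putative DGAT3 acyltransferase motif
  H-X(3–5)-[D/E] (a catalytic histidine with an acidic partner a few
  residues downstream, most often four), and LCAT/PDAT hallmarks
  (the Asp-X-Arg salt bridge; the G-X-S-X-G nucleophile elbow as an
  optional motif).  Coordinates are 1-based inclusive throughout.
* `kd_profile()` computes windowed Kyte–Doolittle hydropathy
  (window 9, the convention for hydrophobic-region identification; one
  score per full window; `X` contributes 0).
* `hydrophobic_segments()` defines a hydrophobic region as the residue
  span covered by a maximal run of windows with score strictly above 0
  (the conventional midline; the cutoff is exposed), merging overlapping
  spans, and reports the hydrophobic fraction as the percentage of
  residues covered by any region, rounded to the nearest integer.  This
  *coverage* convention is the package's documented choice; window-count
  conventions give systematically different numbers.
* `colocate()` classifies each motif as `embedded` in a hydrophobic
  region, `flanking_hydrophobic` (within 5 residues by default), or
  `flanked_by_hydrophilic` — the feature that distinguishes
  membrane-type acyltransferase architectures from the soluble DGAT3
  arrangement.
* `logo_bits()` computes per-column information content
  `R = log2 20 − H − e(n)` with the small-sample correction
  `e(n) = 19/(2 ln 2 n)` off by default (so the closed-form checks are
  exact) and available to mimic standard web-logo output.
* Externally produced labels (e.g. subcellular-targeting predictions
  from dedicated tools, which this package does not reimplement) attach
  to any report via `attach_annotations()`.

# Desk-scale phylogeny

Full maximum-likelihood and Bayesian tree inference is out of scope: the
package substitutes corrected-distance neighbor joining with
nonparametric bootstrap, which is exact on additive matrices and
therefore testable without reference datasets.  `protein_distance()`
uses the Kimura correction `d = −ln(1 − p − p²/5)` on the mismatch
fraction over shared non-gap columns (at least 30 required per pair;
saturation raises an error naming the pair).  `nj_tree()` wraps the
standard Q-criterion/Saitou–Nei algorithm, clamping negative branch
lengths to zero with the deficit logged.  `bootstrap_support()`
resamples columns with replacement, rebuilds the tree per replicate, and
reports bipartition frequencies; replicates whose distances saturate are
dropped with a warning and the support denominator adjusted.  Trees are
midpoint-rooted for display.  Deep mined families can saturate the
correction entirely; the pipeline then skips the tree with a warning
rather than aborting, since the census does not depend on it.

# The simulator and what passing tests mean

`simulate_family()` draws a root sequence from the WAG stationary
frequencies and evolves it down a clade tree (balanced clades on a star
of stems; arbitrary topologies via `evolve_along_tree()`) under the WAG
substitution model — the same model family the field's Bayesian analyses
assume — with indels placed uniformly (events per site per unit branch
length; geometric lengths of mean 3; inserted residues from the
background).  Site lineages are tracked, so the *true* leaf alignment is
returned alongside the sequences.  A chosen fraction of members is
emitted with 20–60% of one terminus removed (truncated gene models,
their alignment rows gapped accordingly) and another fraction re-emitted
byte-identically under new ids (redundant gene models).
`simulate_proteome()` shuffles the family among decoys drawn i.i.d. from
the background.

Default study conditions used throughout the tests and the acceptance
script: one family of 10 members (2 truncated, 2 duplicates), root
length 300 residues, 0.3 substitutions/site on within-clade branches,
indel rate 0.01, among 200 decoys of 200–400 residues; a remote-clade
chain (clade radii 0.15, stems 0.8) built so that the third clade lies
beyond the seed profile's reach but within reach of the once-enriched
profile — the operational definition of why iteration is needed; and a
4-clade star (radius 0.3, stems 0.8) with 10 training and 100 held-out
members per clade for classification.  These sizes keep the full test
suite under two minutes while leaving wide score margins.

The simulator does *not* model rate heterogeneity across sites, domain
architecture (e.g. fused 2Fe-2S domains), codon-level effects, or the
composition biases of real proteomes.  Passing recovery tests therefore
demonstrates the correctness of the machinery under its stated model,
not field performance on real proteome collections; the E-value
calibration in particular will be optimistic on compositionally biased
real sequences.

# Determinism and configuration

Every stochastic stage takes a seed; nested stages derive sub-seeds
deterministically from the configuration seed and a stage label, so a
pipeline run is reproducible byte for byte (the census determinism check
asserts exactly this).  RNG state is always restored on exit, so library
calls never disturb a user's session.  Pipeline configurations are YAML
(or equivalent in-memory lists); each written artifact carries the
package version and a hash of the scientific configuration (the output
directory is excluded from the hash).  Exported per-stage functions
remain the primary interface — the pipeline is a convenience, not a
gate.

# Known limitations

* No Dirichlet-mixture emission priors, no multi-hit scoring, no
  heuristic acceleration filters; models beyond a few thousand match
  states will be slow.
* The Gumbel null is fitted empirically per model; its tail behavior on
  real, compositionally biased proteomes is untested here.
* The BMGE-style trimmer is parameter-compatible with the standard tool
  (`-m BLOSUM30 -h 0.7 -g 0.4:0.2 -b 3` maps onto
  `trim_config(similarity_matrix = "BLOSUM30", entropy_cutoff = 0.7,
  sequence_gap_cutoff = 0.4, column_gap_cutoff = 0.2, min_block = 3)`)
  but is not bit-compatible with it.
* Neighbor joining is a deliberate desk-scale stand-in for ML/Bayesian
  inference; it shares none of their ability to model rate variation.
* The reference-protein hydropathy comparison (DGAT3 Cre06.g310200,
  DGTT4 Cre03.g205050) requires the user to supply the protein FASTA
  files, which are not redistributed with the package.
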