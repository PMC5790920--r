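---
title: "Screening metagenomes for 9,10-seco steroid catabolism: models and methods"
author: "secoscreen"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Screening metagenomes for 9,10-seco steroid catabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Aerobic bacterial steroid degradation proceeds through the 9,10-seco
pathway: side-chain β-oxidation, oxygen-dependent opening of the steroid
nucleus by 3-ketosteroid 9α-hydroxylase (KshA) and the meta-cleavage
dioxygenase HsaC, and hydrolytic breakdown of the opened rings. The
pathway's protein families are conserved across the two phyla known to
host it (*Actinobacteria* and *Proteobacteria*), which makes their joint
presence in an assembled metagenome a workable genomic proxy for steroid
degradation potential in a community. `secoscreen` implements the whole
inference chain from contigs to classified metagenome-assembled genomes
(MAGs), plus a seeded synthetic-community generator that provides ground
truth for every estimator.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the validation on synthetic
communities does and does not establish.

# Family registry

The screen is keyed on a registry of 10 pathway protein families.
`KshA` and `HsaC` are mandatory: they are the diagnostic ring-opening
enzymes on which the degrader classification rules pivot. The remaining
default members (`KshB`, `KstD`, `HsaA`, `HsaB`, `HsaD`, `HsaE`, `HsaF`,
`HsaG`) are the canonical A/B-ring and
2-hydroxyhexa-2,4-dienoate-branch enzymes of the pathway. The registry
is a configuration surface (`steroid_families()` is only a default), not
a claim that these ten names are the uniquely correct set; any family
list containing KshA and HsaC can be screened.

# Assembly QC

`compute_assembly_stats()` uses the standard N50 definition (largest L
such that contigs of length ≥ L cover half the assembly) with ambiguous
bases counting toward length — the statistics describe assembly extent,
not information content. The selection gate `select_metagenome()` is
deliberately strict on both sides: N50 strictly greater than 300 bp and
at least one contig strictly longer than 600 bp. "At least one contig"
is a reading choice (the alternative, *all* contigs longer than 600 bp,
would discard almost any real assembly); both thresholds are arguments.

# The profile-HMM engine

## Model construction

`build_profile_hmm()` turns a seed alignment into a match/insert/delete
profile: match states are the columns with at most 50% gap characters;
match emissions are Laplace-smoothed residue counts (pseudocount 1 by
default); transition probabilities are Laplace-smoothed counts of the
seed sequences' state paths. Insert states emit the background
distribution. Construction is deterministic.

## Scoring model

Scores are log2-odds against a uniform 20-letter null, in local mode:

- entry into any match state `j` costs `log2(1/M)`;
- exit from any match state is free;
- insert emissions cancel against the null (log-odds 0);
- `D↔I` transitions are not modelled (the standard simplification);
- residues outside the 20-letter alphabet (B, Z, X, ...) emit background
  in both numerator and null, contributing 0.

`viterbi_bits()` maximizes over local paths and `forward_bits()` sums
over them, so forward ≥ Viterbi always. Both are exact dynamic programs
(compiled via Rcpp); the test suite checks them against an independent
exhaustive path enumeration for small models (M ≤ 4) and peptides
(length ≤ 6).

## Calibration, thresholds and E-values

Published screens of this kind rarely state their reporting cutoffs, so
calibration is internal and reproducible: `calibrate_hmm()` scores
`n_decoys` (default 1000) seeded random proteins, fits a Gumbel by the
method of moments, and sets the reporting threshold at the Gumbel
quantile for a decoy false-positive rate `fpr`. E-values are the fitted
upper-tail probability times the number of proteins scanned.

The default `fpr` is `1e-6`, deliberately far stricter than a
per-comparison convention such as `1e-3`. The reason is multiplicity: a
sample scan performs (number of models) × (number of proteins)
comparisons, and at `1e-3` several random ORFs per sample cross the
threshold. False *marker* assignments are particularly damaging because
they enter single-copy contamination estimates directly. Genuine family
members score hundreds of bits — orders of magnitude above either
threshold — so the strict default costs no sensitivity in any regime the
generator can produce. `fpr`, `n_decoys` and an explicit
`bit_threshold` override are all exposed.

## ORF calling

`call_orfs()` is deliberately simple: all six frames, maximal
stop-to-stop stretches, reported from the first ATG, minimum protein
length 60 residues. Codons containing N translate to the X wildcard.
Externally predicted proteins can be supplied to `scan_sample()`
directly, bypassing the caller.

# Quantification

Genome equivalents are estimated from the assembly itself:
`estimate_genome_equivalents()` takes the median copy number over the
*detected* universal single-copy marker families (40 bundled). The
median is robust to individual markers split across contig breaks; the
restriction to detected families keeps the estimator strictly positive
(a median over the full registry including zeros would return 0 — an
invalid genome count — whenever fewer than half the markers are seen).
When no marker is detected the estimate is explicitly undefined, and
such samples are excluded from normalized comparisons rather than
silently zeroed. `normalize_hits()` is exact division, no rounding.

Sample selection for downstream binning requires HMM hits for the
complete family registry (`gate_all_families()`), and the per-taxon
display filter keeps taxa with strictly more than 10% of a sample's hits
and strictly more than 5 families.

# LCA taxonomy

Each hit is aligned locally against a labelled protein reference;
references scoring within a relative window (default 10%) of the best
score vote, and the hit is assigned their lowest common ancestor in the
bundled rank tree. The window, the assignment floor and the reference
set are all parameters — published LCA analyses rarely state them, so
they are exposed rather than asserted. Unassigned hits stay in
denominators (percentages are conservative).

The report-rank rollup follows the field's reporting convention for this
pathway: *Actinobacteria* at the phylum, *Proteobacteria* at the class
when the lineage resolves that far (Alpha-, Beta-, Gammaproteobacteria)
and at the phylum otherwise, domain-only lineages as
unclassified-Bacteria. The bundled taxonomy is a small curated tree
covering every label used by the MAG catalogue and the synthetic
lineages; users may load a different tree in the same four-column TSV
shape.

# Binning and MAG quality

`tnf()` computes 4-mer frequencies over the 136 canonical classes
(reverse-complement pairs collapsed), skipping windows containing N, so
a contig and its reverse complement have identical signatures.
`cluster_contigs()` runs k-means on log-transformed vectors. The number
of clusters is selected by maximizing the Calinski–Harabasz index over a
candidate range (2–8 by default). Mean silhouette width — the more
common textbook choice — was evaluated first and rejected: on
three-genome communities with GC 0.35/0.50/0.65 it prefers merging the
two nearest genomes (k = 2) while Calinski–Harabasz selects the true
k = 3; silhouette is retained as a weak-structure guard (if the best
clustering's silhouette is below 0.25, everything goes into a single
bin). Contigs shorter than 1000 bp stay unbinned, standard practice for
composition-based binning.

Bin quality uses the same marker registry as quantification:
completeness = percentage of marker families present; contamination =
percentage of extra copies. The MAG gate keeps completeness strictly
above 25% and contamination strictly below 10%. These marker estimates
are intentionally simple and universal — lineage-specific marker sets
would give different (usually higher-resolution) values, so bundled
catalogue completeness numbers are treated as recorded data, not as
recomputation targets.

# Orthology and degrader classification

`smith_waterman()` is exact local DP under BLOSUM62 with affine gaps
(open 11, extend 1; a length-L gap costs open + L·extend). Reciprocal
best hits between a MAG and a reference proteome require mutual best
scores plus identity ≥ 30% and query coverage ≥ 70% — stated defaults,
both flags, since no standard values exist for this step. Ties break by
identity, then lexicographic id, making calls deterministic.

The reference degrader panel (the five characterized strains spanning
actinobacterial and proteobacterial pathways) ships as
`synthetic_reference_panel()`: deterministically generated stand-in
proteomes with per-family annotations, because the real proteomes cannot
be bundled. Any panel of the same shape can be swapped in.

Two classification rules, both pluggable:

- **predicted degrader**: HMM hits for ≥ 5 of the 10 families, including
  at least one KshA or HsaC hit;
- **confirmed degrader** (default rule): ortholog calls for ≥ 6 families
  including KshA or HsaC. The exact criterion behind published per-MAG
  confirmation flags is under-determined (some catalogued MAGs with
  pathway completeness 9 carry a negative flag), so the rule object is
  replaceable and the bundled catalogue's recorded flags are treated as
  the ground truth for counting.

# Phylogeny and novelty

`progressive_msa()` is a deterministic center-star alignment (center =
maximal summed pairwise score, ties lexicographic; "once a gap, always a
gap" merging). Distances are p-distances over mutually ungapped columns.
Trees come from neighbor joining — chosen over likelihood methods
because it is deterministic, fast, and exactly checkable: on additive
matrices NJ provably recovers the generating topology, which the tests
exploit with random trees of up to 8 leaves. Negative branch lengths
(an NJ artifact on non-additive input) are clamped to zero with the
deficit reported. Bootstrap supports resample alignment columns with a
fixed seed; the display convention shows supports above 70%. An
externally inferred tree can be annotated instead, via the same
bipartition-counting machinery.

`novelty_score()` reports the best global-alignment identity of a query
against a reference set with three report bands: low below 60.4%, high
above 80%, intermediate between. The band edges are report annotations
reflecting an observed empirical split between divergent (e.g.
sponge-derived) and well-represented homologs — not a fitted classifier,
and documented as such.

# The synthetic-community generator

`generate_reference_panel()` + `fragment_community()` emulate the
statistical structure the pipeline assumes:

- degrader genomes carry exactly one planted gene per registry family;
  background genomes carry none; every genome carries each of the 40
  markers exactly once, making marker-based estimators exact on truth;
- genes are embedded in frame (ATG…TAA) with codon usage biased toward a
  per-genome GC drawn from \[0.35, 0.65\] (or set explicitly), giving
  tetranucleotide binning its compositional signal;
- planted family proteins diverge from fixed family ancestors by a
  per-site substitution rate (`mutate_protein()`: expected changed
  fraction = divergence, no indels); markers diverge at a fixed 5% so
  they stay detectable while differing between genomes;
- fragmentation emits, per genome, a contiguous tiling with log-normal
  piece lengths (the log-normal is a modelling choice; real contig-length
  distributions are characterized here only through the N50 gate).
  Abundance acts as fragment retention probability, so expected contig
  mass is proportional to abundance and zero-abundance genomes vanish.
  A tiling — rather than overlapping random substrings — is the faithful
  emulation of an assembly, where each locus is represented once;
  overlapping sampling would multiply single-copy markers and bias
  contamination upward in proportion to depth. `depth > 1` (multiple
  tilings) is available and documents exactly that effect.

Everything is seeded; a fixed seed gives byte-identical FASTA output.

What passing tests on these communities show: the estimators are exact
or near-exact when their assumptions hold (single-copy markers, clean
compositional contrast, genes drawn from the modelled families). What
they do not show: robustness to real-assembly artifacts — chimeric
contigs, strain mixtures, uneven coverage, horizontally transferred
pathway fragments, lineage-specific marker loss — none of which the
generator produces.

# Problem sizes and numerical choices

The shipped test and validation suites use three-genome communities of
30 kb genomes (≈ 90 kb of contigs), model calibration with 200 decoys
per model, 100 bootstrap replicates, and oracle suites at the sizes
where exhaustive enumeration is exact (HMMs M ≤ 4 with peptides ≤ 6,
alignments ≤ 10 residues, trees ≤ 50 nodes, 8 leaves). These sizes were
chosen as the smallest at which every property under test is
non-trivial; all thresholds and seeds are frozen in the tests
themselves. Other numerical conventions: emission/transition rows are
exact simplexes (checked to 1e-9); forward uses log2-sum-exp; k-means
uses 10 restarts under a fixed seed; E-values are floored at the
smallest positive double rather than reported as 0.

# Known limitations

- The ORF caller requires an ATG start and misses genes whose start
  codon is split across a contig break (partial genes are still found
  when an in-frame internal methionine exists).
- Marker-based contamination can be slightly inflated by genes split
  across contigs; the median genome-equivalent estimator is robust to
  this, the per-bin estimate less so.
- Composition-only binning cannot separate genomes of similar GC/4-mer
  profile; no coverage-differential information is used.
- The LCA assignment is only as good as the labelled reference; with
  sparse references the top-hit window widens assignments toward the
  root rather than guessing.
- NJ topologies on strongly non-additive distances (deep divergence,
  saturated p-distances) should be read with their bootstrap supports,
  not as point estimates.
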