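---
title: "Surveying huge proteins: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying huge proteins: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hugeprot)
```

## The problem

Most proteins are 100–500 amino acids long, and protein length
distributions across proteomes are well approximated by a log-normal (or
gamma) law. The far right tail — sequences of 5000 residues or more, which
we call huge proteins (HPs) — is populated by well-characterized giants
such as titin, midasin or the NRPS/PKS megaenzymes, but also by plausible
gene-prediction artifacts. `hugeprot` implements a survey pipeline for
this tail over a collection of proteomes: how prevalent HPs are per
phylum, what evidence supports their existence, whether they form
families of homologues, what domain architectures they carry, and which
of them look like annotation artifacts.

The package deliberately consumes *files* — protein FASTA, a proteome
metadata table, an annotation table, HMMER `domtblout` hits, a GO OBO
file — rather than querying databases or running the upstream predictors
(hmmscan, SignalP, DeepTMHMM, IUPred, BUSCO). Those tools' outputs reduce
here to their semantic content: a presence flag, a count, a per-residue
score vector, a hit table.

## Core definitions

* **Huge protein**: length ≥ 5000 residues. The boundary is inclusive.
* **Likelihood of HPs** for a proteome of size $s$ containing $h$ HPs:
  $L = 100\,h/s$ (percent). Phylum summaries report the exact median of
  $L$, sorted by superkingdom and then median.
* **Proteome filtering** before prevalence statistics, in order:
  (1) drop phyla with fewer than 5 proteomes; (2) within each surviving
  phylum drop proteomes with $s < \bar{s} - \mathrm{sd}(s)$, both moments
  computed over the phylum *before* any size-based removal; (3) drop
  plasmid proteomes. The standard deviation is the sample SD ($n-1$
  denominator); whether the original procedure used the sample or
  population SD is not documented anywhere we could verify, so we chose
  the default of mainstream statistics stacks and record each removal in
  a log so the decision is auditable. Rule 2 is applied exactly once:
  re-applying it after removals could cascade (shrinking a phylum below
  5 proteomes), which is why only rules 1 and 3 are idempotent.

## Clustering model

HP homology clustering is a native greedy set-cover procedure at the
standard thresholds: minimum pairwise identity 0.3 (the classical
homology floor of 0.25–0.35) and bidirectional coverage 0.8 ("coverage
mode 0": both sequences must have ≥ 80% of their own length inside the
alignment envelope).

The pairwise engine is a local (Smith–Waterman) alignment under BLOSUM62
with affine gaps, gap open 11 and extension 1, where a gap of length $L$
costs $11 + (L-1)$. Identity is defined as identical aligned columns
divided by *all* alignment columns, gaps included — the conservative
reading, chosen so that the independent dynamic-programming oracle in
the test suite can check the implementation to exact equality. Coverage
is measured on the aligned envelope. Selenocysteine (U) and pyrrolysine
(O) are retained in sequences but scored as X, since standard matrices
do not cover them; a self-alignment of an X-containing sequence can
therefore trim terminal X residues.

Greedy order: candidates sorted by length descending, ties by id
ascending; the first unassigned sequence becomes a representative and
absorbs every unassigned sequence meeting both thresholds. This makes
the clustering a deterministic function of the sequence *set*,
independent of file order, and guarantees that representatives pairwise
fail the joint criterion. For long HPs the dynamic program runs in a
diagonal band of half-width $\max(200, 0.1\,\mathrm{len})$, widened by
the length difference; the full quadratic program is used whenever the
oracle comparison runs. Because the synthetic family generator is
indel-free, the band cannot clip a true family alignment. No k-mer
prefilter is used: at desk scale the all-vs-representative scan is
seconds, and a prefilter would change performance, not semantics.

Tie-breaking in the aligner is part of the contract (first best cell in
row-major order; diagonal preferred over a horizontal gap over a
vertical gap; gap opening preferred over extension on score ties), and
the reference implementation in the tests mirrors it, so score *and*
identity are checked to exact equality rather than within a tolerance.

## Architectures

Pfam hits are read from HMMER3 `--domtblout` files (any ≥ 23-column
3.x layout) and filtered at E ≤ 0.001 for both the full-sequence E-value
and the per-domain independent E-value. The envelope coordinates are
kept 1-based inclusive end to end; no coordinate convention conversion
happens anywhere.

The overlap policy is our own, since none is documented for the original
procedure: two hits conflict when their envelopes overlap more than 50%
of the shorter one; hits are admitted greedily by descending bit score
(ties: smaller domain E-value, then accession). Setting the tolerance to
0 reproduces strict non-overlap. After resolution, the architecture is
the `|`-joined list of version-stripped accessions ordered by envelope
start. Repeats are *not* collapsed — repeat counts carry signal (the
repeat-domain census counts a protein once however many copies it has) —
but a secondary collapsed view (`PF00435*`) is emitted for reporting.

Architecture groups are defined by exact pattern equality (order
matters). Each pattern gets a 6-character upper-case base-36 code
derived from a fixed 64-bit FNV-1a hash; truncated-hash collisions are
resolved deterministically by appending `#1`, `#2`, … and rehashing,
with patterns processed in sorted order. Any stable injective scheme
satisfies the contract; this one needs no external dependency and is
reproducible across platforms.

Per-domain distributions subsample each phylum to at most 50 proteomes
(deterministic under a seed) and retain the top 15 phyla per
superkingdom, so that heavily sequenced phyla do not dominate the
stacked counts.

## Existence statistics

Existence levels are UniProt's evidence tiers (1 = protein level, 2 =
transcript level, 3 = inferred from homology, 4 = predicted); the
"Uncertain" level 5 is rejected on ingest. The original description of
the Kruskal–Wallis / one-way ANOVA comparison leaves the unit of
observation ambiguous (per-protein scores vs. per-replicate category
counts); we treat the existence level of each protein as an ordinal
score and compare the two cohorts (HP vs non-HP), the only reading under
which both tests are well-defined on the described data. Both statistics
are computed natively — H with the standard tie correction, F as the
between/within mean-square ratio — and the test suite checks them
against `stats::kruskal.test` and `stats::lm`/`anova` to 1e-9 on random
cohorts. Resampling of the non-HP cohort is without replacement (the
population is a set of distinct proteins), at the HP cohort size, with
5, 10 and 100 replicates by default.

## Features and artifacts

Disorder enters only as the percentage of residues with score ≥ 0.5 —
the usual convention for IUPred-style scores; the threshold is a
parameter. Signal peptides and TMH counts are consumed as annotations.
Artifact flags: `no_domain` (empty architecture), `no_homology_no_cog`
(singleton cluster and no COG category), `disorder_ge_99` and
`disorder_eq_100`. Flags are three-valued: when an input table is absent
the flag is `NA`, never silently `FALSE`. GO terms are propagated to all
`is_a` ancestors within one namespace; a protein counts once per term,
which makes the roll-up idempotent and the counts monotone along `is_a`.

## The synthetic generator

Every downstream stage is exercised on collections from
`simulate_proteomes()`, which provides exact ground truth:

* Bulk lengths are log-normal, ln-scale mean 5.8 and SD 0.9 by default.
  No parametric fit of the real survey's length distribution is
  published, so these defaults are an explicit choice (they put the bulk
  mode near 250–350 residues) and are documented as such. Bulk lengths
  are capped at 4999 so the planted HP set *is* the ground-truth HP set.
* Per-proteome HP counts are Poisson with mean
  `hp_rate × proteome_size / 1000`. Default per-phylum rates span the
  reported range: about 4 per 1000 for the most HP-rich eukaryotic phyla
  (Apicomplexa-like), 0.4 for a Chordata-like phylum, 0.8 and 0.1 for
  HP-enriched and typical bacteria, 0.05 for archaea.
* HP existence levels default to the reported HP proportions (0.8%,
  0.06%, ~22%, ~77% for levels 1–4). The non-HP defaults (0.3%, 1%,
  27%, 71.7%) follow the same predicted-dominated trend with a smaller
  protein-level fraction, as a plausible background.
* Planted families derive `m` members from a common random ancestor by
  i.i.d. per-site substitution, uniform over the 19 alternative residues,
  with the substitution probability solving
  $(1-p)^2 + p^2/19 = \text{target identity}$. There are no indels in
  this generator, deliberately: identity and coverage ground truth stay
  analytic and family coverage is exactly 100%. Two independent random
  sequences have ~5% expected column identity, far below the 0.3
  threshold, so family recovery has an unambiguous answer.
* Architectures from a library of ordered accession vectors are planted
  on HPs (recycled in id order); the simulated `domtblout` writes true
  hits below the 0.001/0.001 thresholds with at least 5 residues between
  envelopes, plus optional above-threshold decoys. `n_disorder_99` /
  `n_disorder_100` plant near-total-disorder artifacts
  (`n_disorder_99` is the total count at ≥ 99%, of which
  `n_disorder_100` are exactly 100%).
* One global seed; each stage derives its substream by a fixed offset,
  so adding proteomes does not perturb earlier draws, and a fixed config
  reproduces every output file byte for byte.

What the generator does *not* emulate: domain-level evolution, indels,
codon structure, gamma-length alternatives, taxonomic correlation of
annotation quality, or the sheer scale of a real sequence database.
Passing tests therefore demonstrate correctness of the survey machinery
on data satisfying its assumptions — not that real collections satisfy
them. In particular the real survey's headline counts (41 754 HPs, 7183
clusters, …) depend on a specific database release and are out of reach
by design.

## Problem sizes

The bundled tests and the acceptance script run the full machinery at
deliberately small scale, chosen as the smallest sizes at which each
property is statistically decidable: 10-proteome collections of 120–260
proteins for pipeline runs; 5 planted families of 6 members at lengths
5000–6000 plus 10 random singletons for clustering recovery; 50 random
short pairs for the exact aligner-oracle comparison; 100-replicate
resampling against hypergeometric expectations (3-standard-error bands);
200 generator seeds for the Poisson calibration of HP counts.

## Orchestration

`run_pipeline()` executes extract → prevalence → existence → cluster →
architect → features on one configuration object, validates every input
path and threshold before any stage runs, writes one TSV per stage plus
a JSON manifest (config hash, seed, row counts), and is byte-identical
under re-run. The exported functions are the interface; the manifest and
the removal log make a run auditable after the fact. `render_report()`
re-reads a run directory into the summary tables (likelihood by phylum,
existence proportions, category table, architecture groups) and is
idempotent.

## Known limitations

* The aligner's identity definition (gap columns in the denominator) is
  one defensible reading among several used by clustering tools; with a
  different denominator the 0.3 threshold selects a slightly different
  neighborhood.
* Banded alignment can underestimate identity for highly gapped true
  homologue pairs; with the indel-free generator this cannot affect the
  shipped tests, but real indel-rich families may need `band = NULL`.
* `resolve_overlaps` is greedy, not optimal; a hit chain constructed to
  defeat greedy admission could retain a lower-score set.
* The existence-test design (per-protein ordinal scores) is one reading
  of an ambiguous description; p-values from database-scale cohorts are
  not comparable to desk-scale ones.
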