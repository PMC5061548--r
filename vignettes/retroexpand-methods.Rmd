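---
title: "Models and methods behind retroexpand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retroexpand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

retroexpand studies how a processed-pseudogene (retrogene) family grows in a
lineage, with the elephant TP53 repertoire as its model system: a single
retrotransposition of the parent tumor-suppressor gene on the Paenungulata
stem, a long quiescent interval, then rapid amplification via segmental
duplications restricted to the Proboscidean lineage, ending with ~19
retrogene copies beside the single parent gene in modern elephant genomes.
The package has two halves: a seeded generator that simulates this scenario
down to reads and expression tables, and an inference toolkit that recovers
the repertoire, its copy number, its duplication mechanism, and its
trajectory through time from those (or equivalent real) data.

```{r setup}
library(retroexpand)
library(dplyr)
```

## The simulator

### Species tree

`build_species_tree("paenungulata")` encodes the study clade with node ages
in millions of years before present (MY BP): the Paenungulata crown at 64.2
MY, the mastodon--elephant split at 25 MY, the African--(Asian
elephant/mammoth) split at 8 MY. Ages the calibration literature does not
fix for us we set once at paleontologically conventional values: Tethytheria
(manatee versus Proboscidea) at 60 MY, Asian elephant versus mammoth at 6.7
MY, an afrotherian outgroup at 80 MY, and extinct tips ending above the
present (mammoth 0.011 MY, mastodon 0.09 MY, the midpoint of its 50--130 ky
dating window). Branch lengths are parent age minus child age, so extinct
tips simply stop early; any table of labels, parents and ages builds a
custom tree the same way.

```{r}
tr <- build_species_tree("paenungulata")
tr
```

### Gene-family history

`simulate_gene_family()` is a birth--death process riding on the species
tree. One retrotransposition seeds the family at `t_retro` (default 64.5 MY,
just above the Paenungulata crown). Each gene lineage then duplicates as a
Poisson process with a piecewise-constant rate \(\lambda(t)\) and dies at
rate \(\mu\); at speciations every surviving lineage enters both daughter
branches; at a tip the surviving lineages are the species' true copy
number. The default rate function is 0 before 40 MY BP (the observed
quiescent interval) and \(\log(19)/40 \approx 0.074\) per lineage per MY on
(40, 0], restricted to the Proboscidean clade, so that a pure-birth lineage
expects \(e^{\lambda \cdot 40} = 19\) extant copies -- the published
repertoire size. The per-lineage rates themselves are not published
anywhere, so they are free parameters chosen to reproduce that repertoire;
\(\mu\) defaults to 0 and can be raised for loss-aware experiments. The
test suite checks the pure-birth mean against the analytic expectation over
2000 replicates.

Every stochastic stage derives its own seed from the single master seed via
a labelled hash (`derive_seed()`), so adding a stage never shifts another
stage's stream, and a fixed config reproduces every file byte-for-byte.

### Sequences, loci, reads, expression

`evolve_sequences()` evolves the parent CDS along the species tree under a
2-parameter (transition/transversion, default ratio 2) substitution model
at 0.0015 substitutions/site/MY -- enough to land related copies in the
80--85% identity band over the clade's depth, which is all the
identity-threshold analyses need; we deliberately do not simulate the
GTR+I+G machinery used for phylogenetic inference on real data. The parent
gene is kept coding by restoring its start codon and recoding in-frame
stops after each branch (a cheap stand-in for purifying selection). At the
retrotransposition the nascent copy receives the single diagnostic deletion
(default 21 nt, constrained to 15--30 nt; 21 is frame-preserving, matching
a repertoire where most copies still carry substantial ORFs), and a
configured fraction of sampled copies (default 5/19, the non-coding
fraction of the published table) get a premature stop codon.

`assemble_loci()` embeds each copy in `flank | gene | flank` contigs.
Under the default segmental mechanism the new copy of each duplication
inherits its parent locus' flanks with a per-event drift (each site
replaced by a different base with probability `flank_drift`, so expected
sister-flank identity is exactly \(1 - p\)) and the family-wide
transposable-element fingerprint labels; the independent-retrotransposition
mode gives every copy unrelated random flanks and private labels. Five
single-copy control regions, equal in length to the average family gene,
evolve neutrally along the species tree so that focal-genome reads map onto
the reference species' controls. Flanks do not accumulate additional
per-MY drift between duplications; the classifier contrast
(inherited versus unrelated flanks) is what matters, not flank dating.

`simulate_reads()` draws per-contig read counts from a Poisson with mean
`coverage * length / read_length`, uniform start positions, and per-base
miscalls at `error_rate`. The ancient profile draws lengths uniformly on
40--100 nt at low coverage (default 0.5x); a deamination-damage flag is
reserved but off -- the 90%-identity assignment threshold plays the role
the permissive ancient mapping mode plays on real data. Reads are emitted
in reference orientation by default (assignment is orientation-symmetric;
a `paired` flag emits /1 + reverse-complement /2 mates when mate plumbing
is being exercised).

`simulate_expression()` emits the observed expression pattern: the parent
robustly expressed, one high plus two low retrogenes above threshold, the
rest exactly silent, and a lognormal background transcriptome (default 500
genes) -- without a transcriptome-scale denominator a TPM threshold of 2 is
meaningless, so the background is part of the generator's contract that
*exactly* the designated copies pass the call.

## The inference toolkit

### Alignment

All homology search runs through an in-package Smith--Waterman/Gotoh local
aligner (C++ core) with affine gaps: a gap of length L costs
`gap_open + (L-1) * gap_extend`, defaults match +1 / mismatch -2 / open -5
/ extend -2 (stringent, BLAT-like). Ties between equally scoring alignments
are broken deterministically (smaller start on the first sequence, then the
second, then smaller ends), percent identity is matches over aligned
columns including internal gaps, and `N` matches nothing. The test suite
holds the aligner to exhaustive enumeration of all alignments on every
5-mer pair over a reduced alphabet and on random pairs under gap-friendly
scoring schemes.

### Repertoire characterization

`reciprocal_best_hit()` pairs genes across two sets when each is the
other's best hit (ties by identity then lexical id).
`assess_coding_potential()` scans the three forward frames of the supplied
orientation for the longest ATG-initiated, stop-terminated ORF and calls a
gene coding at >= 25 aa. The published table's coding criterion is not
stated; 25 aa is safely permissive (its shortest listed ORF is 79 aa) and
both the threshold and the start-codon requirement are explicit arguments.
`find_diagnostic_indels()` reports maximal MSA gap blocks carried by every
ingroup row and no outgroup row within the 15--30 column band -- the
deletion that separates retrogenes from the parent -- and
`predict_amplicon()` turns primer pairs spanning such a deletion into
expected product lengths (exact site matching by default, as
paralog-specific primers are designed exact). `classify_expansion_mechanism()`
calls a duplicate segmental when its flanks align to the parent locus at
>= 80% identity *and* the fingerprint labels match, otherwise independent.

### Copy number, three ways

`estimate_copy_number()` composes the three estimators on one read set:

* **Minimum -- 1:1 orthology.** `assign_reads()` aligns every read against
  every reference (the desk-scale analogue of a very-sensitive mapper),
  assigns it to the best-scoring gene, splits exact score ties fractionally
  (1/k to each of k genes) and discards reads under 90% identity (the
  ancient-data stringency) or 30 aligned columns. A reference gene is
  *recovered* when half its positions reach depth 1
  (`recovered_orthologs()`); the recovered count is the minimum estimate.
  Published analyses of this kind judged orthologs from read-assembly
  output without stating a rule, so breadth >= 0.5 at depth >= 1 is our
  documented, configurable convention -- breadth-based, not
  assembly-based.
* **Average -- normalized read depth.** The summed mean depth across family
  genes over the mean depth of the single-copy controls
  (`depth_copy_number()`). Fractional tie-splitting keeps this ratio
  unbiased even when copies are nearly identical, which is precisely the
  regime that defeats per-copy assignment. The 95% CI is a seeded
  percentile bootstrap over 100-nt windows resampled within the family set
  and within the control set (1000 replicates); published estimates report
  a 95% CI without describing its construction, so the bootstrap is our
  choice. The ratio is invariant to overall coverage by
  construction.
* **Maximum -- reconciliation with unsampled genes.** `reconcile_lca()` is
  the standard most-parsimonious LCA mapping (duplication where a node maps
  with a child; losses read off mapping gaps and attributed to species
  branches), verified against exhaustive search over all valid mappings on
  random trees. A reference paralog absent from the focal sample is
  *unsampled* -- present but missed -- exactly when its divergence age
  predates the focal--reference split (`infer_unsampled()`); for ancient
  genomes the same rule at their deeper split discounts younger reference
  paralogs as reference-lineage duplicates. Maximum = recovered +
  unsampled. Inside `estimate_copy_number()` the missing-paralog set and
  ages come directly from the dated reference gene tree (each tip's parent
  node age); for 1:1-grafted topologies this is precisely the
  reconciliation's focal-branch loss set, without building the composite
  tree.

The three numbers are reported together (with `tidy()`/`glance()` and an
`autoplot()`), and the combined `[minimum, maximum]` envelope is how a
range like the published "12--17" is meant to be read; how such published
ranges were assembled is not stated, so the envelope is our explicit
convention. Note the maximum is still a lower bound on truth whenever the
focal lineage duplicated after its split from the reference -- read mapping
onto a reference cannot see focal-specific duplicates; the depth estimator
is the one that stays centred on truth in that regime, and the pipeline
report shows exactly this behavior.

### Trajectory and expression

`copies_through_time()` counts gene-tree lineages ancestral to the focal
species' sampled copies: a right-continuous step function rising by one at
each duplication on the focal path, starting at 1 at the family origin.
Lost lineages are by definition not ancestral to sampled copies, so on real
(sampled) trees the curve never steps down; the simulator's truth-side
`true_copies_through_time()` counts lineages alive at each age, stepping
-1 at losses, and the suite checks both against the event list.
`correlate_series()` resamples two series onto a common 1-MY grid (step
interpolation for counts, linear for masses), computes Pearson (or
Spearman) correlation and a circular-shift permutation p-value -- shifts
preserve each series' autocorrelation, which i.i.d. shuffling would
destroy; the visual correspondence between copy number and body size has
not previously been given a statistic, so this test is the package's way
of making the claim quantitative. Age uncertainty can be explored by resampling node ages
within externally supplied intervals before calling the function; Bayesian
dating itself is out of scope and dated trees are inputs.

`fpkm_to_tpm()` and `call_expressed()` implement
\(\mathrm{TPM}_i = \mathrm{FPKM}_i / \sum_j \mathrm{FPKM}_j \times 10^6\)
with an inclusive threshold at TPM = 2; `unique_read_counts()` counts
single-best-reference reads per gene, the ambiguity-robust evidence used to
corroborate which copies are really transcribed.

## A worked run

```{r, eval = FALSE}
report <- run_end_to_end(config = sim_config(seed = 1))
report
tidy(report$objects$cn_modern)
autoplot(report$objects$correlation)
```

## Numerical choices and problem sizes

* Coordinates: genomic features are 0-based half-open; alignment spans are
  1-based inclusive (the R convention); times are MY BP with present = 0.
* Degenerate inputs error loudly: all-zero FPKM vectors, constant series,
  zero control depth, ragged MSAs, non-binary trees, grids reaching past
  the family origin (clamped with a warning).
* The statistical checks in the test suite run at desk scale chosen once
  for the package: 400-nt genes and 80--100-nt reads for the
  read-assignment-heavy checks (the full 1182-nt default is used where
  alignment volume is modest), 50 seeded replicates for coverage and
  under-recovery rates, 1000-replicate bootstraps, 2000 replicates for the
  pure-birth mean. The co-trending trajectory check conditions on families
  that actually expanded (>= 5 extant copies) because a flat trajectory has
  no trend to correlate; its mass series uses elephant-scale log-linear
  drift (5 kg to ~9500 kg over the family's lifespan) with Brownian noise
  of sd 0.1 per MY on the log scale.

## What passing tests do and do not show

The generator emulates the *statistical structure* the inference assumes:
uniform-coverage reads, a single shared deletion, clean flank inheritance,
label-perfect TE fingerprints, no assembly error, no damage patterns, no
paralogy outside the focal family, and an expression pattern designed to be
unambiguous. Success on it shows the estimators are correct and calibrated
under their own assumptions -- not that real assemblies, ancient damage,
repeat-riddled flanks or reference bias are handled; those enter real
analyses through the configurable thresholds (identity, breadth, flank
identity) whose defaults mirror the published settings. Sequence-level
realism is similarly bounded: no indel evolution beyond the diagnostic
deletion and frameshifts, no TE sequence libraries, no
recombination-mediated duplication mechanics.
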