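---
title: "Multi-evidence miRNA target identification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-evidence miRNA target identification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmeta)
```

# The problem

A microRNA represses its targets through short "seed" pairing between
its 5' end and sites in target 3'UTRs. Any single line of evidence for
targeting — expression change after perturbing the miRNA, presence of a
seed match, Argonaute binding — is individually noisy. `mirmeta`
implements a multi-evidence strategy: a gene is called a
**high-confidence target** only when

1. its expression is *inversely correlated* with the miRNA in every
   dataset of a loss-of-function (LOF: knockout vs wild type, targets
   expected up) / gain-of-function (GOF: induced overexpression,
   targets expected down) panel,
2. its 3'UTR carries a **7mer or 8mer seed match**, and
3. an **Ago2 HITS-CLIP cluster** with a seed match sits in its 3'UTR.

Every stage is an exported function; `run_all()` composes them and a
seeded synthetic-study generator provides ground truth to validate the
whole chain.

# Seed-site conventions

For a mature miRNA sequence, the k-mer site (`seed_site_motif()`) is
the reverse complement of miRNA positions 2..k+1 (1-based): the 8mer
pairs positions 2–9, the 7mer 2–8, the 6mer 2–7. For mmu-miR-203-3p
(`GUGAAAUGUUUAGGACCACUAG`) the 8mer site is `ACAUUUCA` (DNA
`ACATTTCA`). **This differs from the TargetScan 7mer-A1/8mer-A1
convention**, which anchors an `A` opposite position 1; here all three
classes are pure seed pairing, and the three motifs are nested suffixes
(`ACATTTCA` ⊃ `CATTTCA` ⊃ `ATTTCA`). A gene's seed class
(`classify_seed_class()`) is the longest class present anywhere in its
(longest) 3'UTR — a set-membership definition, not a site-count
weighted one. All sequences are handled in DNA space (`U` mapped to `T`
at parse time); coordinates are 0-based, half-open, and strand-aware
(BED conventions).

# Quantification

* **Small RNA.** Each trimmed read is assigned to the miRNA with the
  longest exact contiguous match of ≥ 18 nt (`count_mirnas()`); ties go
  to the lexicographically first name so counting is deterministic for
  paralogous seeds. Tables are filtered to ≥ 50 reads in ≥ 2 libraries.
* **3' ends (3Seq).** Per-position 3'-end counts are pooled across
  libraries, merged into peaks when consecutive positions lie closer
  than 10 nt (`call_3p_peaks()`; the peak position is the modal end
  site, leftmost on ties), and filtered for internal poly(A) priming:
  a peak is discarded when the 10 genomic nt immediately 3' of it
  (strand-aware) contain ≥ 7 A or the adjacent 6 nt are all A
  (`filter_internal_priming()` — a field-standard heuristic, thresholds
  exposed as arguments). Counts of clean peaks whose modal site falls
  in a 3'UTR are summed per transcript (`transcript_counts()`);
  transcripts with < 10 reads in 2 libraries are excluded.
* **Normalisation and fold change.** Reads per million (`rpm()`) and a
  pseudocounted log2 fold change of condition means (`log2fc()`,
  pseudocount 1 RPM). No dispersion model is fitted: the meta-analysis
  consumes only the *sign* and *rank* of each gene's fold change, so a
  moderated test would change nothing downstream.
* **Translation efficiency.** TE = Ribo-Seq CDS RPM / 3Seq mRNA RPM by
  default (`translation_efficiency()`); the inverse is available as a
  mode switch because both directions appear in the literature, and the
  choice only relabels the symmetric downstream comparison.
  ΔTE = TE(KO)/TE(WT).

# CLIP analysis

Reads identical in (chrom, strand, start, end) collapse to one
(`collapse_duplicates()`). A **cluster** is a maximal strand-specific
chain of reads overlapping by ≥ 1 nt — under half-open coordinates
abutting reads do *not* overlap — with ≥ 2 members
(`call_clusters()`, equivalent to connected components of the pairwise
overlap graph). The summit is the leftmost position of maximal read
coverage. Clusters are annotated hierarchically
(`annotate_clusters()`): 3'UTR (with a 5 kb downstream extension to
catch unannotated UTR isoforms), then CDS, 5'UTR, ncRNA, intron,
intergenic; the first matching category wins.

Target-site prediction (`predict_target_sites()`) scans the
strand-corrected genomic sequence of every 3'UTR cluster for the 6mer
motif of each miRNA in the set covering 90% of cumulative small-RNA
abundance (`top_expressed_mirnas()`). Site *existence* is 6mer-based;
the reported class is upgraded to 7/8mer when the longer motif is
present at the same locus. `positional_seed_profile()` histograms motif
offsets relative to summits (5-nt bins centred on their labels, so bin
0 covers ±2.5 nt) against two backgrounds: dinucleotide shuffles of the
cluster sequences and length-matched random 3'UTR windows. The
dinucleotide shuffle is the Altschul–Erickson Euler-path construction
(`dinucleotide_shuffle()`), which preserves the full dinucleotide count
vector exactly — note that fully constrained sequences (e.g.
`ACGTACGT`) have a unique valid shuffle.

# De novo motif discovery

`motif_enrichment()` replaces heuristic motif finders with exhaustive
enumeration: for every one of the 4^k k-mers it counts foreground and
background sequences *containing* the motif and computes a one-sided
Fisher (hypergeometric) p-value on the containment 2×2 table. A
binomial test treating the background frequency as a known null rate
was considered and rejected: the background is itself an estimate from
a finite (often equally sized, shuffled) set, and ignoring its sampling
error makes rare-motif tails strongly anti-conservative — under the
null (shuffled foreground vs its own shuffle) it produced spurious
Bonferroni-significant motifs in every seeded run, whereas the Fisher
form is valid whenever foreground and background are exchangeable.

# Meta-analysis

The **universe** is the intersection of gene ids detected in every
dataset — genes missing anywhere are dropped, never imputed as zero.
A gene is a **candidate** iff log2FC > 0 in every LOF dataset and
< 0 in every GOF dataset (`sign_consistent_candidates()`); exact zeros
never qualify (they are measure-zero on arrays but common with
pseudocounted counts, and a zero is evidence of no change). Seed
enrichment among candidates is a hypergeometric upper tail against the
universe's seed-class distribution (`seed_enrichment()`), with two
negative controls: a size-matched uniformly random gene set and the
anti-correlated set (down in all LOF, up in all GOF; its size is
whatever the data yields). The **ranked correlation metric**
(`rank_correlation_metric()`) ranks genes within each dataset (rank 1 =
most up in LOF, most down in GOF), sums ranks across datasets and ranks
the sums; ties receive average ranks at both stages, which makes the
metric invariant under any strictly monotone transform of each
dataset's values.

Distribution shifts by seed class use a **one-sided two-sample
Kolmogorov–Smirnov test** (`cdf_shift_tests()`): in a GOF dataset a
seeded class is expected to shift down, in a LOF dataset up. The
statistic is the one-sided maximal CDF difference; the p-value is the
asymptotic bound `exp(-2 D² nm/(n+m))`, replaced by exhaustive
permutation enumeration when `choose(n+m, n)` is small enough to
enumerate (≤ 1e5 label assignments) — a size-based criterion chosen
because full enumeration, not an approximation, is what a small-sample
"exact" test should mean. Classes with fewer than 5 genes are reported
with `p = NA`. No multiple-testing correction is applied across the
three seed classes by default (raw per-class p-values are reported;
`motif_enrichment()` reports a Bonferroni column). `target_response()`
reuses the same machinery for an independent perturbation dataset with
target membership as the class.

# The synthetic study

`sim_config()` fixes the study conditions; all emitters derive their
RNG streams from `rng_seed`, so every output is byte-reproducible.
Defaults and their rationale:

| parameter | default | why |
|---|---|---|
| `n_genes` / `n_true_targets` | 6000 / 300 | matches the scale on which a 5-dataset panel typically intersects (~6k genes detected everywhere); 5% true targets |
| `seed_class_mix` | 8mer .4 / 7mer .4 / 6mer .2 | 7/8mer-dominated, as in measured target sets |
| `lof_effect_mean` / `gof_effect_mean` | 0.5 / 1.0 log2 | knockout perturbs transcripts more mildly than induced overexpression |
| `class_effect_scalars` | 1 / 0.75 / 0.5 | repression strength ordered 8mer > 7mer > 6mer |
| `noise_sd` | 0.25 log2 | moderate inter-platform measurement noise; the source studies report no noise model, so this is a free parameter of the simulation, not an estimate |
| `library_depth` | 2e6, 2 replicates/condition | small but sufficient count depth per library |
| `clip_reads_per_site` / `clip_background_rate` | 10 / 0.05 per kb | sites stand well above a sparse background |
| `utr_len_range` | 200–1200 nt | short mammalian-like UTRs keep the genome compact |
| `intergenic_gap` | 6000 nt | larger than the 5 kb 3'UTR annotation extension, so extensions cannot spill onto neighbouring loci |

True-target UTRs carry the exact motif of their class at the planted
position, and rejection sampling guarantees the gene classifies to
*exactly* that class (no accidental longer site). Non-target UTRs keep
chance ("decoy") seeds by default — enrichment statistics need a
realistic null — with `decoy_free = TRUE` available for construction
tests. The five log2FC tables are planted effect + N(0, `noise_sd`)
(LOF positive, GOF negative; zero for non-targets). Count tables are
per-library multinomial draws whose expected abundance ratios encode
the planted effects; ribosome-footprint weights track mRNA weights
exactly, so the planted ΔTE is 1 for every gene. Note that multinomial
(RPM-style) data are *compositional*: upregulating targets shifts every
gene's relative abundance down by the total-mass ratio (about 0.03
log2 units at the defaults). This is a property of real RPM data too;
it slightly favours "down" calls in count-based LOF datasets and is
left uncorrected. CLIP reads are centred on planted sites with ±15 nt
jitter and 25–40 nt lengths, giving each cluster a coverage peak at the
site, plus a uniform background.

What the simulation does **not** model: sequencing errors, adaptors and
alignment (reads are emitted as intervals); isoform structure and
alternative UTRs; miRNA-family cross-targeting; secondary structure or
site accessibility; correlated noise between datasets. Passing the
end-to-end checks therefore demonstrates that the *pipeline logic*
recovers planted structure under its stated assumptions — not that it
would achieve the same precision/recall on real libraries.

# Numerical and degenerate-input choices

* Summit ties break leftmost (genomic coordinates); modal 3'-end ties
  leftmost; miRNA assignment ties lexicographic.
* `rpm()` refuses zero-total libraries; `translation_efficiency()`
  skips zero-denominator features with a warning; `log2fc()` floors
  both means with the pseudocount so 0/0 gives 0.
* `top_expressed_mirnas()` returns the smallest descending-abundance
  prefix reaching the cumulative fraction, with equal abundances
  ordered by name for determinism (so ten equal miRNAs at 10% yield
  nine, not ten).
* Empty candidate sets give enrichment p = 1; empty read sets give
  empty cluster tables; a truthless simulation reports recall `NA`.
* Peaks at contig edges evaluate whatever downstream window exists.

# Problem sizes used in validation

The packaged checks run the full default study (6000 genes, 300
targets, five datasets, CLIP at default depth; about two minutes), a
3000-gene panel for the CDF-shift ordering, an 800-gene universe for
200-run null calibration, and 1000-case brute-force oracle comparisons
for cluster calling, motif scanning and the K–S statistic. These sizes
were chosen so each statistical property is tested with comfortable
power while the whole suite stays fast to iterate on.

# Known limitations

* The candidate rule is an all-datasets sign intersection: one flipped
  sign anywhere removes a gene, so recall decays with panel size and
  per-dataset noise; the rank metric is provided as the graded
  alternative.
* The hierarchical annotation assigns a cluster to the first matching
  feature; on compact genomes a 5 kb 3'UTR extension can capture
  downstream loci (the simulator spaces genes accordingly).
* K–S p-values for large samples use the asymptotic one-sided bound,
  which is conservative for heavily tied data.
* The Euler-path shuffle preserves dinucleotide counts only; higher-
  order composition (codon structure, CpG clustering) is not preserved.
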