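---
title: "Quantifying an electrode-attached microbial community from metagenome and multi-region 16S data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying an electrode-attached microbial community from metagenome and multi-region 16S data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biocathodr)
```

## The problem

Aerobic biocathode biofilms are low-complexity marine communities growing on
a poised electrode, where one uncultivated member — an electroautotroph —
is hypothesized to take up electrons from the cathode. Because the key
organisms cannot be isolated, community composition must be quantified from
sequencing alone, and two independent routes are available for each
replicate bioelectrochemical system (BES):

* **genome route** — shotgun reads are mapped to metagenomic bin genomes;
  the length-weighted mean fold-coverage of each bin, normalized across
  bins, is its relative abundance;
* **amplicon route** — 16S rRNA gene amplicons from seven hypervariable
  regions are clustered into OTUs; OTU read counts over the per-sample read
  total give relative abundance.

The two routes disagree systematically: each genome carries between 1 and
~13 rRNA operons, so amplicon counts over-represent high-copy-number
organisms, and each primer set amplifies taxa with its own multiplicative
bias. `biocathodr` implements the full reconciliation: consensus taxonomy
for unassembled read pairs, coverage-based bin abundance with a
reproducible split-bin merge, OTU-to-reference linking at 97% identity,
cross-region averaging under quality control, iterative integer
copy-number estimation anchored on genomes whose operon counts are known,
and finally correlation of taxon abundance with cathodic current magnitude
— the signature of the electroautotroph.

## Paired-read consensus taxonomy

Each unassembled read mate comes with a ranked list of database hits
(e-value, bit score, lineage). `classify_read()` discards hits with
e-value above 0.001, keeps at most the top five (ties broken by higher bit
score, then subject id), and forms the lowest common ancestor (LCA) of the
top hit together with every retained hit whose e-value lies within two
orders of magnitude of it. `classify_pair()` then takes the LCA of the two
mates; a pair with a single classified mate keeps that mate's lineage
(disable with `require_both_mates = TRUE`).

Three choices here were genuinely open and are fixed as configuration with
documented defaults:

* **window membership** — the two-orders rule is applied to *all* retained
  hits, not only the second best; `window` and `max_hits` expose the
  narrower reading.
* **boundary** — "within two orders of magnitude" is inclusive
  (`evalue <= 100 × top`). Because decimal e-values are not exact in
  binary floating point (`100 * 1e-20 != 1e-18`), the comparison carries a
  relative guard of 1e-9; no realistic e-value resolution is finer.
* **profile denominator** — `taxon_profile()` divides by classified pairs
  by default (`denominator = "total"` divides by all pairs instead).
  Proportions at a rank therefore sum to at most 1; the shortfall is mass
  unresolved at that rank.

## Bin abundance and split-bin merging

`bin_depth()` is the length-weighted mean of contig depths, with contigs
below 1 kbp excluded from the computation (mirroring the contig-length
cutoff used when clustering); `coverage_abundance()` normalizes per
sample. Clustering of pooled assemblies tends to split one organism's
genome into several bins. `merge_split_bins()` reunites a group when
either

1. the bins' contigs map to the same closed reference genome, or
2. their depth profiles co-vary (Pearson correlation of
   `log(depth + 0.1)` at least `coverage_corr_min = 0.9`), their
   single-copy marker gene multisets are disjoint — a shared marker would
   be duplicated in the merged genome, evidence the bins are different
   organisms — and their taxonomies agree to at least genus.

Merging is the transitive closure over qualifying pairs, processed in bin-id
order, so the result is deterministic and order-independent. The depth
correlation is computed on the log scale because coverage noise is
multiplicative; the pseudocount 0.1 only guards `log(0)`. The 0.9 threshold
is a declared default, not a literature constant.

## OTU linking and cross-region averaging

`percent_identity()` aligns an OTU representative globally against a local
window of a full-length reference (query end-gaps free on the reference),
scoring match +1, mismatch −1, gap opening 2 and gap extension 1 per base
(a length-L gap costs 2 + L). Identity is matching columns over all
alignment columns. The 97% linking threshold is applied to the best-identity
reference; ties break by longer alignment, then reference id. The identity
convention — semi-global over the full OTU, not a local high-scoring pair —
is declared here because tools differ.

`region_abundance()` sums counts of OTUs linked to the same reference and
divides by the *total* reads of the sample-region, so the unlinked mass is
visible as `1 - linked_fraction`. `average_regions()` takes the unweighted
mean of each cell over regions whose linked fraction reaches
`min_linked_fraction = 0.8` for that sample — the guard that removes a
failed amplification (observed in real data as a region-sample with almost
no reads mapping to any long reference) — then renormalizes each sample to
sum to 1. Unweighted averaging is the default because no principled weights
exist without a primer-bias model; `weighted = TRUE` weights by linked read
mass.

## Copy-number reconciliation

`scale_abundance()` multiplies each bin's genome abundance by its 16S copy
number and renormalizes — the abundance an amplicon library should report.
`estimate_copy_numbers()` treats copy numbers known from closed genomes as
fixed anchors and estimates the rest by coordinate descent: unknown bins
are visited in order of descending mean genome abundance (most-constrained
first, ties by bin id), each scanning every integer in `[1, 13]` and
keeping the value minimizing the summed squared difference between scaled
genome abundance and amplicon abundance, over all bins and samples; passes
repeat until a pass changes nothing (at most `max_iter = 50`).

Numerical notes:

* the objective is squared error on the relative-abundance scale because
  zeros are legal; a `log` objective with pseudocount 1e-4 is available;
* exhaustive per-coordinate integer scan is exact — the search space per
  coordinate is 13 values, so no continuous relaxation is needed;
* renormalization makes the model scale-degenerate: multiplying every copy
  number by a constant changes nothing, which is why at least one known
  anchor is required; the degeneracy itself is part of the test suite;
* when one 16S sequence represents several genome sub-clusters,
  `sum_subclusters()` sums their genome-abundance rows before
  reconciliation.

The coordinate descent can only decrease the objective, so it terminates;
with noise it may stop in a local minimum, which is why the validation
protocol (re-estimating held-out known bins) matters and is part of the
tests.

## Current correlation

`correlate_taxon_current()` correlates abundance against the magnitude of
the (negative, cathodic) current, using the exact t transform
`t = r\sqrt{n-2}/\sqrt{1-r^2}` on `n − 2` degrees of freedom, two-sided.
Both the maximum current and the current at sampling are available;
`max_current_mA_m2` is the default. `rank_taxa()` reports every taxon
sorted by R², flags rather than drops degenerate rows, and offers
Benjamini–Hochberg adjustment (off by default: raw per-taxon p-values are
reported, matching common practice for n = 8 screens).

Because relative abundances sum to one, taxa are negatively dependent by
construction: when a dominant taxon rises, everything else must fall, so a
strong positive correlation for the dominant organism induces negative
correlations of comparable size in the next most abundant members. The
package documents and tests this compositional behaviour (a two-taxon
community always yields two opposite-signed correlations with equal R²)
and makes no causal claim. `method_agreement()` implements the
cross-method screen: taxa above a 0.5% floor in both profiles, top 25 by
pooled mean abundance, counted as agreeing at R² ≥ 0.78.

## The synthetic community generator

`community_spec()` / `generate_dataset()` emit every input file the
pipeline consumes plus a truth record. The defaults are the emulated study
design: 8 replicate BES, 20 taxa, 7 region windows on a 1500-bp 16S
coordinate, copy numbers in `[1, 13]`, and a Dirichlet prior
(concentration 12, 6, 4, then 0.6 for the tail) under which the first
taxon — also the designated electro-taxon — occupies roughly 30–60% of the
community, as the dominant organism does in real biocathode data.

What the generator models:

* abundances drawn once per sample (one steady-state time point, no
  dynamics);
* per-(taxon, region) multiplicative primer bias, log-normal with
  `primer_bias_sd = 0.4` — chosen once so that a dominant taxon's apparent
  relative abundance can swing by more than 20 percentage points between
  regions, the magnitude of inter-region fluctuation seen in practice; the
  bias is a multiplier, not a mechanistic primer model;
* OTU counts multinomial at `reads_per_region = 1e5` per sample with
  expectation ∝ abundance × copy number × bias, so every count column sums
  exactly to its read total;
* coverage depth `wgs_depth_mean × abundance` under mean-corrected
  log-normal noise (`depth_noise_cv = 0.1`);
* hit tables whose best hit is the true taxon, with congeneric decoys at
  rate 0.3 whose e-values sit log-uniformly within 1e4× of the best —
  deliberately straddling the two-orders consensus window;
* currents `−(intercept + slope × abundance of the electro-taxon) + noise`
  in mA·m⁻², negative (cathodic) by construction; setting
  `current_model$target_r` derives the noise s.d. so the planted
  population correlation equals a requested value;
* OTU representatives cut from the reference at the region window and
  mutated at exactly `round(rate × length)` sites (default rate 1%), so
  "mutated at 1%" means 1% divergent by construction and linking at the
  97% bar is deterministic given references at least 5% divergent;
* optional *twin pairs*: two taxa with near-identical references (0.5%
  divergence, below the floor) represented by a single long 16S sequence
  and sharing one operon count — the sub-cluster scenario that
  `sum_subclusters()` addresses.

What it does **not** model: read-level sequence error and FASTQ output,
chimeras, assembly and binning error, database incompleteness, and any
taxonomic misclassification mechanism beyond the congeneric decoys.
Passing tests on this generator therefore demonstrate the correctness of
the estimators under their own statistical assumptions, not robustness to
every artifact of real sequencing.

## Problem sizes and determinism

The test suite runs the generator at reduced sizes (hundreds to a few
thousand reads, 2–8 samples) for unit checks and at the full emulated
design — 8 samples, 20 taxa, 7 regions, 1e5 reads per region-sample, 2000
read pairs per sample — for the end-to-end checks; statistical
property tests use 50–1000 seeded replicates, sizes chosen to keep each
block in seconds to a couple of minutes on one core. Every random draw in
the generator flows from a single integer seed; identical spec and seed
reproduce every emitted file byte for byte, and `run_pipeline()` with a
fixed configuration is byte-deterministic end to end (checksums of all
intermediates are part of the run report).

## Known limitations

* With n = 8 samples a sample correlation is a noisy estimate; under a
  planted population correlation of 0.9 for the dominant taxon, the
  compositional anti-correlation of the second and third most abundant
  taxa occasionally produces a competitor with a larger sample R², so
  "the planted taxon ranks first" holds in the large majority of draws
  but not with certainty — the same overlap is visible in real data,
  where the negative correlate's R² range overlaps the positive one's.
* The copy-number objective is non-convex over the integer lattice;
  anchors and the most-abundant-first pass order make recovery reliable at
  coverage-noise levels around 10%, but heavy primer bias degrades
  identifiability (bias and copy number enter the amplicon expectation the
  same way and are only separable because bias varies by region).
* The merge heuristic's depth-correlation threshold is a declared default;
  at small sample counts chance correlations near 1 occur, and the marker
  disjointness condition is the effective guard.
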