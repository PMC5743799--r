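# biocathodr

Quantify the composition of low-complexity, electrode-attached microbial
communities (aerobic biocathode biofilms) from paired shotgun-metagenome and
multi-region 16S rRNA gene amplicon sequencing, and relate taxon abundance
to cathodic current.

Biocathode communities host an uncultivated electroautotroph whose activity
is read out as negative (cathodic) current, so composition must be measured
culture-independently — and the two available sequencing routes disagree:
amplicon counts inflate taxa with many rRNA operons and carry per-primer
bias, while genome (coverage-based) abundance does not. `biocathodr`
implements the reconciliation end to end:

* **paired-read consensus taxonomy** — per mate, hits at e ≤ 0.001 (top 5)
  within two orders of magnitude of the best hit form an LCA consensus;
  mates combine by a second LCA (`classify_read()`, `classify_pair()`,
  `taxon_profile()`);
* **bin-genome abundance** — length-weighted mean fold-coverage per bin,
  normalized per sample, with a reproducible split-bin merge based on
  shared reference mapping, or co-varying depth profiles plus disjoint
  single-copy marker sets and genus-level taxonomic agreement
  (`bin_depth()`, `coverage_abundance()`, `merge_split_bins()`);
* **OTU linking** — semi-global alignment identity of region-specific OTUs
  against full-length 16S references at a 97% threshold; per-region
  relative abundance and cross-region averaging with linked-fraction QC
  (`percent_identity()`, `link_otus()`, `region_abundance()`,
  `average_regions()`);
* **16S copy-number reconciliation** — genome abundance times copy number,
  renormalized, should equal amplicon abundance:
  `v_i = a_i c_i / Σ_j a_j c_j`. Copy numbers known from closed genomes
  anchor the model; unknown integers in [1, 13] are estimated by exact
  per-coordinate descent on the squared disagreement
  (`scale_abundance()`, `estimate_copy_numbers()`, `sum_subclusters()`);
* **current correlation** — Pearson r of abundance vs current magnitude
  with the exact two-sided t test, `t = r√(n−2)/√(1−r²)`, per-taxon
  ranking, and a cross-method agreement screen
  (`correlate_taxon_current()`, `rank_taxa()`, `method_agreement()`);
* **ground-truthed synthetic communities** — a generator emitting every
  input the pipeline consumes (hit tables, coverage, OTU counts, reference
  FASTA, metadata) with a truth record for validation
  (`community_spec()`, `generate_dataset()`);
* **orchestration** — `run_pipeline()` runs both abundance routes,
  reconciles them and writes all intermediates plus a checksummed,
  rerunnable report.

## Worked example

```r
library(biocathodr)

# 8 BES, 20 taxa, 7 regions; a tight current coupling for illustration
spec <- community_spec(seed = 7,
                       current_model = list(intercept = 2, slope = 60,
                                            noise_sd = 0.5))
cfg  <- pipeline_config(spec = spec, out_dir = tempfile("mcl_run_"),
                        classify_reads = FALSE)
rep  <- run_pipeline(cfg)
head(rep$headline$wgs, 3)
```

```
     taxon          r r_squared     p_value n     sign
1  bin_T01  0.9439054 0.8909574 0.000422913 8 positive
7  bin_T07 -0.5418275 0.2935771 0.165396516 8 negative
19 bin_T19 -0.4625730 0.2139737 0.248456747 8 negative
```

The dominant bin (`bin_T01`, the planted electro-taxon) is positively
correlated with current magnitude across the 8 reactors (R² 0.89,
p = 4.2e-4 on 6 degrees of freedom); other taxa show the weaker negative
correlations that compositional closure imposes.
The 16S-route table (`rep$headline$amplicon`) gives the independent
estimate after OTU linking, cross-region averaging and copy-number
scaling, and `rep$copy_model$copy_number` holds the fitted operon counts.

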