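# debloom

Bloom detection and removal for microbiome feature tables from
room-temperature-shipped fecal samples.

## The problem

Mail-in microbiome cohorts and remote fieldwork cannot freeze samples at
collection. During days at ambient temperature a small set of
fast-growing gut bacteria — mostly *Gammaproteobacteria* — keep
multiplying inside the sample. Because amplicon data are compositional,
every read these "blooms" gain depresses the apparent abundance of
everything else: shipped cohorts separate from fresh-frozen cohorts in
ordination space, and real within-cohort biology (e.g. the association
of age with alpha diversity) is buried under transit-time noise.

debloom is an R toolkit for the standard correction: identify the exact
16S sequence variants (sOTUs) that bloom, remove exact sequence matches
to them from every table of an analysis, and measure what the filtering
costs and restores. It is aimed at microbiome analysts working with
Deblur-style exact-sequence feature tables (BIOM HDF5 or TSV).

## The method in brief

Every feature (an exact sequence) gets two scores:

- **max storage fold change** — in paired storage studies (frozen day-0
  baseline vs room-temperature day *t* per subject), the maximum of
  `log2(max(c_t, 10) / max(c_0, 10))` over all comparisons, computed on
  depth-normalized counts with a 10-read detection floor; comparisons
  with both counts below the floor are excluded, and features excluded
  everywhere are *absent*;
- **min cross-study fold change** — `min_i fbar / max(gbar_i, 1e-6)`,
  the shipped cohort's mean relative frequency over every fresh-frozen
  cohort's.

A feature is a candidate bloom if (storage >= 2 **and** cross >= 2), or
storage >= 50 alone, or (absent from the storage studies **and**
cross >= 2). Candidates are ranked by severity
`mean shipped frequency x log2(max(minFC, 1) + 1)` and filtered in
nested fashion: depth *k* removes blooms 1..*k*. The evaluation battery
(Kruskal-Wallis alpha-diversity sweep across nested depths, Bray-Curtis
PCoA, cross-study random-pair distance sweep, class-level taxonomy
summaries) quantifies the trade-off between data lost and signal
restored. A fully ground-truthed compositional simulator backs all of
it. The methods vignette (`vignettes/bloom-filtering.Rmd`) derives each
piece and documents every default.

## Worked example

Simulate a benchmark (two paired storage studies plus a four-cohort
meta-analysis sharing one feature space, five planted blooms), detect,
and filter:

```r
library(debloom)

cfg   <- sim_config()                      # 500 features, 5 planted blooms
bench <- simulate_benchmark(cfg, seed = 42)

ranked <- detect_blooms(bench$storage$table, bench$storage$metadata,
                        bench$cohort$tables$shipped,
                        bench$cohort$tables[-1])
ranked[, c("rank", "criterion", "max_storage_fold", "min_cross_fold", "severity")]
#>   rank criterion max_storage_fold min_cross_fold severity
#> 1    1 both_axes            313.2         104.13   2.2295
#> 2    2 both_axes            119.8          46.94   0.8354
#> 3    3 both_axes             80.8          24.76   0.3439
#> 4    4 both_axes             37.5          13.06   0.1636
#> 5    5 both_axes             18.9           7.35   0.0674

res <- remove_blooms(bench$cohort$tables$shipped,
                     setNames(ranked$sequence, paste0("bloom_", ranked$rank)))
res$report
#> filter_report: 5 feature(s) removed, 154,970 reads removed
#> per-sample dropped read fraction: 22.4% / 84.5% / 99.0% (25th/50th/75th percentile)
res$table
#> feature_table: 50 samples x 495 features, 95,030 reads
```

All five detected sequences are exactly the five planted blooms; each
scored >2-fold on both axes (`both_axes`), and the fold changes track
the planted growth rates (2.4 down to 1.6 doublings/day). The removal
report shows the compositional reality of shipping: the median shipped
sample loses 84.5% of its reads to five sequences.

The same workflow is available from the shell via the bundled
`exec/debloom` tool (`simulate`, `detect`, `filter`, `evaluate`
subcommands; `--help` lists options; every output carries a provenance
header with version, seed and option digest).

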