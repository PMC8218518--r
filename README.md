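# polesig

Detection of POLE-driven hypermutated tumors from RNA-seq mutational
signatures.

## What it does, and for whom

Tumors with exonuclease-domain *POLE* mutations are hypermutated, enriched
in the endometrioid histotype of ovarian cancer, and candidates for
immunotherapy — but *POLE* status is rarely assayed clinically. Their
mutations leave a highly specific fingerprint: COSMIC v2 signature 10,
dominated by TCT>TAT and TCG>TTG substitutions. `polesig` is an R package
for computational biologists who want to find these tumors using only
tumor-only bulk RNA-seq variant calls:

1. **eSNV filtering** — keep expressed SNVs with quality score > 0.1,
   depth > 10, population allele frequency < 2% (or unobserved), not in a
   panel of recurrent normal-tissue variants; capture region = positions
   at ≥ 20×, samples with < 5 Mb capture excluded;
   TMB = variants / capture bases × 10⁶.
2. **96-channel profiles** — trinucleotide-context binning with
   pyrimidine-strand collapse, fixed catalog channel order.
3. **De novo NMF** — V ≈ WH minimizing the generalized Kullback–Leibler
   divergence D(V‖WH) with Lee–Seung multiplicative updates, multi-restart,
   W columns normalized to 1 with the count scale kept in H.
4. **Catalog matching** — cosine similarity against a reference signature
   catalog; average-linkage clustering (distance 1 − cosine) orders the
   catalog.
5. **POLE calling** — per-sample signature TMB H[k,s]/capture × 10⁶;
   hypermutation outliers above the Tukey fence Q3 + 1.5·IQR (type-7
   quantiles, upper fence only); exact-allele confirmation of the POLE
   hotspots P286R, S297F, V411L, A456P.
6. **Cohort statistics** — two-sided exact Mann–Whitney and Fisher tests,
   group summaries.

A deterministic synthetic-cohort generator (reference FASTA, per-sample
VCFs, coverage, panel of normals, hotspot spikes, ground-truth manifest)
makes the whole pipeline testable end to end without external data. The
bundled signature catalog is likewise synthetic (see the vignette); real
analyses should load the genuine COSMIC v2 TSV with `read_catalog()`.

## Worked example

```r
library(polesig)

cfg <- run_config(
  seed = 1,
  simulation = default_simulation_config(seed = 1, n_background = 60,
                                         reference_length = 1e7),
  min_capture = 2e6, n_restarts = 15
)
run <- run_pipeline(cfg)
subset(run$calls, outlier,
       select = c(sample_id, pole_tmb, threshold, hotspot_labels))
```

```
   sample_id  pole_tmb threshold hotspot_labels
61        P1 74.507708  3.952693          A456P
62        P2 76.912175  3.952693          S297F
63        P3 70.169636  3.952693          V411L
64        P4 27.585684  3.952693          P286R
65        P5 21.114359  3.952693          P286R
66        P6  6.150733  3.952693          V411L
```

The six planted hypermutated samples (and only they) exceed the
cohort-derived fence of ≈ 4.0 mut/Mb, and each carries its spiked POLE
hotspot (the planted burdens were 75.2, 71.7, 64.1, 28.6, 21.6 and 5.8
mut/Mb). `run$pole$similarity` reports the cosine between the extracted
POLE-like signature and the catalog's POLE column (0.9992 here);
`run$report` holds the age (Mann–Whitney) and histology (Fisher)
comparisons between called and uncalled samples.

At full scale — `run_pipeline(run_config(seed = 1))`, 195 samples on a
30 Mb reference, ~2 minutes — the call set equals the planted set equals
the hotspot-positive set, mirroring the 6/6 concordance this assay is
designed to achieve.

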