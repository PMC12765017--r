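# caninetc

Canine thyroid carcinoma (TC) splits into two entities of different cell
origin: follicular carcinoma (FTC, thyrocyte-derived, the majority in dogs)
and medullary carcinoma (MTC, calcitonin-producing C-cell-derived). This
package implements, as tested and reusable R code, the full desk-side
analysis chain used to characterize a two-subtype canine TC cohort from
bulk RNA-seq and whole-exome sequencing:

* **Expression**: median-of-ratios normalization, TPM, low-count filtering,
  variable-gene selection, 2-D embedding + k-means subtype clustering, and
  differential-gene flagging (|log2FC| > 2, adjusted p < 0.05).
* **Signature scores**: the thyroid differentiation score
  (TDS = Σ over 16 thyroid-function genes of median-centered log2
  expression), the MAPK pathway activation score
  (MPAS = Σ z<sub>i</sub> / √n over 10 MAPK target genes), the ERK output
  score (mean z over the resolvable members of a 52-gene RAF–MEK–ERK
  signature), transcriptome-wide Spearman/Pearson correlation screens with
  BH FDR, and a pre-ranked weighted-KS enrichment statistic with
  permutation p-values.
* **Variants**: the exome somatic filter cascade (PASS ∧ not in matched
  normal ∧ not in panel-of-normals ∧ not in population germline sites), the
  RNA-seq variant rules (DP > 10, alt count > 5, no splice terms,
  0.25 ≤ AF ≤ 0.85), canonical-isoform consequence mapping, tumor
  mutational burden (non-synonymous coding variants / Mb), and oncoplot
  gene selection (recurrent cancer genes, singleton predicted drivers,
  recurrent thyroid-panel genes).
* **Mutational signatures**: 96-type trinucleotide spectra (pyrimidine
  strand convention), de novo extraction by Kullback–Leibler NMF with
  multiplicative updates and restarts, and cosine matching against a
  reference catalog with a novelty threshold.
* **Fusions**: the four artifact filters (same gene family, unofficial
  symbol, > 80% cohort frequency, present in normals), cancer-gene
  cross-referencing, and per-sample recurrence counting.
* **Ortholog mapping**: global BLOSUM62 pairwise alignment of dog/human
  protein pairs and residue-level projection of p.RefPosAlt variants onto
  the orthologous position, with concordance flags.
* **DNA repair pathways**: mapping variant genes onto MMR/BER/NER/DSBR
  sets, genotype assignment from detection sources (matched normal ⇒
  germline; tumor exome without normal ⇒ somatic; RNA only ⇒ unassigned),
  cohort burden summaries, and the MSI-score association test.
* **Clinical statistics**: exact tied Mann–Whitney on ordinal tables (full
  null distribution by dynamic programming over midranks), Kruskal–Wallis,
  Kaplan–Meier with log-rank and Cox hazard ratios, BH FDR.

A synthetic cohort generator (`cohort_config()` / `generate_cohort()` /
`write_cohort()`) reproduces the statistical structure all of these stages
assume — negative-binomial counts with planted subtype markers and a
differentiation gradient, variant sets with germline/somatic truth and
signature-driven trinucleotide contexts on a self-contained reference,
fusion calls spanning all four artifact classes, ortholog pairs with known
residue maps, and size-dependent exponential survival — so the entire
pipeline runs and is tested without access to the original sequencing
data.

## Worked example

```r
library(caninetc)

co <- generate_cohort(cohort_config(seed = 1))
em <- normalize_median_of_ratios(co$expression)
hv <- select_variable_genes(em$layers$log2, var_threshold = 1)
cl <- cluster_samples(em$layers$log2, hv, n_clusters = 3, seed = 1)
table(cl$labels, co$truth_subtype[names(cl$labels)])
#>     normal subtype1 subtype2
#>   1      5        0        0
#>   2      0        0        5
#>   3      0       25        0

som <- wes_somatic_filter(co$wes_tumor_variants,
                          germline_resources(matched_normals = co$wes_normal_variants))
compute_tmb(som[som$sample_id == "T1_01", ], megabases_sequenced = 50)
#> [1] 1.34
```

The clustering table shows perfect recovery of the two planted tumor
subtypes and the normal group; the burden value is the per-sample count of
non-synonymous somatic variants per megabase over a 50 Mb capture.

The numbered scripts under `analysis/` run the whole workflow end to end
(simulate → cluster → score → filter variants → extract signatures →
filter fusions → project ortholog positions → repair-pathway/clinical
statistics), each printing what it found and writing tables under
`results/`.

On the packaged cohort DNA-repair variant table, the pipeline reports
26 variants in 24 genes across 60% of the 30 sequenced tumors, partitioned
into 11 germline, 8 somatic and 7 unassignable calls; the exact
Mann–Whitney comparisons of the packaged clinical table give
p = 0.0015 (histologic pattern), p = 0.0015 (differentiation) and
p = 0.0007 (HER2 immunohistochemistry grade) between the two subtypes.

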