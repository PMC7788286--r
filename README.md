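# dubscreen

Analysis toolkit for pooled **in vivo shRNA dropout/enrichment screens**
in hematopoietic stem and progenitor cells, plus the **AP-MS interactome
filtering** scheme used to map a bait protein's interaction partners.

Pooled screens transduce bone-marrow progenitors with a barcoded shRNA
library at low MOI, transplant them into recipient mice, and sequence the
hairpin census before injection (T0) and in tissues harvested weeks
later. Hairpins that drop out relative to T0 implicate their target gene
in supporting stem/progenitor fitness in vivo. The statistical challenge
is that per-animal engraftment bottlenecks add biological drift on top of
PCR and sequencing noise, replicates are few, and robust gene-level calls
need more than a per-hairpin p-value.

dubscreen covers the whole desk-side workflow:

- **Simulation with ground truth** (`simulate_screen()`): plasmid pool →
  multinomial transduction (T0) → per-mouse engraftment bottleneck →
  multiplicative fitness selection `2^(fitness·efficacy·weeks)` →
  multinomial sequencing with lognormal PCR overdispersion. Every stage's
  realized state is recorded, so downstream statistics can be tested
  against known truth.
- **Deconvolution** (`build_index()`, `count_sample()`): exact-match
  assignment of reads to 21-nt hairpin keys on either strand, with strict
  ambiguity handling and read-count conservation, plus representation QC
  (`representation_stats()`).
- **Differential abundance** (`differential_table()`): log2-CPM
  normalization, PCA-based replicate outlier removal, and an
  empirical-Bayes **moderated t-test** implemented in-package — per-feature
  variances are shrunk toward a moment-matched scaled-F prior
  (s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)), and t = logFC / (s̃_g·√(1/n₁+1/n₂))
  is referred to t with d₀ + d_g df — followed by Benjamini–Hochberg FDR
  adjustment.
- **Two-tier hit calling** (`screen_hit_calls()`,
  `consolidate_screens()`): per hairpin |logFC| ≥ 1, adj. p ≤ 0.02,
  average abundance > 2.5; per gene ≥ 2 qualifying hairpins each with a
  ≥ 10-fold median change across mice; replication in ≥ 2 independent
  screens; opposite-direction genes excluded.
- **AP-MS interactome** (`interactome_analysis()`): peptide and
  valid-value filters, column-wise Gaussian-downshift imputation of
  missing intensities (N(μ − 1.8σ, (0.2σ)²)), moderated bait-vs-IgG
  enrichment at a 10% FDR tier, and cross-condition consensus at
  adj. p < 0.05 with novelty annotation against a known-interactor list.

## Worked example

Two simulated screens with two planted dropout genes (`Usp1` at
2^(−1.25·4) ≈ 32-fold, `Usp2` at ≈ 21-fold expected depletion), analyzed
end-to-end and consolidated:

```r
library(dubscreen)

lib <- synthetic_dub_library()                      # 508 hairpins, 98 test genes
eff <- planted_dropout_effects(lib, c("Usp1", "Usp2"),
                               fitness = c(-1.25, -1.1), seed = 42)

calls <- lapply(c("primary", "secondary"), function(sid) {
  sim <- simulate_screen(lib,
                         screen_sim_params(seed = substream_seed(42, sid)),
                         eff, screen_id = sid)
  screen_hit_calls(sim$counts, sid, lib)
})
names(calls) <- c("primary", "secondary")
cons <- consolidate_screens(calls)
subset(cons$genes, consolidated != "not_hit")
#>  gene_symbol consolidated n_dropout_screens supporting_screens
#>         Usp1  dropout_hit                 2  primary;secondary
#>         Usp2  dropout_hit                 2  primary;secondary
```

Both planted genes — and nothing else — come back as consolidated
dropout hits. The per-hairpin evidence behind the `Usp1` call (primary
screen differential table):

```r
tb <- attr(calls$primary, "diff_table")
subset(tb, gene_symbol == "Usp1")[, c("hairpin_id", "log_fc", "ave_abund",
                                      "adj_p", "status")]
#>  hairpin_id     log_fc ave_abund        adj_p status
#>    shUsp1#1 -1.4291207 10.398691 3.514569e-01 tested
#>    shUsp1#2 -4.9210159  6.924177 5.101194e-08 tested
#>    shUsp1#3 -4.9656651  7.157820 4.676697e-08 tested
#>    shUsp1#4 -1.6915421  9.411482 1.826082e-02 tested
#>    shUsp1#5 -0.3314724  9.745395 8.919299e-01 tested
#>    shUsp1#6 -2.3768889  7.706679 7.668254e-04 tested
```

The two fully effective hairpins (#2, #3) show ~30-fold depletion at
vanishing adjusted p; partially effective hairpins (efficacy < 1) show
correspondingly weaker log-fold changes — the heterogeneity real
knockdown reagents display. The gene call requires two such qualifying
hairpins per screen, so single-hairpin noise cannot create a hit.

A whole run can also be driven from one config through
`run_pipeline()`, which writes counts, QC, differential tables, gene
calls and a checksummed provenance manifest to an output directory.

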