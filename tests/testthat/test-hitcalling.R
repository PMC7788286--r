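fake_row <- function(log_fc, adj_p, ave = 6, status = "tested") {
  data.frame(hairpin_id = "h", gene_symbol = "G", log_fc = log_fc,
             ave_abund = ave, t_mod = 0, p_value = adj_p, adj_p = adj_p,
             status = status, stringsAsFactors = FALSE)
}

test_that("hairpin flags apply the logFC / adjusted-p / abundance gates", {
  cfg <- hit_rule_config()
  expect_identical(flag_hairpin(fake_row(-2.1, 0.001), cfg), "depleted")
  expect_identical(flag_hairpin(fake_row(2.1, 0.001), cfg), "enriched")
  expect_identical(flag_hairpin(fake_row(0, 0.0001), cfg), "ns")
  expect_identical(flag_hairpin(fake_row(-3, 0.5), cfg), "ns")
  expect_identical(flag_hairpin(fake_row(-3, 0.001, ave = 1), cfg), "ns")
  expect_true(is.na(flag_hairpin(fake_row(-3, 0.001, status = "absent"), cfg)))
  expect_error(hit_rule_config(min_shrnas = 0), "min_shrnas")
})

test_that("median fold change takes the midpoint of the middle pair", {
  expect_equal(median_fold_change(c(0.1, 0.1, 0.1)), 0.1)
  expect_equal(median_fold_change(c(0.05, 0.08, 0.5, 0.9)), 0.29)
  expect_equal(median_fold_change(0.2), 0.2)
  expect_error(median_fold_change(numeric(0)), "no fold changes")
})

# Build a differential table + median FCs directly, to exercise the gene
# rules on constructed evidence.
gene_fixture <- function(genes, log_fc, adj_p, mfc, ave = 6) {
  n <- length(genes)
  tbl <- data.frame(
    hairpin_id = paste0("hp", seq_len(n)), gene_symbol = genes,
    log_fc = log_fc, ave_abund = ave, t_mod = 0, p_value = adj_p,
    adj_p = adj_p, status = "tested", stringsAsFactors = FALSE)
  list(tbl = tbl, mfc = setNames(mfc, tbl$hairpin_id))
}

test_that("per-screen gene calls follow the two-shRNA 10-fold median rule", {
  cfg <- hit_rule_config()
  # USP15-like: 3 hairpins, all >= 15-fold depleted and significant
  fx <- gene_fixture(rep("Usp15", 3), c(-4, -4.2, -3.9), c(1e-5, 1e-4, 1e-3),
                     c(1/16, 1/15, 1/20))
  calls <- call_genes_screen(fx$tbl, fx$mfc, cfg)
  expect_identical(calls$verdict, "dropout")

  # opposite qualifying directions -> excluded
  fx2 <- gene_fixture(rep("G2", 2), c(-4, 4), c(1e-4, 1e-4), c(1/15, 15))
  expect_identical(call_genes_screen(fx2$tbl, fx2$mfc, cfg)$verdict,
                   "excluded_opposite")

  # one qualifying hairpin only -> not_hit at min_shrnas = 2
  fx3 <- gene_fixture(rep("G3", 3), c(-4, -0.2, 0.1), c(1e-4, 0.9, 0.9),
                      c(1/15, 0.9, 1.1))
  expect_identical(call_genes_screen(fx3$tbl, fx3$mfc, cfg)$verdict, "not_hit")

  # significant but median FC above 1/10 -> fails the magnitude gate
  fx4 <- gene_fixture(rep("G4", 2), c(-3, -3), c(1e-4, 1e-4), c(1/8, 1/9))
  expect_identical(call_genes_screen(fx4$tbl, fx4$mfc, cfg)$verdict, "not_hit")

  # untested gene
  fx5 <- gene_fixture("G5", NA_real_, NA_real_, NA_real_)
  fx5$tbl$status <- "absent"
  expect_identical(call_genes_screen(fx5$tbl, fx5$mfc, cfg)$verdict,
                   "untested")
})

test_that("consolidation needs two concordant screens; exclusion dominates", {
  cfg <- hit_rule_config()
  mk <- function(verdict) data.frame(gene_symbol = "G", verdict = verdict,
                                     n_tested = 3L,
                                     n_depleted_qualifying = 2L,
                                     n_enriched_qualifying = 0L,
                                     evidence = "", stringsAsFactors = FALSE)
  cons <- consolidate_screens(list(primary = mk("dropout"),
                                   secondary2 = mk("dropout")), cfg)
  expect_identical(cons$genes$consolidated, "dropout_hit")

  cons1 <- consolidate_screens(list(primary = mk("dropout"),
                                    secondary2 = mk("not_hit")), cfg)
  expect_identical(cons1$genes$consolidated, "not_hit")

  cons2 <- consolidate_screens(list(primary = mk("dropout"),
                                    secondary1 = mk("dropout"),
                                    secondary2 = mk("excluded_opposite")), cfg)
  expect_identical(cons2$genes$consolidated, "excluded")

  expect_error(consolidate_screens(list(mk("dropout"), mk("dropout")), cfg),
               "screen ids")
  expect_error(consolidate_screens(list(a = mk("dropout")), cfg),
               "at least 2")
})

test_that("overlap counts equal brute-force set intersections", {
  cfg <- hit_rule_config(min_screens = 2L)
  verd <- function(g, v) data.frame(gene_symbol = g, verdict = v,
                                    n_tested = 3L, n_depleted_qualifying = 2L,
                                    n_enriched_qualifying = 0L, evidence = "",
                                    stringsAsFactors = FALSE)
  s1 <- verd(c("A", "B", "C"), c("dropout", "dropout", "not_hit"))
  s2 <- verd(c("A", "B", "C"), c("dropout", "not_hit", "enriched"))
  s3 <- verd(c("A", "B", "C"), c("not_hit", "dropout", "enriched"))
  cons <- consolidate_screens(list(p = s1, q = s2, r = s3), cfg)
  ov <- setNames(cons$overlap$n_genes, cons$overlap$screens)
  # brute force: A hits in {p,q}; B hits in {p,r}; C hits in {q,r}
  expect_identical(unname(ov["p+q"]), 1L)
  expect_identical(unname(ov["p+r"]), 1L)
  expect_identical(unname(ov["q+r"]), 1L)
  expect_identical(sum(cons$overlap$n_genes), 3L)
})

test_that("relaxing thresholds never removes a hit (monotone configuration)", {
  lib <- synthetic_dub_library()
  panel <- planted_panel(lib)
  eff <- planted_dropout_effects(lib, panel$genes, fitness = panel$fitness,
                                 seed = 2)
  strict <- hit_rule_config()
  lax <- hit_rule_config(logfc_min = 0.5, adj_p_max = 0.05,
                         ave_abund_min = 1, fold_median_min = 5)
  g_strict <- two_screen_calls(lib, 2, eff, strict)$genes
  g_lax <- two_screen_calls(lib, 2, eff, lax)$genes
  hits_strict <- g_strict$gene_symbol[g_strict$consolidated == "dropout_hit"]
  hits_lax <- g_lax$gene_symbol[g_lax$consolidated == "dropout_hit"]
  expect_true(all(hits_strict %in% hits_lax))
  expect_gte(length(hits_strict), 8L)
})

test_that("an opposite-direction qualifying hairpin flips a hit to excluded", {
  cfg <- hit_rule_config()
  fx <- gene_fixture(rep("G", 3), c(-4, -4, -3.8), rep(1e-4, 3),
                     c(1/15, 1/16, 1/14))
  expect_identical(call_genes_screen(fx$tbl, fx$mfc, cfg)$verdict, "dropout")
  fx$tbl <- rbind(fx$tbl, gene_fixture("G", 4, 1e-4, 15)$tbl)
  fx$tbl$hairpin_id[4] <- "hp4"
  fx$mfc <- c(fx$mfc, hp4 = 15)
  expect_identical(call_genes_screen(fx$tbl, fx$mfc, cfg)$verdict,
                   "excluded_opposite")
})
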