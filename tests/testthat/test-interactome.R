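# Small constructed intensity matrix: 1 condition, 4 bait + 4 IgG samples.
toy_intensities <- function(n_prot = 6) {
  samples <- data.frame(
    sample_id = c(paste0("bait_r", 1:4), paste0("igg_r", 1:4)),
    condition = "cond1",
    group = rep(c("bait", "IgG"), each = 4),
    replicate = rep(1:4, 2), stringsAsFactors = FALSE)
  m <- matrix(rnorm(n_prot * 8, 25, 1), n_prot, 8,
              dimnames = list(paste0("P", seq_len(n_prot)),
                              samples$sample_id))
  list(m = m, samples = samples)
}

test_that("protein filtering enforces peptides and valid bait values", {
  tx <- toy_intensities()
  m <- tx$m
  m["P1", 1:2] <- NA  # only 2 valid bait values
  m["P3", ] <- NA
  m["P3", 5:8] <- 24  # IgG-only protein: 0 valid bait values
  pep <- setNames(c(5L, 1L, 4L, 2L, 3L, 5L), rownames(m))
  im <- intensity_matrix(m, pep, tx$samples)
  f <- filter_proteins(im, "cond1")
  expect_setequal(rownames(f$intensity), c("P4", "P5", "P6"))
  # P1 removed for valid values, P2 for peptides, P3 for both
  expect_false(any(c("P1", "P2", "P3") %in% rownames(f$intensity)))
})

test_that("downshift imputation has the prescribed moments and determinism", {
  set.seed(1)
  obs <- rnorm(2000, 25, 2)
  col <- c(obs, rep(NA_real_, 10000))
  done <- impute_downshift(col, seed = 7)
  expect_identical(done[seq_along(obs)], obs)
  imp <- done[-seq_along(obs)]
  mu <- mean(obs); sg <- sd(obs)
  expect_lt(abs(mean(imp) - (mu - 1.8 * sg)), 0.02 * sg * 3)
  expect_lt(abs(sd(imp) - 0.2 * sg), 0.01 * sg * 3)

  # same seed -> identical; different seed -> different
  expect_identical(impute_downshift(col, seed = 7), done)
  expect_false(identical(impute_downshift(col, seed = 8), done))

  # width 0 degenerates to the point mass
  pt <- impute_downshift(col, width = 0, seed = 7)
  expect_true(all(pt[-seq_along(obs)] == mu - 1.8 * sg))

  # no missing values -> unchanged without touching the RNG
  expect_identical(impute_downshift(obs, seed = 7), obs)
  expect_error(impute_downshift(c(25, rep(NA, 3)), seed = 1), "2 observed")
})

test_that("bait-vs-IgG enrichment finds a constructed 4v4 shift", {
  set.seed(3)
  tx <- toy_intensities(n_prot = 50)
  m <- tx$m
  m[, ] <- rnorm(length(m), 25, 0.3)
  m["P1", 1:4] <- m["P1", 1:4] + 5
  m["P2", 5:8] <- m["P2", 1:4]  # identical group means
  im <- intensity_matrix(m, setNames(rep(3L, nrow(m)), rownames(m)),
                         tx$samples)
  tb <- enrich_vs_igg(im)
  p1 <- tb[tb$protein_id == "P1", ]
  expect_lt(p1$adj_p, 0.05)
  expect_gt(p1$log_enrich, 4)
  # sanity lower bound: ordinary t on the same data is already decisive
  expect_lt(t.test(m["P1", 1:4], m["P1", 5:8], var.equal = TRUE)$p.value,
            1e-4)
  expect_false(tb$significant[tb$protein_id == "P2"])
  # the 10% FDR tier admits 0.05 <= adj_p < 0.1
  tb$adj_p[3] <- 0.08
  expect_true(tb$adj_p[3] < 0.1 && tb$adj_p[3] >= 0.05)
})

test_that("consensus is the intersection of per-condition hit sets", {
  mk <- function(ids, sig_ids) data.frame(
    protein_id = ids, log_enrich = 1, t_mod = 1, p_value = 0.5,
    adj_p = ifelse(ids %in% sig_ids, 0.01, 0.9),
    significant = ids %in% sig_ids, stringsAsFactors = FALSE)
  all_ids <- c("A", "B", "C", "D", "E")
  tables <- list(c1 = mk(all_ids, c("A", "B", "C")),
                 c2 = mk(all_ids, c("B", "C", "D")),
                 c3 = mk(all_ids, "C"),
                 c4 = mk(all_ids, c("C", "E")))
  cons <- intersect_conditions(tables)
  expect_identical(cons$protein_id, "C")

  # disjoint per-condition hits -> empty consensus
  t2 <- list(c1 = mk(all_ids, "A"), c2 = mk(all_ids, "B"))
  expect_identical(nrow(intersect_conditions(t2)), 0L)

  expect_error(intersect_conditions(tables, required = c("c1", "missing")),
               "missing required condition")

  # novelty flag against a known list
  known <- c("C", "Z")
  cons_k <- intersect_conditions(tables, known = known)
  expect_false(cons_k$novel[cons_k$protein_id == "C"])
})

test_that("consensus shrinks as thresholds tighten and conditions are added", {
  si <- simulate_interactome(n_background = 300L, n_true = 15L, seed = 4)
  ia <- interactome_analysis(si$data, seed = 4)
  tabs <- ia$per_condition
  base <- intersect_conditions(tabs, names(tabs)[1:2], consensus_p = 0.05)
  tighter <- intersect_conditions(tabs, names(tabs)[1:2], consensus_p = 0.01)
  more_cond <- intersect_conditions(tabs, names(tabs), consensus_p = 0.05)
  expect_true(all(tighter$protein_id %in% base$protein_id))
  expect_true(all(more_cond$protein_id %in% base$protein_id))
})

test_that("planted interactors are recovered across conditions", {
  si <- simulate_interactome(seed = 12)
  ia <- interactome_analysis(si$data, seed = 12)
  cons <- ia$consensus$protein_id
  tp <- sum(cons %in% si$truth)
  expect_gte(tp / length(si$truth), 0.9)
  expect_gte(tp / max(1, length(cons)), 0.9)
})

test_that("intensity matrices load from TSV with missing values intact", {
  tx <- toy_intensities()
  m <- tx$m
  m[1, 1] <- NA
  ipath <- withr::local_tempfile(fileext = ".tsv")
  lpath <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(protein_id = rownames(m), peptide_count = 3L, m,
                   check.names = FALSE)
  utils::write.table(df, ipath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tx$samples, lpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  im <- load_intensities(ipath, lpath)
  expect_true(is.na(im$intensity[1, 1]))
  expect_equal(im$intensity[-1, ], m[-1, ], tolerance = 1e-9)
})
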