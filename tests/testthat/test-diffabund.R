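test_that("log2-CPM normalization follows the pseudocounted formula", {
  m <- matrix(c(10L, 990L, 3L, 7L), 2, 2,
              dimnames = list(c("h1", "h2"), c("a", "b")))
  la <- normalize_log_cpm(m, pseudocount = 0.5)
  expect_equal(la["h1", "a"], log2(10.5 / 1001 * 1e6))
  # equal counts in a sample -> equal normalized values
  eq <- matrix(c(5L, 5L), 2, 1, dimnames = list(c("h1", "h2"), "a"))
  expect_equal(unname(diff(normalize_log_cpm(eq)[, 1])), 0)
  # scaling a deep sample leaves its column essentially unchanged (the
  # fixed pseudocount bounds the drift at ~pc/(count * ln 2))
  big <- matrix(rpois(200, 2000) + 1L, 100, 2,
                dimnames = list(paste0("h", 1:100), c("a", "b")))
  scaled <- big; scaled[, 1] <- scaled[, 1] * 10L
  d <- abs(normalize_log_cpm(big)[, 1] - normalize_log_cpm(scaled)[, 1])
  expect_lt(max(d), 1e-3)
  expect_error(normalize_log_cpm(matrix(0L, 2, 1,
                                        dimnames = list(c("h1", "h2"), "z"))),
               "all-zero")
})

test_that("PCA outlier detection flags the constructed outlier only", {
  set.seed(5)
  base <- rnorm(50, 8, 1)
  m <- sapply(1:5, function(i) base + rnorm(50, 0, 0.05))
  colnames(m) <- paste0("s", 1:5)
  # shift one sample by ~10x the replicate spread along its own direction
  m[, 5] <- m[, 5] + 0.5
  res <- pca_outliers(m, colnames(m))
  expect_identical(res$flagged, "s5")
  expect_setequal(res$retained, paste0("s", 1:4))

  # identical replicates: zero spread, nothing flagged
  ident <- matrix(rep(base, 5), ncol = 5,
                  dimnames = list(NULL, paste0("s", 1:5)))
  expect_length(pca_outliers(ident, colnames(ident))$flagged, 0L)

  # permutation invariance of the flag set
  perm <- sample(colnames(m))
  expect_setequal(pca_outliers(m[, perm], perm)$flagged, "s5")

  expect_error(pca_outliers(m[, 1:2], colnames(m)[1:2]), "at least 3")
})

test_that("moderated t matches an independent implementation to 1e-8", {
  skip_if_not_installed("limma")
  set.seed(42)
  m <- matrix(rnorm(200 * 6, 8, 1), 200, 6,
              dimnames = list(paste0("h", 1:200), paste0("s", 1:6)))
  m[1:20, 1:3] <- m[1:20, 1:3] + rnorm(60, 1, 0.5)
  mt <- moderated_t(m, test = paste0("s", 1:3), reference = paste0("s", 4:6))
  design <- cbind(Intercept = 1, grp = c(1, 1, 1, 0, 0, 0))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(mt, "df_prior"), fit$df.prior, tolerance = 1e-8)
  expect_equal(attr(mt, "s2_prior"), fit$s2.prior, tolerance = 1e-8)
  expect_lt(max(abs(mt$log_fc - fit$coefficients[, "grp"])), 1e-8)
  expect_lt(max(abs(mt$t_mod - fit$t[, "grp"])), 1e-8)
  expect_lt(max(abs(mt$p_value - fit$p.value[, "grp"])), 1e-8)
})

test_that("moderated t oracle equivalence holds on random small matrices", {
  skip_if_not_installed("limma")
  for (seed in 1:5) {
    set.seed(seed)
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    m <- matrix(rnorm(80 * (n1 + n2), 10, sample(c(0.5, 1, 2), 1)),
                80, n1 + n2,
                dimnames = list(paste0("g", 1:80),
                                paste0("s", seq_len(n1 + n2))))
    mt <- moderated_t(m, paste0("s", 1:n1), paste0("s", n1 + 1:n2))
    design <- cbind(1, c(rep(1, n1), rep(0, n2)))
    fit <- limma::eBayes(limma::lmFit(m, design))
    expect_lt(max(abs(mt$t_mod - fit$t[, 2])), 1e-8)
    expect_lt(max(abs(mt$p_value - fit$p.value[, 2])), 1e-8)
  }
})

test_that("moderated t has the right limits and symmetries", {
  set.seed(8)
  m <- matrix(rnorm(100 * 6, 8, 1), 100, 6,
              dimnames = list(paste0("h", 1:100), paste0("s", 1:6)))
  test <- paste0("s", 1:3); ref <- paste0("s", 4:6)

  # equal group means -> t = 0, p = 1
  m0 <- m
  m0[1, 4:6] <- m0[1, 1:3]
  mt0 <- moderated_t(m0, test, ref)
  expect_equal(mt0$t_mod[1], 0)
  expect_equal(mt0$p_value[1], 1)

  # prior_df = 0 -> ordinary pooled-variance two-sample t
  mt_raw <- moderated_t(m, test, ref, prior_df = 0)
  ot <- apply(m, 1, function(r)
    t.test(r[1:3], r[4:6], var.equal = TRUE)$statistic)
  expect_lt(max(abs(mt_raw$t_mod - ot)), 1e-10)

  # swapping groups negates log_fc and t, leaves p unchanged
  mt <- moderated_t(m, test, ref)
  mt_sw <- moderated_t(m, ref, test)
  expect_equal(mt_sw$log_fc, -mt$log_fc)
  expect_equal(mt_sw$t_mod, -mt$t_mod)
  expect_equal(mt_sw$p_value, mt$p_value)

  expect_error(moderated_t(m, test, test), "disjoint")
  expect_error(moderated_t(m, "s1", "s2"), "at least 3")
})

test_that("BH adjustment equals the brute-force step-up computation", {
  step_up <- function(p) {  # independent oracle, straight from the definition
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
    out <- numeric(m)
    out[o] <- q
    out
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.4), 0.4)
  for (seed in 1:10) {
    set.seed(seed)
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, step_up(p))
    expect_true(all(q >= p & q <= 1))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
    # re-adjustment never decreases values (BH dominance), and is
    # idempotent on constant vectors such as the (0.03, 0.03, 0.03) case
    expect_true(all(bh_adjust(q) >= q - 1e-12))
  }
  expect_equal(bh_adjust(c(0.03, 0.03, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("differential_table removes absent hairpins and flags outliers", {
  lib <- toy_library()
  sim <- simulate_screen(lib, small_params(seed = 6, n_mice = 4L),
                         screen_id = "s1")
  cm <- sim$counts
  cm$counts[3, ] <- 0L  # make one hairpin absent everywhere
  tbl <- differential_table(cm, "s1", lib = lib)
  expect_identical(tbl$status[3], "absent")
  expect_true(is.na(tbl$p_value[3]))
  tested <- tbl[tbl$status == "tested", ]
  expect_true(all(is.finite(tested$p_value)))
  expect_true(all(tested$adj_p >= tested$p_value))
  # adjusted p is monotone in p-rank
  o <- order(tested$p_value)
  expect_true(all(diff(tested$adj_p[o]) >= -1e-12))
})

test_that("neutral screens keep the significant fraction near nominal", {
  lib <- synthetic_dub_library()
  frac <- vapply(1:5, function(s) {
    sim <- simulate_screen(lib, screen_sim_params(seed = s), screen_id = "n")
    tbl <- differential_table(sim$counts, "n", lib = lib)
    mean(tbl$adj_p[tbl$status == "tested"] <= 0.02)
  }, numeric(1))
  expect_lt(mean(frac), 0.02 + 0.01)
})

test_that("a planted 60-fold dropout gene is recovered with high power", {
  lib <- synthetic_dub_library()
  gene <- unique(lib$gene_symbol[lib$role == "test"])[1]
  hp <- lib$hairpin_id[lib$gene_symbol == gene]
  eff <- effect_model(lib, fitness = setNames(-log2(60) / 4, gene))
  hits <- vapply(1:10, function(s) {
    sim <- simulate_screen(lib, screen_sim_params(seed = s), eff,
                           screen_id = "p")
    tbl <- differential_table(sim$counts, "p", lib = lib)
    i <- match(hp, tbl$hairpin_id)
    all(tbl$log_fc[i] <= -4 & tbl$adj_p[i] <= 0.02)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
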