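#' Log2 counts-per-million normalization with pseudocount
#'
#' `value = log2((count + pc) / (library_size + 2 * pc) * 1e6)`, computed
#' per sample on assigned reads. Zero-tolerant and (up to the fixed
#' pseudocount) invariant to rescaling a sample's counts.
#'
#' @param cm a [count_matrix()] or a plain non-negative count matrix.
#' @param pseudocount pseudocount added to each count.
#' @return A numeric matrix of log2-CPM values with the same dimnames.
#' @export
normalize_log_cpm <- function(cm, pseudocount = 0.5) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop_ds("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop_ds("all-zero sample(s): ",
            paste(colnames(counts)[lib == 0], collapse = ", "))
  log2(sweep(counts + pseudocount, 2L, lib + 2 * pseudocount, "/") * 1e6)
}

#' PCA-based replicate outlier detection
#'
#' Projects the group's samples onto the first two principal components of
#' the centered log-abundance matrix and flags samples whose Euclidean
#' distance from the group's componentwise median in PC space sits more than
#' `mad_factor` MADs above the median distance (a robust z-score on
#' distances). Deterministic given the input; invariant to sample order.
#'
#' @param m numeric matrix, features x samples.
#' @param group character vector of sample (column) names to screen.
#' @param mad_factor robust z-score threshold.
#' @return A list with `retained`, `flagged` and the per-sample `distance`.
#' @export
pca_outliers <- function(m, group = colnames(m), mad_factor = 3) {
  stopifnot(is.matrix(m))
  bad <- setdiff(group, colnames(m))
  if (length(bad)) stop_ds("unknown sample id(s): ", paste(bad, collapse = ", "))
  if (length(group) < 3L)
    stop_ds("outlier detection needs at least 3 samples")
  x <- t(m[, group, drop = FALSE])
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pr$x))
  sc <- pr$x[, seq_len(k), drop = FALSE]
  med <- apply(sc, 2L, stats::median)
  d <- sqrt(rowSums(sweep(sc, 2L, med)^2))
  s <- stats::mad(d)
  flagged <- if (s > 0) d - stats::median(d) > mad_factor * s
             else rep(FALSE, length(d))
  list(retained = group[!flagged], flagged = group[flagged],
       distance = stats::setNames(d, group))
}

# Moment-method fit of the scaled-F model for sample variances: matches the
# mean and variance of log(s^2) to the scaled F distribution via
# digamma/trigamma inversion, yielding the prior df d0 and prior variance
# s0^2 used for empirical-Bayes shrinkage.
fit_scaled_f <- function(s2, df_resid) {
  n <- length(s2)
  stopifnot(n >= 2L, length(df_resid) %in% c(1L, n))
  x <- pmax(s2, 0)
  m <- stats::median(x)
  if (m == 0) {
    warning("more than half the residual variances are zero; shrinkage unreliable")
    m <- 1
  }
  x <- pmax(x, 1e-5 * m)  # guard exact zeros before taking logs
  z <- log(x)
  e <- z - digamma(df_resid / 2) + log(df_resid / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (n - 1L) - mean(trigamma(df_resid / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- mean(x)
  }
  list(df_prior = d0, s2_prior = s0_sq)
}

# Newton inversion of the trigamma function (y = trigamma(x), solve for x).
trigamma_inverse <- function(y) {
  stopifnot(length(y) == 1L, is.finite(y))
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' Empirical-Bayes moderated two-group t-test
#'
#' For each feature the log2 fold change is `mean(test) - mean(reference)`;
#' the residual variance from the two-group model is shrunk toward a prior
#' estimated by closed-form moment matching on the log sample variances
#' (see `fit_scaled_f`): the posterior variance is
#' `(d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)` and the moderated t is the fold
#' change over its posterior standard error, referred to a t distribution
#' with `d0 + d_g` degrees of freedom.
#'
#' @param m numeric matrix of log2 abundances, features x samples.
#' @param test,reference disjoint character vectors of column names.
#' @param prior_df optional override of the estimated prior df; `0` gives
#'   the ordinary pooled-variance two-sample t-test.
#' @return A data frame with `feature_id`, `log_fc`, `ave_abund` (mean
#'   log2 abundance over the samples in the comparison), `t_mod`, `p_value`,
#'   `s2`, `df_resid`, plus attributes `df_prior` and `s2_prior`.
#' @export
moderated_t <- function(m, test, reference, prior_df = NULL) {
  stopifnot(is.matrix(m))
  if (length(intersect(test, reference)))
    stop_ds("test and reference samples must be disjoint")
  if (length(reference) == 0L || length(test) == 0L)
    stop_ds("test and reference must be non-empty")
  missing_s <- setdiff(c(test, reference), colnames(m))
  if (length(missing_s))
    stop_ds("unknown sample id(s): ", paste(missing_s, collapse = ", "))
  n1 <- length(test); n2 <- length(reference)
  if (n1 + n2 < 3L)
    stop_ds("need at least 3 samples across the two groups")
  x1 <- m[, test, drop = FALSE]; x2 <- m[, reference, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  log_fc <- m1 - m2
  ave <- rowMeans(cbind(x1, x2))
  df_resid <- n1 + n2 - 2L
  if (df_resid < 1L) stop_ds("no residual degrees of freedom")
  s2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / df_resid

  if (is.null(prior_df)) {
    fit <- fit_scaled_f(s2, df_resid)
  } else if (prior_df == 0) {
    fit <- list(df_prior = 0, s2_prior = NA_real_)
  } else if (is.infinite(prior_df)) {
    fit <- list(df_prior = Inf, s2_prior = mean(s2))
  } else {
    fit <- list(df_prior = prior_df,
                s2_prior = fit_scaled_f(s2, df_resid)$s2_prior)
  }
  d0 <- fit$df_prior; s0 <- fit$s2_prior
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2))
             else if (d0 == 0) s2
             else (d0 * s0 + df_resid * s2) / (d0 + df_resid)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, log_fc / se, ifelse(log_fc == 0, 0, sign(log_fc) * Inf))
  df_total <- min(d0 + df_resid, nrow(m) * df_resid)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(feature_id = rownames(m) %||% seq_len(nrow(m)),
                    log_fc = log_fc, ave_abund = ave, t_mod = t_mod,
                    p_value = p, s2 = s2, df_resid = df_resid,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "df_prior") <- d0
  attr(out, "s2_prior") <- s0
  attr(out, "df_total") <- df_total
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p values in (0, 1].
#' @return Adjusted p values in input order, each >= the input and <= 1,
#'   monotone non-decreasing in p-rank.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop_ds("p values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-hairpin differential abundance table for one screen/tissue comparison
#'
#' Pipeline: log2-CPM normalization over the screen's samples, removal of
#' hairpins with zero counts in every sample (reported with status
#' `"absent"`), PCA outlier removal within the test group (when it has at
#' least 3 samples), moderated t of test vs the T0 reference, and BH
#' adjustment within the comparison.
#'
#' @param cm a [count_matrix()].
#' @param screen_id screen to analyze.
#' @param tissue test tissue (`"BM"` or `"spleen"`).
#' @param pseudocount pseudocount for normalization.
#' @param mad_factor PCA outlier threshold; `NULL` disables outlier removal.
#' @param gene_map optional named vector hairpin -> gene; defaults to
#'   the library mapping carried by `lib`.
#' @param lib optional [shrna_library()] used to annotate gene symbols.
#' @return A data frame with `hairpin_id`, `gene_symbol` (if a library was
#'   given), `log_fc`, `ave_abund`, `t_mod`, `p_value`, `adj_p`, `status`;
#'   attributes `outliers` (samples removed), `test_samples`,
#'   `reference_sample`, `df_prior`, `s2_prior`.
#' @export
differential_table <- function(cm, screen_id, tissue = "BM",
                               pseudocount = 0.5, mad_factor = 3,
                               lib = NULL, gene_map = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  sheet <- cm$sheet[cm$sheet$screen_id == screen_id, , drop = FALSE]
  if (!nrow(sheet)) stop_ds("unknown screen_id: ", screen_id)
  ref <- sheet$sample_id[sheet$role == "reference"]
  test <- sheet$sample_id[sheet$role == "test" & sheet$tissue == tissue]
  if (length(test) < 2L)
    stop_ds("screen ", screen_id, " has fewer than 2 test samples in ", tissue)
  counts <- cm$counts[, c(test, ref), drop = FALSE]
  absent <- rowSums(counts) == 0L
  la <- normalize_log_cpm(counts, pseudocount = pseudocount)

  outliers <- character(0)
  if (!is.null(mad_factor) && length(test) >= 3L) {
    oc <- pca_outliers(la[!absent, , drop = FALSE], group = test,
                       mad_factor = mad_factor)
    outliers <- oc$flagged
    test <- oc$retained
  }
  if (length(test) < 2L)
    stop_ds("fewer than 2 test samples remain after outlier removal")

  mt <- moderated_t(la[!absent, , drop = FALSE], test = test, reference = ref)
  adj <- bh_adjust(mt$p_value)

  ids <- rownames(cm$counts)
  out <- data.frame(hairpin_id = ids, log_fc = NA_real_, ave_abund = NA_real_,
                    t_mod = NA_real_, p_value = NA_real_, adj_p = NA_real_,
                    status = ifelse(absent, "absent", "tested"),
                    stringsAsFactors = FALSE, row.names = NULL)
  idx <- match(mt$feature_id, ids)
  out$log_fc[idx] <- mt$log_fc
  out$ave_abund[idx] <- mt$ave_abund
  out$t_mod[idx] <- mt$t_mod
  out$p_value[idx] <- mt$p_value
  out$adj_p[idx] <- adj
  if (!is.null(lib)) gene_map <- stats::setNames(lib$gene_symbol, lib$hairpin_id)
  if (!is.null(gene_map))
    out <- cbind(out[1L], gene_symbol = unname(gene_map[out$hairpin_id]),
                 out[-1L])
  attr(out, "outliers") <- outliers
  attr(out, "test_samples") <- test
  attr(out, "reference_sample") <- ref
  attr(out, "df_prior") <- attr(mt, "df_prior")
  attr(out, "s2_prior") <- attr(mt, "s2_prior")
  out
}
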