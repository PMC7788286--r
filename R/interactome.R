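#' Protein LFQ intensity matrix for AP-MS enrichment analysis
#'
#' Log2 label-free quantification (LFQ) intensities indexed by (protein,
#' IP sample), with missing values kept as `NA`, a peptide count per
#' protein, and sample labels giving the condition (cell line x treatment)
#' and group (`bait` immunoprecipitation vs `IgG` control).
#'
#' @param intensity numeric matrix (log2 LFQ), proteins x samples, NA for
#'   missing values, with dimnames.
#' @param peptide_count named integer vector per protein.
#' @param samples data frame with columns `sample_id`, `condition`,
#'   `group` (`"bait"` or `"IgG"`) and `replicate`.
#' @return An `intensity_matrix` object.
#' @export
intensity_matrix <- function(intensity, peptide_count, samples) {
  stopifnot(is.matrix(intensity), !is.null(rownames(intensity)),
            !is.null(colnames(intensity)))
  need <- c("sample_id", "condition", "group", "replicate")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols))
    stop_ds("sample labels missing column(s): ",
            paste(missing_cols, collapse = ", "))
  if (!setequal(samples$sample_id, colnames(intensity)))
    stop_ds("sample labels and intensity columns differ")
  bad_g <- setdiff(unique(samples$group), c("bait", "IgG"))
  if (length(bad_g)) stop_ds("group must be 'bait' or 'IgG'; got: ",
                             paste(bad_g, collapse = ", "))
  both <- tapply(samples$group, samples$condition,
                 function(g) all(c("bait", "IgG") %in% g))
  if (!all(both))
    stop_ds("condition(s) lacking both bait and IgG samples: ",
            paste(names(both)[!both], collapse = ", "))
  pc <- peptide_count[rownames(intensity)]
  if (anyNA(pc)) stop_ds("peptide_count must cover every protein")
  if (any(pc < 0)) stop_ds("peptide_count must be >= 0")
  structure(list(intensity = intensity, peptide_count = pc,
                 samples = samples),
            class = "intensity_matrix")
}

#' Load an LFQ intensity matrix and sample labels from TSV
#'
#' The intensity file has columns `protein_id`, `peptide_count`, then one
#' column per IP sample (empty cells / `NA` are missing values). The label
#' file has columns `sample_id`, `condition`, `group`, `replicate`.
#'
#' @param intensity_path,labels_path file paths.
#' @return An [intensity_matrix()].
#' @export
load_intensities <- function(intensity_path, labels_path) {
  df <- read_tsv(intensity_path)
  if (!all(c("protein_id", "peptide_count") %in% names(df)))
    stop_ds("intensity file needs protein_id and peptide_count columns")
  m <- as.matrix(df[, setdiff(names(df), c("protein_id", "peptide_count")),
                    drop = FALSE])
  rownames(m) <- df$protein_id
  storage.mode(m) <- "double"
  labels <- read_tsv(labels_path)
  intensity_matrix(m, stats::setNames(as.integer(df$peptide_count),
                                      df$protein_id), labels)
}

#' Filter proteins by peptide support and valid values in the bait group
#'
#' Retains, for the given condition, proteins identified by at least
#' `min_peptides` peptides and quantified (non-missing) in at least
#' `min_valid_in_bait` bait-IP samples of that condition. Columns are
#' restricted to the condition's samples.
#'
#' @param im an [intensity_matrix()].
#' @param condition condition to analyze.
#' @param min_peptides minimum peptides per protein.
#' @param min_valid_in_bait minimum non-missing bait values.
#' @return A filtered [intensity_matrix()] restricted to the condition.
#' @export
filter_proteins <- function(im, condition, min_peptides = 2L,
                            min_valid_in_bait = 3L) {
  stopifnot(inherits(im, "intensity_matrix"))
  sm <- im$samples[im$samples$condition == condition, , drop = FALSE]
  if (!nrow(sm)) stop_ds("unknown condition: ", condition)
  bait <- sm$sample_id[sm$group == "bait"]
  keep <- im$peptide_count >= min_peptides &
    rowSums(!is.na(im$intensity[, bait, drop = FALSE])) >= min_valid_in_bait
  intensity_matrix(im$intensity[keep, sm$sample_id, drop = FALSE],
                   im$peptide_count[keep], sm)
}

#' Gaussian-downshift imputation of missing intensities
#'
#' Column-wise (per IP sample): missing entries are drawn independently
#' from `Normal(mu_obs - downshift * sd_obs, (width * sd_obs)^2)`, where
#' `mu_obs` and `sd_obs` are the column's observed mean and standard
#' deviation. Models missing-not-at-random dropout of low-abundance
#' proteins. Observed entries are untouched; the draw is deterministic
#' given the seed.
#'
#' @param x numeric matrix (or [intensity_matrix()]) with NAs, or a single
#'   numeric column.
#' @param width imputation sd as a fraction of the observed sd.
#' @param downshift shift below the observed mean, in observed-sd units.
#' @param seed integer seed (per-column substreams are derived from it).
#' @return The completed object of the same shape.
#' @export
impute_downshift <- function(x, width = 0.2, downshift = 1.8, seed = 1L) {
  if (width < 0 || downshift < 0)
    stop_ds("width and downshift must be >= 0")
  if (inherits(x, "intensity_matrix")) {
    x$intensity <- impute_downshift(x$intensity, width, downshift, seed)
    return(x)
  }
  if (is.matrix(x)) {
    for (j in seq_len(ncol(x)))
      x[, j] <- impute_column(x[, j], width, downshift,
                              substream_seed(seed, paste0("impute/",
                                                          colnames(x)[j] %||% j)))
    return(x)
  }
  impute_column(x, width, downshift, substream_seed(seed, "impute/column"))
}

impute_column <- function(col, width, downshift, seed) {
  miss <- is.na(col)
  if (!any(miss)) return(col)
  obs <- col[!miss]
  if (length(obs) < 2L)
    stop_ds("imputation needs at least 2 observed values per column")
  mu <- mean(obs); sg <- stats::sd(obs)
  col[miss] <- with_seed(seed,
    stats::rnorm(sum(miss), mean = mu - downshift * sg, sd = width * sg))
  col
}

#' Moderated enrichment of bait IPs over IgG controls for one condition
#'
#' Runs the empirical-Bayes moderated t ([moderated_t()]) of bait vs IgG on
#' a filtered, imputed condition matrix and BH-adjusts the p values. A
#' protein is flagged `significant` at the 10% FDR tier
#' (`adj_p < fdr`); the stricter per-condition consensus threshold is
#' applied later by [intersect_conditions()].
#'
#' @param im a filtered and imputed [intensity_matrix()] restricted to one
#'   condition (see [filter_proteins()], [impute_downshift()]).
#' @param fdr FDR tier for the `significant` flag.
#' @return A data frame with `protein_id`, `log_enrich`, `t_mod`,
#'   `p_value`, `adj_p`, `significant`.
#' @export
enrich_vs_igg <- function(im, fdr = 0.1) {
  stopifnot(inherits(im, "intensity_matrix"))
  if (anyNA(im$intensity))
    stop_ds("intensity matrix still contains missing values; impute first")
  cond <- unique(im$samples$condition)
  if (length(cond) != 1L)
    stop_ds("enrich_vs_igg expects a single condition; got: ",
            paste(cond, collapse = ", "))
  bait <- im$samples$sample_id[im$samples$group == "bait"]
  igg <- im$samples$sample_id[im$samples$group == "IgG"]
  if (length(bait) < 2L || length(igg) < 2L)
    stop_ds("need at least 2 bait and 2 IgG samples")
  mt <- moderated_t(im$intensity, test = bait, reference = igg)
  adj <- bh_adjust(mt$p_value)
  data.frame(protein_id = mt$feature_id, log_enrich = mt$log_fc,
             t_mod = mt$t_mod, p_value = mt$p_value, adj_p = adj,
             significant = adj < fdr, stringsAsFactors = FALSE)
}

#' Cross-condition consensus interactors
#'
#' Consensus interactors are proteins with `adj_p < consensus_p` against
#' IgG in every required condition; a protein absent from any required
#' condition's table (e.g. filtered out) cannot be consensus. A supplied
#' known-interactor list flags novelty.
#'
#' @param tables named list of [enrich_vs_igg()] data frames per condition.
#' @param required conditions that must each pass; default all supplied.
#' @param consensus_p per-condition adjusted-p threshold.
#' @param known optional character vector (or single-column file path) of
#'   known interactor protein ids.
#' @return A data frame of consensus interactors with per-condition
#'   adjusted p values and, when a known list is given, a `novel` flag.
#' @export
intersect_conditions <- function(tables, required = names(tables),
                                 consensus_p = 0.05, known = NULL) {
  if (is.null(names(tables)) || anyDuplicated(names(tables)))
    stop_ds("tables must be uniquely named by condition")
  missing_cond <- setdiff(required, names(tables))
  if (length(missing_cond))
    stop_ds("missing required condition(s): ",
            paste(missing_cond, collapse = ", "))
  hit_sets <- lapply(tables[required], function(tb)
    tb$protein_id[tb$adj_p < consensus_p])
  consensus <- Reduce(intersect, hit_sets)
  out <- data.frame(protein_id = consensus, stringsAsFactors = FALSE)
  for (cond in required)
    out[[paste0("adj_p_", cond)]] <-
      tables[[cond]]$adj_p[match(consensus, tables[[cond]]$protein_id)]
  if (!is.null(known)) {
    if (is.character(known) && length(known) == 1L && file.exists(known))
      known <- read_tsv(known)[[1L]]
    out$novel <- !(out$protein_id %in% known)
  }
  out
}

#' End-to-end interactome analysis across conditions
#'
#' For each condition: peptide/valid-value filtering, column-wise
#' Gaussian-downshift imputation, moderated bait-vs-IgG enrichment with BH
#' adjustment; then cross-condition consensus at `consensus_p`.
#'
#' @param im an [intensity_matrix()] covering all conditions.
#' @param conditions conditions to analyze; default all in the labels.
#' @param min_peptides,min_valid_in_bait see [filter_proteins()].
#' @param width,downshift,seed see [impute_downshift()].
#' @param fdr significance tier for per-condition tables.
#' @param consensus_p consensus threshold.
#' @param known optional known-interactor list (vector or file path).
#' @return A list with `per_condition` (named list of enrichment tables)
#'   and `consensus` (the [intersect_conditions()] data frame).
#' @export
interactome_analysis <- function(im, conditions = NULL, min_peptides = 2L,
                                 min_valid_in_bait = 3L, width = 0.2,
                                 downshift = 1.8, seed = 1L, fdr = 0.1,
                                 consensus_p = 0.05, known = NULL) {
  stopifnot(inherits(im, "intensity_matrix"))
  conditions <- conditions %||% unique(im$samples$condition)
  tables <- lapply(conditions, function(cond) {
    f <- filter_proteins(im, cond, min_peptides, min_valid_in_bait)
    f <- impute_downshift(f, width = width, downshift = downshift,
                          seed = substream_seed(seed, paste0("cond/", cond)))
    enrich_vs_igg(f, fdr = fdr)
  })
  names(tables) <- conditions
  list(per_condition = tables,
       consensus = intersect_conditions(tables, conditions,
                                        consensus_p = consensus_p,
                                        known = known))
}

#' Synthetic AP-MS interactome with planted true interactors
#'
#' Emulates a bait-vs-IgG AP-MS design over several conditions: background
#' proteins bind both IPs equally (log-normal abundance), planted true
#' interactors are enriched in the bait IP by `effect_log2`, and low
#' intensities drop out missing-not-at-random through a probit detection
#' model - so the IgG side of true interactors is largely missing, the
#' situation Gaussian-downshift imputation is designed for.
#'
#' @param n_background number of background proteins.
#' @param n_true number of planted true interactors.
#' @param conditions character vector of condition names.
#' @param n_rep replicates per group per condition.
#' @param effect_log2 bait-over-IgG enrichment of true interactors (log2).
#' @param base_mean,base_sd background protein abundance distribution (log2).
#' @param true_base_mean,true_base_sd abundance of true interactors in the
#'   IgG (unbound) state; kept near the detection limit.
#' @param rep_sd replicate-level measurement sd (log2).
#' @param condition_sd protein x condition abundance wobble (log2).
#' @param detect_mid,detect_scale probit detection model: an intensity x is
#'   observed with probability `pnorm((x - detect_mid) / detect_scale)`.
#' @param seed integer seed.
#' @return A list with `data` (an [intensity_matrix()]) and `truth`
#'   (character vector of true-interactor protein ids).
#' @export
simulate_interactome <- function(n_background = 1000L, n_true = 30L,
                                 conditions = c("MV4-11", "MV4-11_MMC",
                                                "Kasumi-1", "Kasumi-1_MMC"),
                                 n_rep = 4L, effect_log2 = 3,
                                 base_mean = 25, base_sd = 2,
                                 true_base_mean = 21, true_base_sd = 0.25,
                                 rep_sd = 0.3, condition_sd = 0.2,
                                 detect_mid = 21.5, detect_scale = 0.6,
                                 seed = 1L) {
  n <- n_background + n_true
  prot <- c(sprintf("BG%04d", seq_len(n_background)),
            sprintf("TRUE%03d", seq_len(n_true)))
  is_true <- c(rep(FALSE, n_background), rep(TRUE, n_true))
  samples <- do.call(rbind, lapply(conditions, function(cond)
    data.frame(sample_id = paste0(cond, "_", rep(c("bait", "IgG"), each = n_rep),
                                  "_r", rep(seq_len(n_rep), 2L)),
               condition = cond,
               group = rep(c("bait", "IgG"), each = n_rep),
               replicate = rep(seq_len(n_rep), 2L),
               stringsAsFactors = FALSE)))
  base <- with_seed(substream_seed(seed, "protein_base"), {
    b <- stats::rnorm(n, base_mean, base_sd)
    b[is_true] <- stats::rnorm(n_true, true_base_mean, true_base_sd)
    b
  })
  peptides <- with_seed(substream_seed(seed, "peptides"), {
    p <- 1L + stats::rpois(n, 2.5)
    p[is_true] <- 2L + stats::rpois(n_true, 2)
    p
  })
  intensity <- matrix(NA_real_, n, nrow(samples),
                      dimnames = list(prot, samples$sample_id))
  for (cond in conditions) {
    wobble <- with_seed(substream_seed(seed, paste0("wobble/", cond)),
                        stats::rnorm(n, 0, condition_sd))
    for (j in which(samples$condition == cond)) {
      s <- samples$sample_id[j]
      mu <- base + wobble
      if (samples$group[j] == "bait") mu <- mu + ifelse(is_true, effect_log2, 0)
      intensity[, j] <- with_seed(substream_seed(seed, paste0("sample/", s)), {
        x <- stats::rnorm(n, mu, rep_sd)
        p_obs <- stats::pnorm((x - detect_mid) / detect_scale)
        x[stats::runif(n) > p_obs] <- NA_real_
        x
      })
    }
  }
  list(data = intensity_matrix(intensity,
                               stats::setNames(peptides, prot), samples),
       truth = prot[is_true])
}
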