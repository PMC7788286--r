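#' Hit-calling thresholds
#'
#' Defaults are the stringent two-tier criteria used to call gene-level
#' screen hits: per hairpin, |log2 FC| >= 1 with BH-adjusted p <= 0.02 and
#' average log2-CPM abundance > 2.5; per gene, at least two hairpins each
#' changed by a 10-fold median across replicate mice in the same direction;
#' and replication in at least two independent screens.
#'
#' @param logfc_min minimum |log2 fold change| per hairpin.
#' @param adj_p_max maximum BH-adjusted p per hairpin.
#' @param ave_abund_min minimum average log2-CPM abundance per hairpin.
#' @param fold_median_min minimum median fold change (linear scale) per
#'   qualifying hairpin.
#' @param min_shrnas minimum qualifying hairpins per gene and screen.
#' @param min_screens minimum concordant screens for a consolidated hit.
#' @return A `hit_rule_config` list.
#' @export
hit_rule_config <- function(logfc_min = 1, adj_p_max = 0.02,
                            ave_abund_min = 2.5, fold_median_min = 10,
                            min_shrnas = 2L, min_screens = 2L) {
  cfg <- list(logfc_min = logfc_min, adj_p_max = adj_p_max,
              ave_abund_min = ave_abund_min,
              fold_median_min = fold_median_min,
              min_shrnas = as.integer(min_shrnas),
              min_screens = as.integer(min_screens))
  if (any(unlist(cfg[1:4]) <= 0) || cfg$min_shrnas < 1L || cfg$min_screens < 1L)
    stop_ds("all thresholds must be positive; min_shrnas and min_screens >= 1")
  structure(cfg, class = "hit_rule_config")
}

#' Flag hairpins as depleted / enriched / not significant
#'
#' A tested hairpin is `depleted` iff `log_fc <= -logfc_min`,
#' `adj_p <= adj_p_max` and `ave_abund > ave_abund_min`; `enriched` is
#' symmetric with `log_fc >= +logfc_min`; otherwise `ns`.
#'
#' @param tbl a [differential_table()] (rows with status `"absent"` get NA).
#' @param cfg a [hit_rule_config()].
#' @return Character vector of flags aligned to `tbl` rows.
#' @export
flag_hairpin <- function(tbl, cfg = hit_rule_config()) {
  tested <- tbl$status == "tested"
  gate <- tested & tbl$adj_p <= cfg$adj_p_max & tbl$ave_abund > cfg$ave_abund_min
  flag <- rep(NA_character_, nrow(tbl))
  flag[tested] <- "ns"
  flag[gate & tbl$log_fc <= -cfg$logfc_min] <- "depleted"
  flag[gate & tbl$log_fc >= cfg$logfc_min] <- "enriched"
  flag
}

#' Median fold change across replicate mice
#'
#' @param per_mouse_fc numeric vector of linear-scale fold changes, one per
#'   mouse (pseudocounted CPM ratio of sample over T0).
#' @return The median (midpoint of the middle pair for even n).
#' @export
median_fold_change <- function(per_mouse_fc) {
  if (!length(per_mouse_fc)) stop_ds("no fold changes supplied")
  stats::median(per_mouse_fc)
}

#' Per-mouse fold changes of each hairpin relative to T0
#'
#' Fold changes are back-transformed ratios of pseudocounted log2-CPM:
#' `2^(logCPM_mouse - logCPM_T0)` per hairpin.
#'
#' @param cm a [count_matrix()].
#' @param screen_id screen to use.
#' @param tissue test tissue.
#' @param samples optional subset of test samples (e.g. after outlier
#'   removal); defaults to all test samples of the tissue.
#' @param pseudocount pseudocount for normalization.
#' @return A numeric matrix, hairpins x mice, of linear fold changes.
#' @export
per_mouse_fold_changes <- function(cm, screen_id, tissue = "BM",
                                   samples = NULL, pseudocount = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  sheet <- cm$sheet[cm$sheet$screen_id == screen_id, , drop = FALSE]
  ref <- sheet$sample_id[sheet$role == "reference"]
  test <- samples %||% sheet$sample_id[sheet$role == "test" &
                                         sheet$tissue == tissue]
  la <- normalize_log_cpm(cm$counts[, c(test, ref), drop = FALSE],
                          pseudocount = pseudocount)
  fc <- 2^(la[, test, drop = FALSE] - la[, ref])
  colnames(fc) <- test
  fc
}

#' Per-screen gene verdicts
#'
#' A gene is a per-screen `dropout` iff at least `min_shrnas` of its
#' hairpins are flagged depleted, each with a median fold change across mice
#' of at most `1/fold_median_min`; `enriched` is symmetric (median fold
#' change at least `fold_median_min`). A gene with at least one qualifying
#' hairpin in each direction is `excluded_opposite`. Genes with no tested
#' hairpin are `untested`; everything else is `not_hit`.
#'
#' @param tbl a [differential_table()] with a `gene_symbol` column.
#' @param median_fc named numeric vector of per-hairpin median fold changes
#'   (linear scale), e.g. row medians of [per_mouse_fold_changes()].
#' @param cfg a [hit_rule_config()].
#' @return A data frame with `gene_symbol`, `verdict`, counts of qualifying
#'   hairpins, and a semicolon-joined `evidence` column listing supporting
#'   hairpins with their median FC and adjusted p.
#' @export
call_genes_screen <- function(tbl, median_fc, cfg = hit_rule_config()) {
  if (is.null(tbl$gene_symbol) || anyNA(tbl$gene_symbol))
    stop_ds("every hairpin must be mapped to a gene")
  flag <- flag_hairpin(tbl, cfg)
  mfc <- median_fc[tbl$hairpin_id]
  dep_q <- !is.na(flag) & flag == "depleted" & !is.na(mfc) &
    mfc <= 1 / cfg$fold_median_min
  enr_q <- !is.na(flag) & flag == "enriched" & !is.na(mfc) &
    mfc >= cfg$fold_median_min
  genes <- unique(tbl$gene_symbol)
  res <- lapply(genes, function(g) {
    i <- which(tbl$gene_symbol == g)
    tested <- sum(tbl$status[i] == "tested")
    nd <- sum(dep_q[i]); ne <- sum(enr_q[i])
    verdict <- if (tested == 0L) "untested"
    else if (nd >= 1L && ne >= 1L) "excluded_opposite"
    else if (nd >= cfg$min_shrnas) "dropout"
    else if (ne >= cfg$min_shrnas) "enriched"
    else "not_hit"
    support <- i[dep_q[i] | enr_q[i]]
    evidence <- paste(sprintf("%s(medianFC=%.3g,adj_p=%.2g)",
                              tbl$hairpin_id[support], mfc[support],
                              tbl$adj_p[support]), collapse = ";")
    data.frame(gene_symbol = g, verdict = verdict, n_tested = tested,
               n_depleted_qualifying = nd, n_enriched_qualifying = ne,
               evidence = evidence, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' One-call per-screen hit analysis
#'
#' Convenience wrapper: differential table, per-mouse fold changes on the
#' retained (non-outlier) samples, and per-screen gene verdicts.
#'
#' @inheritParams differential_table
#' @param cfg a [hit_rule_config()].
#' @return The [call_genes_screen()] data frame, with the differential table
#'   attached as attribute `diff_table`.
#' @export
screen_hit_calls <- function(cm, screen_id, lib, tissue = "BM",
                             cfg = hit_rule_config(), pseudocount = 0.5,
                             mad_factor = 3) {
  tbl <- differential_table(cm, screen_id, tissue = tissue,
                            pseudocount = pseudocount,
                            mad_factor = mad_factor, lib = lib)
  fc <- per_mouse_fold_changes(cm, screen_id, tissue = tissue,
                               samples = attr(tbl, "test_samples"),
                               pseudocount = pseudocount)
  mfc <- apply(fc, 1L, median_fold_change)
  calls <- call_genes_screen(tbl, mfc, cfg)
  attr(calls, "diff_table") <- tbl
  calls
}

#' Consolidate per-screen verdicts across independent screens
#'
#' A gene is a consolidated `dropout_hit` (resp. `enriched_hit`) iff at
#' least `min_screens` screens give that same per-screen verdict; any
#' `excluded_opposite` verdict in any screen dominates and marks the gene
#' `excluded`. Also returns Venn-style overlap counts of per-screen hits.
#'
#' @param calls named list of [call_genes_screen()] data frames, one per
#'   screen; names are screen ids and must be unique.
#' @param cfg a [hit_rule_config()].
#' @return A list with `genes` (consolidated verdict per gene with the
#'   supporting screens) and `overlap` (hit counts per screen combination).
#' @export
consolidate_screens <- function(calls, cfg = hit_rule_config()) {
  if (length(calls) < 2L) stop_ds("need at least 2 screens")
  if (is.null(names(calls)) || anyDuplicated(names(calls)))
    stop_ds("duplicate or missing screen ids")
  screens <- names(calls)
  genes <- sort(unique(unlist(lapply(calls, `[[`, "gene_symbol"))))
  verdict_of <- function(scr, g) {
    tb <- calls[[scr]]
    v <- tb$verdict[match(g, tb$gene_symbol)]
    ifelse(is.na(v), "untested", v)
  }
  per_screen <- sapply(screens, function(s) verdict_of(s, genes))
  if (is.null(dim(per_screen)))
    per_screen <- matrix(per_screen, nrow = length(genes),
                         dimnames = list(NULL, screens))
  n_drop <- rowSums(per_screen == "dropout")
  n_enr <- rowSums(per_screen == "enriched")
  any_excl <- rowSums(per_screen == "excluded_opposite") > 0L
  consolidated <- ifelse(any_excl, "excluded",
                  ifelse(n_drop >= cfg$min_screens, "dropout_hit",
                  ifelse(n_enr >= cfg$min_screens, "enriched_hit", "not_hit")))
  support <- vapply(seq_along(genes), function(i) {
    hit_scr <- screens[per_screen[i, ] %in% c("dropout", "enriched")]
    paste(hit_scr, collapse = ";")
  }, character(1))
  gene_df <- data.frame(gene_symbol = genes, consolidated = consolidated,
                        n_dropout_screens = n_drop,
                        n_enriched_screens = n_enr,
                        supporting_screens = support,
                        stringsAsFactors = FALSE)
  gene_df <- cbind(gene_df, as.data.frame(per_screen,
                                          stringsAsFactors = FALSE))

  # Venn-style overlap of per-screen hit sets (dropout or enriched)
  hit_mat <- per_screen %in% c("dropout", "enriched")
  dim(hit_mat) <- dim(per_screen)
  combo <- apply(hit_mat, 1L, function(r)
    paste(screens[r], collapse = "+"))
  combo <- combo[nzchar(combo)]
  tab <- table(combo)
  overlap <- data.frame(screens = names(tab), n_genes = as.integer(tab),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(genes = gene_df, overlap = overlap)
}
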