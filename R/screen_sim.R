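#' Simulation parameters for an in vivo pooled shRNA screen
#'
#' Defaults mirror the screen design being emulated: ~1e6 transduced
#' lineage-negative cells injected per mouse (about 2,000-fold coverage of a
#' 508-hairpin pool), low-MOI transduction so each cell carries one hairpin,
#' five replicate recipient mice, a four-week in vivo window, and an
#' engraftment bottleneck in which a fraction of the injected cells seeds
#' hematopoiesis in each recipient.
#'
#' @param n_cells_transduced number of transduced cells in the T0 input.
#' @param moi multiplicity of infection, in (0, 1); recorded for provenance
#'   (the transduced cell number is given directly).
#' @param plasmid_abundance_sd sd of per-hairpin plasmid abundance, log2 units.
#' @param engraftment_fraction fraction of injected cells that engraft each
#'   mouse, in (0, 1].
#' @param n_mice number of replicate recipient mice.
#' @param weeks weeks of in vivo growth before harvest.
#' @param reads_per_sample sequencing depth per sample.
#' @param pcr_overdispersion sd (the lognormal sigma parameter, natural-log
#'   units) of the per-hairpin PCR amplification factor applied before read
#'   sampling.
#' @param include_spleen also simulate a spleen sample per mouse (an
#'   independent second bottleneck from the same T0 population).
#' @param seed integer seed; all per-sample randomness is derived from it
#'   via named substreams.
#' @return A `screen_sim_params` list.
#' @export
screen_sim_params <- function(n_cells_transduced = 1e6, moi = 0.3,
                              plasmid_abundance_sd = 0.5,
                              engraftment_fraction = 0.1, n_mice = 5L,
                              weeks = 4L, reads_per_sample = 2e6,
                              pcr_overdispersion = 0.25,
                              include_spleen = FALSE, seed = 1L) {
  p <- list(n_cells_transduced = n_cells_transduced, moi = moi,
            plasmid_abundance_sd = plasmid_abundance_sd,
            engraftment_fraction = engraftment_fraction,
            n_mice = as.integer(n_mice), weeks = weeks,
            reads_per_sample = reads_per_sample,
            pcr_overdispersion = pcr_overdispersion,
            include_spleen = isTRUE(include_spleen), seed = as.integer(seed))
  if (p$n_cells_transduced <= 0 || p$n_mice <= 0 || p$weeks <= 0 ||
      p$reads_per_sample <= 0)
    stop_ds("n_cells_transduced, n_mice, weeks and reads_per_sample must be positive")
  if (p$moi <= 0 || p$moi >= 1) stop_ds("moi must be in (0, 1)")
  if (p$engraftment_fraction <= 0 || p$engraftment_fraction > 1)
    stop_ds("engraftment_fraction must be in (0, 1]")
  if (p$plasmid_abundance_sd < 0 || p$pcr_overdispersion < 0)
    stop_ds("plasmid_abundance_sd and pcr_overdispersion must be >= 0")
  structure(p, class = "screen_sim_params")
}

#' Per-gene fitness effects with per-hairpin knockdown efficacy
#'
#' Fitness is the log2 change in relative abundance per week conferred by
#' knocking the gene down (negative values model dropout of cells carrying
#' the hairpin, positive values enrichment). Each hairpin scales the gene
#' effect by an efficacy in \[0, 1\], modeling heterogeneous knockdown
#' potency across hairpins targeting the same gene.
#'
#' @param lib an [shrna_library()].
#' @param fitness named numeric vector of log2-per-week fitness effects,
#'   indexed by gene symbol; genes not named are neutral (0).
#' @param efficacy named numeric vector in \[0, 1\] indexed by hairpin id;
#'   hairpins not named get efficacy 1.
#' @return An `effect_model` list with full per-gene and per-hairpin vectors.
#' @export
effect_model <- function(lib, fitness = NULL, efficacy = NULL) {
  genes <- unique(lib$gene_symbol)
  f <- stats::setNames(rep(0, length(genes)), genes)
  if (!is.null(fitness)) {
    unknown <- setdiff(names(fitness), genes)
    if (length(unknown))
      stop_ds("fitness given for gene(s) not in the library: ",
              paste(unknown, collapse = ", "))
    f[names(fitness)] <- fitness
  }
  e <- stats::setNames(rep(1, nrow(lib)), lib$hairpin_id)
  if (!is.null(efficacy)) {
    unknown <- setdiff(names(efficacy), lib$hairpin_id)
    if (length(unknown))
      stop_ds("efficacy given for hairpin(s) not in the library: ",
              paste(unknown, collapse = ", "))
    if (any(efficacy < 0 | efficacy > 1))
      stop_ds("efficacy must be in [0, 1]")
    e[names(efficacy)] <- efficacy
  }
  if (any(!is.finite(f))) stop_ds("fitness must be finite")
  structure(list(fitness = f, efficacy = e), class = "effect_model")
}

#' Plant dropout effects on a set of genes
#'
#' Convenience constructor for simulation studies: the named genes get the
#' given per-week fitness, with `n_effective` of their hairpins at full
#' efficacy and the rest at low efficacy drawn uniformly from
#' \[0, `weak_max`\]; everything else is neutral.
#'
#' @param lib an [shrna_library()].
#' @param genes character vector of genes to plant.
#' @param fitness log2-per-week fitness, a scalar or one value per planted
#'   gene.
#' @param n_effective number of fully effective hairpins per planted gene.
#' @param weak_max efficacy ceiling for the remaining hairpins.
#' @param seed integer seed used to pick the effective hairpins.
#' @return An [effect_model()].
#' @export
planted_dropout_effects <- function(lib, genes, fitness = -1,
                                    n_effective = 2L, weak_max = 0.5,
                                    seed = 1L) {
  stopifnot(all(genes %in% lib$gene_symbol),
            length(fitness) %in% c(1L, length(genes)))
  fitness <- rep_len(fitness, length(genes))
  eff <- stats::setNames(rep(1, nrow(lib)), lib$hairpin_id)
  with_seed(substream_seed(seed, "planted_efficacies"), {
    for (g in genes) {
      hp <- lib$hairpin_id[lib$gene_symbol == g]
      strong <- sample(hp, min(n_effective, length(hp)))
      weak <- setdiff(hp, strong)
      eff[weak] <- stats::runif(length(weak), 0, weak_max)
    }
  })
  effect_model(lib, fitness = stats::setNames(fitness, genes),
               efficacy = eff)
}

#' Simulate an in vivo pooled shRNA screen with known ground truth
#'
#' The generative pipeline is: (i) plasmid pool proportions are lognormal in
#' log2 with sd `plasmid_abundance_sd`; (ii) the T0 input is a multinomial
#' draw of `n_cells_transduced` cells from the plasmid proportions; (iii)
#' each mouse engrafts a multinomial bottleneck of
#' `n_cells_transduced * engraftment_fraction` cells drawn from the T0 cell
#' proportions; (iv) selection multiplies each hairpin's proportion by
#' `2^(fitness * efficacy * weeks)` and renormalizes; (v) sequencing draws
#' `reads_per_sample` reads multinomially from proportions perturbed by
#' per-hairpin lognormal PCR factors. Spleen samples, when requested, are an
#' independent second bottleneck from the same T0 followed by the same
#' selection and sequencing.
#'
#' @param lib an [shrna_library()].
#' @param params a [screen_sim_params()].
#' @param effects an [effect_model()]; default all-neutral.
#' @param screen_id screen label used in sample ids and the sample sheet.
#' @param format `"counts"` returns a [count_matrix()] directly; `"fastq"`
#'   additionally writes one FASTQ per sample into `outdir`.
#' @param outdir output directory for FASTQ files (format `"fastq"`).
#' @param layout a [read_layout()] used when writing FASTQ.
#' @return A list with `counts` (a [count_matrix()]), `sheet` (sample
#'   sheet data frame), `truth` (a `screen_truth` list holding the planted
#'   per-gene direction and magnitude, per-hairpin effective fitness,
#'   realized pre-sequencing cell counts and post-selection proportions)
#'   and, for FASTQ output, `fastq` (named file paths).
#' @export
simulate_screen <- function(lib, params = screen_sim_params(),
                            effects = effect_model(lib),
                            screen_id = "primary",
                            format = c("counts", "fastq"), outdir = NULL,
                            layout = read_layout()) {
  format <- match.arg(format)
  stopifnot(inherits(lib, "shrna_library"),
            inherits(params, "screen_sim_params"),
            inherits(effects, "effect_model"))
  missing_genes <- setdiff(unique(lib$gene_symbol), names(effects$fitness))
  if (length(missing_genes))
    stop_ds("effect model is missing gene(s): ",
            paste(missing_genes, collapse = ", "))
  n <- nrow(lib)
  ids <- lib$hairpin_id
  sub <- function(label) substream_seed(params$seed, paste0(screen_id, "/", label))

  fit_hp <- effects$fitness[lib$gene_symbol] * effects$efficacy[ids]
  growth <- 2^(fit_hp * params$weeks)

  p0 <- with_seed(sub("plasmid_pool"), {
    w <- 2^stats::rnorm(n, 0, params$plasmid_abundance_sd)
    w / sum(w)
  })

  # sequencing: lognormal per-hairpin PCR factor, then multinomial reads
  seq_reads <- function(prop, label) {
    with_seed(sub(paste0("seq/", label)), {
      pcr <- stats::rlnorm(n, 0, params$pcr_overdispersion)
      q <- prop * pcr
      stats::rmultinom(1L, params$reads_per_sample, q / sum(q))[, 1L]
    })
  }

  t0_cells <- with_seed(sub("T0_cells"),
                        stats::rmultinom(1L, params$n_cells_transduced, p0)[, 1L])
  t0_prop <- t0_cells / sum(t0_cells)

  n_engraft <- max(1L, round(params$n_cells_transduced * params$engraftment_fraction))
  bottleneck <- function(label) {
    # engraftment_fraction 1 is the no-bottleneck limit: the whole T0
    # population engrafts rather than being resampled
    if (params$engraftment_fraction == 1) return(t0_cells)
    with_seed(sub(paste0("engraft/", label)),
              stats::rmultinom(1L, n_engraft, t0_prop)[, 1L])
  }
  select_prop <- function(cells) {
    w <- cells * growth
    if (sum(w) <= 0) stop_ds("selection annihilated the population")
    w / sum(w)
  }

  tissues <- c("BM", if (params$include_spleen) "spleen")
  sample_ids <- c(paste0(screen_id, "_plasmid"), paste0(screen_id, "_T0"),
                  unlist(lapply(tissues, function(ts)
                    paste0(screen_id, "_", ts, "_m", seq_len(params$n_mice)))))
  counts <- matrix(0L, n, length(sample_ids),
                   dimnames = list(ids, sample_ids))
  cells <- matrix(NA_integer_, n, 0, dimnames = list(ids, NULL))
  sel_prop <- matrix(NA_real_, n, 0, dimnames = list(ids, NULL))

  counts[, 1L] <- seq_reads(p0, "plasmid")
  counts[, 2L] <- seq_reads(t0_prop, "T0")
  cells <- cbind(cells, T0 = t0_cells)
  for (ts in tissues) {
    for (m in seq_len(params$n_mice)) {
      lab <- paste0(ts, "_m", m)
      b <- bottleneck(lab)
      pr <- select_prop(b)
      counts[, paste0(screen_id, "_", lab)] <- seq_reads(pr, lab)
      cells <- cbind(cells, b)
      colnames(cells)[ncol(cells)] <- lab
      sel_prop <- cbind(sel_prop, pr)
      colnames(sel_prop)[ncol(sel_prop)] <- lab
    }
  }

  sheet <- data.frame(
    sample_id = sample_ids,
    screen_id = screen_id,
    mouse_id = c("pool", "pool",
                 unlist(lapply(tissues, function(ts) paste0("m", seq_len(params$n_mice))))),
    tissue = c("plasmid", "T0",
               unlist(lapply(tissues, function(ts) rep(ts, params$n_mice)))),
    role = c("test", "reference",
             rep("test", length(tissues) * params$n_mice)),
    stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)

  direction <- ifelse(effects$fitness < 0, "dropout",
                      ifelse(effects$fitness > 0, "enriched", "neutral"))
  truth <- structure(list(
    gene = data.frame(gene_symbol = names(effects$fitness),
                      fitness = unname(effects$fitness),
                      direction = unname(direction),
                      expected_fold_change = unname(2^(effects$fitness * params$weeks)),
                      stringsAsFactors = FALSE, row.names = NULL),
    hairpin = data.frame(hairpin_id = ids, gene_symbol = lib$gene_symbol,
                         efficacy = unname(effects$efficacy[ids]),
                         fitness_per_week = unname(fit_hp),
                         stringsAsFactors = FALSE, row.names = NULL),
    plasmid_proportions = stats::setNames(p0, ids),
    cells = cells, selected_proportions = sel_prop),
    class = "screen_truth")

  cm <- count_matrix(counts, unassigned = stats::setNames(rep(0L, ncol(counts)),
                                                          sample_ids),
                     sheet = sheet)
  out <- list(counts = cm, sheet = sheet, truth = truth)
  if (format == "fastq") {
    if (is.null(outdir)) stop_ds("outdir is required for format = 'fastq'")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- stats::setNames(file.path(outdir, paste0(sample_ids, ".fastq")),
                             sample_ids)
    for (s in sample_ids)
      write_fastq(counts[, s], lib, paths[[s]], layout = layout,
                  seed = sub(paste0("fastq/", s)))
    out$fastq <- paths
  }
  out
}

#' Read layout for synthetic FASTQ
#'
#' Each synthetic read is `flank5 | 21-nt hairpin key | flank3` with constant
#' Phred+33 qualities; an optional uniform substitution error rate corrupts
#' bases independently.
#'
#' @param flank5,flank3 constant vector sequences flanking the hairpin key.
#' @param error_rate per-base substitution probability in \[0, 1).
#' @return A `read_layout` list.
#' @export
read_layout <- function(flank5 = "TTTGTACACCGGT", flank3 = "CTCGAGTACTTCGA",
                        error_rate = 0) {
  stopifnot(error_rate >= 0, error_rate < 1)
  if (grepl("[^ACGT]", paste0(flank5, flank3)))
    stop_ds("flanks must be DNA over A/C/G/T")
  structure(list(flank5 = flank5, flank3 = flank3, error_rate = error_rate),
            class = "read_layout")
}

#' Write per-hairpin counts as a synthetic FASTQ file
#'
#' Emits exactly `counts[h]` reads per hairpin, each embedding the hairpin's
#' 21-nt key at a fixed offset inside the layout's constant flanks, with
#' constant base qualities.
#'
#' @param counts named non-negative integer vector indexed by hairpin id.
#' @param lib an [shrna_library()] supplying the 21-nt keys.
#' @param path output FASTQ path (".gz" suffix compresses).
#' @param layout a [read_layout()].
#' @param seed seed for the substitution-error stream (needed when
#'   `layout$error_rate > 0`).
#' @return The path, invisibly.
#' @export
write_fastq <- function(counts, lib, path, layout = read_layout(), seed = 1L) {
  stopifnot(inherits(lib, "shrna_library"))
  counts <- counts[lib$hairpin_id]
  counts[is.na(counts)] <- 0L
  if (any(counts < 0)) stop_ds("counts must be non-negative")
  keys <- rep(lib$target_seq, counts)
  owners <- rep(lib$hairpin_id, counts)
  reads <- paste0(layout$flank5, keys, layout$flank3)
  if (layout$error_rate > 0 && length(reads)) {
    reads <- with_seed(seed, mutate_reads(reads, layout$error_rate))
  }
  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- sprintf("read%06d %s", seq_along(dna),
                        if (length(dna)) owners else character(0))
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(dna)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

# Uniform substitution errors: each base independently replaced by one of
# the three other bases with probability `rate`.
mutate_reads <- function(reads, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    ch <- strsplit(r, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
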