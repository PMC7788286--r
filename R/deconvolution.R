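#' Hairpin count matrix
#'
#' Integer read counts indexed by (hairpin, sample), together with the
#' per-sample count of reads that matched no hairpin and the sample sheet.
#' The hairpin index always equals the library's full hairpin set; zeros are
#' kept. Per sample, assigned + unassigned equals the total reads processed.
#'
#' @param counts integer matrix, hairpins x samples, with dimnames.
#' @param unassigned named integer vector of unassigned read counts.
#' @param sheet sample sheet data frame (see [load_sample_sheet()]).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, unassigned, sheet) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop_ds("counts must be non-negative")
  sheet <- validate_sample_sheet(sheet)
  if (!setequal(colnames(counts), sheet$sample_id))
    stop_ds("count matrix columns and sample sheet sample_ids differ")
  unassigned <- unassigned[colnames(counts)]
  if (anyNA(unassigned)) stop_ds("unassigned must cover every sample")
  structure(list(counts = counts, unassigned = unassigned, sheet = sheet),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "hairpins x", ncol(x$counts),
      "samples\n")
  cat("screens:", paste(unique(x$sheet$screen_id), collapse = ", "), "\n")
  invisible(x)
}

#' Exact-match index over hairpin keys
#'
#' Builds a matching index over each hairpin's 21-nt key and its reverse
#' complement. Two hairpins sharing a key on either strand are a collision
#' and rejected at build time.
#'
#' @param lib an [shrna_library()].
#' @return An `shrna_index` object.
#' @export
build_index <- function(lib) {
  stopifnot(inherits(lib, "shrna_library"))
  keys <- Biostrings::DNAStringSet(lib$target_seq)
  names(keys) <- lib$hairpin_id
  rc <- Biostrings::reverseComplement(keys)
  all_keys <- c(as.character(keys), as.character(rc))
  owner <- rep(lib$hairpin_id, 2L)
  by_key <- split(owner, all_keys)
  clash <- Filter(function(h) length(unique(h)) > 1L, by_key)
  if (length(clash))
    stop_ds("key collision between hairpins: ",
            paste(vapply(clash, function(h)
              paste(unique(h), collapse = " and "), character(1)),
              collapse = "; "))
  structure(list(keys = keys, rc = rc, hairpin_id = lib$hairpin_id,
                 width = 21L),
            class = "shrna_index")
}

# Structural FASTQ validation: 4-line records, '@' sequence header,
# '+' separator. Gives record-numbered errors; sequence parsing itself is
# delegated to Biostrings.
check_fastq_structure <- function(path) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop_ds("malformed FASTQ ", path, ": truncated record ",
            length(lines) %/% 4L + 1L)
  if (length(lines)) {
    rec_at <- seq(1L, length(lines), by = 4L)
    bad <- which(!startsWith(lines[rec_at], "@") |
                   !startsWith(lines[rec_at + 2L], "+"))
    if (length(bad))
      stop_ds("malformed FASTQ ", path, ": record ", bad[1L],
              " lacks '@'/'+' markers")
  }
  length(lines) %/% 4L
}

#' Count hairpins in one FASTQ sample
#'
#' A read is assigned to a hairpin iff exactly one hairpin key occurs as a
#' substring of the read on either strand; reads hitting zero or more than
#' one distinct hairpin (and reads shorter than the key) are counted as
#' unassigned. Assigned + unassigned always equals the total reads.
#'
#' @param fastq path to a FASTQ file (optionally gzipped).
#' @param index an [build_index()] result.
#' @return A list with `counts` (named integer vector over all hairpins),
#'   `unassigned` and `total`.
#' @export
count_sample <- function(fastq, index) {
  stopifnot(inherits(index, "shrna_index"))
  n_rec <- check_fastq_structure(fastq)
  ids <- index$hairpin_id
  nh <- length(ids)
  counts <- stats::setNames(integer(nh), ids)
  if (n_rec == 0L)
    return(list(counts = counts, unassigned = 0L, total = 0L))
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  total <- length(reads)
  ok <- Biostrings::width(reads) >= index$width
  reads <- reads[ok]
  if (length(reads)) {
    hit_f <- Biostrings::vwhichPDict(Biostrings::PDict(index$keys), reads)
    hit_r <- Biostrings::vwhichPDict(Biostrings::PDict(index$rc), reads)
    read_i <- c(rep(seq_along(reads), lengths(hit_f)),
                rep(seq_along(reads), lengths(hit_r)))
    hp_i <- c(unlist(hit_f), unlist(hit_r))
    if (length(read_i)) {
      keep <- !duplicated(read_i * (nh + 1) + hp_i)  # distinct (read, hairpin)
      read_i <- read_i[keep]; hp_i <- hp_i[keep]
      per_read <- tabulate(read_i, nbins = length(reads))
      uniq <- per_read[read_i] == 1L
      counts <- counts + stats::setNames(
        tabulate(hp_i[uniq], nbins = nh), ids)
    }
  }
  assigned <- sum(counts)
  list(counts = counts, unassigned = as.integer(total - assigned),
       total = as.integer(total))
}

#' Deconvolve a set of per-sample FASTQ files into a count matrix
#'
#' @param fastq_files named character vector of FASTQ paths; names are
#'   sample ids matching the sample sheet.
#' @param lib an [shrna_library()].
#' @param sheet sample sheet covering exactly these samples.
#' @return A [count_matrix()].
#' @export
count_samples <- function(fastq_files, lib, sheet) {
  index <- build_index(lib)
  if (is.null(names(fastq_files)) || any(!nzchar(names(fastq_files))))
    stop_ds("fastq_files must be named by sample_id")
  counts <- matrix(0L, nrow(lib), length(fastq_files),
                   dimnames = list(lib$hairpin_id, names(fastq_files)))
  unassigned <- stats::setNames(integer(length(fastq_files)), names(fastq_files))
  for (s in names(fastq_files)) {
    res <- count_sample(fastq_files[[s]], index)
    counts[, s] <- res$counts
    unassigned[[s]] <- res$unassigned
  }
  count_matrix(counts, unassigned, sheet)
}

#' Library-representation QC
#'
#' Per sample, the fraction of library hairpins detected with at least one
#' assigned read; optionally, for given sample pairs, the squared Pearson
#' correlation of `log2(count + 0.5)` across all hairpins (the statistic
#' behind plasmid-vs-T0 and BM-vs-spleen concordance checks).
#'
#' @param cm a [count_matrix()].
#' @param pairs optional data frame with columns `sample_a`, `sample_b`.
#' @return A list with `fraction_detected` (data frame per sample) and, if
#'   pairs were given, `r_squared` (data frame per pair).
#' @export
representation_stats <- function(cm, pairs = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  frac <- data.frame(
    sample_id = colnames(cm$counts),
    fraction_detected = colMeans(cm$counts >= 1L),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(fraction_detected = frac)
  if (!is.null(pairs)) {
    bad <- setdiff(unique(c(pairs$sample_a, pairs$sample_b)),
                   colnames(cm$counts))
    if (length(bad))
      stop_ds("unknown sample id(s): ", paste(bad, collapse = ", "))
    r2 <- mapply(function(a, b) {
      stats::cor(log2(cm$counts[, a] + 0.5), log2(cm$counts[, b] + 0.5))^2
    }, pairs$sample_a, pairs$sample_b)
    out$r_squared <- data.frame(sample_a = pairs$sample_a,
                                sample_b = pairs$sample_b,
                                r_squared = unname(r2),
                                stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Write / read a count matrix as TSV
#'
#' Rows are hairpins plus a final `"unassigned"` row; columns are samples.
#'
#' @param cm a [count_matrix()].
#' @param path output TSV path.
#' @return `write_counts`: the path, invisibly. `read_counts`: a
#'   [count_matrix()].
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- rbind(cm$counts, unassigned = cm$unassigned)
  df <- data.frame(hairpin_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_counts
#' @param sheet sample sheet for the samples in the file.
#' @export
read_counts <- function(path, sheet) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$hairpin_id
  storage.mode(m) <- "integer"
  if (!"unassigned" %in% rownames(m))
    stop_ds("count file lacks the 'unassigned' row: ", path)
  ua <- m["unassigned", ]
  m <- m[rownames(m) != "unassigned", , drop = FALSE]
  count_matrix(m, ua, sheet)
}
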