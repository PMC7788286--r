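#' shRNA library objects
#'
#' An `shrna_library` is a validated data frame with one row per hairpin and
#' columns `hairpin_id`, `gene_symbol`, `target_seq` (the 21-nt sense target
#' sequence), `pools` (comma-joined subset of `FULL`, `DUB1`, `DUB2`) and
#' `role` (`test`, `positive_control` or `neutral_control`). Unknown extra
#' columns from vendor exports are preserved but ignored.
#'
#' @param records data frame with at least the columns above.
#' @param name library name, stored as an attribute.
#' @return A validated `shrna_library` (a data frame subclass).
#' @export
shrna_library <- function(records, name = "library") {
  validate_library(records)
  rownames(records) <- records$hairpin_id
  structure(records, name = name, class = c("shrna_library", "data.frame"))
}

LIBRARY_COLUMNS <- c("hairpin_id", "gene_symbol", "target_seq", "pools", "role")
POOL_NAMES <- c("FULL", "DUB1", "DUB2")
HAIRPIN_ROLES <- c("test", "positive_control", "neutral_control")

validate_library <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_ds("no records in library")
  missing_cols <- setdiff(LIBRARY_COLUMNS, names(records))
  if (length(missing_cols))
    stop_ds("library is missing required column(s): ",
            paste(missing_cols, collapse = ", "))
  dup <- records$hairpin_id[duplicated(records$hairpin_id)]
  if (length(dup))
    stop_ds("duplicate hairpin_id: ", paste(unique(dup), collapse = ", "))
  bad <- which(nchar(records$target_seq) != 21L |
                 grepl("[^ACGT]", records$target_seq))
  if (length(bad))
    stop_ds("invalid target_seq (must be 21 nt over A/C/G/T) at library row ",
            paste(bad, collapse = ", "), " (file line ",
            paste(bad + 1L, collapse = ", "), ")")
  dup_seq <- records$target_seq[duplicated(records$target_seq)]
  if (length(dup_seq))
    stop_ds("duplicate target_seq shared by multiple hairpins: ",
            paste(unique(dup_seq), collapse = ", "))
  bad_role <- setdiff(unique(records$role), HAIRPIN_ROLES)
  if (length(bad_role))
    stop_ds("unknown hairpin role(s): ", paste(bad_role, collapse = ", "))
  pl <- pools_list(records$pools)
  empty <- which(lengths(pl) == 0L)
  if (length(empty))
    stop_ds("empty pools field at library row ", paste(empty, collapse = ", "))
  bad_pool <- setdiff(unique(unlist(pl)), POOL_NAMES)
  if (length(bad_pool))
    stop_ds("unknown pool(s): ", paste(bad_pool, collapse = ", "))
  invisible(records)
}

pools_list <- function(pools) {
  lapply(strsplit(as.character(pools), ","), function(x) trimws(x[nzchar(trimws(x))]))
}

#' Load an shRNA library from a TSV file
#'
#' Expects a tab-separated file with header columns `hairpin_id`,
#' `gene_symbol`, `target_seq`, `pools`, `role` (extra columns are kept).
#' Duplicate hairpin ids or target sequences, bad sequence alphabet/length
#' and empty files are rejected with informative errors.
#'
#' @param path path to the library TSV.
#' @param name library name; defaults to the file name.
#' @return An [shrna_library()].
#' @export
load_library <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop_ds("library file not found: ", path)
  records <- tryCatch(read_tsv(path), error = function(e)
    stop_ds("cannot read library file ", path, ": ", conditionMessage(e)))
  if (nrow(records) == 0L) stop_ds("no records in library file ", path)
  shrna_library(records, name = name)
}

#' Write an shRNA library to TSV
#'
#' @param lib an [shrna_library()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_library <- function(lib, path) {
  write_tsv(as.data.frame(lib), path)
}

#' Load or validate a sample sheet
#'
#' A sample sheet maps each sequenced sample to its screen, replicate mouse
#' and tissue. Columns: `sample_id`, `screen_id`, `mouse_id` (or `"pool"`),
#' `tissue` (`plasmid`, `T0`, `BM` or `spleen`) and `role` (`reference` for
#' the T0 input, `test` otherwise). Each screen must have exactly one
#' reference sample.
#'
#' @param path path to the sample sheet TSV.
#' @return A validated data frame.
#' @export
load_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_ds("sample sheet not found: ", path)
  validate_sample_sheet(read_tsv(path))
}

SHEET_COLUMNS <- c("sample_id", "screen_id", "mouse_id", "tissue", "role")
TISSUES <- c("plasmid", "T0", "BM", "spleen")

#' @rdname load_sample_sheet
#' @param sheet a data frame to validate in place of a file.
#' @export
validate_sample_sheet <- function(sheet) {
  missing_cols <- setdiff(SHEET_COLUMNS, names(sheet))
  if (length(missing_cols))
    stop_ds("sample sheet is missing column(s): ",
            paste(missing_cols, collapse = ", "))
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup))
    stop_ds("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  bad_t <- setdiff(unique(sheet$tissue), TISSUES)
  if (length(bad_t))
    stop_ds("unknown tissue(s): ", paste(bad_t, collapse = ", "))
  bad_r <- setdiff(unique(sheet$role), c("reference", "test"))
  if (length(bad_r))
    stop_ds("unknown role(s): ", paste(bad_r, collapse = ", "))
  nref <- tapply(sheet$role == "reference", sheet$screen_id, sum)
  off <- names(nref)[nref != 1L]
  if (length(off))
    stop_ds("each screen needs exactly one reference (T0) sample; violated by screen(s): ",
            paste(off, collapse = ", "))
  sheet
}

#' Split a library into DUB1/DUB2 sub-pools
#'
#' Divides the test hairpins of a library into two sub-pools according to a
#' per-gene assignment, mirroring the primary/secondary screen design in
#' which a full pool is split into two mostly non-overlapping sub-libraries.
#' Control hairpins (positive and neutral) are carried into both sub-pools.
#'
#' @param lib an [shrna_library()].
#' @param assignment named character vector mapping every test gene to
#'   `"DUB1"`, `"DUB2"` or `"both"`. Defaults to the assignment encoded in
#'   the library's own `pools` column.
#' @return A list with elements `DUB1` and `DUB2` (both `shrna_library`),
#'   plus an `overlap` attribute listing genes present in both sub-pools.
#' @export
split_pools <- function(lib, assignment = pool_assignment(lib)) {
  test_genes <- unique(lib$gene_symbol[lib$role == "test"])
  missing_genes <- setdiff(test_genes, names(assignment))
  if (length(missing_genes))
    stop_ds("unassigned test gene(s): ", paste(missing_genes, collapse = ", "))
  bad <- setdiff(unique(assignment), c("DUB1", "DUB2", "both"))
  if (length(bad))
    stop_ds("invalid sub-pool assignment value(s): ", paste(bad, collapse = ", "))
  is_ctrl <- lib$role != "test"
  take <- function(pool) {
    genes <- names(assignment)[assignment %in% c(pool, "both")]
    keep <- is_ctrl | lib$gene_symbol %in% genes
    sub <- as.data.frame(lib)[keep, , drop = FALSE]
    sub$pools <- vapply(pools_list(sub$pools), function(p)
      paste(union(p, pool), collapse = ","), character(1))
    shrna_library(sub, name = paste0(attr(lib, "name"), "_", pool))
  }
  out <- list(DUB1 = take("DUB1"), DUB2 = take("DUB2"))
  attr(out, "overlap") <- sort(names(assignment)[assignment == "both"])
  out
}

#' @rdname split_pools
#' @export
pool_assignment <- function(lib) {
  test <- lib[lib$role == "test", , drop = FALSE]
  pl <- pools_list(test$pools)
  per_gene <- tapply(seq_len(nrow(test)), test$gene_symbol, function(i)
    unique(unlist(pl[i])))
  vapply(per_gene, function(p) {
    in1 <- "DUB1" %in% p; in2 <- "DUB2" %in% p
    if (in1 && in2) "both" else if (in1) "DUB1" else if (in2) "DUB2"
    else stop_ds("test gene without a DUB1/DUB2 pool assignment in 'pools' column")
  }, character(1))
}
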