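#' Run the screen workflow end-to-end with plain-file handoff
#'
#' Wires the stages together: `simulate` (synthetic screens to count
#' matrices), `count` (deconvolve FASTQ when simulation emitted reads;
#' otherwise pass counts through), `qc` (representation stats), `test`
#' (differential tables per screen), `call_hits` (per-screen verdicts and
#' cross-screen consolidation). Stage outputs are TSV files in
#' `config$outdir`; a JSON provenance manifest records the seed, a config
#' hash and the MD5 of every artifact, making reruns verifiable.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   `outdir`; `seed`; `library` (path to a library TSV or `"synthetic"`);
#'   `screens` (list of per-screen blocks with `screen_id` and optional
#'   [screen_sim_params()] overrides); optional `hits` block of
#'   [hit_rule_config()] overrides; optional `sim` block (e.g.
#'   `format: fastq`).
#' @param stages ordered subset of
#'   `c("simulate", "count", "qc", "test", "call_hits")`; must be
#'   prefix-closed with respect to data dependencies (later stages may also
#'   find their inputs as files from an earlier run in the same outdir).
#' @return Invisibly, a list with the manifest and the per-stage outputs.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "count", "qc", "test",
                                    "call_hits")) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$outdir))
  known_stages <- c("simulate", "count", "qc", "test", "call_hits")
  stages <- match.arg(stages, known_stages, several.ok = TRUE)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  lib <- if (is.null(config$library) || identical(config$library, "synthetic"))
    synthetic_dub_library() else load_library(config$library)
  lib_path <- file.path(outdir, "library.tsv")
  write_library(lib, lib_path)

  screens <- config$screens %||% list(list(screen_id = "primary"),
                                      list(screen_id = "secondary"))
  screen_ids <- vapply(screens, function(s) s$screen_id, character(1))
  fmt <- config$sim$format %||% "counts"
  outputs <- list()

  counts_path <- function(sid) file.path(outdir, paste0("counts_", sid, ".tsv"))
  sheet_path <- function(sid) file.path(outdir, paste0("samples_", sid, ".tsv"))
  diff_path <- function(sid) file.path(outdir, paste0("diff_", sid, ".tsv"))

  if ("simulate" %in% stages) {
    for (s in screens) {
      pars <- s[setdiff(names(s), c("screen_id", "effects"))]
      pars$seed <- pars$seed %||% substream_seed(seed, s$screen_id)
      params <- do.call(screen_sim_params, pars)
      eff <- if (is.null(s$effects)) effect_model(lib) else
        effect_model(lib, fitness = unlist(s$effects))
      sim <- simulate_screen(lib, params, eff, screen_id = s$screen_id,
                             format = fmt,
                             outdir = if (fmt == "fastq")
                               file.path(outdir, "fastq") else NULL)
      write_tsv(sim$sheet, sheet_path(s$screen_id))
      if (fmt == "counts")
        write_counts(sim$counts, counts_path(s$screen_id))
      outputs$simulate[[s$screen_id]] <- sim
    }
  }

  load_cm <- function(sid) {
    if (!file.exists(counts_path(sid)))
      stop_ds("missing artifact for screen ", sid, ": ", counts_path(sid),
              " (run the 'simulate'/'count' stages first)")
    read_counts(counts_path(sid), load_sample_sheet(sheet_path(sid)))
  }

  if ("count" %in% stages && fmt == "fastq") {
    for (sid in screen_ids) {
      sheet <- load_sample_sheet(sheet_path(sid))
      files <- stats::setNames(
        file.path(outdir, "fastq", paste0(sheet$sample_id, ".fastq")),
        sheet$sample_id)
      missing_fq <- files[!file.exists(files)]
      if (length(missing_fq))
        stop_ds("missing FASTQ artifact(s): ",
                paste(missing_fq, collapse = ", "))
      cm <- count_samples(files, lib, sheet)
      write_counts(cm, counts_path(sid))
      outputs$count[[sid]] <- cm
    }
  }

  if ("qc" %in% stages) {
    qc <- do.call(rbind, lapply(screen_ids, function(sid) {
      st <- representation_stats(load_cm(sid))$fraction_detected
      st$screen_id <- sid
      st
    }))
    write_tsv(qc, file.path(outdir, "representation_qc.tsv"))
    outputs$qc <- qc
  }

  if ("test" %in% stages) {
    for (sid in screen_ids) {
      tbl <- differential_table(load_cm(sid), sid, tissue = "BM", lib = lib)
      write_tsv(tbl, diff_path(sid))
      outputs$test[[sid]] <- tbl
    }
  }

  if ("call_hits" %in% stages) {
    cfg <- do.call(hit_rule_config, config$hits %||% list())
    for (sid in screen_ids)
      if (!file.exists(diff_path(sid)))
        stop_ds("missing artifact: differential table ", diff_path(sid),
                " (run the 'test' stage first)")
    calls <- lapply(screen_ids, function(sid)
      screen_hit_calls(load_cm(sid), sid, lib, cfg = cfg))
    names(calls) <- screen_ids
    cons <- consolidate_screens(calls, cfg)
    for (sid in screen_ids)
      write_tsv(calls[[sid]], file.path(outdir, paste0("gene_calls_", sid, ".tsv")))
    write_tsv(cons$genes, file.path(outdir, "hits.tsv"))
    write_tsv(cons$overlap, file.path(outdir, "hit_overlap.tsv"))
    outputs$call_hits <- cons
  }

  manifest <- write_manifest(outdir, seed, config)
  invisible(list(manifest = manifest, outputs = outputs))
}

# Provenance manifest: seed, config hash, MD5 of every artifact in outdir.
write_manifest <- function(outdir, seed, config) {
  cfg_file <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_file))
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  files <- setdiff(list.files(outdir, recursive = TRUE),
                   "manifest.json")
  sums <- tools::md5sum(file.path(outdir, files))
  manifest <- list(
    package = "dubscreen",
    version = as.character(utils::packageVersion("dubscreen")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    artifacts = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Verify a pipeline output directory against its manifest
#'
#' Recomputes the MD5 checksum of every artifact recorded in
#' `manifest.json` and reports mismatches (tampered or regenerated files)
#' and missing files.
#'
#' @param outdir pipeline output directory.
#' @return A list with `ok` (logical), `mismatched` and `missing`.
#' @export
verify_manifest <- function(outdir) {
  path <- file.path(outdir, "manifest.json")
  if (!file.exists(path)) stop_ds("no manifest.json in ", outdir)
  manifest <- jsonlite::read_json(path)
  files <- names(manifest$artifacts)
  exists <- file.exists(file.path(outdir, files))
  sums <- tools::md5sum(file.path(outdir, files[exists]))
  recorded <- unlist(manifest$artifacts[exists])
  mism <- files[exists][sums != recorded]
  list(ok = all(exists) && length(mism) == 0L,
       mismatched = mism, missing = files[!exists])
}
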