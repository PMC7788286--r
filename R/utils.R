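# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a global seed and a label
#'
#' All randomness in the package flows from a single integer seed; each
#' random stage (a simulated sample, an imputed column) draws from its own
#' substream whose seed is a deterministic function of the global seed and
#' a human-readable label. Keeps whole-pipeline runs reproducible while
#' allowing stages to be generated independently.
#'
#' @param seed integer global seed.
#' @param label character scalar naming the substream.
#' @return An integer seed between 0 and 2^31 - 2.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  codes <- utf8ToInt(label)
  h <- 0
  for (ch in codes) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

# Run code under a given seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = NA, ...)
}

write_tsv <- function(x, path, row_names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

stop_ds <- function(...) stop(..., call. = FALSE)
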