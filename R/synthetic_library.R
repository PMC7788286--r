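#' Synthetic DUB-like shRNA library
#'
#' Builds a synthetic 508-hairpin library with the same shape as a pooled
#' deubiquitinase (DUB) knockdown library: 98 test genes carrying three to
#' six hairpins each (490 test hairpins), four positive-control genes
#' targeting known HSC regulators (Bmi1, Brca1, Brca2, Cdkn1a; 13 hairpins)
#' and five neutral scramble hairpins. Test genes are split between the
#' DUB1 and DUB2 sub-pools (every 20th gene is placed in both, so the
#' sub-pools are mostly non-overlapping); control hairpins belong to both
#' sub-pools. Target sequences are random unique 21-mers. The gene identities
#' are synthetic stand-ins, not the published library.
#'
#' @param seed integer seed controlling hairpin counts per gene and target
#'   sequences; the default yields the packaged reference library.
#' @return An [shrna_library()] with 508 rows.
#' @export
synthetic_dub_library <- function(seed = 20201L) {
  genes <- c(paste0("Usp", c(1:8, 10:54)), "Usp9x",
             paste0("Otud", c("1", "3", "4", "5", "6a", "6b", "7a", "7b")),
             "Uchl1", "Uchl3", "Uchl5", "Bap1", "Otub1", "Otub2",
             "Atxn3", "Atxn3l", "Josd1", "Josd2", "Stambp", "Stambpl1",
             "Brcc3", "Mysm1", "Mpnd", "Zranb1", "Vcpip1", "Cyld",
             "Tnfaip3", "Eif3f", "Eif3h", "Cops5", "Cops6", "Psmd7",
             "Psmd14", "Prpf8", "Mindy1", "Mindy2", "Mindy3", "Mindy4",
             "Zup1", "Pan2", "Ataxin2l", "Otulin", "Fam63c", "Alg13")
  stopifnot(length(genes) == 98L)
  with_seed(seed, {
    # per-gene hairpin counts in 3..6 summing to 490
    sizes <- sample(3:6, length(genes), replace = TRUE)
    excess <- sum(sizes) - 490L
    while (excess != 0L) {
      i <- sample(length(sizes), 1L)
      if (excess > 0L && sizes[i] > 3L) { sizes[i] <- sizes[i] - 1L; excess <- excess - 1L }
      if (excess < 0L && sizes[i] < 6L) { sizes[i] <- sizes[i] + 1L; excess <- excess + 1L }
    }
    ctrl_genes <- c("Bmi1", "Brca1", "Brca2", "Cdkn1a")
    ctrl_sizes <- c(4L, 3L, 3L, 3L)
    n_scr <- 5L
    total <- sum(sizes) + sum(ctrl_sizes) + n_scr
    seqs <- unique_21mers(total)
    gene_symbol <- c(rep(genes, sizes), rep(ctrl_genes, ctrl_sizes),
                     rep("Scramble", n_scr))
    role <- c(rep("test", sum(sizes)),
              rep("positive_control", sum(ctrl_sizes)),
              rep("neutral_control", n_scr))
    idx <- unlist(lapply(c(sizes, ctrl_sizes, n_scr), seq_len))
    hairpin_id <- paste0("sh", gene_symbol, "#", idx)
    hairpin_id[gene_symbol == "Scramble"] <-
      paste0("shScr#", seq_len(n_scr))
    sub <- rep(c("DUB1", "DUB2"), length.out = length(genes))
    sub[seq(20, length(genes), by = 20)] <- "both"
    names(sub) <- genes
    pools <- c(
      vapply(rep(genes, sizes), function(g)
        if (sub[[g]] == "both") "FULL,DUB1,DUB2" else paste0("FULL,", sub[[g]]),
        character(1)),
      rep("FULL,DUB1,DUB2", sum(ctrl_sizes) + n_scr))
    shrna_library(
      data.frame(hairpin_id = hairpin_id, gene_symbol = gene_symbol,
                 target_seq = seqs, pools = unname(pools), role = role,
                 stringsAsFactors = FALSE),
      name = "synthetic_dub_508")
  })
}

# Random unique 21-nt sequences whose reverse complements are also distinct
# from every other key (so the matching index has no strand collisions).
unique_21mers <- function(n) {
  out <- character(0)
  seen <- character(0)  # holds accepted keys and their reverse complements
  while (length(out) < n) {
    k <- (n - length(out)) + 16L
    cand <- apply(matrix(sample(c("A", "C", "G", "T"), 21L * k, replace = TRUE),
                         ncol = 21L), 1L, paste, collapse = "")
    rc <- revcomp_chr(cand)
    for (i in seq_along(cand)) {
      if (length(out) >= n) break
      if (cand[i] %in% seen || rc[i] %in% seen || cand[i] == rc[i]) next
      out <- c(out, cand[i])
      seen <- c(seen, cand[i], rc[i])
    }
  }
  out
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
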