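# Small in-code fixtures shared across tests.

# A 10-hairpin toy library: 3 test genes (3/3/2 hairpins), one positive
# control, one scramble.
toy_library <- function() {
  seqs <- c("ACGTACGTACGTACGTACGTA", "TGCATGCATGCATGCATGCAT",
            "AAGGCCTTAAGGCCTTAAGGC", "CCGGAATTCCGGAATTCCGGA",
            "GGATCCGGATCCGGATCCGGA", "TTCAGTTCAGTTCAGTTCAGT",
            "CATGCCATGGCATGCCATGGC", "GAATTCGAATTCGAATTCGAA",
            "CTTAAGCTTAAGCTTAAGCTT", "AGCTTAGCTTAGCTTAGCTTA")
  shrna_library(data.frame(
    hairpin_id = paste0("sh", c("GeneA#1", "GeneA#2", "GeneA#3",
                                "GeneB#1", "GeneB#2", "GeneB#3",
                                "GeneC#1", "GeneC#2", "Bmi1#1", "Scr#1")),
    gene_symbol = c(rep("GeneA", 3), rep("GeneB", 3), rep("GeneC", 2),
                    "Bmi1", "Scramble"),
    target_seq = seqs,
    pools = c(rep("FULL,DUB1", 3), rep("FULL,DUB2", 3), rep("FULL,DUB1", 2),
              "FULL,DUB1,DUB2", "FULL,DUB1,DUB2"),
    role = c(rep("test", 8), "positive_control", "neutral_control"),
    stringsAsFactors = FALSE), name = "toy")
}

toy_sheet <- function(screen_id = "s1", n_mice = 3) {
  data.frame(
    sample_id = c(paste0(screen_id, "_T0"),
                  paste0(screen_id, "_BM_m", seq_len(n_mice))),
    screen_id = screen_id,
    mouse_id = c("pool", paste0("m", seq_len(n_mice))),
    tissue = c("T0", rep("BM", n_mice)),
    role = c("reference", rep("test", n_mice)),
    stringsAsFactors = FALSE)
}

# Fast small-scale screen parameters for property tests.
small_params <- function(seed, n_mice = 3L, ...) {
  screen_sim_params(n_cells_transduced = 2e4, reads_per_sample = 5e4,
                    n_mice = n_mice, seed = seed, ...)
}

# Two full-scale screens -> consolidated gene table (used by the
# calibration and recovery tests).
two_screen_calls <- function(lib, seed, effects, cfg = hit_rule_config()) {
  calls <- lapply(c("screen1", "screen2"), function(sid) {
    p <- screen_sim_params(seed = substream_seed(seed, sid))
    sim <- simulate_screen(lib, p, effects, screen_id = sid)
    screen_hit_calls(sim$counts, sid, lib, cfg = cfg)
  })
  names(calls) <- c("screen1", "screen2")
  consolidate_screens(calls, cfg)
}

# Planted dropout genes spanning the validated-hit magnitude range
# (20- to 60-fold over the in vivo window).
planted_panel <- function(lib, n_genes = 10L) {
  genes <- unique(lib$gene_symbol[lib$role == "test"])[seq_len(n_genes)]
  folds <- exp(seq(log(20), log(60), length.out = n_genes))
  list(genes = genes, fitness = -log2(folds) / 4)
}
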