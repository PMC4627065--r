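# Shared fixture builders.  Everything is generated in code at test time;
# callers are responsible for seeding.

# plant an IUPAC word into a fraction of sequences (uniform position/strand)
plant_motif <- function(seqs, word, frac) {
  idx <- which(stats::runif(length(seqs)) < frac)
  m <- nchar(word)
  for (i in idx) {
    inst <- coldcis:::instantiate_iupac(word)
    if (stats::runif(1) < 0.5) inst <- iupac_revcomp(inst)
    pos <- sample.int(nchar(seqs[i]) - m + 1L, 1L)
    substr(seqs[i], pos, pos + m - 1L) <- inst
  }
  seqs
}

# independent per-sequence containment oracle (PCRE, both strands)
iupac_regex <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                 S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
                 D = "[AGT]", H = "[ACT]", V = "[ACG]")
regex_contains <- function(seqs, word) {
  pat <- paste(iupac_regex[strsplit(word, "")[[1L]]], collapse = "")
  rc <- paste(iupac_regex[strsplit(iupac_revcomp(word), "")[[1L]]], collapse = "")
  grepl(pat, seqs) | grepl(rc, seqs)
}

# three mean-zero mutually orthogonal 16-condition patterns, 100 genes each
orthogonal_profiles <- function(noise_sd = 0.2) {
  pat <- rbind(c(rep(1, 8), rep(-1, 8)),
               c(rep(1, 4), rep(-1, 4), rep(1, 4), rep(-1, 4)),
               rep(c(1, -1), 8)) * 2
  x <- pat[rep(1:3, each = 100), ] + stats::rnorm(4800, 0, noise_sd)
  rownames(x) <- sprintf("g%03d", 1:300)
  x
}

# a hand-sized count table: counts is a genes x libraries matrix
manual_counts <- function(counts, lengths = rep(1000, nrow(counts))) {
  rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  count_table(counts, lengths)
}

# minimal rpkm_table constructed directly (for arithmetic tests)
manual_rpkm <- function(rpkm, tissue, temperature) {
  structure(list(rpkm = rpkm, gene_id = rownames(rpkm),
                 gene_length = rep(1000, nrow(rpkm)),
                 tissue = tissue, temperature = temperature,
                 library_totals = rep(1e6, ncol(rpkm))),
            class = "rpkm_table")
}

# The end-to-end runs here use a compact configuration so the whole file
# stays in tens of seconds: 800 genes, 1e6-read libraries, k = 20.
small_pipeline_config <- function(seed) {
  pipeline_config(
    sim = sim_config(n_genes = 800, library_size = 1e6, dispersion = 0.005,
                     cluster_specs = list(
                       list(id = "K0", n = 80,
                            pattern = setNames(rep(2, 8),
                                               paste0(c("br", "gi", "he", "in",
                                                        "ki", "li", "mu", "sp"),
                                                      "_10"))),
                       list(id = "K1", n = 80,
                            pattern = setNames(rep(-2, 8),
                                               paste0(c("br", "gi", "he", "in",
                                                        "ki", "li", "mu", "sp"),
                                                      "_10")))),
                     motif_specs = list(
                       list(cluster = "K0", consensus = "TGACGTCA",
                            freq = 0.5, background = 0.03)),
                     go_specs = list(
                       list(term = "GO:SYN0001", size = 40,
                            length_biased = FALSE, cluster = "K0",
                            overlap = 20),
                       list(term = "GO:SYN0002", size = 40,
                            length_biased = FALSE, cluster = NA, overlap = 0)),
                     seed = seed),
    k = 20, min_len = 5, max_len = 8, beam = 5, max_motifs = 2,
    db_n_null = 2000, seed = seed)
}
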