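test_that("promoter extraction is strand-aware and truncates at contig ends", {
  set.seed(1)
  chr <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
               collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  bed <- data.frame(
    chrom = "chr1",
    start = c(5000L, 3000L, 300L, 0L, 9990L),
    end = c(5100L, 5001L, 400L, 50L, 10000L),
    name = c("plus", "minus", "trunc", "zero", "edge"),
    score = 0L,
    strand = c("+", "-", "+", "+", "-"))
  warns <- capture_warnings(pr <- extract_promoters(genome, bed, window = 1000))
  expect_true(any(grepl("zero-length", warns)))
  # plus-strand TSS 5000 -> bases 4000..4999 (0-based)
  expect_identical(unname(pr["plus"]), substr(chr, 4001, 5000))
  # minus-strand TSS = end - 1 = 5000 -> revcomp of bases 5001..6000
  expect_identical(unname(pr["minus"]),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(substr(chr, 5002, 6001)))))
  # plus-strand TSS 300 -> 300 bp truncated window
  expect_identical(unname(pr["trunc"]), substr(chr, 1, 300))
  expect_identical(nchar(unname(pr["trunc"])), 300L)
  # minus-strand TSS 9999 -> nothing left of the contig -> excluded
  expect_false("zero" %in% names(pr))
  expect_false("edge" %in% names(pr))
  expect_error(extract_promoters(genome, transform(bed, strand = "?")),
               "unknown strand")
})

test_that("promoter extraction round-trips the synthetic genome annotation", {
  cfg <- sim_config(n_genes = 30, library_size = 5e4, seed = 9)
  cx <- generate_counts(cfg)
  pr <- generate_promoters(cx$truth, cfg)
  genome <- Biostrings::DNAStringSet(pr$genome)
  extracted <- extract_promoters(genome, pr$bed, window = 1000)
  expect_identical(unname(extracted[names(pr$promoters)]),
                   unname(pr$promoters))
})

test_that("IUPAC containment follows code sets and masked bases never match", {
  expect_true(seq_contains("ACGT", "CGT"))
  expect_false(seq_contains("TTTT", "ACG"))
  expect_true(seq_contains("CGTA", "TACG"))       # via reverse complement
  expect_false(seq_contains("CGTA", "TACG", both_strands = FALSE))
  expect_true(seq_contains("AGAAACCA", "AGMAACCA"))  # M = A or C
  expect_false(seq_contains("ANGT", "ANG"))          # N in sequence matches nothing
  expect_error(seq_contains("ACGT", "AXG"), "invalid IUPAC")
  expect_error(seq_contains("ACGT", ""), "empty")
})

test_that("containment counts agree with a per-sequence regex oracle", {
  set.seed(21)
  for (i in 1:50) {
    seqs <- coldcis:::random_dna(20, 120)
    word <- paste(sample(names(iupac_regex), sample(3:8, 1), replace = TRUE),
                  collapse = "")
    expect_identical(seq_contains(seqs, word), regex_contains(seqs, word),
                     label = word)
  }
  set.seed(22)
  pos <- plant_motif(coldcis:::random_dna(15, 100), "TGACGTCA", 1)
  neg <- coldcis:::random_dna(25, 100)
  cc <- containment_counts("TGACGTCA", pos, neg)
  expect_identical(unname(cc["pos_with"]), unname(cc["pos_total"]))
  zero <- containment_counts("TGACGTCATTT", neg, neg)
  expect_identical(unname(zero[c("pos_with", "neg_with")]), c(0L, 0L))
})

test_that("one-sided motif P is the hypergeometric upper tail", {
  expect_equal(fisher_motif_pvalue(0, 10, 5, 100), 1)
  # exhaustive summation oracle over sampled margins up to 200
  set.seed(23)
  for (i in 1:200) {
    pt <- sample(1:200, 1); nt <- sample(1:200, 1)
    pw <- sample(0:pt, 1); nw <- sample(0:nt, 1)
    k <- pw + nw
    xs <- max(0, k - nt):min(k, pt)
    lp <- lchoose(pt, xs) + lchoose(nt, k - xs) - lchoose(pt + nt, k)
    oracle <- sum(exp(lp)[xs >= pw])
    expect_equal(fisher_motif_pvalue(pw, pt, nw, nt), oracle,
                 tolerance = 1e-10)
  }
  expect_error(fisher_motif_pvalue(-1, 10, 0, 10), "non-negative")
  expect_error(fisher_motif_pvalue(11, 10, 0, 10), "exceed")
})

test_that("E-values scale P by the candidate count and never fall below P", {
  expect_equal(evalue(1e-6, 1e4), 0.01)
  expect_equal(evalue(0.2, 1), 0.2)
  set.seed(24)
  p <- runif(100); n <- sample(1:1e6, 100)
  expect_true(all(evalue(p, n) >= p))
  expect_error(evalue(0.5, 0), ">= 1")
})

test_that("the top exact seed equals exhaustive enumeration on a small fixture", {
  set.seed(25)
  pos <- plant_motif(coldcis:::random_dna(30, 60), "GCGTAC", 0.8)
  neg <- coldcis:::random_dna(40, 60)
  sc <- coldcis:::score_exact_words(pos, neg, 6L)
  sc$p <- fisher_motif_pvalue(sc$pos_with, length(pos), sc$neg_with, length(neg))
  best <- sc[order(sc$p, sc$word), ][1L, ]
  # naive oracle: enumerate every 6-mer present in >= 2 positives via regex
  all_words <- unique(unlist(lapply(pos, function(s) {
    substring(s, 1:(nchar(s) - 5), 6:nchar(s))
  })))
  all_words <- all_words[!duplicated(vapply(all_words, coldcis:::iupac_canonical, ""))]
  naive <- do.call(rbind, lapply(all_words, function(w) {
    pw <- sum(regex_contains(pos, w)); nw <- sum(regex_contains(neg, w))
    data.frame(word = coldcis:::iupac_canonical(w), pw = pw, nw = nw)
  }))
  naive <- naive[naive$pw >= 2, ]
  naive$p <- fisher_motif_pvalue(naive$pw, length(pos), naive$nw, length(neg))
  naive <- naive[order(naive$p, naive$word), ]
  expect_identical(best$word, naive$word[1L])
  expect_equal(best$p, naive$p[1L])
})

test_that("motif discovery is deterministic and strand-symmetric", {
  set.seed(26)
  pos <- plant_motif(coldcis:::random_dna(60, 150), "TGACGTCA", 0.7)
  neg <- coldcis:::random_dna(300, 150)
  r1 <- discover_motifs(pos, neg, min_len = 5, max_len = 8, beam = 5,
                        max_motifs = 2)
  r2 <- discover_motifs(pos, neg, min_len = 5, max_len = 8, beam = 5,
                        max_motifs = 2)
  expect_identical(r1, r2)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x)))
  r3 <- discover_motifs(rc(pos), rc(neg), min_len = 5, max_len = 8, beam = 5,
                        max_motifs = 2)
  expect_identical(r1, r3)
  expect_gte(nrow(r1), 1L)
  expect_lte(consensus_distance(r1$consensus[1L], "TGACGTCA")$mismatch, 1)
  expect_true(all(r1$e_value >= r1$p_value))
  expect_true(all(r1$e_value < 0.05))
})

test_that("masking removes a reported motif's own support", {
  set.seed(27)
  pos <- plant_motif(coldcis:::random_dna(60, 150), "TGACGTCA", 0.7)
  neg <- coldcis:::random_dna(300, 150)
  r <- discover_motifs(pos, neg, min_len = 5, max_len = 8, beam = 5,
                       max_motifs = 1)
  w <- r$consensus[1L]
  mpos <- coldcis:::.iupac_mask(pos, w, TRUE)
  mneg <- coldcis:::.iupac_mask(neg, w, TRUE)
  cc <- containment_counts(w, mpos, mneg)
  expect_identical(unname(cc["pos_with"]), 0L)
  p_after <- fisher_motif_pvalue(cc["pos_with"], cc["pos_total"],
                                 cc["neg_with"], cc["neg_total"])
  expect_gte(p_after, r$p_value[1L])
})

test_that("the motif-gene table is consistent with the report counts", {
  set.seed(28)
  pos <- plant_motif(coldcis:::random_dna(60, 150), "TGACGTCA", 0.7)
  neg <- coldcis:::random_dna(120, 150)
  r <- discover_motifs(pos, neg, min_len = 6, max_len = 8, beam = 5,
                       max_motifs = 1)
  proms <- setNames(c(pos, neg), sprintf("g%03d", seq_along(c(pos, neg))))
  tab <- motif_gene_table(r, proms)
  expect_identical(sum(tab[seq_along(pos), r$consensus[1L]]),
                   as.integer(r$pos_with[1L]))
  empty <- motif_gene_table(r[0, ], proms)
  expect_identical(ncol(empty), 0L)
})

test_that("the negative set is the expressed complement of the loose DEG union", {
  # the planted mass share is kept small so library totals stay comparable
  cfg <- sim_config(n_genes = 2000, library_size = 5e5, dispersion = 0.001,
                    cluster_specs = list(list(id = "K", n = 40, pattern = 2.5)),
                    motif_specs = list(), go_specs = list(), seed = 31)
  cx <- generate_counts(cfg)
  degs <- call_degs(cx$table)
  neg <- suppressMessages(build_negative_set(degs))
  expect_identical(neg, sort(setdiff(degs$table$gene_id, loose_deg_union(degs))))
  expect_length(intersect(neg, loose_deg_union(degs)), 0)
  planted <- cx$truth$gene_id[!is.na(cx$truth$cluster)]
  expect_lt(length(intersect(neg, planted)) / length(planted), 0.1)
})
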