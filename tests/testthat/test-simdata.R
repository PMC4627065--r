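test_that("configuration invariants are enforced", {
  expect_error(sim_config(library_size = 0), "library_size")
  expect_error(sim_config(tissues = character()), "tissue list")
  expect_error(sim_config(n_genes = 100,
                          cluster_specs = list(list(id = "K", n = 200,
                                                    pattern = 2))),
               "exceed")
  expect_error(sim_config(motif_specs = list(
    list(cluster = "K0", consensus = "ACGT", freq = 0.1, background = 0.2))),
    "exceed the background")
  expect_error(sim_config(n_genes = 30, go_specs = list(
    list(term = "T", size = 50, length_biased = FALSE,
         cluster = NA, overlap = 0))), "larger than n_genes")
  expect_error(sim_config(promoter_length = 6, motif_specs = list(
    list(cluster = "K0", consensus = "ACGTACGT", freq = 0.5,
         background = 0))), "longer than the promoter")
})

test_that("identical seeds give byte-identical generated files", {
  cfg <- sim_config(n_genes = 60, library_size = 1e5, seed = 17)
  d1 <- file.path(tempdir(), "sim-a")
  d2 <- file.path(tempdir(), "sim-b")
  simulate_inputs(cfg, d1)
  simulate_inputs(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the data
  simulate_inputs(sim_config(n_genes = 60, library_size = 1e5, seed = 18), d2)
  expect_false(identical(readLines(file.path(d1, "counts.tsv")),
                         readLines(file.path(d2, "counts.tsv"))))
})

test_that("library sizes are honoured and the null model is calibrated", {
  cfg <- sim_config(n_genes = 400, library_size = 2e5, dispersion = 0,
                    cluster_specs = list(), motif_specs = list(),
                    go_specs = list(), seed = 21)
  cx <- generate_counts(cfg)
  totals <- colSums(cx$table$counts)
  # Poisson column sums: within 3 SD of the configured library size
  expect_true(all(abs(totals - 2e5) <= 3 * sqrt(2e5)))
  # no planted effects: cold/control RPKM ratios concentrate at 1
  rk <- compute_rpkm(cx$table)
  r18 <- (rk$rpkm[, "br_18C"] + 1) / (rk$rpkm[, "br_28C"] + 1)
  expect_lt(abs(median(r18) - 1), 0.1)
  expect_true(all(cx$truth$lfc == 0))
})

test_that("planted fold changes reach the configured RPKM ratio", {
  # one 50-gene cluster at +2 everywhere cold, deep Poisson libraries; the
  # host transcriptome is large enough that the planted mass barely shifts
  # the library totals, so the cold/control RPKM ratio sits near 4.  The
  # band is only +-0.18 log2 wide: this checks the planted means, not
  # robustness to overdispersion (other tests cover the NB noise model)
  hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_genes = 3000, library_size = 5e6, dispersion = 0,
                      cluster_specs = list(list(id = "K", n = 50, pattern = 2)),
                      motif_specs = list(), go_specs = list(), seed = 30 + s)
    cx <- generate_counts(cfg)
    rk <- compute_rpkm(cx$table)
    members <- cx$truth$gene_id[!is.na(cx$truth$cluster)]
    ratio <- (rk$rpkm[members, "br_10C"] + 1) / (rk$rpkm[members, "br_28C"] + 1)
    hits <- hits + (mean(ratio >= 3.5 & ratio <= 4.5) >= 0.9)
  }
  expect_gte(hits, 9L)
})

test_that("motif planting frequencies behave binomially", {
  # frequency 1 -> every cluster promoter carries a match
  cfg1 <- sim_config(n_genes = 80, seed = 41,
                     cluster_specs = list(list(id = "K0", n = 40, pattern = 2)),
                     motif_specs = list(list(cluster = "K0",
                                             consensus = "TGACGTCATG",
                                             freq = 1, background = 0)))
  cx1 <- generate_counts(cfg1)
  pr1 <- generate_promoters(cx1$truth, cfg1)
  members <- cx1$truth$gene_id[!is.na(cx1$truth$cluster)]
  expect_true(all(seq_contains(pr1$promoters[members], "TGACGTCATG")))
  # frequency 0 everywhere -> no containment anywhere
  cfg0 <- sim_config(n_genes = 80, seed = 42,
                     cluster_specs = list(list(id = "K0", n = 40, pattern = 2)),
                     motif_specs = list(list(cluster = "K0",
                                             consensus = "TGACGTCATG",
                                             freq = 0, background = 0)))
  cx0 <- generate_counts(cfg0)
  pr0 <- generate_promoters(cx0$truth, cfg0)
  expect_identical(sum(seq_contains(pr0$promoters, "TGACGTCATG")), 0L)
  # frequency 0.3 over 200 members: counts land in the binomial 99% interval
  # [42, 78] in at least 95 of 100 seeds
  inside <- 0L
  for (s in 1:100) {
    cfg <- sim_config(n_genes = 200, seed = 500 + s,
                      cluster_specs = list(list(id = "K0", n = 200, pattern = 2)),
                      motif_specs = list(list(cluster = "K0",
                                              consensus = "TGACGTCATG",
                                              freq = 0.3, background = 0)))
    cx <- generate_counts(cfg)
    pr <- generate_promoters(cx$truth, cfg)
    n_with <- sum(seq_contains(pr$promoters, "TGACGTCATG"))
    inside <- inside + (n_with >= 42L && n_with <= 78L)
  }
  expect_gte(inside, 95L)
})

test_that("planted motif positions lie inside their promoters", {
  cfg <- sim_config(n_genes = 100, seed = 43)
  cx <- generate_counts(cfg)
  pr <- generate_promoters(cx$truth, cfg)
  for (i in seq_len(nrow(pr$planted))) {
    m <- nchar(pr$planted$consensus[i])
    expect_gte(pr$planted$position[i], 1L)
    expect_lte(pr$planted$position[i] + m - 1L, cfg$promoter_length)
  }
  expect_true(all(pr$planted$gene %in% names(pr$promoters)))
})

test_that("GO annotations respect sizes, bias and planted overlap", {
  cfg <- sim_config(n_genes = 400, seed = 44)
  cx <- generate_counts(cfg)
  lens <- setNames(cx$table$gene_length, cx$table$gene_id)
  go <- generate_go_annotations(cx$truth, cfg, lens)
  sizes <- table(go$term_id)
  for (s in cfg$go_specs) {
    expect_identical(unname(sizes[s$term]), as.integer(s$size))
  }
  # deterministic under seed
  go2 <- generate_go_annotations(cx$truth, cfg, lens)
  expect_identical(go, go2)
  # planted overlap: GO:SYN0001 takes its configured overlap from cluster K0
  k0 <- cx$truth$gene_id[!is.na(cx$truth$cluster) & cx$truth$cluster == "K0"]
  ov <- cfg$go_specs[[1L]]$overlap
  expect_gte(length(intersect(go$gene_id[go$term_id == "GO:SYN0001"], k0)), ov)
  # length-biased term: member median length above the genome median
  # in at least 95 of 100 seeds
  above <- 0L
  for (s in 1:100) {
    cfg_s <- sim_config(n_genes = 400, seed = 600 + s)
    cx_s <- generate_counts(cfg_s)
    lens_s <- setNames(cx_s$table$gene_length, cx_s$table$gene_id)
    go_s <- generate_go_annotations(cx_s$truth, cfg_s, lens_s)
    biased <- go_s$gene_id[go_s$term_id == "GO:SYN0002"]
    above <- above + (median(lens_s[biased]) > median(lens_s))
  }
  expect_gte(above, 95L)
  # a term with no planted overlap has hypergeometric-scale overlap with K0
  neutral <- go$gene_id[go$term_id == "GO:SYN0003"]
  expect_lte(length(intersect(neutral, k0)), 30L)
})

test_that("the generated motif database is planted-faithful with distant decoys", {
  cfg <- sim_config(n_genes = 50, seed = 45)
  db <- generate_motif_db(cfg)
  planted <- vapply(cfg$motif_specs, function(s) s$consensus, character(1L))
  cons <- vapply(db, function(m) pfm_to_iupac(m$pfm), character(1L))
  for (p in planted) expect_true(p %in% cons)
  decoys <- cons[grep("^DEC", names(db))]
  for (d in decoys) {
    for (p in planted) {
      expect_gte(consensus_distance(d, p)$mismatch, 3L)
    }
  }
  expect_gte(length(decoys), 1L)
})
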