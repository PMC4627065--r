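test_that("count table TSV round-trips and bad input is rejected with the line", {
  set.seed(1)
  cx <- generate_counts(sim_config(n_genes = 40, library_size = 5e4, seed = 1))
  tmp <- tempfile(fileext = ".tsv")
  write_counts(cx$table, tmp)
  back <- read_counts(tmp)
  expect_identical(back$gene_id, cx$table$gene_id)
  expect_equal(back$counts, cx$table$counts)
  expect_equal(back$gene_length, cx$table$gene_length)

  # header-only file -> zero genes; empty file -> error
  hdr <- tempfile(fileext = ".tsv")
  writeLines(readLines(tmp)[1L], hdr)
  expect_identical(length(read_counts(hdr)$gene_id), 0L)
  empty <- tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(read_counts(empty), "empty")

  lines <- readLines(tmp)
  dup <- tempfile(fileext = ".tsv")
  writeLines(c(lines, lines[2L]), dup)
  expect_error(read_counts(dup), "duplicate gene id")
  neg <- tempfile(fileext = ".tsv")
  bad <- strsplit(lines[3L], "\t")[[1L]]
  bad[3L] <- "-4"
  writeLines(c(lines[1:2], paste(bad, collapse = "\t")), neg)
  expect_error(read_counts(neg), "invalid count at line 3")
})

test_that("low-count filter keeps a gene when either library of a pair has >= 5 reads", {
  # 2 tissues x 3 temps; gene 1: (0, 4) everywhere -> dropped;
  # gene 2: (5, 0) in one pair -> kept for that pair; gene 3: >= 5 everywhere
  cm <- rbind(c(0, 4, 0, 4, 0, 4),
              c(5, 0, 0, 0, 0, 0),
              c(9, 9, 9, 9, 9, 9))
  colnames(cm) <- c("aa_28C", "aa_18C", "aa_10C", "bb_28C", "bb_18C", "bb_10C")
  ft <- filter_low_counts(manual_counts(cm))
  expect_identical(ft$gene_id, c("g02", "g03"))
  ret <- attr(ft, "retained")
  expect_true(ret["g02", "aa.28v18"])   # 5 passes the < 5 boundary
  expect_false(ret["g02", "aa.18v10"])
  expect_true(all(ret["g03", ]))
  # all genes >= 5 everywhere -> identity
  full <- manual_counts(matrix(5, 3, 6, dimnames = list(NULL, colnames(cm))))
  expect_identical(filter_low_counts(full)$gene_id, full$gene_id)
})

test_that("RPKM matches the unit definition and a hand-computed table", {
  cm <- rbind(c(10, 0), c(20, 50), c(40, 100))
  colnames(cm) <- c("aa_28C", "aa_18C")
  tab <- manual_counts(cm, lengths = c(1000, 2000, 500))
  rk <- compute_rpkm(tab)
  # library totals: 70 and 150 reads
  expect_equal(rk$rpkm["g01", "aa_28C"], 10 / (1 * 70 / 1e6))
  expect_equal(rk$rpkm["g01", "aa_18C"], 0)
  hand <- rbind(c(10 / (1 * 7e-5), 0 / (1 * 1.5e-4)),
                c(20 / (2 * 7e-5), 50 / (2 * 1.5e-4)),
                c(40 / (0.5 * 7e-5), 100 / (0.5 * 1.5e-4)))
  expect_equal(unname(rk$rpkm), hand)
  # metamorphic: doubling all counts in a library leaves RPKM unchanged
  cm2 <- cm
  cm2[, 2L] <- cm2[, 2L] * 2L
  rk2 <- compute_rpkm(manual_counts(cm2, lengths = c(1000, 2000, 500)))
  expect_equal(rk2$rpkm[, 2L], rk$rpkm[, 2L])
  expect_error(compute_rpkm(manual_counts(cbind(aa_28C = c(0L, 0L)))), "zero total")
})

test_that("two-sided Fisher DEG P agrees with stats::fisher.test and is symmetric", {
  expect_equal(fisher_deg_pvalue(10, 1000, 10, 1000), 1)
  expect_equal(fisher_deg_pvalue(0, 100, 0, 100), 1)
  set.seed(42)
  for (i in 1:50) {
    A <- sample(20:400, 1); B <- sample(20:400, 1)
    a <- sample(0:A, 1); b <- sample(0:B, 1)
    ref <- stats::fisher.test(matrix(c(a, A - a, b, B - b), 2, byrow = TRUE))$p.value
    expect_equal(fisher_deg_pvalue(a, A, b, B), ref, tolerance = 1e-10)
  }
  expect_error(fisher_deg_pvalue(5, 0, 1, 10), "positive")
  expect_error(fisher_deg_pvalue(11, 10, 1, 10), "0 <= a <= A")
})

test_that("BH adjustment equals the step-up formula and is idempotent", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  for (i in 1:20) {
    p <- stats::runif(sample(1:50, 1))
    # direct formula: min over j >= i of p_(j) * n / j, in sorted order
    n <- length(p)
    o <- order(p)
    direct <- numeric(n)
    direct[o] <- pmin(1, rev(cummin(rev(sort(p) * n / seq_len(n)))))
    adj <- bh_adjust(p)
    expect_equal(adj, direct)
    expect_true(all(diff(adj[o]) >= -1e-12))     # monotone in sorted order
    expect_true(all(adj >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG tiers follow the strict fold-change and adjusted-P inequalities", {
  # one tissue pair; filler genes equalise the library totals (12212 each)
  # so RPKM ratios equal count ratios exactly
  filler <- cbind(c(3000L, 3000L, 3000L, 3000L),
                  c(2895L, 2895L, 2896L, 2896L))
  cm <- rbind(c(100, 400),    # fold 4, tiny p        -> strict
              c(12, 30),      # fold 2.5, p ~ 0.01    -> loose only
              c(100, 200),    # fold exactly 2        -> excluded
              filler)
  colnames(cm) <- c("aa_28C", "aa_18C")
  tab <- manual_counts(cm)
  degs <- call_degs(tab, pseudocount = 0)
  rec <- degs$records
  expect_identical(rec$tier[rec$gene == "g01"], "strict")
  expect_identical(rec$direction[rec$gene == "g01"], "up")
  g2 <- rec[rec$gene == "g02", ]
  expect_identical(g2$tier, "loose")
  expect_gt(g2$p_adj, 0.001)
  expect_false("g03" %in% rec$gene)   # > 2 is strict
  expect_identical(strict_deg_union(degs), "g01")
  expect_identical(loose_deg_union(degs), c("g01", "g02"))
  expect_identical(strict_deg_union(data.frame(gene = character(),
                                               tier = character())),
                   character(0))
})

test_that("profiles are pseudocounted log2 cold/control ratios", {
  rk <- manual_rpkm(rbind(g1 = c(10, 10, 30, 0),
                          g2 = c(5, 15, 5, 5)),
                    tissue = c("aa", "aa", "bb", "bb"),
                    temperature = c(28, 18, 28, 18))
  colnames(rk$rpkm) <- c("aa_28C", "aa_18C", "bb_28C", "bb_18C")
  pr <- build_profiles(rk, pseudocount = 1)
  expect_equal(pr["g1", "aa_18"], 0)                     # equal rpkm
  expect_equal(pr["g2", "aa_18"], log2(16 / 6))
  expect_equal(pr["g1", "bb_18"], log2(1 / 31))          # zero cold rpkm
  big <- manual_rpkm(rbind(g1 = c(1000, 3000)), "aa", c(28, 18))
  colnames(big$rpkm) <- c("aa_28C", "aa_18C")
  expect_equal(build_profiles(big)[1, 1], log2(3), tolerance = 1e-3)
  expect_error(build_profiles(rk, genes = "nope"), "unknown gene")
})

test_that("classical MDS recovers planar configurations and fixes signs", {
  set.seed(3)
  pts <- matrix(rnorm(12), 6, 2)
  emb <- classical_mds(pts, k = 2)
  expect_equal(as.matrix(dist(emb$points)), as.matrix(dist(pts)),
               tolerance = 1e-9, ignore_attr = TRUE)
  for (j in 1:2) {
    expect_gt(emb$points[which.max(abs(emb$points[, j])), j], 0)
  }
  # 4-point configuration vs an independent double-centering eigendecomposition
  x <- matrix(c(0, 0, 1, 0, 0, 2, 3, 1), 4, 2, byrow = TRUE)
  d2 <- as.matrix(dist(x))^2
  J <- diag(4) - 1 / 4
  B <- -0.5 * J %*% d2 %*% J
  eg <- eigen(B, symmetric = TRUE)
  oracle <- eg$vectors[, 1:2] %*% diag(sqrt(eg$values[1:2]))
  emb4 <- classical_mds(x, k = 2)
  expect_equal(abs(emb4$points), abs(oracle), tolerance = 1e-9,
               ignore_attr = TRUE)
  # identical samples -> the origin
  same <- matrix(1, 5, 3)
  embs <- suppressWarnings(classical_mds(same, k = 2))
  expect_true(all(abs(embs$points) < 1e-12))
  expect_error(classical_mds(pts[1:2, ], k = 2), "k \\+ 1")
})

test_that("strict DEG calls are controlled under null Poisson simulation", {
  frac <- numeric(20)
  for (s in 1:20) {
    cfg <- sim_config(n_genes = 300, library_size = 5e4, dispersion = 0,
                      cluster_specs = list(), motif_specs = list(),
                      go_specs = list(), seed = 700 + s)
    cx <- generate_counts(cfg)
    degs <- call_degs(cx$table)
    frac[s] <- length(strict_deg_union(degs)) / length(degs$table$gene_id)
  }
  expect_true(all(frac <= 0.005))
})
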