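## Expression module: count-table I/O, RPKM normalisation, Fisher-exact
## DEG calling for pooled single-library designs, log2-ratio profiles and
## classical MDS of the tissue responses.

#' Construct a count table
#'
#' A count table holds integer read counts for one pooled library per
#' (tissue, temperature) condition, plus per-gene lengths.  This is the
#' root input of the pipeline; there are no replicate libraries.
#'
#' @param counts integer matrix, genes x libraries; column names
#'   \code{"<tissue>_<temp>C"} (e.g. \code{"ki_28C"}).
#' @param gene_length integer vector of gene lengths in bp.
#' @param gene_id character vector of unique gene identifiers.
#' @return An object of class \code{count_table} with fields
#'   \code{counts}, \code{gene_id}, \code{gene_length}, \code{tissue},
#'   \code{temperature}.
#' @export
count_table <- function(counts, gene_length, gene_id = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_id)) stop("gene ids are required")
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene id: ", gene_id[duplicated(gene_id)][1L])
  }
  if (anyDuplicated(colnames(counts))) stop("duplicate library labels")
  if (length(gene_length) != nrow(counts)) stop("gene_length length mismatch")
  if (any(gene_length <= 0)) stop("gene lengths must be > 0")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  lab <- parse_library_labels(colnames(counts))
  structure(list(
    counts = `dimnames<-`(counts, list(gene_id, colnames(counts))),
    gene_id = gene_id,
    gene_length = as.numeric(gene_length),
    tissue = lab$tissue,
    temperature = lab$temperature
  ), class = "count_table")
}

parse_library_labels <- function(labels) {
  m <- regmatches(labels, regexec("^(.+)_([0-9]+)C$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed library label '", labels[bad][1L],
         "': expected <tissue>_<temp>C")
  }
  list(tissue = vapply(m, `[`, "", 2L),
       temperature = as.numeric(vapply(m, `[`, "", 3L)))
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", length(x$gene_id), "genes x", ncol(x$counts),
      "libraries\n")
  cat("tissues:", paste(unique(x$tissue), collapse = ", "), "\n")
  cat("temperatures (deg C):", paste(sort(unique(x$temperature), decreasing = TRUE),
                                     collapse = ", "), "\n")
  invisible(x)
}

#' Read a count table from TSV
#'
#' Expects columns \code{gene_id}, \code{length_bp}, then one integer
#' column per library labelled \code{<tissue>_<temp>C}.
#'
#' @param path path to a tab-separated file.
#' @return A \code{\link{count_table}}.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  if (file.size(path) == 0L) stop("empty count file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene_id", "length_bp")
  if (!all(need %in% names(df))) {
    stop("malformed header: need columns gene_id, length_bp")
  }
  libcols <- setdiff(names(df), need)
  cm <- as.matrix(df[libcols])
  if (nrow(df) > 0L) {
    bad <- which(!is.finite(cm) | cm < 0 | cm != round(cm), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop("invalid count at line ", bad[1L, 1L] + 1L, ", column '",
           libcols[bad[1L, 2L]], "'")
    }
    if (anyDuplicated(df$gene_id)) {
      stop("duplicate gene id at line ",
           which(duplicated(df$gene_id))[1L] + 1L, ": ",
           df$gene_id[duplicated(df$gene_id)][1L])
    }
  }
  count_table(cm, df$length_bp, df$gene_id)
}

#' Write a count table to TSV
#' @param table a \code{count_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(table, path) {
  df <- data.frame(gene_id = table$gene_id,
                   length_bp = table$gene_length,
                   table$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Temperature-pair comparisons of the cooling design
#'
#' The three pairwise comparisons per tissue: control vs mild cold
#' (28v18), mild vs severe (18v10), control vs severe (28v10).
#' @return data.frame with columns \code{label}, \code{t_ref}, \code{t_cold}.
#' @export
temperature_comparisons <- function() {
  data.frame(label = c("28v18", "18v10", "28v10"),
             t_ref = c(28, 18, 28),
             t_cold = c(18, 10, 10))
}

#' Filter genes with low read counts
#'
#' A gene is retained for a pairwise comparison if it has at least
#' \code{min_reads} reads in at least one of the two libraries compared;
#' it is retained overall if retained in at least one comparison.
#'
#' @param table a \code{count_table}.
#' @param min_reads retention threshold in reads (default 5; counts below
#'   it in both libraries of a pair drop the gene from that comparison).
#' @return The filtered \code{count_table}; attribute \code{"retained"}
#'   holds the per-(tissue, comparison) retention matrix over the kept genes.
#' @export
filter_low_counts <- function(table, min_reads = 5) {
  cmp <- temperature_comparisons()
  tissues <- unique(table$tissue)
  ret <- list()
  for (ti in tissues) {
    for (i in seq_len(nrow(cmp))) {
      c1 <- which(table$tissue == ti & table$temperature == cmp$t_ref[i])
      c2 <- which(table$tissue == ti & table$temperature == cmp$t_cold[i])
      if (length(c1) != 1L || length(c2) != 1L) next
      ret[[paste(ti, cmp$label[i], sep = ".")]] <-
        table$counts[, c1] >= min_reads | table$counts[, c2] >= min_reads
    }
  }
  if (length(ret) == 0L) stop("no comparable temperature pairs found")
  retm <- do.call(cbind, ret)
  keep <- rowSums(retm) > 0L
  out <- count_table(table$counts[keep, , drop = FALSE],
                     table$gene_length[keep], table$gene_id[keep])
  attr(out, "retained") <- retm[keep, , drop = FALSE]
  out
}

#' Reads per kilobase per million mapped reads
#'
#' \code{rpkm = count / (gene length in kb x library total in millions)};
#' the library total is the per-library column sum of the (filtered)
#' count table.
#'
#' @param table a \code{count_table}.
#' @return An \code{rpkm_table}: the same axes with an \code{rpkm} matrix
#'   and the library totals used.
#' @export
compute_rpkm <- function(table) {
  totals <- colSums(table$counts)
  if (any(totals == 0)) {
    stop("library with zero total reads: ",
         colnames(table$counts)[totals == 0][1L])
  }
  rpkm <- sweep(table$counts, 1L, table$gene_length / 1e3, "/")
  rpkm <- sweep(rpkm, 2L, totals / 1e6, "/")
  structure(list(rpkm = rpkm, gene_id = table$gene_id,
                 gene_length = table$gene_length,
                 tissue = table$tissue, temperature = table$temperature,
                 library_totals = totals),
            class = "rpkm_table")
}

#' @export
print.rpkm_table <- function(x, ...) {
  cat("rpkm_table:", length(x$gene_id), "genes x", ncol(x$rpkm), "libraries\n")
  invisible(x)
}

#' Two-sided Fisher exact P for one gene between two pooled libraries
#'
#' The 2x2 table is \code{[[a, A-a], [b, B-b]]}: the gene's reads versus
#' the remaining reads in each library.  The two-sided P is the sum of
#' probabilities of all tables (with fixed margins) whose point
#' probability does not exceed that of the observed table — the same
#' definition \code{stats::fisher.test} uses.  Vectorised over tables.
#'
#' @param a,b gene read counts in libraries 1 and 2.
#' @param A,B total mapped reads of libraries 1 and 2.
#' @return Numeric vector of two-sided P values.
#' @export
fisher_deg_pvalue <- function(a, A, b, B) {
  n <- max(length(a), length(A), length(b), length(B))
  a <- rep_len(as.numeric(a), n); A <- rep_len(as.numeric(A), n)
  b <- rep_len(as.numeric(b), n); B <- rep_len(as.numeric(B), n)
  if (any(A <= 0) || any(B <= 0)) stop("library totals must be positive")
  if (any(a < 0 | b < 0 | a > A | b > B)) stop("counts must satisfy 0 <= a <= A, 0 <= b <= B")
  vapply(seq_len(n), function(i) {
    k <- a[i] + b[i]
    lo <- max(0, k - B[i])
    hi <- min(k, A[i])
    x <- lo:hi
    d <- stats::dhyper(x, A[i], B[i], k)
    pobs <- d[match(a[i], x)]
    # relative tolerance guards against ties broken by rounding error
    min(1, sum(d[d <= pobs * (1 + 1e-7)]))
  }, numeric(1L))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p vector of P values in [0, 1].
#' @return Adjusted P values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0L))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes per tissue and temperature pair
#'
#' For every tissue and each of the three comparisons, genes passing the
#' low-count filter are tested with \code{\link{fisher_deg_pvalue}} and
#' adjusted by Benjamini-Hochberg within that (tissue, comparison)
#' family.  The loose tier requires a pseudocounted RPKM fold change
#' strictly above \code{fc_threshold}; the strict tier additionally
#' requires adjusted P strictly below \code{padj_threshold}.
#'
#' @param table a \code{count_table} (unfiltered; filtering is applied
#'   internally with \code{min_reads}).
#' @param fc_threshold fold-change threshold (strict inequality; default 2).
#' @param padj_threshold adjusted-P threshold for the strict tier
#'   (strict inequality; default 0.001).
#' @param pseudocount RPKM pseudocount for all ratio computations
#'   (default 1 RPKM).
#' @param min_reads low-count filter threshold (default 5).
#' @return A \code{deg_result}: data.frame \code{records} with one row per
#'   loose-or-better call (gene, tissue, comparison, rpkm_fold_change,
#'   log2fc, p, p_adj, direction, tier), plus the filtered table and RPKM.
#' @export
call_degs <- function(table, fc_threshold = 2, padj_threshold = 0.001,
                      pseudocount = 1, min_reads = 5) {
  ft <- filter_low_counts(table, min_reads)
  retained <- attr(ft, "retained")
  rk <- compute_rpkm(ft)
  cmp <- temperature_comparisons()
  tissues <- unique(ft$tissue)
  recs <- list()
  for (ti in tissues) {
    present <- unique(ft$temperature[ft$tissue == ti])
    if (length(present) < 2L) {
      warning("tissue '", ti, "' present at fewer than two temperatures; skipped")
      next
    }
    for (i in seq_len(nrow(cmp))) {
      key <- paste(ti, cmp$label[i], sep = ".")
      if (!key %in% colnames(retained)) next
      c1 <- which(ft$tissue == ti & ft$temperature == cmp$t_ref[i])
      c2 <- which(ft$tissue == ti & ft$temperature == cmp$t_cold[i])
      test <- which(retained[, key])
      if (length(test) == 0L) next
      a <- ft$counts[test, c1]; b <- ft$counts[test, c2]
      A <- rk$library_totals[c1]; B <- rk$library_totals[c2]
      p <- fisher_deg_pvalue(a, A, b, B)
      padj <- bh_adjust(p)
      r_ref <- rk$rpkm[test, c1] + pseudocount
      r_cold <- rk$rpkm[test, c2] + pseudocount
      l2 <- log2(r_cold / r_ref)
      fc <- pmax(r_cold / r_ref, r_ref / r_cold)
      loose <- fc > fc_threshold
      strict <- loose & padj < padj_threshold
      if (!any(loose)) next
      recs[[key]] <- data.frame(
        gene = ft$gene_id[test][loose],
        tissue = ti,
        comparison = cmp$label[i],
        rpkm_fold_change = fc[loose],
        log2fc = l2[loose],
        p = p[loose],
        p_adj = padj[loose],
        direction = ifelse(l2[loose] > 0, "up", "down"),
        tier = ifelse(strict[loose], "strict", "loose"),
        row.names = NULL
      )
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene = character(), tissue = character(),
               comparison = character(), rpkm_fold_change = numeric(),
               log2fc = numeric(), p = numeric(), p_adj = numeric(),
               direction = character(), tier = character())
  rownames(records) <- NULL
  structure(list(records = records, table = ft, rpkm = rk,
                 fc_threshold = fc_threshold,
                 padj_threshold = padj_threshold,
                 pseudocount = pseudocount),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat("deg_result:", nrow(x$records), "loose calls,",
      sum(x$records$tier == "strict"), "strict calls,",
      length(strict_deg_union(x)), "genes in the strict union\n")
  invisible(x)
}

#' Union of strictly differentially expressed genes
#'
#' Genes passing the strict tier (fold change and adjusted P) in at least
#' one (tissue, comparison); the compact DEG set used for clustering.
#'
#' @param degs a \code{deg_result} or its \code{records} data.frame.
#' @return Character vector of gene ids.
#' @export
strict_deg_union <- function(degs) {
  rec <- if (inherits(degs, "deg_result")) degs$records else degs
  sort(unique(rec$gene[rec$tier == "strict"]))
}

#' Union of loose differentially expressed genes
#' @param degs a \code{deg_result} or its \code{records} data.frame.
#' @return Character vector of gene ids with fold change above the loose
#'   threshold in at least one comparison.
#' @export
loose_deg_union <- function(degs) {
  rec <- if (inherits(degs, "deg_result")) degs$records else degs
  sort(unique(rec$gene))
}

#' Build log2 cold/control expression profiles
#'
#' One column per (tissue, cold temperature): \code{log2((rpkm_cold + c)
#' / (rpkm_ref + c))} with pseudocount \code{c}.  With the default
#' 8-tissue, 28/18/10 design this yields 16 condition columns.
#'
#' @param rpkm an \code{rpkm_table}.
#' @param genes gene ids to keep as rows (typically the strict DEG
#'   union); default all genes.
#' @param reference_temp control temperature (default 28).
#' @param pseudocount RPKM pseudocount (default 1).
#' @return Numeric matrix genes x conditions, columns \code{<tissue>_<temp>}.
#' @export
build_profiles <- function(rpkm, genes = rpkm$gene_id, reference_temp = 28,
                           pseudocount = 1) {
  idx <- match(genes, rpkm$gene_id)
  if (anyNA(idx)) stop("unknown gene id: ", genes[is.na(idx)][1L])
  tissues <- unique(rpkm$tissue)
  cold_temps <- sort(setdiff(unique(rpkm$temperature), reference_temp),
                     decreasing = TRUE)
  cols <- list()
  for (ti in tissues) {
    ref <- which(rpkm$tissue == ti & rpkm$temperature == reference_temp)
    if (length(ref) != 1L) stop("missing reference library for tissue ", ti)
    for (tc in cold_temps) {
      cold <- which(rpkm$tissue == ti & rpkm$temperature == tc)
      if (length(cold) != 1L) next
      cols[[paste(ti, tc, sep = "_")]] <-
        log2((rpkm$rpkm[idx, cold] + pseudocount) /
             (rpkm$rpkm[idx, ref] + pseudocount))
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- genes
  mat
}

#' Classical multidimensional scaling with a fixed sign convention
#'
#' Classical (Torgerson) MDS of a samples-x-features matrix or a
#' \code{dist}: Euclidean distances, double-centering of the squared
#' distances, top-\code{k} eigenvectors scaled by the square root of
#' their eigenvalues.  Each returned axis is reflected so that its
#' largest-magnitude loading is positive, making the embedding
#' deterministic.
#'
#' @param x numeric matrix (samples in rows) or a \code{dist}.
#' @param k number of dimensions (default 2).
#' @return List with \code{points} (samples x k) and \code{eig}
#'   (all eigenvalues).  If fewer than \code{k} eigenvalues are positive
#'   the available dimensions are returned with a warning.
#' @export
classical_mds <- function(x, k = 2) {
  d <- if (inherits(x, "dist")) x else stats::dist(x)
  n <- attr(d, "Size")
  if (n < k + 1L) stop("need at least k + 1 samples")
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {
    warning("only ", ncol(pts), " positive eigenvalue(s); returning ",
            ncol(pts), " dimension(s)")
  }
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  list(points = pts, eig = fit$eig)
}

#' MDS embedding of tissue cold responses
#'
#' Embeds the libraries in 2-D from log2(RPKM + pseudocount) expression,
#' with each tissue's control (28 degree) column subtracted so every
#' control library maps to the origin and distances reflect the cold
#' response itself.
#'
#' @param rpkm an \code{rpkm_table}.
#' @param k embedding dimension (default 2).
#' @param reference_temp control temperature (default 28).
#' @param pseudocount RPKM pseudocount (default 1).
#' @return As \code{\link{classical_mds}}, with library labels on rows.
#' @export
mds_samples <- function(rpkm, k = 2, reference_temp = 28, pseudocount = 1) {
  lg <- log2(rpkm$rpkm + pseudocount)
  for (ti in unique(rpkm$tissue)) {
    ref <- which(rpkm$tissue == ti & rpkm$temperature == reference_temp)
    if (length(ref) != 1L) stop("missing reference library for tissue ", ti)
    sel <- rpkm$tissue == ti
    lg[, sel] <- lg[, sel] - lg[, ref]
  }
  classical_mds(t(lg), k = k)
}
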