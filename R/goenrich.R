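## Gene-length-aware GO enrichment.  Long genes accumulate more reads and
## are therefore more likely to be called differentially expressed at a
## fixed significance level; a probability weighting function (PWF) of
## gene length captures that propensity, and category enrichment is
## tested with the Wallenius noncentral hypergeometric distribution whose
## odds come from the PWF.

#' Fit a probability weighting function of gene length
#'
#' The DE indicator is smoothed by a moving average over
#' \code{smooth_window} length-ranked genes (constant-width windows,
#' shifted inward at the extremes so variance is uniform along the
#' ranking), then isotonic (monotone non-decreasing) regression is
#' applied to the smoothed rate, floored at 1e-6 and rescaled to mean 1.
#' Smoothing before isotonizing keeps the edge blocks of the monotone
#' fit from being dominated by a handful of genes, which matters for
#' calibration when DE status is independent of length.
#'
#' @param de_flags logical (or 0/1) vector: is the gene in the DE set?
#' @param gene_lengths numeric vector of gene lengths in bp.
#' @param smooth_window moving-average width in genes (default 200).
#' @return A \code{pwf} object: data.frame with \code{gene} (names of
#'   \code{de_flags} if any), \code{length}, \code{de}, \code{weight}
#'   (positive, non-decreasing in length, mean 1).
#' @export
fit_pwf <- function(de_flags, gene_lengths, smooth_window = 200) {
  de <- as.numeric(de_flags)
  if (length(de) != length(gene_lengths)) stop("length mismatch")
  if (any(is.na(de)) || any(!de %in% c(0, 1))) stop("de_flags must be logical or 0/1")
  n <- length(de)
  if (all(de == 1) || all(de == 0)) {
    warning("all genes ", if (all(de == 1)) "DE" else "non-DE",
            "; returning a flat weighting function")
    w <- rep(1, n)
  } else {
    ord <- order(gene_lengths)
    half <- min(floor(smooth_window / 2), floor((n - 1) / 2))
    cs <- cumsum(c(0, de[ord]))
    sm <- vapply(seq_len(n), function(i) {
      lo <- min(max(1L, i - half), n - 2L * half)
      hi <- lo + 2L * half
      (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }, numeric(1L))
    fit <- pmax(stats::isoreg(gene_lengths[ord], sm)$yf, 1e-6)
    w <- numeric(n)
    w[ord] <- fit
    w <- w / mean(w)
  }
  out <- data.frame(gene = if (!is.null(names(de_flags))) names(de_flags) else
                      as.character(seq_len(n)),
                    length = gene_lengths, de = de, weight = w,
                    stringsAsFactors = FALSE)
  class(out) <- c("pwf", "data.frame")
  out
}

# log density of the Wallenius noncentral hypergeometric distribution,
# computed by numeric integration of
#   d(x) = C(m1,x) C(m2,n-x) * D * Int_0^1 (1-u^w)^x (1-u)^(n-x) u^(D-1) du,
# D = w*(m1-x) + (m2-n+x), in log space with a mode shift so that urns
# far larger than double-precision binomials still integrate.
dwallenius_log <- function(x, m1, m2, n, odds) {
  D <- odds * (m1 - x) + (m2 - n + x)
  if (D <= 0) return(-Inf)
  h <- function(u) {
    x * log1p(-exp(odds * log(u))) + (n - x) * log1p(-u) + (D - 1) * log(u)
  }
  opt <- stats::optimize(h, c(1e-12, 1 - 1e-12), maximum = TRUE, tol = 1e-12)
  hmax <- opt$objective
  intg <- stats::integrate(function(u) exp(h(u) - hmax), 0, 1,
                           rel.tol = 1e-10, subdivisions = 500L)
  lchoose(m1, x) + lchoose(m2, n - x) + log(D) + hmax + log(intg$value)
}

#' Upper-tail P value of the Wallenius noncentral hypergeometric
#'
#' Probability of drawing at least \code{n_white_drawn} white balls when
#' \code{n_drawn} balls are taken without replacement from an urn of
#' \code{n_white} white and \code{n_black} black balls, white balls
#' having odds \code{odds} relative to black.  The density is obtained
#' by numeric integration; \code{odds = 1} reduces to the central
#' hypergeometric.
#'
#' @param n_white_drawn observed white draws (the tail starts here).
#' @param n_white,n_black urn composition.
#' @param n_drawn number of draws.
#' @param odds relative sampling odds of white balls (> 0).
#' @return P(X >= n_white_drawn).
#' @export
wallenius_pvalue <- function(n_white_drawn, n_white, n_black, n_drawn, odds) {
  args <- c(n_white_drawn, n_white, n_black, n_drawn)
  if (any(args != round(args)) || any(args < 0)) {
    stop("urn counts must be non-negative integers")
  }
  if (odds <= 0) stop("odds must be positive")
  if (n_drawn > n_white + n_black) stop("cannot draw more than the urn holds")
  lo <- max(0, n_drawn - n_black)
  if (n_white_drawn <= lo) return(1)
  hi <- min(n_drawn, n_white)
  if (n_white_drawn > hi) return(0)
  xs <- n_white_drawn:hi
  lp <- vapply(xs, dwallenius_log, numeric(1L),
               m1 = n_white, m2 = n_black, n = n_drawn, odds = odds)
  mx <- max(lp)
  min(1, exp(mx) * sum(exp(lp - mx)))
}

#' Length-aware GO enrichment per cluster
#'
#' For every (cluster, term) pair the overlap between the cluster's
#' member genes and the term's annotated genes is tested against the
#' background of all expressed genes using the Wallenius distribution.
#' The odds for a term are the mean PWF weight of its genes divided by
#' the mean weight of the remaining background genes, so that length
#'-driven inflation of the overlap is absorbed into the null.
#' Benjamini-Hochberg adjustment is applied across terms within each
#' cluster.
#'
#' @param assignments data.frame with columns \code{gene}, \code{cluster}
#'   (as returned by \code{\link{assign_members}}).
#' @param go_table data.frame with columns \code{gene_id}, \code{term_id}
#'   and optionally \code{term_name}.
#' @param pwf a \code{\link{fit_pwf}} result over the background genes.
#' @param fdr_cutoff FDR at which a record is flagged enriched (default 0.05).
#' @return data.frame of enrichment records: \code{cluster},
#'   \code{term_id}, \code{n_category}, \code{n_in_cluster},
#'   \code{cluster_size}, \code{odds}, \code{p_wallenius}, \code{fdr},
#'   \code{enriched}, \code{member_genes} (comma-separated).
#' @export
enrich_clusters <- function(assignments, go_table, pwf, fdr_cutoff = 0.05) {
  background <- pwf$gene
  wts <- stats::setNames(pwf$weight, pwf$gene)
  go_table <- go_table[go_table$gene_id %in% background, , drop = FALSE]
  terms <- split(unique(go_table[c("gene_id", "term_id")])$gene_id,
                 unique(go_table[c("gene_id", "term_id")])$term_id)
  terms <- terms[vapply(terms, length, 1L) > 0L]
  if (length(terms) == 0L) stop("no term has annotated expressed genes")
  out <- list()
  for (cl in unique(assignments$cluster)) {
    members <- intersect(assignments$gene[assignments$cluster == cl], background)
    if (length(members) == 0L) next
    recs <- lapply(names(terms), function(tid) {
      cat_genes <- terms[[tid]]
      overlap <- intersect(members, cat_genes)
      in_w <- mean(wts[cat_genes])
      out_w <- mean(wts[setdiff(background, cat_genes)])
      odds <- if (is.finite(out_w) && out_w > 0) in_w / out_w else 1
      p <- wallenius_pvalue(length(overlap), length(cat_genes),
                            length(background) - length(cat_genes),
                            length(members), odds)
      data.frame(cluster = cl, term_id = tid,
                 n_category = length(cat_genes),
                 n_in_cluster = length(overlap),
                 cluster_size = length(members),
                 odds = odds, p_wallenius = p,
                 member_genes = paste(sort(overlap), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    recs$fdr <- bh_adjust(recs$p_wallenius)
    recs$enriched <- recs$fdr < fdr_cutoff
    out[[cl]] <- recs
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cluster, res$p_wallenius), ]
}
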