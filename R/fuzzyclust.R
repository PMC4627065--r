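## Fuzzy k-means clustering of DEG log2-ratio profiles.  Distances are
## correlation based (d = 1 - Pearson r between a gene profile and a
## centroid); memberships are squared positive correlations, normalised
## per gene; near-duplicate centroids are merged after convergence.

row_correlations <- function(x, centroids) {
  # Pearson correlation of each row of x with each row of centroids
  xs <- x - rowMeans(x)
  cs <- centroids - rowMeans(centroids)
  xn <- sqrt(rowSums(xs^2))
  cn <- sqrt(rowSums(cs^2))
  r <- (xs %*% t(cs)) / (xn %o% cn)
  r[!is.finite(r)] <- 0
  pmin(pmax(r, -1), 1)
}

membership_from_cor <- function(r) {
  w <- pmax(r, 0)^2
  tot <- rowSums(w)
  zero <- tot < 1e-12
  if (any(zero)) {
    # no positively correlated centroid: uninformative uniform membership
    w[zero, ] <- 1 / ncol(w)
    tot[zero] <- 1
  }
  w / tot
}

farthest_point_init <- function(x, k) {
  n <- nrow(x)
  first <- sample.int(n, 1L)
  centers <- integer(k)
  centers[1L] <- first
  mind <- 1 - row_correlations(x, x[first, , drop = FALSE])[, 1L]
  if (k > 1L) {
    for (j in 2:k) {
      cand <- which.max(mind)  # ties -> smallest index
      centers[j] <- cand
      dnew <- 1 - row_correlations(x, x[cand, , drop = FALSE])[, 1L]
      mind <- pmin(mind, dnew)
    }
  }
  centers
}

#' Fuzzy k-means clustering of expression profiles
#'
#' Iterative fuzzy clustering with correlation distance.  Raw membership
#' of gene g in cluster c is \code{max(r_gc, 0)^2} (r = Pearson
#' correlation of the gene profile with the centroid), normalised across
#' clusters; centroids are membership-weighted means.  Initial centers
#' come from farthest-point seeding on correlation distance, applied to
#' genes in sorted-id order so the result does not depend on input row
#' order.  Iteration stops when the maximum centroid movement falls
#' below \code{tol} or after \code{max_iter} sweeps; centroids whose
#' total membership drops below 1e-6 are removed.
#'
#' @param profiles numeric matrix genes x conditions (row names = gene ids).
#' @param k number of initial centers (default 60, reduced with a warning
#'   if fewer profiles are available).
#' @param seed integer seed for the initialisation.
#' @param tol convergence threshold on centroid movement (default 1e-4).
#' @param max_iter iteration cap (default 200).
#' @return A \code{fuzzy_clustering}: \code{centroids} (C x conditions),
#'   \code{membership} (genes x C, rows sum to 1), \code{objective}
#'   (per-iteration trace of sum of membership-weighted distances),
#'   \code{k_initial}, and bookkeeping fields.
#' @export
fuzzy_kmeans <- function(profiles, k = 60, seed = 1, tol = 1e-4,
                         max_iter = 200) {
  if (is.null(rownames(profiles))) stop("profiles must carry gene ids as row names")
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  v <- apply(profiles, 1L, stats::var)
  if (any(v < 1e-12)) {
    warning(sum(v < 1e-12), " constant profile(s) excluded (undefined correlation)")
    profiles <- profiles[v >= 1e-12, , drop = FALSE]
  }
  n <- nrow(profiles)
  if (n < 2L) stop("need at least 2 non-constant profiles")
  if (k > n) {
    warning("k = ", k, " exceeds ", n, " profiles; reduced to ", n)
    k <- n
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  centroids <- profiles[farthest_point_init(profiles, k), , drop = FALSE]
  rownames(centroids) <- NULL
  objective <- numeric(0L)
  for (it in seq_len(max_iter)) {
    r <- row_correlations(profiles, centroids)
    m <- membership_from_cor(r)
    objective <- c(objective, sum(m * (1 - r)))
    tot <- colSums(m)
    keep <- tot >= 1e-6
    new_cent <- (t(m[, keep, drop = FALSE]) %*% profiles) / tot[keep]
    moved <- if (sum(keep) == nrow(centroids)) {
      max(abs(new_cent - centroids))
    } else Inf
    centroids <- new_cent
    rownames(centroids) <- NULL
    if (moved < tol) break
  }
  r <- row_correlations(profiles, centroids)
  m <- membership_from_cor(r)
  colnames(m) <- rownames(centroids) <- paste0("C", seq_len(nrow(centroids)) - 1L)
  rownames(m) <- rownames(profiles)
  structure(list(centroids = centroids, membership = m,
                 profiles = profiles, objective = objective,
                 k_initial = k, seed = seed, iterations = it,
                 merge_threshold = NA_real_),
            class = "fuzzy_clustering")
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat("fuzzy_clustering:", nrow(x$membership), "genes,",
      nrow(x$centroids), "centroids (k_initial =", x$k_initial, ")\n")
  invisible(x)
}

#' Merge highly correlated centroids
#'
#' While any centroid pair has Pearson correlation above
#' \code{r_threshold}, the most correlated pair is replaced by its
#' membership-weighted mean.  Memberships are recomputed against the
#' final centroids and renormalised.  This is how an intentionally
#' generous initial k collapses to the number of distinct response
#' patterns actually present.
#'
#' @param clustering a \code{fuzzy_clustering}.
#' @param r_threshold correlation above which two centroids are
#'   considered duplicates (default 0.9).
#' @return A \code{fuzzy_clustering} with merged centroids.
#' @export
merge_centroids <- function(clustering, r_threshold = 0.9) {
  cent <- clustering$centroids
  wt <- colSums(clustering$membership)
  repeat {
    if (nrow(cent) < 2L) break
    r <- row_correlations(cent, cent)
    diag(r) <- -Inf
    if (max(r) <= r_threshold) break
    ij <- which(r == max(r), arr.ind = TRUE)[1L, ]
    i <- min(ij); j <- max(ij)
    cent[i, ] <- (wt[i] * cent[i, ] + wt[j] * cent[j, ]) / (wt[i] + wt[j])
    wt[i] <- wt[i] + wt[j]
    cent <- cent[-j, , drop = FALSE]
    wt <- wt[-j]
  }
  rownames(cent) <- paste0("C", seq_len(nrow(cent)) - 1L)
  out <- clustering
  out$centroids <- cent
  out$membership <- recompute_membership(clustering$profiles, cent)
  out$merge_threshold <- r_threshold
  out
}

#' Recompute memberships of profiles against a set of centroids
#' @param profiles numeric matrix genes x conditions.
#' @param centroids numeric matrix clusters x conditions.
#' @return Membership matrix genes x clusters, rows summing to 1.
#' @export
recompute_membership <- function(profiles, centroids) {
  r <- row_correlations(profiles, centroids)
  m <- membership_from_cor(r)
  dimnames(m) <- list(rownames(profiles), rownames(centroids))
  m
}

#' Threshold fuzzy memberships into cluster assignments
#'
#' A gene is assigned to every cluster in which its normalised
#' membership strictly exceeds \code{cutoff}; multi-assignment is
#' allowed, and genes below the cutoff everywhere remain unassigned.
#'
#' @param clustering a \code{fuzzy_clustering}.
#' @param cutoff membership threshold (default 0.12; 0.4 gives the
#'   strict assignment used for tight co-regulation).
#' @return data.frame with columns \code{gene}, \code{cluster},
#'   \code{membership}, one row per assignment.
#' @export
assign_members <- function(clustering, cutoff = 0.12) {
  m <- clustering$membership
  idx <- which(m > cutoff, arr.ind = TRUE)
  out <- data.frame(gene = rownames(m)[idx[, 1L]],
                    cluster = colnames(m)[idx[, 2L]],
                    membership = m[idx])
  out <- out[order(out$cluster, -out$membership, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Per-cluster summary table
#'
#' Member count, centroid profile and per-condition mean log2 fold
#' change of the assigned members for every cluster.
#'
#' @param clustering a \code{fuzzy_clustering}.
#' @param profiles the profile matrix the clustering was fitted on.
#' @param cutoff membership cutoff for assignment (default 0.12).
#' @return data.frame with one row per cluster: \code{cluster},
#'   \code{n_members}, then \code{centroid_<cond>} and
#'   \code{mean_<cond>} columns.
#' @export
cluster_summary <- function(clustering, profiles, cutoff = 0.12) {
  asg <- assign_members(clustering, cutoff)
  cls <- rownames(clustering$centroids)
  conds <- colnames(clustering$centroids)
  rows <- lapply(cls, function(cl) {
    genes <- asg$gene[asg$cluster == cl]
    means <- if (length(genes)) {
      colMeans(profiles[genes, , drop = FALSE])
    } else rep(NA_real_, length(conds))
    c(list(cluster = cl, n_members = length(genes)),
      stats::setNames(as.list(clustering$centroids[cl, ]),
                      paste0("centroid_", conds)),
      stats::setNames(as.list(means), paste0("mean_", conds)))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
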