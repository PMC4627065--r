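## Seeded synthetic-data generators for every pipeline input, with
## planted ground truth.  The generated design mirrors the study's:
## one pooled library per (tissue, temperature), 8 tissues at 28/18/10
## degrees C, no replicates; cluster-structured log2 fold-change
## patterns over the 16 cold-vs-control conditions; 1-kb promoters with
## planted IUPAC motifs; length-biased GO categories; typed interaction
## edges.

#' Configuration for the synthetic-data generators
#'
#' @param n_genes number of genes (default 2000).
#' @param tissues tissue labels (default the study's 8 abbreviations).
#' @param temperatures sampled temperatures in degrees C; the first is
#'   the control (default 28, 18, 10).
#' @param library_size expected mapped reads per pooled library
#'   (default 1e6).
#' @param length_range gene-length interval in bp (default 500-5000).
#' @param cluster_specs list of cluster plans, each
#'   \code{list(id, n, pattern)}; \code{pattern} is either a single
#'   log2 fold change applied to every cold condition or a named vector
#'   over \code{<tissue>_<temp>} conditions (unnamed conditions are 0).
#' @param motif_specs list of \code{list(cluster, consensus, freq,
#'   background)}: the IUPAC consensus is planted in a fraction
#'   \code{freq} of the cluster's promoters and \code{background} of all
#'   other promoters.
#' @param go_specs list of \code{list(term, size, length_biased,
#'   cluster, overlap)}: \code{overlap} member genes are drawn from the
#'   cluster, the rest from the background (length-weighted when
#'   \code{length_biased}).
#' @param interaction_specs list of \code{list(tf, degree)}: each TF
#'   node receives \code{degree} typed edges to sampled genes.
#' @param dispersion negative-binomial dispersion (variance
#'   \code{mu + dispersion * mu^2}; 0 gives Poisson counts).  The default
#'   0.02 keeps stable genes mostly within 2-fold between libraries, the
#'   regime in which no-replicate Fisher DEG calling is informative.
#' @param gc promoter background GC content (default 0.4).
#' @param promoter_length promoter window in bp (default 1000).
#' @param exact_consensus plant the consensus deterministically (first
#'   allowed base per ambiguity code) instead of sampling (default FALSE).
#' @param n_decoys decoy motifs added to the generated database (default 8).
#' @param seed integer seed; every generator derives its stream from it.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_genes = 2000,
                       tissues = c("br", "gi", "he", "in", "ki", "li", "mu", "sp"),
                       temperatures = c(28, 18, 10),
                       library_size = 1e6,
                       length_range = c(500, 5000),
                       cluster_specs = default_cluster_specs(tissues, temperatures,
                                                             n_genes),
                       motif_specs = default_motif_specs(),
                       go_specs = default_go_specs(n_genes),
                       interaction_specs = default_interaction_specs(),
                       dispersion = 0.02,
                       gc = 0.4,
                       promoter_length = 1000,
                       exact_consensus = FALSE,
                       n_decoys = 8,
                       seed = 1) {
  if (library_size <= 0) stop("library_size must be positive")
  if (length(tissues) == 0L) stop("tissue list is empty")
  if (n_genes < 1L) stop("n_genes must be positive")
  n_members <- sum(vapply(cluster_specs, function(s) s$n, numeric(1L)))
  if (n_members > n_genes) stop("cluster member counts exceed n_genes")
  for (s in motif_specs) {
    if (s$freq < 0 || s$freq > 1 || s$background < 0 || s$background > 1) {
      stop("planting frequencies must lie in [0, 1]")
    }
    if (s$freq > 0 && s$freq <= s$background) {
      stop("planting frequency must exceed the background frequency for ",
           s$consensus)
    }
    if (nchar(s$consensus) > promoter_length) {
      stop("motif longer than the promoter window: ", s$consensus)
    }
  }
  for (s in go_specs) {
    if (s$size > n_genes) stop("GO term ", s$term, " larger than n_genes")
  }
  structure(list(n_genes = n_genes, tissues = tissues,
                 temperatures = temperatures, library_size = library_size,
                 length_range = length_range, cluster_specs = cluster_specs,
                 motif_specs = motif_specs, go_specs = go_specs,
                 interaction_specs = interaction_specs,
                 dispersion = dispersion, gc = gc,
                 promoter_length = promoter_length,
                 exact_consensus = exact_consensus,
                 n_decoys = n_decoys, seed = as.integer(seed)),
            class = "sim_config")
}

#' @noRd
default_cluster_specs <- function(tissues, temperatures, n_genes = 2000) {
  cold <- setdiff(temperatures, temperatures[1L])
  conds <- as.vector(outer(tissues, cold, paste, sep = "_"))
  severe <- grep(paste0("_", min(temperatures), "$"), conds, value = TRUE)
  two_tissues <- grep(paste0("^(", tissues[1L], "|", tissues[2L], ")_"),
                      conds, value = TRUE)
  n <- max(1L, min(100L, n_genes %/% 6L))  # scale members to the genome
  # patterns are condition-structured (not flat across all 16 conditions):
  # correlation-based clustering is blind to a gene's overall level, so
  # distinguishable clusters must differ in profile shape
  list(
    list(id = "K0", n = n,                    # induced in severe cold only
         pattern = stats::setNames(rep(2, length(severe)), severe)),
    list(id = "K1", n = n,                    # repressed in severe cold only
         pattern = stats::setNames(rep(-2, length(severe)), severe)),
    list(id = "K2", n = n,                    # induced in two tissues, both colds
         pattern = stats::setNames(rep(2, length(two_tissues)), two_tissues))
  )
}

#' @noRd
default_motif_specs <- function() {
  list(list(cluster = "K0", consensus = "TGACTCA", freq = 0.4, background = 0.05),
       list(cluster = "K1", consensus = "WCACCTGW", freq = 0.35, background = 0.05))
}

#' @noRd
default_go_specs <- function(n_genes = 2000) {
  s1 <- min(60L, max(4L, n_genes %/% 12L))
  ov <- min(25L, s1 %/% 2L, max(1L, n_genes %/% 6L))
  list(list(term = "GO:SYN0001", size = s1, length_biased = FALSE,
            cluster = "K0", overlap = ov),
       list(term = "GO:SYN0002", size = min(80L, max(4L, n_genes %/% 10L)),
            length_biased = TRUE, cluster = NA_character_, overlap = 0),
       list(term = "GO:SYN0003", size = min(50L, max(4L, n_genes %/% 12L)),
            length_biased = FALSE, cluster = NA_character_, overlap = 0))
}

#' @noRd
default_interaction_specs <- function() {
  list(list(tf = "TF_TGACTCA", degree = 5),
       list(tf = "TF_WCACCTGW", degree = 3))
}

# run code with a derived, restorable RNG stream
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

#' Cold-condition labels of a configuration
#' @param config a \code{sim_config}.
#' @return Character vector \code{<tissue>_<temp>} over cold conditions.
#' @export
sim_conditions <- function(config) {
  cold <- setdiff(config$temperatures, config$temperatures[1L])
  as.vector(outer(config$tissues, cold, paste, sep = "_"))
}

expand_pattern <- function(pattern, conds) {
  out <- stats::setNames(rep(0, length(conds)), conds)
  if (is.null(names(pattern)) && length(pattern) == 1L) {
    out[] <- pattern
  } else {
    bad <- setdiff(names(pattern), conds)
    if (length(bad)) stop("unknown condition in cluster pattern: ", bad[1L])
    out[names(pattern)] <- pattern
  }
  out
}

#' Generate the synthetic count table and its ground truth
#'
#' Gene lengths are uniform over \code{length_range}; a per-gene
#' baseline expression level is log-normal; the expected read count of
#' a gene in a library is proportional to gene length times expression
#' (so RPKM removes the length factor), scaled by the planted log2 fold
#' change for cluster members in cold libraries, and normalised so the
#' expected column sum equals \code{library_size}.  Counts are negative
#' binomial with the configured dispersion (Poisson when dispersion is
#' 0).
#'
#' @param config a \code{\link{sim_config}}.
#' @return List: \code{table} (a \code{\link{count_table}}) and
#'   \code{truth} (per-gene cluster id, the planted log2 fold-change
#'   matrix over cold conditions, and per-(tissue, comparison) true-DE
#'   flags).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 101L, {
    n <- config$n_genes
    gene_id <- sprintf("g%04d", seq_len(n))
    len <- round(stats::runif(n, config$length_range[1L], config$length_range[2L]))
    expr <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
    conds <- sim_conditions(config)
    lfc <- matrix(0, n, length(conds), dimnames = list(gene_id, conds))
    cluster <- rep(NA_character_, n)
    at <- 1L
    for (s in config$cluster_specs) {
      rows <- at:(at + s$n - 1L)
      cluster[rows] <- s$id
      lfc[rows, ] <- matrix(expand_pattern(s$pattern, conds), s$n,
                            length(conds), byrow = TRUE)
      at <- at + s$n
    }
    base_w <- (len / 1e3) * expr
    libs <- as.vector(outer(config$tissues, config$temperatures,
                            function(ti, te) paste0(ti, "_", te, "C")))
    counts <- matrix(0L, n, length(libs), dimnames = list(gene_id, libs))
    control <- config$temperatures[1L]
    for (j in seq_along(libs)) {
      lab <- sub("C$", "", libs[j])
      w <- base_w
      if (!endsWith(lab, paste0("_", control))) {
        w <- w * 2^lfc[, lab]
      }
      mu <- w / sum(w) * config$library_size
      counts[, j] <- if (config$dispersion > 0) {
        stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
      } else {
        stats::rpois(n, mu)
      }
    }
    cmp <- temperature_comparisons()
    de_true <- list()
    for (ti in config$tissues) {
      for (i in seq_len(nrow(cmp))) {
        ref_lab <- paste0(ti, "_", cmp$t_ref[i])
        cold_lab <- paste0(ti, "_", cmp$t_cold[i])
        ref_lfc <- if (ref_lab %in% conds) lfc[, ref_lab] else 0
        cold_lfc <- if (cold_lab %in% conds) lfc[, cold_lab] else 0
        de_true[[paste(ti, cmp$label[i], sep = ".")]] <- cold_lfc != ref_lfc
      }
    }
    truth <- list(gene_id = gene_id, cluster = stats::setNames(cluster, gene_id),
                  lfc = lfc, de = do.call(cbind, de_true),
                  baseline_expression = stats::setNames(expr, gene_id))
    list(table = count_table(counts, len, gene_id), truth = truth)
  })
}

#' Generate promoters, annotation and a matching synthetic genome
#'
#' Each promoter is \code{promoter_length} bp of i.i.d. background
#' sequence at the configured GC content.  For every motif spec the
#' consensus is instantiated (ambiguity codes resolved uniformly, or
#' deterministically under \code{exact_consensus}) at a uniform position
#' and strand in the stated fraction of in-cluster promoters and at the
#' background frequency elsewhere.  A one-contig-per-gene genome and a
#' BED6 annotation consistent with the promoters (random gene strand)
#' are also produced, so promoter extraction can be exercised
#' end-to-end.
#'
#' @param truth ground truth from \code{\link{generate_counts}}.
#' @param config a \code{\link{sim_config}}.
#' @return List: \code{promoters} (named character), \code{bed}
#'   (BED6 data.frame), \code{genome} (named character, one contig per
#'   gene), \code{planted} (data.frame of planted instances: gene,
#'   consensus, position, strand).
#' @export
generate_promoters <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 202L, {
    genes <- truth$gene_id
    L <- config$promoter_length
    prom <- stats::setNames(random_dna(length(genes), L, config$gc), genes)
    planted <- list()
    for (s in config$motif_specs) {
      m <- nchar(s$consensus)
      in_cluster <- !is.na(truth$cluster) & truth$cluster == s$cluster
      plant_p <- ifelse(in_cluster, s$freq, s$background)
      do_plant <- stats::runif(length(genes)) < plant_p
      for (i in which(do_plant)) {
        inst <- instantiate_iupac(s$consensus, config$exact_consensus)
        if (stats::runif(1) < 0.5) inst <- iupac_revcomp(inst)
        pos <- sample.int(L - m + 1L, 1L)
        substr(prom[i], pos, pos + m - 1L) <- inst
        planted[[length(planted) + 1L]] <-
          data.frame(gene = genes[i], consensus = s$consensus,
                     position = pos, strand = "*", stringsAsFactors = FALSE)
      }
    }
    strand <- sample(c("+", "-"), length(genes), replace = TRUE)
    stub <- 20L
    body <- random_dna(length(genes), stub, config$gc)
    genome <- character(length(genes))
    bed <- vector("list", length(genes))
    for (i in seq_along(genes)) {
      ctg <- paste0("ctg_", genes[i])
      if (strand[i] == "+") {
        genome[i] <- paste0(prom[i], body[i])
        bed[[i]] <- data.frame(chrom = ctg, start = L, end = L + stub,
                               name = genes[i], score = 0L, strand = "+")
      } else {
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(prom[i])))
        genome[i] <- paste0(body[i], rc)
        bed[[i]] <- data.frame(chrom = ctg, start = 0L, end = stub,
                               name = genes[i], score = 0L, strand = "-")
      }
    }
    names(genome) <- paste0("ctg_", genes)
    list(promoters = prom, bed = do.call(rbind, bed), genome = genome,
         planted = if (length(planted)) do.call(rbind, planted) else
           data.frame(gene = character(), consensus = character(),
                      position = integer(), strand = character()))
  })
}

#' Generate a gene-to-GO annotation table
#'
#' Terms have the configured sizes; length-biased terms sample genes
#' with probability proportional to the square of the gene-length rank,
#' and planted-enriched terms take their stated overlap from the
#' cluster's members before filling up from the background.
#'
#' @param truth ground truth from \code{\link{generate_counts}}.
#' @param config a \code{\link{sim_config}}.
#' @param gene_lengths named vector of gene lengths (from the count
#'   table) used for the length bias.
#' @return data.frame with columns \code{gene_id}, \code{term_id},
#'   \code{term_name}.
#' @export
generate_go_annotations <- function(truth, config, gene_lengths) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 303L, {
    genes <- truth$gene_id
    lens <- gene_lengths[genes]
    rows <- list()
    for (s in config$go_specs) {
      picked <- character(0L)
      if (!is.na(s$cluster) && s$overlap > 0) {
        members <- genes[!is.na(truth$cluster) & truth$cluster == s$cluster]
        picked <- sample(members, min(s$overlap, length(members)))
      }
      pool <- setdiff(genes, picked)
      prob <- if (isTRUE(s$length_biased)) rank(lens[pool])^2 else NULL
      picked <- c(picked, sample(pool, s$size - length(picked), prob = prob))
      rows[[s$term]] <- data.frame(gene_id = sort(picked), term_id = s$term,
                                   term_name = s$term, stringsAsFactors = FALSE)
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Generate a known-motif database with planted consensi and decoys
#'
#' The database holds each planted consensus as a uniform-over-allowed
#'-bases position frequency matrix, plus random 8-mer decoys kept only
#' if their consensus distance to every planted motif is at least 3.
#'
#' @param config a \code{\link{sim_config}}.
#' @return Named list of motifs in the \code{\link{read_meme}} shape.
#' @export
generate_motif_db <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 404L, {
    planted <- vapply(config$motif_specs, function(s) s$consensus, character(1L))
    db <- list()
    for (i in seq_along(planted)) {
      id <- sprintf("SYN%04d", i)
      db[[id]] <- list(id = id, name = paste0("TF_", planted[i]),
                       pfm = consensus_to_pfm(planted[i]))
    }
    n_added <- 0L
    tries <- 0L
    while (n_added < config$n_decoys && tries < 1000L) {
      tries <- tries + 1L
      w <- paste(sample(c("A", "C", "G", "T"), 8L, replace = TRUE),
                 collapse = "")
      dmin <- min(vapply(planted, function(p) {
        consensus_distance(w, p)$mismatch
      }, numeric(1L)))
      if (dmin >= 3) {
        n_added <- n_added + 1L
        id <- sprintf("DEC%04d", n_added)
        db[[id]] <- list(id = id, name = paste0("decoy_", n_added),
                         pfm = consensus_to_pfm(w))
      }
    }
    db
  })
}

#' Generate a typed interaction edge list with planted TF degrees
#'
#' Each configured TF node receives exactly \code{degree} edges to
#' distinct sampled genes; evidence types are drawn from
#' \code{physical}, \code{colocalization}, \code{genetic}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth ground truth from \code{\link{generate_counts}} (edge
#'   partners are drawn preferentially from cluster members).
#' @return data.frame with columns \code{node_a}, \code{node_b},
#'   \code{evidence}.
#' @export
generate_interactions <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 505L, {
    members <- truth$gene_id[!is.na(truth$cluster)]
    if (length(members) == 0L) members <- truth$gene_id
    rows <- list()
    for (s in config$interaction_specs) {
      partners <- sample(members, min(s$degree, length(members)))
      rows[[s$tf]] <- data.frame(
        node_a = s$tf, node_b = partners,
        evidence = sample(c("physical", "colocalization", "genetic"),
                          length(partners), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write every synthetic input to a directory
#'
#' Runs all generators and writes \code{counts.tsv},
#' \code{promoters.fa}, \code{annotation.bed}, \code{genome.fa},
#' \code{motif_db.meme}, \code{edges.tsv} and \code{truth.json}.
#' Identical seeds give byte-identical files.
#'
#' @param config a \code{\link{sim_config}}.
#' @param outdir output directory (created if missing).
#' @return Named list of the generated objects, invisibly.
#' @export
simulate_inputs <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cx <- generate_counts(config)
  pr <- generate_promoters(cx$truth, config)
  go <- generate_go_annotations(cx$truth, config,
                                stats::setNames(cx$table$gene_length,
                                                cx$table$gene_id))
  db <- generate_motif_db(config)
  edges <- generate_interactions(config, cx$truth)
  write_counts(cx$table, file.path(outdir, "counts.tsv"))
  writeLines(paste0(">", names(pr$promoters), "\n", pr$promoters),
             file.path(outdir, "promoters.fa"))
  writeLines(paste0(">", names(pr$genome), "\n", pr$genome),
             file.path(outdir, "genome.fa"))
  utils::write.table(pr$bed, file.path(outdir, "annotation.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(go, file.path(outdir, "go_annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_meme(db, file.path(outdir, "motif_db.meme"))
  utils::write.table(edges, file.path(outdir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_out <- list(cluster = as.list(cx$truth$cluster[!is.na(cx$truth$cluster)]),
                    planted_motifs = pr$planted,
                    enriched_terms = vapply(
                      Filter(function(s) !is.na(s$cluster) && s$overlap > 0,
                             config$go_specs),
                      function(s) s$term, character(1L)))
  jsonlite::write_json(truth_out, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(counts = cx$table, truth = cx$truth, promoters = pr,
                 go = go, db = db, edges = edges))
}
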