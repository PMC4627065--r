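## End-to-end pipeline execution with a single manifest of every
## threshold, stage-wise resumability, and a machine-readable summary.

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults equal to the published
#' thresholds: fold change 2, adjusted P 0.001, k = 60, membership
#' cutoffs 0.12 and 0.4, 1-kb promoter window, motif E-value 0.05,
#' GO FDR 0.05, database match P 5e-3 and mismatch bound 2.
#'
#' @param simulate generate inputs with the synthetic module (default
#'   TRUE); otherwise \code{inputs} must name existing files.
#' @param sim a \code{\link{sim_config}} used when simulating.
#' @param inputs named list of paths (\code{counts}, \code{promoters}
#'   or \code{genome} + \code{annotation}, \code{go}, \code{motif_db},
#'   \code{edges}) used when \code{simulate = FALSE}.
#' @param fc,padj,pseudocount,min_reads DEG-stage parameters.
#' @param k,merge_r,cutoffs clustering parameters (initial centers,
#'   centroid-merge correlation, membership cutoffs).
#' @param go_fdr GO enrichment FDR threshold.
#' @param window,e_cutoff,beam,max_motifs,min_len,max_len motif-search
#'   parameters.
#' @param db_p,db_mismatch,db_n_null database-matching parameters.
#' @param min_cluster_size smallest positive set submitted to motif
#'   discovery (default 10).
#' @param seed global seed, fanned out to the stages by fixed offsets.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(simulate = TRUE, sim = sim_config(seed = seed),
                            inputs = list(),
                            fc = 2, padj = 0.001, pseudocount = 1,
                            min_reads = 5,
                            k = 60, merge_r = 0.9, cutoffs = c(0.12, 0.4),
                            go_fdr = 0.05,
                            window = 1000, e_cutoff = 0.05, beam = 10,
                            max_motifs = 10, min_len = 3, max_len = 8,
                            db_p = 5e-3, db_mismatch = 2, db_n_null = 10000,
                            min_cluster_size = 10,
                            seed = 1) {
  structure(list(simulate = simulate, sim = sim, inputs = inputs,
                 fc = fc, padj = padj, pseudocount = pseudocount,
                 min_reads = min_reads, k = k, merge_r = merge_r,
                 cutoffs = cutoffs, go_fdr = go_fdr, window = window,
                 e_cutoff = e_cutoff, beam = beam, max_motifs = max_motifs,
                 min_len = min_len, max_len = max_len, db_p = db_p,
                 db_mismatch = db_mismatch, db_n_null = db_n_null,
                 min_cluster_size = min_cluster_size,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_run <- function(name, outdir, outputs, resume, code) {
  paths <- file.path(outdir, outputs)
  if (resume && all(file.exists(paths))) {
    message("[", name, "] outputs present; skipped (resume)")
    return(invisible(NULL))
  }
  tryCatch(code, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> DEG calling -> MDS -> fuzzy
#' clustering -> GO enrichment -> motif discovery per cluster at each
#' membership cutoff -> database annotation -> network assembly,
#' writing every stage output, the resolved configuration
#' (\code{config.yaml}) and a machine-readable \code{summary.json}
#' into \code{outdir}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param outdir run directory (created if missing).
#' @param resume skip stages whose outputs already exist (default FALSE).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, outdir, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_out <- config
  cfg_out$sim <- unclass(config$sim)
  yaml::write_yaml(unclass(cfg_out), file.path(outdir, "config.yaml"))

  indir <- file.path(outdir, "inputs")
  if (config$simulate) {
    stage_run("simulate", indir,
              c("counts.tsv", "promoters.fa", "go_annotations.tsv",
                "motif_db.meme", "edges.tsv"), resume, {
      simulate_inputs(config$sim, indir)
    })
    paths <- list(counts = file.path(indir, "counts.tsv"),
                  promoters = file.path(indir, "promoters.fa"),
                  go = file.path(indir, "go_annotations.tsv"),
                  motif_db = file.path(indir, "motif_db.meme"),
                  edges = file.path(indir, "edges.tsv"))
  } else {
    paths <- config$inputs
    missing <- vapply(paths, function(p) !file.exists(p), logical(1L))
    if (any(missing)) {
      stop("missing input path(s): ",
           paste(unlist(paths[missing]), collapse = ", "))
    }
  }

  counts <- read_counts(paths$counts)
  degs <- call_degs(counts, fc_threshold = config$fc,
                    padj_threshold = config$padj,
                    pseudocount = config$pseudocount,
                    min_reads = config$min_reads)
  utils::write.table(degs$records, file.path(outdir, "degs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  strict <- strict_deg_union(degs)
  if (length(strict) < 2L) stop("pipeline stage 'deg' failed: fewer than 2 strict DEGs")

  mds <- mds_samples(degs$rpkm)
  utils::write.table(data.frame(sample = rownames(mds$points),
                                x = mds$points[, 1L], y = mds$points[, 2L]),
                     file.path(outdir, "mds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  profiles <- build_profiles(degs$rpkm, genes = strict,
                             pseudocount = config$pseudocount)
  utils::write.table(data.frame(gene = rownames(profiles), profiles,
                                check.names = FALSE),
                     file.path(outdir, "profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cl <- fuzzy_kmeans(profiles, k = config$k, seed = config$seed + 11L)
  cl <- merge_centroids(cl, r_threshold = config$merge_r)
  utils::write.table(data.frame(cluster = rownames(cl$centroids),
                                cl$centroids, check.names = FALSE),
                     file.path(outdir, "centroids.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(cl$membership),
                                cl$membership, check.names = FALSE),
                     file.path(outdir, "membership.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  assignments <- assign_members(cl, cutoff = config$cutoffs[1L])
  utils::write.table(assignments, file.path(outdir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  go_table <- utils::read.delim(paths$go, stringsAsFactors = FALSE)
  pwf <- fit_pwf(stats::setNames(degs$table$gene_id %in% strict,
                                 degs$table$gene_id),
                 degs$table$gene_length)
  enrichment <- enrich_clusters(assignments, go_table, pwf,
                                fdr_cutoff = config$go_fdr)
  utils::write.table(enrichment, file.path(outdir, "go_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  promoters <- read_promoter_fasta(paths$promoters)
  negatives_genes <- build_negative_set(degs, fold = config$fc)
  negatives <- promoters[intersect(negatives_genes, names(promoters))]
  motif_rows <- list()
  for (cutoff in config$cutoffs) {
    asg <- assign_members(cl, cutoff = cutoff)
    for (clu in unique(asg$cluster)) {
      pos_genes <- asg$gene[asg$cluster == clu]
      pos <- promoters[intersect(pos_genes, names(promoters))]
      if (length(pos) < config$min_cluster_size) next
      found <- discover_motifs(pos, negatives, min_len = config$min_len,
                               max_len = config$max_len,
                               e_cutoff = config$e_cutoff,
                               beam = config$beam,
                               max_motifs = config$max_motifs)
      if (nrow(found)) {
        found$cluster <- clu
        found$cutoff <- cutoff
        motif_rows[[paste(clu, cutoff)]] <- found
      }
    }
  }
  motifs <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    data.frame(consensus = character(), pos_with = integer(),
               pos_total = integer(), neg_with = integer(),
               neg_total = integer(), p_value = numeric(),
               e_value = numeric(), candidates_evaluated = integer(),
               round = integer(), cluster = character(), cutoff = numeric())
  rownames(motifs) <- NULL

  if (nrow(motifs)) {
    db <- read_meme(paths$motif_db)
    ann <- match_to_db(unique(motifs["consensus"]), db,
                       max_mismatch = config$db_mismatch,
                       p_cutoff = config$db_p, n_null = config$db_n_null,
                       seed = config$seed + 13L)
    motifs <- merge(motifs, ann[c("consensus", "annotation", "db_id",
                                  "mismatch", "match_p")],
                    by = "consensus", all.x = TRUE, sort = FALSE)
    write_meme(unique(motifs["consensus"]),
               file.path(outdir, "motifs_discovered.meme"))
    mgt <- motif_gene_table(unique(motifs["consensus"]), promoters)
    go_mat <- motif_go_matrix(mgt, enrichment[enrichment$enriched, , drop = FALSE])
    utils::write.table(data.frame(term = rownames(go_mat), go_mat,
                                  check.names = FALSE),
                       file.path(outdir, "motif_go_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tf_map <- ann[ann$annotation != "Novel", c("consensus", "db_name")]
    names(tf_map)[2L] <- "tf"
    edges <- utils::read.delim(paths$edges, stringsAsFactors = FALSE)
    network <- build_network(mgt, tf_map, edges)
    write_network(network, file.path(outdir, "network"))
    degrees <- tf_degree(network)
  } else {
    ann <- NULL; network <- NULL; degrees <- integer(0L)
  }
  utils::write.table(motifs, file.path(outdir, "motif_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  summary <- list(
    n_genes = length(counts$gene_id),
    n_expressed = length(degs$table$gene_id),
    n_loose_degs = length(loose_deg_union(degs)),
    n_strict_degs = length(strict),
    n_clusters = nrow(cl$centroids),
    n_assigned_genes = length(unique(assignments$gene)),
    n_enriched_terms = sum(enrichment$enriched),
    n_motifs = nrow(motifs),
    n_known_motifs = if (!is.null(ann)) sum(motifs$annotation != "Novel") else 0L,
    n_novel_motifs = if (!is.null(ann)) sum(motifs$annotation == "Novel") else 0L,
    n_network_nodes = if (!is.null(network)) network$n_nodes else 0L,
    n_network_edges = if (!is.null(network)) network$n_interaction_edges else 0L,
    tf_degrees = as.list(degrees),
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Read a promoter FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_promoter_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
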