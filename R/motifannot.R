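## Matching discovered consensus motifs to a known-motif database and
## building the motif-GO association matrix.  Database PFMs are reduced
## to IUPAC consensus strings; similarity is an ungapped consensus
## distance with an empirical null over shuffled query words.

#' Read a MEME minimal format motif file
#'
#' Parses the plain-text motif exchange format: a version line, an
#' alphabet line, optional background frequencies, then one
#' \code{MOTIF} block per motif with a letter-probability matrix.
#'
#' @param path path to a MEME minimal file.
#' @return Named list of motifs; each element has \code{name},
#'   \code{id} and \code{pfm} (4 x width matrix, rows A, C, G, T).
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty motif file: ", path)
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) stop("no MOTIF blocks in ", path)
  motifs <- list()
  for (s in starts) {
    toks <- strsplit(trimws(lines[s]), "\\s+")[[1L]]
    id <- toks[2L]
    name <- if (length(toks) >= 3L) toks[3L] else id
    hdr <- grep("^letter-probability matrix", lines[(s + 1L):length(lines)])[1L]
    if (is.na(hdr)) stop("motif ", id, " lacks a letter-probability matrix")
    hdr <- s + hdr
    wtok <- regmatches(lines[hdr], regexec("w=\\s*([0-9]+)", lines[hdr]))[[1L]]
    w <- as.integer(wtok[2L])
    rows <- lines[(hdr + 1L):(hdr + w)]
    pfm <- t(vapply(rows, function(x) {
      as.numeric(strsplit(trimws(x), "\\s+")[[1L]][1:4])
    }, numeric(4L)))
    pfm <- t(pfm)  # 4 x w
    rownames(pfm) <- c("A", "C", "G", "T")
    colnames(pfm) <- NULL
    motifs[[id]] <- list(id = id, name = name, pfm = pfm)
  }
  motifs
}

#' Write motifs in MEME minimal format
#' @param motifs named list as returned by \code{\link{read_meme}}, or a
#'   data.frame with a \code{consensus} column (consensus strings are
#'   expanded to uniform-over-allowed-bases PFMs).
#' @param path output path.
#' @param background named background frequencies (A, C, G, T).
#' @return \code{path}, invisibly.
#' @export
write_meme <- function(motifs, path,
                       background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  if (is.data.frame(motifs)) {
    motifs <- stats::setNames(lapply(seq_len(nrow(motifs)), function(i) {
      cons <- motifs$consensus[i]
      list(id = cons, name = cons, pfm = consensus_to_pfm(cons))
    }), motifs$consensus)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               paste(sprintf("%s %.5f", names(background), background),
                     collapse = " "), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s %s", m$id, m$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(m$pfm)), con)
    for (j in seq_len(ncol(m$pfm))) {
      writeLines(paste(sprintf("%.6f", m$pfm[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' @noRd
consensus_to_pfm <- function(consensus) {
  m <- iupac_masks(consensus)
  pfm <- vapply(m, function(mask) {
    allowed <- bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L
    allowed / sum(allowed)
  }, numeric(4L))
  rownames(pfm) <- c("A", "C", "G", "T")
  pfm
}

#' Read JASPAR PFM text format
#'
#' Parses entries of the form \code{>MA0099.2 Jun::Fos} followed by four
#' rows \code{A [ 1 2 3 ... ]} (brackets optional).
#'
#' @param path path to a JASPAR PFM text file.
#' @return Named list of motifs as in \code{\link{read_meme}}, with
#'   column-normalised PFMs.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no JASPAR entries in ", path)
  motifs <- list()
  for (s in starts) {
    toks <- strsplit(sub("^>", "", trimws(lines[s])), "\\s+")[[1L]]
    id <- toks[1L]
    name <- if (length(toks) >= 2L) paste(toks[-1L], collapse = " ") else id
    rows <- lines[(s + 1L):(s + 4L)]
    counts <- t(vapply(rows, function(x) {
      x <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", trimws(x))
      as.numeric(strsplit(trimws(x), "\\s+")[[1L]])
    }, numeric(length(strsplit(trimws(gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "",
                                           trimws(rows[1L]))), "\\s+")[[1L]]))))
    pfm <- sweep(counts, 2L, colSums(counts), "/")
    rownames(pfm) <- c("A", "C", "G", "T")
    motifs[[id]] <- list(id = id, name = name, pfm = pfm)
  }
  motifs
}

#' Reduce a position frequency matrix to an IUPAC consensus
#'
#' Each column becomes the ambiguity code covering every base whose
#' frequency is at least \code{threshold}; if no base reaches the
#' threshold the most frequent base is used.
#'
#' @param pfm 4 x width matrix with rows A, C, G, T (column-normalised).
#' @param threshold inclusion frequency (default 0.25).
#' @return IUPAC consensus string.
#' @export
pfm_to_iupac <- function(pfm, threshold = 0.25) {
  stopifnot(nrow(pfm) == 4L)
  codes <- vapply(seq_len(ncol(pfm)), function(j) {
    sel <- pfm[, j] >= threshold
    if (!any(sel)) sel <- pfm[, j] == max(pfm[, j])
    mask_to_letter[sum(c(1L, 2L, 4L, 8L)[sel])]
  }, character(1L))
  paste(codes, collapse = "")
}

#' Ungapped consensus distance between two IUPAC words
#'
#' Over all ungapped offsets whose overlap is at least
#' \code{min(length) - 1} and both strands of the target, the minimum
#' number of overlapping positions whose IUPAC base sets are disjoint.
#' Positions with intersecting sets (e.g. \code{M} vs \code{A}) count as
#' matches; overhanging positions are free.
#'
#' @param query,target IUPAC strings.
#' @return List: \code{mismatch}, \code{offset} (of the query start
#'   relative to the target start at the optimum), \code{strand}
#'   (\code{"+"} or \code{"-"}).
#' @export
consensus_distance <- function(query, target) {
  if (nchar(query) == 0L || nchar(target) == 0L) stop("empty consensus string")
  qm <- iupac_masks(query)
  best <- list(mismatch = Inf, offset = 0L, strand = "+")
  for (strand in c("+", "-")) {
    tg <- if (strand == "+") target else iupac_revcomp(target)
    tm <- iupac_masks(tg)
    lq <- length(qm); lt <- length(tm)
    min_overlap <- min(lq, lt) - 1L
    for (off in (-lq + 1L):(lt - 1L)) {
      qi <- max(1L, 1L - off):min(lq, lt - off)
      if (length(qi) < min_overlap || min_overlap < 1L) next
      ti <- qi + off
      mm <- sum(bitwAnd(qm[qi], tm[ti]) == 0L)
      if (mm < best$mismatch) best <- list(mismatch = mm, offset = off, strand = strand)
    }
  }
  best
}

#' Match discovered motifs against a known-motif database
#'
#' Each database PFM is reduced to an IUPAC consensus
#' (\code{\link{pfm_to_iupac}}).  A discovered motif matches a database
#' entry when the \code{\link{consensus_distance}} mismatch count is
#' strictly below \code{max_mismatch} and the empirical match P — the
#' fraction of \code{n_null} random words with the query's code
#' composition achieving a mismatch count at most as small — is below
#' \code{p_cutoff}.  Motifs with no retained match are labelled
#' \code{"Novel"}.
#'
#' @param motifs data.frame with a \code{consensus} column.
#' @param db named list of database motifs (\code{\link{read_meme}} /
#'   \code{\link{read_jaspar}}).
#' @param max_mismatch mismatch bound, exclusive (default 2: "fewer than
#'   2 bases different").
#' @param p_cutoff empirical-P threshold (default 5e-3).
#' @param n_null null words drawn per comparison (default 10000).
#' @param seed RNG seed for the null draws.
#' @param iupac_threshold PFM reduction threshold (default 0.25).
#' @return data.frame: one row per discovered motif with its best
#'   retained match (\code{db_id}, \code{db_name}, \code{mismatch},
#'   \code{offset}, \code{strand}, \code{match_p}) or
#'   \code{annotation = "Novel"}.
#' @export
match_to_db <- function(motifs, db, max_mismatch = 2, p_cutoff = 5e-3,
                        n_null = 10000, seed = 1, iupac_threshold = 0.25) {
  if (length(db) == 0L) stop("empty motif database")
  db_cons <- vapply(db, function(m) pfm_to_iupac(m$pfm, iupac_threshold),
                    character(1L))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    q <- motifs$consensus[i]
    qletters <- strsplit(q, "", fixed = TRUE)[[1L]]
    best <- NULL
    for (j in seq_along(db)) {
      d <- consensus_distance(q, db_cons[j])
      if (d$mismatch >= max_mismatch) next
      # empirical null: random words with the query's code composition
      null_mm <- vapply(seq_len(n_null), function(r) {
        w <- paste(sample(qletters), collapse = "")
        consensus_distance(w, db_cons[j])$mismatch
      }, numeric(1L))
      p <- (sum(null_mm <= d$mismatch) + 1) / (n_null + 1)
      if (p >= p_cutoff) next
      if (is.null(best) || d$mismatch < best$mismatch ||
          (d$mismatch == best$mismatch && p < best$match_p)) {
        best <- data.frame(consensus = q, db_id = names(db)[j],
                           db_name = db[[j]]$name, db_consensus = db_cons[j],
                           mismatch = d$mismatch, offset = d$offset,
                           strand = d$strand, match_p = p,
                           annotation = paste0(db[[j]]$name, "(", names(db)[j], ")"),
                           stringsAsFactors = FALSE)
      }
    }
    if (is.null(best)) {
      best <- data.frame(consensus = q, db_id = NA_character_,
                         db_name = NA_character_, db_consensus = NA_character_,
                         mismatch = NA_integer_, offset = NA_integer_,
                         strand = NA_character_, match_p = NA_real_,
                         annotation = "Novel", stringsAsFactors = FALSE)
    }
    best
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motif-GO association matrix
#'
#' For every (enriched term, motif) pair within a cluster, the
#' percentage of the term's annotated cluster genes whose promoter
#' bears the motif.
#'
#' @param motif_gene_table logical matrix genes x motifs
#'   (\code{\link{motif_gene_table}}).
#' @param enrichment_records data.frame from
#'   \code{\link{enrich_clusters}} (uses \code{term_id},
#'   \code{member_genes}).
#' @return Numeric matrix terms x motifs of percentages in [0, 100].
#' @export
motif_go_matrix <- function(motif_gene_table, enrichment_records) {
  terms <- enrichment_records$term_id
  motifs <- colnames(motif_gene_table)
  out <- matrix(NA_real_, length(terms), length(motifs),
                dimnames = list(paste(enrichment_records$cluster, terms,
                                      sep = ":"), motifs))
  for (i in seq_along(terms)) {
    genes <- strsplit(enrichment_records$member_genes[i], ",", fixed = TRUE)[[1L]]
    genes <- intersect(genes, rownames(motif_gene_table))
    if (length(genes) == 0L) { out[i, ] <- 0; next }
    out[i, ] <- 100 * colMeans(motif_gene_table[genes, , drop = FALSE])
  }
  out
}
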