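## Discriminative IUPAC motif discovery in promoter windows: promoter
## extraction, negative-set construction, sequence-containment counting,
## one-sided Fisher enrichment with E-value correction, and an iterative
## seed-and-generalize search (exact-word seeding, single-substitution
## hill climbing over ambiguity codes, N-masking between rounds).

#' Extract promoter windows upstream of annotated TSSs
#'
#' For a plus-strand gene with TSS \code{t} (0-based) the promoter is
#' \code{[t - window, t)} on the forward strand; for a minus-strand gene
#' it is \code{[t + 1, t + 1 + window)} reverse-complemented, so every
#' promoter reads 5' to 3' towards its gene.  Windows are truncated at
#' contig boundaries; genes with no retrievable sequence are excluded
#' with a warning.
#'
#' @param genome a \code{Biostrings::DNAStringSet} or path to a FASTA file.
#' @param annotation data.frame in BED6 shape (\code{chrom}, \code{start},
#'   \code{end}, \code{name}, \code{score}, \code{strand}; 0-based
#'   half-open) or path to a BED file.  The TSS is \code{start} for
#'   \code{+} genes and \code{end - 1} for \code{-} genes.
#' @param window promoter length in bp (default 1000).
#' @return Named character vector of promoter sequences (names = gene
#'   ids), with a \code{"intervals"} attribute recording the source
#'   coordinates.
#' @export
extract_promoters <- function(genome, annotation, window = 1000) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- read_bed(annotation)
  }
  seqs <- character(0L)
  ivs <- list()
  for (i in seq_len(nrow(annotation))) {
    chrom <- as.character(annotation$chrom[i])
    strand <- as.character(annotation$strand[i])
    gene <- as.character(annotation$name[i])
    if (!strand %in% c("+", "-")) stop("unknown strand '", strand, "' for gene ", gene)
    if (!chrom %in% names(genome)) {
      warning("gene ", gene, ": contig '", chrom, "' not in genome; excluded")
      next
    }
    clen <- Biostrings::width(genome[chrom])
    if (strand == "+") {
      tss <- annotation$start[i]
      s <- max(0L, tss - window); e <- tss
    } else {
      tss <- annotation$end[i] - 1L
      s <- tss + 1L; e <- min(clen, tss + 1L + window)
    }
    if (tss < 0L || tss >= clen) {
      warning("gene ", gene, ": TSS outside contig; excluded")
      next
    }
    if (e <= s) {
      warning("gene ", gene, ": zero-length promoter window; excluded")
      next
    }
    sq <- Biostrings::subseq(genome[[chrom]], start = s + 1L, end = e)
    if (strand == "-") sq <- Biostrings::reverseComplement(sq)
    seqs[gene] <- as.character(sq)
    ivs[[gene]] <- data.frame(gene = gene, chrom = chrom, start = s, end = e,
                              strand = strand, stringsAsFactors = FALSE)
  }
  attr(seqs, "intervals") <- do.call(rbind, ivs)
  seqs
}

#' Read a BED6 file
#' @param path path to a 6-column BED file (0-based half-open).
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("BED file must have 6 columns")
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  df
}

#' Construct the expression-stable negative gene set
#'
#' The negative set for discriminative motif discovery: expressed genes
#' (those surviving the low-count filter) whose pseudocounted RPKM fold
#' change stays strictly below \code{fold} in every (tissue, comparison)
#' — equivalently, the expressed genes outside the loose DEG union.
#'
#' @param degs a \code{deg_result} from \code{\link{call_degs}}.
#' @param fold fold-change bound (default 2, matching the loose DEG tier).
#' @return Character vector of gene ids; errors if empty.
#' @export
build_negative_set <- function(degs, fold = 2) {
  if (fold != degs$fc_threshold) {
    warning("negative-set fold ", fold, " differs from the DEG fold threshold ",
            degs$fc_threshold, "; the loose union was computed at the latter")
  }
  neg <- setdiff(degs$table$gene_id, loose_deg_union(degs))
  if (length(neg) == 0L) stop("negative set is empty")
  message("negative set: ", length(neg), " expression-stable genes")
  sort(neg)
}

#' Does a sequence contain an IUPAC word?
#'
#' Exact IUPAC-compatible containment on the forward strand or (by
#' default) either strand.  Sequence letters outside A/C/G/T — including
#' the N used for masking — match no code.
#'
#' @param sequences character vector of DNA sequences.
#' @param word IUPAC word.
#' @param both_strands also match the reverse complement (default TRUE).
#' @return Logical vector, one element per sequence.
#' @export
seq_contains <- function(sequences, word, both_strands = TRUE) {
  if (nchar(word) == 0L) stop("empty motif word")
  iupac_masks(word)  # validates letters
  .iupac_contain(as.character(sequences), toupper(word), both_strands)
}

#' Containment counts of a word in positive and negative promoter sets
#' @param word IUPAC word.
#' @param positives,negatives character vectors of promoter sequences.
#' @param both_strands match either strand (default TRUE).
#' @return Named integer vector: \code{pos_with}, \code{pos_total},
#'   \code{neg_with}, \code{neg_total} (sequences, not occurrences).
#' @export
containment_counts <- function(word, positives, negatives, both_strands = TRUE) {
  c(pos_with = sum(seq_contains(positives, word, both_strands)),
    pos_total = length(positives),
    neg_with = sum(seq_contains(negatives, word, both_strands)),
    neg_total = length(negatives))
}

#' One-sided Fisher exact P for motif enrichment
#'
#' Hypergeometric upper tail \code{P(X >= pos_with)} for the 2x2 table
#' of motif-containing sequences in the positive versus negative set —
#' the enrichment P value behind each motif report row.
#'
#' @param pos_with,pos_total containing / total sequences, positive set.
#' @param neg_with,neg_total containing / total sequences, negative set.
#' @return One-sided P value(s); vectorised.
#' @export
fisher_motif_pvalue <- function(pos_with, pos_total, neg_with, neg_total) {
  if (any(c(pos_with, pos_total, neg_with, neg_total) < 0)) {
    stop("counts must be non-negative")
  }
  if (any(pos_with > pos_total) || any(neg_with > neg_total)) {
    stop("containing counts cannot exceed totals")
  }
  stats::phyper(pos_with - 1, pos_with + neg_with,
                pos_total + neg_total - pos_with - neg_with,
                pos_total, lower.tail = FALSE)
}

#' E-value of a motif P value
#'
#' Bonferroni-style correction of the best motif's P value for the
#' number of candidate words scored during the search round.
#'
#' @param p Fisher P value(s).
#' @param candidates_evaluated number of distinct candidates scored (>= 1).
#' @return \code{p * candidates_evaluated}, capped at 1e308.
#' @export
evalue <- function(p, candidates_evaluated) {
  if (any(candidates_evaluated < 1)) stop("candidates_evaluated must be >= 1")
  pmin(1e308, p * candidates_evaluated)
}

# non-N IUPAC codes whose base set strictly contains the given code's set
iupac_generalizations <- function(letter) {
  m <- IUPAC_MASK[[letter]]
  names(IUPAC_MASK)[bitwAnd(IUPAC_MASK, m) == m & IUPAC_MASK != m &
                      names(IUPAC_MASK) != "N"]
}

# Score all exact words of one length: returns data.frame of canonical
# words (present in >= min_support positives) with containment counts.
score_exact_words <- function(positives, negatives, len, min_support = 2L) {
  pos_counts <- .kmer_seq_counts(positives, len)
  neg_counts <- .kmer_seq_counts(negatives, len)
  nk <- 4L^len
  idx <- 0:(nk - 1L)
  # canonical representative: keep w when w <= revcomp(w) numerically
  rc <- kmer_rc_index(idx, len)
  canon <- idx[idx <= rc]
  pw <- pos_counts[canon + 1L]
  keep <- pw >= min_support
  canon <- canon[keep]
  if (length(canon) == 0L) return(NULL)
  data.frame(word = kmer_index_to_word(canon, len),
             pos_with = pos_counts[canon + 1L],
             neg_with = neg_counts[canon + 1L],
             stringsAsFactors = FALSE)
}

kmer_rc_index <- function(idx, k) {
  rc <- integer(length(idx))
  x <- idx
  for (j in seq_len(k)) {
    rc <- rc * 4L + (3L - x %% 4L)
    x <- x %/% 4L
  }
  rc
}

#' Discover discriminative IUPAC motifs
#'
#' Iterative seed-and-generalize search.  Each round: (1) every exact
#' word of length \code{min_len..max_len} present in at least 2 positive
#' sequences is scored by \code{\link{fisher_motif_pvalue}} (a word and
#' its reverse complement are one candidate); (2) the \code{beam} best
#' seeds are generalized by hill climbing — at each step the single
#' strictly-P-improving replacement of one position's code by a wider
#' ambiguity code (a strict superset of its base set, N excluded) is
#' accepted; (3) the best motif's E-value is its P times the size of the
#' candidate space this round — all exact seeds scored plus the full
#' generalization space of every climbed seed (7^len - 1 words each),
#' so the correction covers everything the greedy search could have
#' reached, not only the words it happened to score; (4) if
#' \code{E < e_cutoff} the motif is reported, its match positions are
#' masked with N in both sets, and the search repeats.  The search stops
#' when the best E-value reaches \code{e_cutoff} or after
#' \code{max_motifs} motifs.  Ties are broken lexicographically, so the
#' output is fully deterministic.
#'
#' @param positives,negatives character vectors of promoter sequences
#'   (named by gene id).
#' @param min_len,max_len word lengths searched (defaults 3 and 8).
#' @param e_cutoff E-value threshold to keep searching (default 0.05).
#' @param beam number of seeds generalized per round (default 10; the
#'   E-value multiplier grows linearly in the beam, so wide beams tax
#'   the best motif's significance).
#' @param max_motifs maximum motifs reported (default 10).
#' @param both_strands match either strand (default TRUE).
#' @return data.frame of motif results: \code{consensus},
#'   \code{pos_with}, \code{pos_total}, \code{neg_with},
#'   \code{neg_total}, \code{p_value}, \code{e_value},
#'   \code{candidates_evaluated}, \code{round}.
#' @export
discover_motifs <- function(positives, negatives, min_len = 3, max_len = 8,
                            e_cutoff = 0.05, beam = 10, max_motifs = 10,
                            both_strands = TRUE) {
  if (length(positives) < 2L) stop("positive set must have at least 2 sequences")
  if (length(negatives) < 1L) stop("negative set is empty")
  positives <- as.character(positives)
  negatives <- as.character(negatives)
  pt <- length(positives); nt <- length(negatives)
  results <- list()
  for (round in seq_len(max_motifs)) {
    cache <- new.env(parent = emptyenv())
    score_word <- function(word) {
      key <- iupac_canonical(word)
      hit <- get0(key, envir = cache)
      if (!is.null(hit)) return(hit)
      pw <- sum(.iupac_contain(positives, key, both_strands))
      nw <- sum(.iupac_contain(negatives, key, both_strands))
      val <- list(word = key, pos_with = pw, neg_with = nw,
                  p = fisher_motif_pvalue(pw, pt, nw, nt))
      assign(key, val, envir = cache)
      val
    }
    seeds <- list()
    n_seed_candidates <- 0L
    for (len in min_len:max_len) {
      sc <- score_exact_words(positives, negatives, len)
      if (is.null(sc)) next
      sc$p <- fisher_motif_pvalue(sc$pos_with, pt, sc$neg_with, nt)
      n_seed_candidates <- n_seed_candidates + nrow(sc)
      seeds[[as.character(len)]] <- sc
    }
    if (length(seeds) == 0L) break
    seeds <- do.call(rbind, seeds)
    seeds <- seeds[order(seeds$p, seeds$word), , drop = FALSE]
    top <- utils::head(seeds, beam)
    n_climb_space <- 0
    best <- NULL
    for (s in seq_len(nrow(top))) {
      cur <- list(word = iupac_canonical(top$word[s]),
                  pos_with = top$pos_with[s], neg_with = top$neg_with[s],
                  p = top$p[s])
      n_climb_space <- n_climb_space + 7^nchar(cur$word) - 1
      repeat {
        letters_cur <- strsplit(cur$word, "", fixed = TRUE)[[1L]]
        cand_best <- NULL
        for (pos in seq_along(letters_cur)) {
          for (code in iupac_generalizations(letters_cur[pos])) {
            w <- letters_cur
            w[pos] <- code
            val <- score_word(paste(w, collapse = ""))
            if (is.null(cand_best) || val$p < cand_best$p ||
                (val$p == cand_best$p && val$word < cand_best$word)) {
              cand_best <- val
            }
          }
        }
        if (!is.null(cand_best) && cand_best$p < cur$p) {
          cur <- cand_best
        } else break
      }
      if (is.null(best) || cur$p < best$p ||
          (cur$p == best$p && cur$word < best$word)) {
        best <- cur
      }
    }
    n_candidates <- n_seed_candidates + n_climb_space
    e <- evalue(best$p, n_candidates)
    if (e >= e_cutoff) break
    results[[round]] <- data.frame(
      consensus = best$word, pos_with = best$pos_with, pos_total = pt,
      neg_with = best$neg_with, neg_total = nt, p_value = best$p,
      e_value = e, candidates_evaluated = n_candidates, round = round,
      stringsAsFactors = FALSE)
    positives <- .iupac_mask(positives, best$word, both_strands)
    negatives <- .iupac_mask(negatives, best$word, both_strands)
  }
  if (length(results) == 0L) {
    return(data.frame(consensus = character(), pos_with = integer(),
                      pos_total = integer(), neg_with = integer(),
                      neg_total = integer(), p_value = numeric(),
                      e_value = numeric(), candidates_evaluated = integer(),
                      round = integer()))
  }
  do.call(rbind, results)
}

#' Gene x motif containment table
#'
#' Boolean containment of each discovered motif in each promoter, plus
#' per-motif containment fractions.
#'
#' @param motifs data.frame with a \code{consensus} column (as returned
#'   by \code{\link{discover_motifs}}).
#' @param promoters named character vector of promoter sequences.
#' @param both_strands match either strand (default TRUE).
#' @return Logical matrix genes x motifs; attribute \code{"fraction"}
#'   gives the per-motif containment fraction.
#' @export
motif_gene_table <- function(motifs, promoters, both_strands = TRUE) {
  if (nrow(motifs) == 0L) {
    out <- matrix(logical(0L), nrow = length(promoters), ncol = 0L,
                  dimnames = list(names(promoters), NULL))
    attr(out, "fraction") <- numeric(0L)
    return(out)
  }
  m <- vapply(motifs$consensus, function(w) {
    seq_contains(promoters, w, both_strands)
  }, logical(length(promoters)))
  m <- matrix(m, nrow = length(promoters),
              dimnames = list(names(promoters), motifs$consensus))
  attr(m, "fraction") <- colMeans(m)
  m
}
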