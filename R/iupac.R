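## IUPAC nucleotide-code utilities shared by the motif modules.

# 4-bit base sets: A=1, C=2, G=4, T=8
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)
IUPAC_LETTERS <- names(IUPAC_MASK)
# ambiguity codes usable during motif generalization (everything but N)
IUPAC_NON_N <- setdiff(IUPAC_LETTERS, "N")

mask_to_letter <- local({
  tab <- character(15L)
  tab[IUPAC_MASK] <- names(IUPAC_MASK)
  tab
})

#' @noRd
iupac_masks <- function(word) {
  ch <- strsplit(toupper(word), "", fixed = TRUE)[[1L]]
  m <- IUPAC_MASK[ch]
  if (anyNA(m)) {
    stop("invalid IUPAC letter(s) in '", word, "': ",
         paste(unique(ch[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

comp_mask <- function(m) {
  # complement of a 4-bit base set (A<->T, C<->G)
  ifelse(bitwAnd(m, 1L) > 0L, 8L, 0L) +
    ifelse(bitwAnd(m, 2L) > 0L, 4L, 0L) +
    ifelse(bitwAnd(m, 4L) > 0L, 2L, 0L) +
    ifelse(bitwAnd(m, 8L) > 0L, 1L, 0L)
}

#' Reverse complement of an IUPAC word
#'
#' Complements each ambiguity code as a base set (e.g. \code{M} = A/C
#' becomes \code{K} = G/T) and reverses the word.
#'
#' @param word IUPAC string.
#' @return The reverse-complement IUPAC string.
#' @examples
#' iupac_revcomp("AGMAACCA")
#' @export
iupac_revcomp <- function(word) {
  m <- rev(comp_mask(iupac_masks(word)))
  paste(mask_to_letter[m], collapse = "")
}

#' @noRd
iupac_canonical <- function(word) {
  word <- toupper(word)
  rc <- iupac_revcomp(word)
  if (rc < word) rc else word
}

#' @noRd
kmer_index_to_word <- function(idx, k) {
  # idx is 0-based with 2-bit encoding A=0, C=1, G=2, T=3
  bases <- c("A", "C", "G", "T")
  vapply(idx, function(w) {
    out <- character(k)
    for (j in k:1) {
      out[j] <- bases[w %% 4L + 1L]
      w <- w %/% 4L
    }
    paste(out, collapse = "")
  }, character(1L))
}

#' @noRd
random_dna <- function(n, length, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  }, character(1L))
}

#' @noRd
instantiate_iupac <- function(word, exact = FALSE) {
  # draw one concrete DNA word compatible with an IUPAC consensus
  m <- iupac_masks(word)
  bases <- c("A", "C", "G", "T")
  vapply(m, function(mask) {
    allowed <- bases[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L]
    if (exact || length(allowed) == 1L) allowed[1L] else sample(allowed, 1L)
  }, character(1L)) |> paste(collapse = "")
}
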