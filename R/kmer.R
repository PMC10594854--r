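# K-mer counting and dinucleotide-content classification.
#
# The k-mer universe is indexed by the canonical 2-bit encoding A=0, C=1,
# G=2, T=3, most-significant base first, i.e. plain lexicographic order.
# Biostrings::oligonucleotideFrequency() enumerates words in exactly this
# order, so its count vector is used as-is.

.BASES <- c("A", "C", "G", "T")

# cache of base-4 digit matrices, one per k
.kmer_cache <- new.env(parent = emptyenv())

# 4^k x k matrix; row m+1 holds the base-4 digits of index m, most
# significant first (i.e. the bases of the k-mer with index m).
.digit_matrix <- function(k) {
  key <- as.character(k)
  if (!is.null(.kmer_cache[[key]])) {
    return(.kmer_cache[[key]])
  }
  idx <- seq_len(4^k) - 1
  d <- vapply(seq_len(k),
              function(j) (idx %/% 4^(k - j)) %% 4,
              numeric(4^k))
  if (k == 1L) d <- matrix(d, ncol = 1L)
  .kmer_cache[[key]] <- d
  d
}

#' Encode a k-mer as its canonical index
#'
#' Bijection between k-length ACGT strings and `0:(4^k - 1)` under the
#' 2-bit encoding A=0, C=1, G=2, T=3, most-significant base first
#' (lexicographic order).
#'
#' @param s A single k-mer string over A, C, G, T.
#' @return Integer index in `[0, 4^k)`.
#' @seealso [decode_kmer()]
#' @examples
#' encode_kmer("AAAAAAAA")  # 0
#' encode_kmer("TTTTTTTT")  # 65535
#' @export
encode_kmer <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  b <- match(strsplit(s, "", fixed = TRUE)[[1L]], .BASES) - 1
  if (anyNA(b)) {
    stop("cannot encode '", s, "': position ", which(is.na(b))[1L],
         " is not one of A, C, G, T", call. = FALSE)
  }
  k <- length(b)
  sum(b * 4^((k - 1):0))
}

#' Decode a canonical k-mer index
#'
#' @param index Integer in `[0, 4^k)`.
#' @param k Word length.
#' @return The k-mer string.
#' @seealso [encode_kmer()]
#' @export
decode_kmer <- function(index, k) {
  stopifnot(index >= 0, index < 4^k)
  digits <- (index %/% 4^((k - 1):0)) %% 4
  paste(.BASES[digits + 1], collapse = "")
}

#' Count k-mers in a genome by sliding window
#'
#' Counts every length-`k` window (step 1, forward strand only) in every
#' record of the genome; windows never span record boundaries. Windows
#' containing any non-ACGT character (N or another IUPAC ambiguity code) are
#' skipped and contribute nothing to `total_windows`.
#'
#' @param genome A `genome` object (see [read_fasta()]).
#' @param k Word length (default 8).
#' @return A `kmer_counts` object: list with `k`, `taxon_id`, `counts`
#'   (integer vector of length `4^k` in canonical k-mer order) and
#'   `total_windows` (`sum(counts)`).
#' @examples
#' g <- genome_from_sequences("toy", "AAAAAAAAA")
#' count_kmers(g, k = 8)$total_windows  # 2 windows, both AAAAAAAA
#' @export
count_kmers <- function(genome, k = 8L) {
  stopifnot(inherits(genome, "genome"), k >= 1L)
  m <- Biostrings::oligonucleotideFrequency(genome$records, width = k,
                                            step = 1L)
  counts <- as.integer(colSums(m))
  total <- sum(as.numeric(counts))  # avoid integer overflow on Gb genomes
  if (total == 0L) {
    stop("no countable windows: every record of '", genome$taxon_id,
         "' is shorter than k = ", k,
         " or every window contains an ambiguous base", call. = FALSE)
  }
  structure(
    list(k = as.integer(k), taxon_id = genome$taxon_id,
         counts = counts, total_windows = total),
    class = "kmer_counts"
  )
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("<kmer_counts> ", x$taxon_id, ": k = ", x$k, ", ",
      format(x$total_windows, big.mark = ","), " windows over ",
      format(4^x$k, big.mark = ","), " words\n", sep = "")
  invisible(x)
}

#' Count (overlapping) occurrences of a dinucleotide in a k-mer
#'
#' Occurrences may overlap: `AA` occurs 7 times in `AAAAAAAA`.
#'
#' @param kmer A k-mer string over A, C, G, T.
#' @param xy Ordered dinucleotide, e.g. `"CG"`.
#' @return Integer occurrence count.
#' @export
dinucleotide_occurrences <- function(kmer, xy) {
  xy <- .check_xy(xy)
  b <- match(strsplit(kmer, "", fixed = TRUE)[[1L]], .BASES)
  if (anyNA(b)) {
    stop("k-mer '", kmer, "' contains a character outside A, C, G, T",
         call. = FALSE)
  }
  k <- length(b)
  if (k < 2L) return(0L)
  x <- match(substr(xy, 1L, 1L), .BASES)
  y <- match(substr(xy, 2L, 2L), .BASES)
  sum(b[-k] == x & b[-1L] == y)
}

.check_xy <- function(xy) {
  xy <- toupper(xy)
  if (!is.character(xy) || length(xy) != 1L || nchar(xy) != 2L ||
      grepl("[^ACGT]", xy)) {
    stop("'xy' must be an ordered dinucleotide over A, C, G, T, e.g. \"CG\"",
         call. = FALSE)
  }
  xy
}

#' Partition the k-mer universe by dinucleotide content
#'
#' Classifies each of the `4^k` k-mers by its number of (overlapping)
#' occurrences of the ordered dinucleotide `xy`: class 0 (none), class 1
#' (exactly one) or class 2 (two or more). At k = 8 and X != Y this yields
#' the subset sizes 40,545 / 21,468 / 3,523; for X == Y it yields
#' 44,631 / 14,931 / 5,974.
#'
#' @param k Word length (>= 2).
#' @param xy Ordered dinucleotide, e.g. `"CG"`.
#' @return A `kmer_partition` object: list with `k`, `xy`, `class_of`
#'   (integer vector of length `4^k`, values 0/1/2, canonical order) and
#'   `sizes` (named vector `n0`, `n1`, `n2`).
#' @examples
#' partition_by_dinucleotide(8, "CG")$sizes
#' @export
partition_by_dinucleotide <- function(k, xy) {
  stopifnot(k >= 2L)
  xy <- .check_xy(xy)
  key <- paste0("part:", k, ":", xy)
  if (!is.null(.kmer_cache[[key]])) {
    return(.kmer_cache[[key]])
  }
  d <- .digit_matrix(k)
  x <- match(substr(xy, 1L, 1L), .BASES) - 1
  y <- match(substr(xy, 2L, 2L), .BASES) - 1
  occ <- rowSums(d[, -k, drop = FALSE] == x & d[, -1L, drop = FALSE] == y)
  class_of <- as.integer(pmin(occ, 2))
  sizes <- c(n0 = sum(class_of == 0L), n1 = sum(class_of == 1L),
             n2 = sum(class_of == 2L))
  res <- structure(
    list(k = as.integer(k), xy = xy, class_of = class_of, sizes = sizes),
    class = "kmer_partition"
  )
  .kmer_cache[[key]] <- res
  res
}

#' @export
print.kmer_partition <- function(x, ...) {
  cat("<kmer_partition> k = ", x$k, ", xy = ", x$xy, ": sizes ",
      paste(x$sizes, collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Minimum usable k for a sequence of given length
#'
#' The smallest word length at which k-mer frequencies in a sequence of
#' length `L` retain statistical meaning, `ceiling(0.7 * log4(L))`. For a
#' typical 3 Gb vertebrate genome this gives 12; the 8-mer analyses here
#' use k = 8, which the formula supports for genomes above ~60 kb.
#'
#' @param L Sequence length in bp (>= 2).
#' @return Integer minimum k.
#' @examples
#' minimum_k(4^10)   # 7
#' minimum_k(3e9)    # 12
#' @export
minimum_k <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || L < 2) {
    stop("'L' must be a single sequence length >= 2", call. = FALSE)
  }
  v <- 0.7 * log(L) / log(4)
  # guard against floating-point residue pushing exact values over the edge
  as.integer(ceiling(v - 1e-9))
}

#' Enumerate all 16 ordered dinucleotides
#'
#' @return Character vector `"AA"`, `"AC"`, ..., `"TT"` in lexicographic
#'   order.
#' @export
dinucleotides <- function() {
  as.vector(t(outer(.BASES, .BASES, paste0)))
}
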