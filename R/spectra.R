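# Subset spectra (relative motif number histograms), the random center and
# separability of the 48 XYi 8-mer subsets.

#' 8-mer subset spectrum (relative motif number histogram)
#'
#' For one XYi subset, tabulates how many subset members occur exactly
#' `i` times in the genome (members absent from the genome are counted at
#' occurrence 0). The relative motif number RMN is that tally divided by
#' `4^k`; the distribution of RMN over occurrence counts is the subset's
#' spectrum.
#'
#' @param counts A `kmer_counts` object.
#' @param partition A `kmer_partition` with the same `k`.
#' @param class_i Subset class: 0, 1 or 2.
#' @return A data frame with columns `occurrence`, `n` (number of subset
#'   k-mers with that occurrence count) and `rmn` (`n / 4^k`), sorted by
#'   occurrence; only occurrence values with `n > 0` are listed. Attributes
#'   `xy`, `class_i`, `subset_size` and `taxon_id` identify the subset.
#' @export
rmn_spectrum <- function(counts, partition, class_i) {
  .check_counts_partition(counts, partition)
  stopifnot(class_i %in% 0:2)
  members <- partition$class_of == class_i
  size <- sum(members)
  if (size == 0L) {
    stop("empty subset: ", partition$xy, class_i, " at k = ", counts$k,
         call. = FALSE)
  }
  tab <- table(counts$counts[members])
  out <- data.frame(
    occurrence = as.integer(names(tab)),
    n = as.integer(tab),
    rmn = as.integer(tab) / 4^counts$k
  )
  out <- out[order(out$occurrence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "xy") <- partition$xy
  attr(out, "class_i") <- as.integer(class_i)
  attr(out, "subset_size") <- size
  attr(out, "taxon_id") <- counts$taxon_id
  out
}

.check_counts_partition <- function(counts, partition) {
  stopifnot(inherits(counts, "kmer_counts"),
            inherits(partition, "kmer_partition"))
  if (counts$k != partition$k) {
    stop("k mismatch: counts have k = ", counts$k, ", partition k = ",
         partition$k, call. = FALSE)
  }
  invisible(TRUE)
}

#' Random center: mean occurrence count over the whole k-mer universe
#'
#' The average frequency of all `4^k` k-mers, `total_windows / 4^k`. It is
#' the reference point against which subset spectra are located.
#'
#' @param counts A `kmer_counts` object.
#' @return A single number.
#' @export
global_mean <- function(counts) {
  stopifnot(inherits(counts, "kmer_counts"))
  counts$total_windows / 4^counts$k
}

#' Mean occurrence count of one XYi subset
#'
#' Sum of counts over the subset members divided by the subset size.
#' Members absent from the genome (count 0) are included in the
#' denominator, so the 48 subset means are always defined.
#'
#' @inheritParams rmn_spectrum
#' @return A single number.
#' @export
subset_mean <- function(counts, partition, class_i) {
  .check_counts_partition(counts, partition)
  stopifnot(class_i %in% 0:2)
  members <- partition$class_of == class_i
  size <- sum(members)
  if (size == 0L) {
    stop("empty subset: ", partition$xy, class_i, " at k = ", counts$k,
         call. = FALSE)
  }
  sum(as.numeric(counts$counts[members])) / size
}

#' Separability of one XYi subset spectrum
#'
#' delta = global mean / subset mean. delta > 1 places the subset at the
#' low-frequency end of the spectrum, away from the random center;
#' delta = 1 means the subset sits exactly at the random center.
#'
#' @inheritParams rmn_spectrum
#' @return A single number, or `NA` (with a warning) when every subset
#'   member is absent from the genome.
#' @export
separability <- function(counts, partition, class_i) {
  sm <- subset_mean(counts, partition, class_i)
  if (sm == 0) {
    warning("subset ", partition$xy, class_i,
            " has zero mean count; separability undefined", call. = FALSE)
    return(NA_real_)
  }
  global_mean(counts) / sm
}

#' Separability table over all 48 XYi subsets
#'
#' One row per (ordered dinucleotide, class) pair: 16 dinucleotides times
#' classes 0/1/2.
#'
#' @param counts A `kmer_counts` object (k >= 2).
#' @return A data frame with columns `xy`, `class`, `subset_size`,
#'   `subset_mean` and `delta` (NA where the subset mean is zero), with
#'   attributes `global_mean` and `taxon_id`.
#' @export
separability_table <- function(counts) {
  stopifnot(inherits(counts, "kmer_counts"), counts$k >= 2L)
  gm <- global_mean(counts)
  rows <- lapply(dinucleotides(), function(xy) {
    part <- partition_by_dinucleotide(counts$k, xy)
    sm <- vapply(0:2, function(i) subset_mean(counts, part, i), numeric(1))
    data.frame(xy = xy, class = 0:2,
               subset_size = as.integer(part$sizes),
               subset_mean = sm,
               delta = ifelse(sm > 0, gm / sm, NA_real_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyNA(out$delta)) {
    warning(sum(is.na(out$delta)),
            " subset(s) have zero mean count; their separability is NA",
            call. = FALSE)
  }
  attr(out, "global_mean") <- gm
  attr(out, "taxon_id") <- counts$taxon_id
  out
}
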