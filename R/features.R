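# Rank ("relative frequency") feature vectors over named 8-mer sets and the
# RMSE distance matrix between genomes.

#' Build a named k-mer feature set
#'
#' Presets: `"CG12"` (union of CG1 and CG2; 24,991 8-mers at k = 8),
#' `"TA12"` (same sizes by symmetry), `"CG0"` (40,545 8-mers), `"TA0"`,
#' and `"TOTAL"` (all `4^k` k-mers). A custom set is given as
#' `list(xy = "CG", classes = c(1, 2))`.
#'
#' @param k Word length (default 8).
#' @param set Preset name or custom `list(xy =, classes =)`.
#' @return A `feature_set` object: list with `k`, `name`, `xy`, `classes`,
#'   `members` (sorted 0-based canonical k-mer indices) and `size`.
#' @examples
#' build_feature_set(8, "CG12")$size  # 24991
#' @export
build_feature_set <- function(k = 8L, set = "CG12") {
  stopifnot(k >= 2L)
  if (is.character(set) && length(set) == 1L) {
    name <- toupper(set)
    if (name == "TOTAL") {
      return(structure(
        list(k = as.integer(k), name = "TOTAL", xy = NA_character_,
             classes = NULL, members = 0:(4^k - 1), size = 4^k),
        class = "feature_set"
      ))
    }
    m <- regmatches(name, regexec("^([ACGT]{2})(0|12)$", name))[[1L]]
    if (length(m) == 0L) {
      stop("unknown feature set preset '", set,
           "'; use e.g. \"CG12\", \"TA12\", \"CG0\", \"TOTAL\" or a ",
           "list(xy =, classes =)", call. = FALSE)
    }
    xy <- m[2L]
    classes <- if (m[3L] == "0") 0L else c(1L, 2L)
  } else if (is.list(set) && all(c("xy", "classes") %in% names(set))) {
    xy <- .check_xy(set$xy)
    classes <- as.integer(set$classes)
    if (length(classes) == 0L || !all(classes %in% 0:2)) {
      stop("custom feature set classes must be drawn from 0, 1, 2",
           call. = FALSE)
    }
    name <- paste0(xy, paste(sort(unique(classes)), collapse = ""))
  } else {
    stop("'set' must be a preset name or list(xy =, classes =)",
         call. = FALSE)
  }
  part <- partition_by_dinucleotide(k, xy)
  members <- which(part$class_of %in% classes) - 1L   # 0-based, sorted
  structure(
    list(k = as.integer(k), name = name, xy = xy,
         classes = sort(unique(classes)), members = members,
         size = length(members)),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> ", x$name, " at k = ", x$k, ": ",
      format(x$size, big.mark = ","), " k-mers\n", sep = "")
  invisible(x)
}

#' Rank-transform k-mer counts within a feature set
#'
#' The members of the feature set are arranged in order of their counts
#' from small to large and the resulting 1-based order is the "relative
#' frequency" feature. Under the default `ordinal` policy count ties are
#' broken by ascending canonical k-mer index, so ranks are a permutation of
#' `1:N` and the output is deterministic; under `average`, tied members
#' share the mean of the ranks they span.
#'
#' @param counts A `kmer_counts` object.
#' @param set A `feature_set` with the same `k`.
#' @param tie_policy `"ordinal"` (default) or `"average"`.
#' @return A `feature_vector` object: list with `taxon_id`, `set`,
#'   `tie_policy` and `ranks` (aligned to `set$members`).
#' @export
relative_frequency <- function(counts, set,
                               tie_policy = c("ordinal", "average")) {
  stopifnot(inherits(counts, "kmer_counts"), inherits(set, "feature_set"))
  tie_policy <- match.arg(tie_policy)
  if (counts$k != set$k) {
    stop("k mismatch: counts have k = ", counts$k, ", feature set k = ",
         set$k, call. = FALSE)
  }
  cnt <- counts$counts[set$members + 1L]
  ranks <- switch(tie_policy,
    # members are in ascending index order, so "first" ties-method breaks
    # count ties by ascending k-mer index
    ordinal = rank(cnt, ties.method = "first"),
    average = rank(cnt, ties.method = "average")
  )
  structure(
    list(taxon_id = counts$taxon_id, set = set, tie_policy = tie_policy,
         ranks = ranks),
    class = "feature_vector"
  )
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> ", x$taxon_id, ": set ", x$set$name, " (N = ",
      format(x$set$size, big.mark = ","), "), ", x$tie_policy, " ranks\n",
      sep = "")
  invisible(x)
}

.check_same_spec <- function(fa, fb) {
  stopifnot(inherits(fa, "feature_vector"), inherits(fb, "feature_vector"))
  if (fa$set$k != fb$set$k || fa$set$name != fb$set$name ||
      !identical(fa$set$members, fb$set$members)) {
    stop("feature vectors were built over different feature sets",
         call. = FALSE)
  }
  if (fa$tie_policy != fb$tie_policy) {
    stop("feature vectors use different tie policies", call. = FALSE)
  }
  invisible(TRUE)
}

#' RMSE distance between two feature vectors
#'
#' `D_ab = sqrt( sum_i (x_ai - x_bi)^2 / N )` over the N members of the
#' shared feature set. On rank vectors this is a metric (Euclidean distance
#' scaled by `1/sqrt(N)`).
#'
#' @param fa,fb `feature_vector` objects over the same feature set and tie
#'   policy.
#' @return A single non-negative number.
#' @export
pairwise_distance <- function(fa, fb) {
  .check_same_spec(fa, fb)
  sqrt(mean((fa$ranks - fb$ranks)^2))
}

#' Pairwise RMSE distance matrix for a set of genomes
#'
#' @param features A list of `feature_vector` objects (>= 3, distinct
#'   `taxon_id`s, same feature set and tie policy).
#' @return A symmetric numeric matrix with zero diagonal, dimnames = taxon
#'   ids, taxa in input order.
#' @export
distance_matrix <- function(features) {
  stopifnot(is.list(features), length(features) >= 3L)
  taxa <- vapply(features, function(f) f$taxon_id, "")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon_id: ", taxa[duplicated(taxa)][1L], call. = FALSE)
  }
  for (f in features[-1L]) .check_same_spec(features[[1L]], f)
  n <- length(features)
  # ranks side by side; dist() gives the scaled Euclidean metric directly
  R <- vapply(features, function(f) as.numeric(f$ranks),
              numeric(features[[1L]]$set$size))
  d <- as.matrix(stats::dist(t(R))) / sqrt(features[[1L]]$set$size)
  dimnames(d) <- list(taxa, taxa)
  d
}

#' Write a distance matrix in square PHYLIP format
#'
#' Relaxed PHYLIP: first line is the taxon count; each subsequent line is a
#' whitespace-delimited taxon name (<= 50 characters, no internal
#' whitespace) followed by the full row of distances with 6 decimals.
#'
#' @param dm Symmetric numeric matrix with taxon dimnames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_phylip <- function(dm, path) {
  .check_dist_matrix(dm)
  taxa <- rownames(dm)
  if (any(grepl("[[:space:]]", taxa))) {
    stop("taxon name contains whitespace, not representable in relaxed ",
         "PHYLIP: '", taxa[grepl("[[:space:]]", taxa)][1L], "'",
         call. = FALSE)
  }
  if (any(nchar(taxa) > 50L)) {
    stop("taxon name longer than 50 characters: '",
         taxa[nchar(taxa) > 50L][1L], "'", call. = FALSE)
  }
  width <- max(nchar(taxa)) + 2L
  lines <- c(
    as.character(nrow(dm)),
    vapply(seq_len(nrow(dm)), function(i) {
      paste0(formatC(taxa[i], width = -width),
             paste(sprintf("%.6f", dm[i, ]), collapse = "  "))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path Path to a file written in the format of [write_phylip()].
#' @return A symmetric numeric matrix with taxon dimnames.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty PHYLIP file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) {
    stop("malformed PHYLIP header in '", path, "': '", lines[1L], "'",
         call. = FALSE)
  }
  if (length(lines) - 1L != n) {
    stop("PHYLIP row count mismatch in '", path, "': header says ", n,
         ", found ", length(lines) - 1L, " rows", call. = FALSE)
  }
  taxa <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1L]]
    if (length(fields) != n + 1L) {
      stop("PHYLIP row ", i, " has ", length(fields) - 1L,
           " distances, expected ", n, call. = FALSE)
    }
    taxa[i] <- fields[1L]
    d[i, ] <- as.numeric(fields[-1L])
  }
  dimnames(d) <- list(taxa, taxa)
  .check_dist_matrix(d, tol = 1e-6)
  d
}

.check_dist_matrix <- function(dm, tol = 1e-8) {
  if (!is.matrix(dm) || !is.numeric(dm) || nrow(dm) != ncol(dm)) {
    stop("distance matrix must be a square numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(dm))) {
    stop("distance matrix must carry taxon names as dimnames",
         call. = FALSE)
  }
  if (any(dm < 0)) stop("negative distances are not allowed", call. = FALSE)
  if (max(abs(dm - t(dm))) > tol) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(dm)) > tol)) {
    stop("distance matrix diagonal must be zero", call. = FALSE)
  }
  invisible(TRUE)
}
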