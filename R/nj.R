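# Neighbor-joining tree construction with deterministic tie-breaking, plus
# Newick serialization and Robinson-Foulds comparison (backed by ape and
# phangorn).

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining: at each step the pair (a, b)
#' minimizing `Q(a,b) = (n-2) d(a,b) - sum_c d(a,c) - sum_c d(b,c)` is
#' joined and branch lengths assigned by the usual formulas. Two departures
#' from a textbook sketch are fixed by contract so identical inputs give
#' identical Newick strings: Q-ties are broken by the smallest (row, col)
#' index pair, and a negative branch length at a join is clamped to zero
#' with the deficit transferred to its sister branch (preserving
#' `la + lb = d(a,b)`); at the final three-cluster step negatives are
#' clamped to zero. On a matrix that is additive on a binary tree with
#' positive branch lengths, NJ recovers that tree exactly.
#'
#' @param dm Symmetric non-negative numeric matrix (>= 3 taxa, zero
#'   diagonal, taxon dimnames).
#' @return An unrooted [ape::phylo] tree with branch lengths.
#' @examples
#' d <- matrix(c(0,3,5,6, 3,0,6,7, 5,6,0,7, 6,7,7,0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' neighbor_joining(d)
#' @export
neighbor_joining <- function(dm) {
  .check_dist_matrix(dm, tol = 1e-8)
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  D <- dm
  sub <- .newick_label(rownames(dm))   # Newick fragment per active cluster
  while (nrow(D) > 3L) {
    m <- nrow(D)
    Tt <- rowSums(D)
    best <- c(NA_integer_, NA_integer_)
    best_q <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * D[i, j] - Tt[i] - Tt[j]
        if (q < best_q) {           # strict <: ties keep smallest (i, j)
          best_q <- q
          best <- c(i, j)
        }
      }
    }
    a <- best[1L]; b <- best[2L]
    la <- 0.5 * D[a, b] + (Tt[a] - Tt[b]) / (2 * (m - 2))
    lb <- D[a, b] - la
    if (la < 0) { lb <- lb + la; la <- 0 }
    if (lb < 0) { la <- max(0, la + lb); lb <- 0 }
    new_sub <- sprintf("(%s:%.15g,%s:%.15g)", sub[a], la, sub[b], lb)
    du <- 0.5 * (D[a, -c(a, b), drop = TRUE] + D[b, -c(a, b), drop = TRUE] -
                   D[a, b])
    D <- D[-c(a, b), -c(a, b), drop = FALSE]
    D <- rbind(cbind(D, u = du), u = c(du, 0))
    sub <- c(sub[-c(a, b)], new_sub)
  }
  l1 <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  l2 <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  l3 <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  lens <- pmax(c(l1, l2, l3), 0)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 sub[1L], lens[1L], sub[2L], lens[2L], sub[3L], lens[3L])
  ape::read.tree(text = nwk)
}

# quote labels containing Newick metacharacters
.newick_label <- function(x) {
  needs <- grepl("[ \t();:,\\[\\]']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Serialize a tree to Newick
#'
#' @param tree An [ape::phylo] tree.
#' @param path Optional output file; if `NULL` the Newick string is
#'   returned.
#' @param precision Significant digits for branch lengths.
#' @return The Newick string (invisibly when writing to a file).
#' @export
to_newick <- function(tree, path = NULL, precision = 6L) {
  stopifnot(inherits(tree, "phylo"))
  s <- if (length(tree$tip.label) == 1L) {
    # ape's serializer needs >= 2 tips; a single leaf is just its label
    paste0(.newick_label(tree$tip.label), ";")
  } else {
    ape::write.tree(tree, digits = as.integer(precision))
  }
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Parse a Newick tree
#'
#' @param x A Newick string, or the path of a file holding one.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(x) {
  text <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  text <- paste(text, collapse = "")
  bare <- trimws(text)
  if (grepl("^[A-Za-z0-9_.|-]+;$", bare)) {
    # bare single-leaf tree, below what ape's parser represents
    return(structure(
      list(edge = matrix(c(2L, 1L), 1L, 2L),
           tip.label = sub(";$", "", bare), Nnode = 1L),
      class = "phylo", order = "cladewise"
    ))
  }
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tree)) {
    stop("malformed Newick: ", text, call. = FALSE)
  }
  tree
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' The number of bipartitions present in exactly one of the two trees
#' (unweighted); 0 means identical unrooted topologies.
#'
#' @param t1,t2 [ape::phylo] trees on the same leaf set.
#' @return A non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets", call. = FALSE)
  }
  # RF.dist warns when a tree is not fully resolved; multifurcations are a
  # legitimate input here (star trees), so the warning is suppressed
  as.integer(suppressWarnings(
    phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                      check.labels = TRUE)
  ))
}
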