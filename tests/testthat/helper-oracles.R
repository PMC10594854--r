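# Independent oracles and small fixture builders used across the suite.

# brute-force subset sizes: enumerate all 4^k k-mer strings and count
# overlapping occurrences of xy with a regex lookahead (independent of the
# digit-matrix implementation in the package)
brute_partition_sizes <- function(k, xy) {
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  hits <- gregexpr(paste0("(?=", xy, ")"), words, perl = TRUE)
  occ <- vapply(hits, function(h) sum(h > 0L), integer(1))
  cls <- pmin(occ, 2L)
  c(n0 = sum(cls == 0L), n1 = sum(cls == 1L), n2 = sum(cls == 2L))
}

# transfer-matrix recurrences for the number of k-mers with zero XY
# occurrences: X != Y -> g(n) = 4 g(n-1) - g(n-2); X == Y (e.g. AA) ->
# f(n) = 3 f(n-1) + 3 f(n-2); both with f(0) = g(0) = 1, f(1) = g(1) = 4
recurrence_n0 <- function(k, self_overlapping) {
  v <- c(1, 4)
  if (k <= 1) return(v[k + 1])
  for (n in 2:k) {
    v <- c(v[2], if (self_overlapping) 3 * v[2] + 3 * v[1]
           else 4 * v[2] - v[1])
  }
  v[2]
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_genome <- function(n, taxon_id = "rnd", seed = NULL) {
  genome_from_sequences(taxon_id, random_dna(n, seed))
}

# a random binary tree with positive branch lengths and its exact
# path-length (additive) distance matrix
random_additive_case <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.1, 2))
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[order(rownames(dm)), order(colnames(dm))]
  list(tree = tr, dm = dm)
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
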