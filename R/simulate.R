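# Synthetic genomes: a first-order Markov chain with controllable CpG/TpA
# suppression, evolved along a known tree under Jukes-Cantor substitution.
# The generator is a validation fixture for the pipeline, not a model of
# the biological mechanism behind dinucleotide depletion.

#' Transition matrix of the dinucleotide-biased base chain
#'
#' Starts from the independence matrix implied by the base composition
#' (A = T = (1-gc)/2, C = G = gc/2), multiplies the C->G entry by
#' `lambda_cg` and the T->A entry by `lambda_ta`, and renormalizes each
#' row. `lambda = 1` means no suppression; smaller values deplete the
#' corresponding dinucleotide the way CpG (and, in invertebrates, TpA) is
#' depleted in real genomes.
#'
#' @param gc_target Stationary G+C fraction of the unsuppressed chain, in
#'   (0, 1).
#' @param lambda_cg,lambda_ta Suppression multipliers in (0, 1].
#' @return A 4x4 row-stochastic matrix with dimnames ACGT.
#' @export
markov_transition <- function(gc_target = 0.5, lambda_cg = 1,
                              lambda_ta = 1) {
  if (!(gc_target > 0 && gc_target < 1)) {
    stop("'gc_target' must lie in (0, 1)", call. = FALSE)
  }
  for (lam in c(lambda_cg, lambda_ta)) {
    if (!(lam > 0 && lam <= 1)) {
      stop("suppression multipliers must lie in (0, 1]", call. = FALSE)
    }
  }
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  M <- matrix(rep(p, each = 4L), 4L, 4L, dimnames = list(.BASES, .BASES))
  M["C", "G"] <- M["C", "G"] * lambda_cg
  M["T", "A"] <- M["T", "A"] * lambda_ta
  M / rowSums(M)
}

#' Stationary distribution of a transition matrix
#'
#' @param P A row-stochastic matrix.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(v, rownames(P))
}

#' Generate a root sequence from the base chain
#'
#' The first base is drawn from the stationary distribution of the chain,
#' subsequent bases from the transition matrix. Reproducible by seed.
#'
#' @param length Sequence length in bp (>= 2).
#' @param transition A 4x4 transition matrix (see [markov_transition()]).
#' @param seed Integer seed.
#' @return A character string over ACGT.
#' @export
generate_root <- function(length, transition, seed) {
  stopifnot(length >= 2L, is.matrix(transition), all(dim(transition) == 4L))
  set.seed(as.integer(seed))
  cum <- t(apply(transition, 1L, cumsum))
  pi0 <- cumsum(stationary_distribution(transition))
  u <- stats::runif(length)
  s <- integer(length)
  s[1L] <- 1L + (u[1L] > pi0[1L]) + (u[1L] > pi0[2L]) + (u[1L] > pi0[3L])
  for (i in 2:length) {
    p <- s[i - 1L]
    s[i] <- 1L + (u[i] > cum[p, 1L]) + (u[i] > cum[p, 2L]) +
      (u[i] > cum[p, 3L])
  }
  .int_to_seq(s)
}

.int_to_seq <- function(s) {
  rawToChar(charToRaw("ACGT")[s])
}

.seq_to_int <- function(x) {
  match(strsplit(x, "", fixed = TRUE)[[1L]], .BASES)
}

#' Jukes-Cantor substitution probability
#'
#' Probability that a site differs from its ancestor after a branch of
#' `b` expected substitutions per site: `(3/4) (1 - exp(-4 b / 3))`.
#'
#' @param b Branch length (expected substitutions per site, >= 0).
#' @return Probability in `[0, 3/4)`.
#' @export
jc_substitution_prob <- function(b) {
  stopifnot(all(b >= 0))
  0.75 * (1 - exp(-4 * b / 3))
}

# mutate an integer-coded sequence along one branch (RNG state is the
# caller's responsibility)
.evolve_branch <- function(s, b) {
  p <- jc_substitution_prob(b)
  if (p == 0) return(s)
  hit <- which(stats::runif(length(s)) < p)
  if (length(hit)) {
    s[hit] <- 1L + (s[hit] - 1L + sample(3L, length(hit),
                                         replace = TRUE)) %% 4L
  }
  s
}

#' Simulation configuration
#'
#' Bundles the generator parameters. Defaults are the package's benchmark
#' conditions: 8 taxa on a balanced tree with 0.05 substitutions/site per
#' branch, 200 kb genomes, neutral base composition (gc = 0.5), CpG
#' suppressed to 0.3 of its independence expectation and TpA unsuppressed.
#'
#' @param n_taxa Number of leaves (for the default balanced tree, a power
#'   of two).
#' @param root_length Root genome length in bp. Lengths well above the
#'   k-mer universe size (>= 10 * 4^k for the intended k) give stable
#'   ranks; a warning is issued below that for k = 8.
#' @param gc_target Stationary G+C fraction of the unsuppressed chain.
#' @param lambda_cg,lambda_ta CpG / TpA suppression multipliers in (0, 1].
#' @param branch_length Branch length (expected substitutions per site)
#'   used for every edge of the default balanced tree.
#' @param tree Optional [ape::phylo] tree with branch lengths; overrides
#'   `n_taxa`/`branch_length`.
#' @param seed Master seed; every per-branch random stream is derived from
#'   it deterministically.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_taxa = 8L, root_length = 200000L,
                       gc_target = 0.5, lambda_cg = 0.3, lambda_ta = 1,
                       branch_length = 0.05, tree = NULL, seed = 1L) {
  if (is.null(tree)) {
    if (n_taxa < 3L || bitwAnd(n_taxa, n_taxa - 1L) != 0L) {
      stop("the default balanced tree needs n_taxa to be a power of two ",
           ">= 4; pass an explicit 'tree' otherwise", call. = FALSE)
    }
    tree <- ape::stree(n_taxa, type = "balanced",
                       tip.label = paste0("t", seq_len(n_taxa)))
    tree$edge.length <- rep(branch_length, nrow(tree$edge))
  }
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0))
  if (root_length < 10 * 4^8) {
    warning("root_length below 10 * 4^8 bp; 8-mer ranks will be noisy",
            call. = FALSE)
  }
  # validated by markov_transition
  invisible(markov_transition(gc_target, lambda_cg, lambda_ta))
  structure(
    list(n_taxa = length(tree$tip.label), root_length = as.integer(root_length),
         gc_target = gc_target, lambda_cg = lambda_cg,
         lambda_ta = lambda_ta, tree = tree, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate genomes along a known tree
#'
#' Generates a dinucleotide-biased root genome, evolves it along each
#' branch of the configured tree under Jukes-Cantor substitution (each
#' site substitutes independently; the new base is uniform over the other
#' three), and returns one genome per leaf together with the true tree.
#' Each branch uses a random stream derived deterministically from the
#' master seed and the child node id, so results are byte-reproducible.
#'
#' @param cfg A [sim_config()] object.
#' @param out_dir Optional directory: writes one FASTA per leaf,
#'   `true_tree.nwk`, and `config.json` echoing all parameters.
#' @return A list with `genomes` (named list of `genome` objects),
#'   `tree` (the true [ape::phylo] tree) and `config`.
#' @export
simulate_genomes <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  tree <- ape::reorder.phylo(cfg$tree, "cladewise")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  set.seed(cfg$seed)
  node_seed <- sample.int(.Machine$integer.max - 1L, n_node)
  P <- markov_transition(cfg$gc_target, cfg$lambda_cg, cfg$lambda_ta)
  root_id <- n_tip + 1L
  seqs <- vector("list", n_node)
  seqs[[root_id]] <- .seq_to_int(
    generate_root(cfg$root_length, P, node_seed[root_id])
  )
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    set.seed(node_seed[child])
    seqs[[child]] <- .evolve_branch(seqs[[parent]], tree$edge.length[e])
  }
  genomes <- lapply(seq_len(n_tip), function(i) {
    genome_from_sequences(tree$tip.label[i],
                          stats::setNames(.int_to_seq(seqs[[i]]), "sim"))
  })
  names(genomes) <- tree$tip.label
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in genomes) {
      write_fasta(g, file.path(out_dir, paste0(g$taxon_id, ".fasta")))
    }
    to_newick(tree, file.path(out_dir, "true_tree.nwk"), precision = 10L)
    cfg_out <- cfg
    cfg_out$tree <- to_newick(tree, precision = 10L)
    jsonlite::write_json(unclass(cfg_out),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(genomes = genomes, tree = tree, config = cfg)
}
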