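# End-to-end orchestration: FASTA genomes -> counts -> separability ->
# rank features -> RMSE distance matrix -> NJ tree, with tabular artifacts
# and a provenance manifest.

#' Run the full rank-feature phylogeny pipeline
#'
#' Counts k-mers in each genome, writes the per-genome count tables and the
#' 48-subset separability table, rank-transforms counts within the chosen
#' feature set, computes the pairwise RMSE distance matrix, builds the
#' neighbor-joining tree, and writes a PHYLIP matrix, a Newick tree and a
#' JSON manifest recording all parameters. Given identical inputs and
#' parameters, the PHYLIP and Newick outputs are byte-identical across
#' runs.
#'
#' @param fasta Either a directory containing `.fasta`/`.fa`/`.fna` files
#'   (one taxon each) or a character vector of FASTA paths; alternatively
#'   pass pre-built `genome` objects via `genomes`.
#' @param out_dir Output directory (created if missing).
#' @param genomes Optional named list of `genome` objects, used instead of
#'   `fasta`.
#' @param k Word length (default 8).
#' @param feature_set Preset name (`"CG12"`, `"TA12"`, `"CG0"`, `"TA0"`,
#'   `"TOTAL"`) or custom `list(xy =, classes =)`.
#' @param tie_policy `"ordinal"` or `"average"` rank ties.
#' @param rank_scope `"union"` (ranks computed jointly over the whole
#'   feature set, the default) or `"per_class"` (ranks computed within each
#'   XYi class of the set separately, then assembled).
#' @param write_tables Write per-genome count and rank TSVs (default TRUE;
#'   the separability table, PHYLIP matrix, Newick tree and manifest are
#'   always written).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `distances` (matrix), `tree`
#'   ([ape::phylo]), `features` (list of `feature_vector`), and `files`
#'   (paths of the written artifacts).
#' @export
run_pipeline <- function(fasta = NULL, out_dir, genomes = NULL, k = 8L,
                         feature_set = "CG12",
                         tie_policy = c("ordinal", "average"),
                         rank_scope = c("union", "per_class"),
                         write_tables = TRUE, quiet = FALSE) {
  tie_policy <- match.arg(tie_policy)
  rank_scope <- match.arg(rank_scope)
  say <- function(...) if (!quiet) message(...)
  if (is.null(genomes)) {
    if (is.null(fasta)) {
      stop("config error: supply 'fasta' (directory or file paths) or ",
           "'genomes'", call. = FALSE)
    }
    files <- if (length(fasta) == 1L && dir.exists(fasta)) {
      list.files(fasta, pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
                 ignore.case = TRUE, full.names = TRUE)
    } else {
      fasta
    }
    if (length(files) < 3L) {
      stop("config error: need at least 3 FASTA inputs, found ",
           length(files), call. = FALSE)
    }
    genomes <- lapply(sort(files), read_fasta)
  } else {
    if (length(genomes) < 3L) {
      stop("config error: need at least 3 genomes", call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set <- build_feature_set(k, feature_set)
  say("feature set ", set$name, " at k = ", k, ": ", set$size, " k-mers")

  written <- character(0)
  counts <- list()
  features <- list()
  for (g in genomes) {
    say("counting ", g$taxon_id, ": ", length(g$records), " record(s), ",
        g$total_length, " bp")
    cnt <- count_kmers(g, k)
    say("  ", cnt$total_windows, " windows counted")
    counts[[g$taxon_id]] <- cnt
    if (write_tables) {
      p <- file.path(out_dir, paste0("counts_", g$taxon_id, ".tsv"))
      write_tsv_table(.counts_table(cnt), p)
      written <- c(written, p)
    }
    features[[g$taxon_id]] <- .ranked_features(cnt, set, tie_policy,
                                               rank_scope)
    if (write_tables) {
      p <- file.path(out_dir, paste0("ranks_", g$taxon_id, ".tsv"))
      write_tsv_table(.ranks_table(features[[g$taxon_id]], cnt), p)
      written <- c(written, p)
    }
  }

  say("separability tables (48 subsets per genome)")
  sep <- do.call(rbind, lapply(counts, function(cnt) {
    tab <- separability_table(cnt)
    cbind(taxon = cnt$taxon_id, tab)
  }))
  rownames(sep) <- NULL
  sep_path <- file.path(out_dir, "separability.tsv")
  write_tsv_table(sep, sep_path)

  say("distance matrix over ", length(features), " taxa")
  dm <- distance_matrix(unname(features))
  phy_path <- file.path(out_dir, "distances.phy")
  write_phylip(dm, phy_path)

  say("neighbor-joining tree")
  tree <- neighbor_joining(dm)
  nwk_path <- file.path(out_dir, "tree.nwk")
  to_newick(tree, nwk_path)

  manifest <- list(
    tool = "kmerphylo",
    version = as.character(utils::packageVersion("kmerphylo")),
    k = as.integer(k),
    feature_set = set$name,
    feature_set_size = set$size,
    tie_policy = tie_policy,
    rank_scope = rank_scope,
    taxa = names(counts),
    total_windows = stats::setNames(
      vapply(counts, function(x) x$total_windows, numeric(1)),
      names(counts)
    ),
    outputs = basename(c(written, sep_path, phy_path, nwk_path))
  )
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("done: ", nwk_path)
  invisible(list(
    distances = dm, tree = tree, features = features,
    files = c(written, separability = sep_path, phylip = phy_path,
              newick = nwk_path, manifest = man_path)
  ))
}

# rank features under either rank scope
.ranked_features <- function(cnt, set, tie_policy, rank_scope) {
  if (rank_scope == "union" || length(set$classes) <= 1L ||
      set$name == "TOTAL") {
    return(relative_frequency(cnt, set, tie_policy))
  }
  # per-class: rank within each XYi class of the set, then assemble the
  # class-wise ranks into one vector aligned to the union's member order
  ranks <- numeric(set$size)
  for (cls in set$classes) {
    sub <- build_feature_set(set$k, list(xy = set$xy, classes = cls))
    fv <- relative_frequency(cnt, sub, tie_policy)
    ranks[match(sub$members, set$members)] <- fv$ranks
  }
  structure(
    list(taxon_id = cnt$taxon_id, set = set,
         tie_policy = tie_policy, ranks = ranks),
    class = "feature_vector"
  )
}

.counts_table <- function(cnt) {
  data.frame(
    kmer = .all_kmers(cnt$k),
    index = 0:(4^cnt$k - 1),
    count = cnt$counts
  )
}

.ranks_table <- function(fv, cnt) {
  data.frame(
    kmer = .all_kmers(fv$set$k)[fv$set$members + 1L],
    index = fv$set$members,
    count = cnt$counts[fv$set$members + 1L],
    rank = fv$ranks
  )
}

.all_kmers <- function(k) {
  key <- paste0("names:", k)
  if (is.null(.kmer_cache[[key]])) {
    .kmer_cache[[key]] <- Biostrings::mkAllStrings(.BASES, k)
  }
  .kmer_cache[[key]]
}
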