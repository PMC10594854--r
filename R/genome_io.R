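#' Read a genome from a FASTA file
#'
#' Reads a (possibly multi-record) FASTA file as one genome: every record is
#' taken to be a chromosome or contig of a single taxon. Sequences are
#' uppercased on read, so soft-masked (lowercase) bases are retained and
#' counted like any other base. IUPAC ambiguity codes are kept; the counting
#' engine skips any window that contains one.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @param taxon_id Taxon label for the genome. Defaults to the file name
#'   without extensions.
#' @param exclude_records Optional character vector of record ids to drop
#'   (e.g. sex chromosomes), matched against the first whitespace-delimited
#'   token of each header.
#'
#' @return A `genome` object: a list with elements `taxon_id` (character),
#'   `records` (a [Biostrings::DNAStringSet] named by record id) and
#'   `total_length` (total bp).
#'
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT", ">chr2", "GGGG"), fa)
#' g <- read_fasta(fa, taxon_id = "toy")
#' g$total_length
#' @export
read_fasta <- function(path, taxon_id = NULL, exclude_records = NULL) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  if (is.null(taxon_id)) {
    taxon_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                    basename(path), ignore.case = TRUE)
    taxon_id <- tools::file_path_sans_ext(taxon_id)
  }
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE)
  )
  if (length(raw) == 0L) {
    stop("FASTA format error in '", path, "': no sequence records",
         call. = FALSE)
  }
  ids <- vapply(strsplit(names(raw), "[[:space:]]+"), `[`, "", 1L)
  names(raw) <- ids
  if (!is.null(exclude_records)) {
    raw <- raw[!ids %in% exclude_records]
    if (length(raw) == 0L) {
      stop("all records of '", path, "' were excluded", call. = FALSE)
    }
  }
  if (any(Biostrings::width(raw) == 0L)) {
    stop("FASTA format error in '", path, "': record '",
         names(raw)[which(Biostrings::width(raw) == 0L)[1L]],
         "' has no sequence", call. = FALSE)
  }
  up <- toupper(as.character(raw))
  bad <- regexpr(sprintf("[^%s]", .iupac_chars()), up)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("FASTA format error in '", path, "': record '", names(up)[i],
         "' position ", bad[i], ": character '",
         substr(up[i], bad[i], bad[i]),
         "' is not an IUPAC nucleotide code", call. = FALSE)
  }
  records <- Biostrings::DNAStringSet(up)
  new_genome(taxon_id, records)
}

# DNA alphabet accepted at read time (IUPAC codes + gap characters).
.iupac_chars <- function() "ACGTNRYSWKMBDHV.+-"

new_genome <- function(taxon_id, records) {
  stopifnot(is.character(taxon_id), length(taxon_id) == 1L,
            nzchar(taxon_id), methods::is(records, "DNAStringSet"),
            length(records) >= 1L)
  structure(
    list(taxon_id = taxon_id,
         records = records,
         total_length = sum(Biostrings::width(records))),
    class = "genome"
  )
}

#' Build a genome object from plain character sequences
#'
#' Convenience constructor used by the simulator and in tests.
#'
#' @param taxon_id Taxon label.
#' @param sequences Named (or unnamed) character vector, one element per
#'   record; unnamed records are labelled `rec1`, `rec2`, ...
#' @return A `genome` object (see [read_fasta()]).
#' @export
genome_from_sequences <- function(taxon_id, sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    names(sequences) <- paste0("rec", seq_along(sequences))
  }
  new_genome(taxon_id, Biostrings::DNAStringSet(toupper(sequences)))
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", x$taxon_id, ": ", length(x$records), " record(s), ",
      format(x$total_length, big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Write a genome to a FASTA file
#'
#' @param genome A `genome` object.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return The path, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome"))
  Biostrings::writeXStringSet(genome$records, path, width = width)
  invisible(path)
}

#' Write a table as TSV
#'
#' Writes a data frame as a tab-separated UTF-8 file with a header line.
#' Integer columns are rendered as integers; double columns with 6
#' significant digits (the precision used for separability and RMN values).
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.double(col)) {
      out[[j]] <- ifelse(is.na(col), "NA",
                         formatC(col, digits = 6L, format = "g"))
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write TSV to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}
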