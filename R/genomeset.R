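#' Construct a genome set
#'
#' A \code{genome_set} is the container used throughout the package for both
#' host/contaminant references and microbial databases: an ordered collection
#' of named contigs over the alphabet \code{\{A,C,G,T,N\}}, plus a map from
#' each contig to the genome it belongs to (so masking can be reported
#' per genome, e.g. per RefSeq assembly).
#'
#' Sequences are uppercased on ingest. Any character outside
#' \code{\{A,C,G,T,N\}} is a hard error naming the contig and offset; it is
#' never silently coerced to \code{N}.
#'
#' @param seqs named character vector of contig sequences. Names are contig
#'   ids and must be nonempty and unique.
#' @param genome_of_contig optional named character vector mapping contig id
#'   to genome id. Defaults to one genome per contig (genome id = contig id).
#' @return an object of class \code{genome_set} with elements \code{seqs}
#'   and \code{genome}.
#' @examples
#' gs <- genome_set(c(chr1 = "ACGTACGT", chr2 = "GGGNACGT"))
#' contig_lengths(gs)
#' @export
genome_set <- function(seqs, genome_of_contig = NULL) {
  if (length(seqs) > 0 && (is.null(names(seqs)) || any(!nzchar(names(seqs)))))
    stop_contract("every contig must have a nonempty id")
  if (anyDuplicated(names(seqs)))
    stop_contract("duplicate contig ids: ",
                  paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop_format("contig '", names(seqs)[i], "' contains a non-ACGTN character at offset ",
                bad[i], " ('", substr(seqs[i], bad[i], bad[i]), "')")
  }
  if (is.null(genome_of_contig)) {
    genome_of_contig <- stats::setNames(names(seqs), names(seqs))
  } else {
    if (!all(names(seqs) %in% names(genome_of_contig)))
      stop_contract("genome_of_contig must cover every contig id")
    genome_of_contig <- genome_of_contig[names(seqs)]
  }
  structure(list(seqs = seqs, genome = genome_of_contig), class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", length(x$seqs), "contig(s),",
      length(unique(x$genome)), "genome(s),",
      sum(nchar(x$seqs)), "bp total\n")
  invisible(x)
}

#' Contig lengths of a genome set
#' @param gs a \code{genome_set}.
#' @return named integer vector of contig lengths.
#' @export
contig_lengths <- function(gs) {
  stats::setNames(nchar(gs$seqs), names(gs$seqs))
}

#' Read a multi-FASTA file into a genome set
#'
#' FASTA headers are truncated at the first whitespace to form contig ids,
#' following common aligner behaviour. Sequences are uppercased and validated
#' against \code{\{A,C,G,T,N\}}.
#'
#' @param path path to a FASTA file.
#' @param genome_of_contig optional contig id to genome id map
#'   (see [genome_set()]).
#' @return a \code{genome_set}.
#' @export
read_fasta <- function(path, genome_of_contig = NULL) {
  if (!file.exists(path)) stop_format("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  genome_set(stats::setNames(as.character(ss), ids), genome_of_contig)
}

#' Write a genome set as FASTA
#'
#' @param gs a \code{genome_set}.
#' @param path output path. Lines are wrapped at 60 characters.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(gs, path) {
  ss <- Biostrings::DNAStringSet(gs$seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read a genome-to-taxon map from TSV
#'
#' Two tab-separated columns without header: genome id, taxon label.
#'
#' @param path path to the TSV file.
#' @return named character vector (genome id -> taxon).
#' @export
read_taxon_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("genome_id", "taxon"),
                          colClasses = "character", quote = "")
  stats::setNames(df$taxon, df$genome_id)
}
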