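#' Create a genome object
#'
#' A genome is an ordered set of chromosome sequences with a free-text label
#' identifying which assembly it is (typically `"female"` or `"male"`).
#' Sequences are normalised to uppercase and validated against the A/C/G/T/N
#' alphabet. All package-internal coordinates on a genome are 0-based
#' half-open; file formats render 1-based inclusive coordinates.
#'
#' @param seqs Named character vector, one element per chromosome.
#' @param label Free-text assembly label.
#' @return An object of class `genome`: a list with elements `label`,
#'   `seq` (named uppercase character vector) and `lengths` (named integer).
#' @export
genome <- function(seqs, label = "genome") {
  if (is.null(names(seqs)) || any(names(seqs) == "") || anyNA(names(seqs)))
    stop("all chromosome sequences must be named", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome name: ",
         names(seqs)[duplicated(names(seqs))][1], call. = FALSE)
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence for '", names(seqs)[bad][1],
         "' contains characters outside A/C/G/T/N", call. = FALSE)
  structure(
    list(label = label,
         seq = seqs,
         lengths = stats::setNames(nchar(seqs), names(seqs))),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> label:", x$label, "|", length(x$seq), "sequence(s),",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

#' @export
length.genome <- function(x) length(x$seq)

#' Read a genome from a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()]; record order is preserved, headers
#' are truncated at the first whitespace, and sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @param label Assembly label to attach.
#' @return A [genome] object.
#' @export
read_genome_fasta <- function(path, label = "genome") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate chromosome name in ", path, ": ",
         nm[duplicated(nm)][1], call. = FALSE)
  genome(stats::setNames(as.character(ss), nm), label = label)
}

#' Write a genome to a FASTA file
#'
#' @param g A [genome] object.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(g, path, width = 70) {
  ss <- Biostrings::DNAStringSet(g$seq)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

genome_subseq <- function(g, chrom, start0, end0) {
  # 0-based half-open extraction
  if (!chrom %in% names(g$seq))
    stop("unknown chromosome '", chrom, "' in genome '", g$label, "'",
         call. = FALSE)
  substr(g$seq[[chrom]], start0 + 1, end0)
}
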