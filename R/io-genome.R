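#' Read or write a genome as FASTA
#'
#' Genomes are held as a named character vector of uppercase DNA strings over
#' A, C, G, T, N (one element per chromosome). All coordinates in the package
#' are 0-based half-open.
#'
#' @param path FASTA file path.
#' @return `read_genome_fasta()` returns the named character vector;
#'   `write_genome_fasta()` returns `path` invisibly.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  genome <- toupper(as.character(seqs))
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (any(nchar(genome) == 0)) stop("empty sequence in FASTA")
  genome
}

#' @rdname read_genome_fasta
#' @param genome Named character vector of chromosome sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path, width = 70L
  )
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Extract genome[chrom][start, end) (0-based half-open); no strand handling.
genome_subseq <- function(genome, chrom, start, end) {
  if (any(!chrom %in% names(genome))) {
    stop("chromosome absent from genome: ",
         paste(unique(setdiff(chrom, names(genome))), collapse = ", "))
  }
  substring(genome[chrom], start + 1L, end)
}

# Strand-oriented sequence: reverse complement for "-" so the string reads
# 5' -> 3' on the transcript strand.
oriented_subseq <- function(genome, chrom, start, end, strand) {
  s <- genome_subseq(genome, chrom, start, end)
  neg <- strand == "-"
  if (any(neg)) s[neg] <- reverse_complement(s[neg])
  unname(s)
}
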