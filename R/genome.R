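# IUPAC nucleotide codes accepted for DNA input. U is deliberately absent:
# the toolkit operates on genomic DNA.
IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Construct a genome sequence object
#'
#' A `genome_seq` holds one chromosome (or plasmid) as an upper-cased IUPAC
#' DNA string together with its identifier and topology. Ambiguity codes are
#' accepted but never contribute to the four base counters downstream.
#'
#' @param genome_id Sequence identifier (the FASTA header token before the
#'   first whitespace when read from file).
#' @param residues Character scalar of IUPAC nucleotide codes; lower case is
#'   normalized to upper case.
#' @param topology `"circular"` (the default, a bacterial chromosome) or
#'   `"linear"`.
#' @return An object of class `genome_seq` with fields `genome_id`,
#'   `residues`, `N` (sequence length) and `topology`.
#' @examples
#' g <- genome_seq("toy", "acgtACGT")
#' g$N
#' @export
genome_seq <- function(genome_id, residues, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  bad <- validate_residues(residues)
  if (length(bad)) {
    stop(sprintf("sequence '%s': invalid nucleotide code '%s' at offset %d",
                 genome_id, substr(residues, bad[1], bad[1]), bad[1]),
         call. = FALSE)
  }
  structure(
    list(genome_id = genome_id, residues = residues,
         N = nchar(residues), topology = topology),
    class = "genome_seq"
  )
}

# Returns the 1-based offsets of residues outside the IUPAC DNA alphabet.
validate_residues <- function(residues) {
  if (!nzchar(residues)) return(integer(0))
  codes <- utf8ToInt(residues)
  allowed <- utf8ToInt(paste(IUPAC_DNA, collapse = ""))
  which(!(codes %in% allowed))
}

#' @export
print.genome_seq <- function(x, ...) {
  head_ <- substr(x$residues, 1L, 60L)
  cat(sprintf("<genome_seq> %s: %s chromosome, %d bp\n",
              x$genome_id, x$topology, x$N))
  cat(sprintf("  %s%s\n", head_, if (x$N > 60L) "..." else ""))
  invisible(x)
}

# Complement each base in place (no reversal); IUPAC-aware.
complement_residues <- function(residues) {
  chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
         "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", residues)
}

#' Complement a genome sequence in place
#'
#' Replaces every residue by its Watson-Crick complement without reversing
#' the sequence, i.e. it yields the antiparallel strand read in the same
#' coordinate direction. Useful for strand-symmetry checks: the ZCC index is
#' invariant under this operation.
#'
#' @param seq A [genome_seq()].
#' @return A `genome_seq` with complemented residues.
#' @export
complement_genome <- function(seq) {
  stopifnot(inherits(seq, "genome_seq"))
  genome_seq(seq$genome_id, complement_residues(seq$residues), seq$topology)
}
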