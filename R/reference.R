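#' Reference sequence window
#'
#' A named stretch of reference DNA with an explicit 1-based coordinate
#' offset, standing in for a genome assembly locally. Lookups outside
#' `[offset, offset + nchar(bases) - 1]` are errors.
#'
#' @param name sequence (chromosome/contig) name.
#' @param bases uppercase DNA string over A,C,G,T,N.
#' @param offset 1-based genomic coordinate of the first base of `bases`.
#' @return a `ReferenceSequence` object.
#' @export
reference_sequence <- function(name, bases, offset = 1L) {
  bases <- toupper(bases)
  if (!is_dna(bases)) stop_data("reference bases must be a non-empty string over A,C,G,T,N")
  if (offset < 1) stop_data("offset must be >= 1")
  structure(
    list(name = as.character(name), bases = bases, offset = as.integer(offset)),
    class = "ReferenceSequence"
  )
}

#' @export
print.ReferenceSequence <- function(x, ...) {
  cat(sprintf("ReferenceSequence %s: %d bp starting at %d\n",
              x$name, nchar(x$bases), x$offset))
  invisible(x)
}

ref_end <- function(refseq) refseq$offset + nchar(refseq$bases) - 1L

#' Extract reference bases by genomic coordinates
#'
#' @param refseq a [reference_sequence()].
#' @param start,end 1-based inclusive genomic coordinates.
#' @return character scalar of bases.
#' @export
ref_slice <- function(refseq, start, end) {
  if (start < refseq$offset || end > ref_end(refseq) || start > end)
    stop_data(sprintf("coordinates %d-%d outside reference window %d-%d of %s",
                      start, end, refseq$offset, ref_end(refseq), refseq$name))
  substr(refseq$bases, start - refseq$offset + 1L, end - refseq$offset + 1L)
}

## Resolve a reference for a chromosome from either a single
## ReferenceSequence or a list of them.
resolve_reference <- function(reference, chrom) {
  if (inherits(reference, "ReferenceSequence")) {
    if (reference$name != chrom)
      stop_data(sprintf("no reference sequence for chromosome '%s'", chrom))
    return(reference)
  }
  nm <- vapply(reference, function(r) r$name, character(1))
  i <- match(chrom, nm)
  if (is.na(i)) stop_data(sprintf("no reference sequence for chromosome '%s'", chrom))
  reference[[i]]
}

#' Apply a variant edit to a reference window
#'
#' Replaces the REF allele at `pos` with the ALT allele and returns the full
#' edited window as a string. Used by the synthetic-data generator to
#' enumerate equivalent indel placements.
#'
#' @param refseq a [reference_sequence()].
#' @param pos 1-based position of the first REF base.
#' @param ref_allele,alt_allele allele strings.
#' @return edited sequence of the whole window (character scalar).
#' @export
apply_variant_edit <- function(refseq, pos, ref_allele, alt_allele) {
  L <- nchar(ref_allele)
  if (ref_slice(refseq, pos, pos + L - 1L) != ref_allele)
    stop_data(sprintf("REF mismatch at %s:%d: expected '%s', reference has '%s'",
                      refseq$name, pos, ref_allele, ref_slice(refseq, pos, pos + L - 1L)))
  i <- pos - refseq$offset + 1L
  paste0(
    substr(refseq$bases, 1L, i - 1L),
    alt_allele,
    substr(refseq$bases, i + L, nchar(refseq$bases))
  )
}

#' Read reference sequences from a FASTA file
#'
#' @param path FASTA file (optionally gzipped).
#' @return named list of [reference_sequence()] objects, offset 1.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  refs <- lapply(seq_along(ss), function(i) {
    nm <- sub("\\s.*$", "", names(ss)[i])
    reference_sequence(nm, as.character(ss[[i]]))
  })
  names(refs) <- vapply(refs, function(r) r$name, character(1))
  refs
}

#' Write reference sequences to a FASTA file
#'
#' @param refs a `ReferenceSequence` or list of them (offset must be 1).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  if (inherits(refs, "ReferenceSequence")) refs <- list(refs)
  for (r in refs) {
    if (r$offset != 1L)
      stop_data("only whole sequences (offset 1) can be written to FASTA")
  }
  ss <- Biostrings::DNAStringSet(vapply(refs, function(r) r$bases, character(1)))
  names(ss) <- vapply(refs, function(r) r$name, character(1))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
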