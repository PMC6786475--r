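#' Read a genome from FASTA
#'
#' Loads a founder genome as a named character vector of uppercase contig
#' sequences. Only `A`, `C`, `G`, `T`, `N` are accepted; anything else is a
#' format error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of contig sequences (class
#'   `podevol_genome`), names are contig ids (first whitespace-delimited token
#'   of each FASTA header).
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  genome(seqs)
}

#' Construct and validate a genome object
#'
#' @param contigs Named character vector of nucleotide sequences.
#' @return The validated genome (uppercased), class `podevol_genome`.
#' @export
genome <- function(contigs) {
  if (length(contigs) == 0) abort("genome must contain at least one contig")
  ids <- names(contigs)
  if (is.null(ids) || any(!nzchar(ids))) abort("all contigs must have non-empty ids")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate contig ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    abort(paste0("illegal characters (not A/C/G/T/N) in contig(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  if (sum(nchar(contigs)) == 0) abort("genome has total length 0")
  structure(contigs, class = "podevol_genome")
}

#' Write a genome to FASTA
#'
#' @param genome A `podevol_genome` (named character vector of contigs).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' @export
print.podevol_genome <- function(x, ...) {
  cat("<podevol_genome> ", length(x), " contig(s), ",
      format(sum(nchar(x)), big.mark = ","), " bp total\n", sep = "")
  for (id in names(x)) cat("  ", id, ": ", nchar(x[[id]]), " bp\n", sep = "")
  invisible(x)
}

#' Forward-strand trinucleotide context of a genomic position
#'
#' Returns the 3-mer centred on `position` (0-based) read on the forward
#' strand. Positions at a contig edge, or whose window contains `N`, have no
#' defined context and return `NA` — callers decide the fallback (the
#' permutation engine places such mutations uniformly).
#'
#' @param genome A `podevol_genome`.
#' @param contig Contig id.
#' @param position 0-based position (vectorised).
#' @return Character vector of 3-mers, `NA` where undefined.
#' @export
trinucleotide_context <- function(genome, contig, position) {
  seq <- genome[[contig]]
  if (is.null(seq)) abort(paste0("unknown contig: ", contig))
  L <- nchar(seq)
  ctx <- rep(NA_character_, length(position))
  ok <- position >= 1 & position <= L - 2
  if (any(ok)) {
    # substring is 1-based: window position-1..position+1 in 0-based
    # coordinates is position..position+2 in 1-based coordinates
    k <- substring(seq, position[ok], position[ok] + 2)
    k[grepl("N", k, fixed = TRUE)] <- NA_character_
    ctx[ok] <- k
  }
  ctx
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, NULL), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
}

# translate a DNA string with the standard code; '*' for stops
translate_dna <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s) %/% 3
    if (n == 0) return("")
    codons <- substring(s, seq(1, by = 3, length.out = n), seq(3, by = 3, length.out = n))
    aa <- Biostrings::GENETIC_CODE[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Is a codon a stop codon?
#'
#' @param codon Character vector of 3-mers (standard genetic code).
#' @return Logical: TAA / TAG / TGA are `TRUE`.
#' @export
is_stop_codon <- function(codon) {
  !is.na(Biostrings::GENETIC_CODE[codon]) & Biostrings::GENETIC_CODE[codon] == "*"
}
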