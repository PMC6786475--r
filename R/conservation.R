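#' Build an ortholog-pair table from gapped alignments
#'
#' @param focal_id,ortholog_id Character vectors of protein ids.
#' @param aln_focal,aln_ortholog Aligned sequences (equal lengths per pair,
#'   gap character `-`).
#' @param max_gap_fraction Reliability threshold: a pair is `reliable` when
#'   its gap fraction (columns with a gap in either sequence / all columns) is
#'   at most this value (boundary inclusive).
#' @return Tibble: `focal_id`, `ortholog_id`, `aln_focal`, `aln_ortholog`,
#'   `gap_fraction`, `conserved_fraction`, `reliable`.
#' @export
ortholog_pairs <- function(focal_id, ortholog_id, aln_focal, aln_ortholog,
                           max_gap_fraction = 0.20) {
  if (any(nchar(aln_focal) != nchar(aln_ortholog))) {
    abort("aligned sequences must have equal length within a pair")
  }
  tb <- tibble(focal_id = focal_id, ortholog_id = ortholog_id,
               aln_focal = toupper(aln_focal),
               aln_ortholog = toupper(aln_ortholog))
  tb |>
    mutate(gap_fraction = map2_dbl_(tb$aln_focal, tb$aln_ortholog, gap_fraction_one),
           conserved_fraction = map2_dbl_(tb$aln_focal, tb$aln_ortholog,
                                          conserved_fraction_one),
           reliable = .data$gap_fraction <= max_gap_fraction)
}

map2_dbl_ <- function(x, y, f) {
  vapply(seq_along(x), function(i) f(x[i], y[i]), numeric(1))
}

gap_fraction_one <- function(a, b) {
  ca <- strsplit(a, NULL)[[1]]; cb <- strsplit(b, NULL)[[1]]
  mean(ca == "-" | cb == "-")
}

conserved_fraction_one <- function(a, b) {
  ca <- strsplit(a, NULL)[[1]]; cb <- strsplit(b, NULL)[[1]]
  focal <- ca != "-"
  if (!any(focal)) return(NA_real_)
  sum(focal & ca == cb & cb != "-") / sum(focal)
}

#' Conserved fraction of an alignment
#'
#' A column is conserved iff both sequences carry the identical residue (any
#' gap makes the column non-conserved). The denominator is the number of
#' columns where the focal sequence has a residue, so mutated-site lookups and
#' the genome-wide background live on the same column universe.
#'
#' @param aln_focal,aln_ortholog One gapped sequence pair.
#' @return Fraction in `[0, 1]` (`NA` for an all-gap focal sequence).
#' @export
conserved_fraction <- function(aln_focal, aln_ortholog) {
  conserved_fraction_one(toupper(aln_focal), toupper(aln_ortholog))
}

#' Is a focal residue at a conserved alignment column?
#'
#' @param aln_focal,aln_ortholog One gapped sequence pair.
#' @param focal_residue_index 1-based index into the ungapped focal sequence
#'   (vectorised).
#' @return Logical: the residue's column carries identical residues in both
#'   sequences.
#' @export
site_is_conserved <- function(aln_focal, aln_ortholog, focal_residue_index) {
  ca <- strsplit(toupper(aln_focal), NULL)[[1]]
  cb <- strsplit(toupper(aln_ortholog), NULL)[[1]]
  col_of <- which(ca != "-")
  if (any(focal_residue_index < 1 | focal_residue_index > length(col_of))) {
    abort("focal_residue_index out of range of the ungapped focal sequence")
  }
  cols <- col_of[focal_residue_index]
  ca[cols] == cb[cols] & cb[cols] != "-"
}

#' Read ortholog pairs from aligned FASTA files or a TSV
#'
#' FASTA input: each file holds exactly two aligned records (focal first).
#' TSV input: columns `focal_id`, `ortholog_id`, `aln_focal`, `aln_ortholog`.
#'
#' @param paths Vector of aligned-FASTA paths, or one TSV path.
#' @param max_gap_fraction Passed to [ortholog_pairs()].
#' @return Ortholog-pair tibble.
#' @export
read_ortholog_pairs <- function(paths, max_gap_fraction = 0.20) {
  if (length(paths) == 1 && grepl("\\.(tsv|txt)$", paths)) {
    tb <- readr::read_tsv(paths, show_col_types = FALSE, progress = FALSE)
    return(ortholog_pairs(tb$focal_id, tb$ortholog_id, tb$aln_focal,
                          tb$aln_ortholog, max_gap_fraction))
  }
  recs <- map(paths, function(p) {
    set <- Biostrings::readBStringSet(p)
    if (length(set) != 2) abort(paste0("expected 2 aligned records in ", p))
    list(ids = sub("\\s.*$", "", names(set)), seqs = as.character(set))
  })
  ortholog_pairs(map_chr(recs, ~ .x$ids[1]), map_chr(recs, ~ .x$ids[2]),
                 map_chr(recs, ~ .x$seqs[1]), map_chr(recs, ~ .x$seqs[2]),
                 max_gap_fraction)
}

#' Write ortholog pairs as a TSV
#'
#' @param pairs Ortholog-pair tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_pairs <- function(pairs, path) {
  readr::write_tsv(pairs[, c("focal_id", "ortholog_id", "aln_focal",
                             "aln_ortholog")], path)
  invisible(path)
}

#' Binomial enrichment test for ortholog-bearing proteins
#'
#' Exact binomial test of `k` ortholog-bearing proteins among `n`
#' mutation-carrying proteins against the genome-wide background fraction of
#' proteins with a reliable ortholog. The default is the two-sided exact test
#' (the convention behind the reported values this models);
#' `alternative = "greater"` gives the right-tail `P(X >= k)`.
#'
#' @param k Number of mutation-carrying proteins with a reliable ortholog.
#' @param n Number of mutation-carrying proteins.
#' @param background Genome-wide reliable-ortholog fraction, in `(0, 1)`.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return The p-value.
#' @export
ortholog_enrichment_test <- function(k, n, background,
                                     alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(k >= 0, k <= n, background > 0, background < 1)
  if (alternative == "greater") {
    pbinom(k - 1, n, background, lower.tail = FALSE)
  } else {
    binom.test(k, n, background)$p.value
  }
}

#' Binomial test for conservation of mutated sites
#'
#' Tests `k` conserved sites among `n` mutated sites against the background
#' fraction of conserved alignment columns. Same conventions as
#' [ortholog_enrichment_test()].
#'
#' @param k Number of mutated sites falling on conserved columns.
#' @param n Number of mutated sites.
#' @param background Background conserved-column fraction.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return The p-value.
#' @export
site_conservation_test <- function(k, n, background,
                                   alternative = c("two.sided", "greater")) {
  ortholog_enrichment_test(k, n, background, match.arg(alternative))
}
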