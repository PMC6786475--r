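#' Read per-sample variant calls
#'
#' Accepts either VCF 4.x (per-sample `DP` and `AD` FORMAT fields; one row per
#' site, expanded to one record per called sample) or a plain TSV dialect with
#' columns `contig, pos_1based, ref, alt, sample, coverage, alt_reads,
#' frequency`. Positions are converted to the internal 0-based convention and
#' indels are normalised (shared bases trimmed, left-aligned against the
#' genome when supplied).
#'
#' @param path Path to a `.vcf` or `.tsv` file.
#' @param genome Optional `podevol_genome`; enables full left-alignment of
#'   indels through repeat tracts.
#' @param sample_map Optional named character vector translating file sample
#'   ids to `population.timepoint` ids (names = file ids).
#' @param freq_tol Tolerance for `frequency` vs `alt_reads/coverage`
#'   consistency (accounts for caller rounding).
#' @return Tibble of calls: `contig`, `pos` (0-based), `ref`, `alt`,
#'   `variant_class`, `sample_id`, `population`, `timepoint`, `coverage`,
#'   `alt_reads`, `frequency`.
#' @export
read_variants <- function(path, genome = NULL, sample_map = NULL,
                          freq_tol = 0.01) {
  raw <- if (grepl("\\.vcf(\\.gz)?$", path)) {
    read_variants_vcf(path)
  } else {
    read_variants_tsv(path)
  }
  if (!is.null(sample_map)) {
    mapped <- unname(sample_map[raw$sample_id])
    raw$sample_id <- ifelse(is.na(mapped), raw$sample_id, mapped)
  }
  validate_calls(normalize_calls(raw, genome), freq_tol)
}

read_variants_tsv <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("contig", "pos_1based", "ref", "alt", "sample", "coverage",
            "alt_reads", "frequency")
  if (!all(need %in% names(tb))) {
    abort(paste0("variant TSV missing column(s): ",
                 paste(setdiff(need, names(tb)), collapse = ", ")))
  }
  tibble(contig = as.character(tb$contig),
         pos = as.integer(tb$pos_1based) - 1L,
         ref = toupper(tb$ref), alt = toupper(tb$alt),
         sample_id = as.character(tb$sample),
         coverage = as.integer(tb$coverage),
         alt_reads = as.integer(tb$alt_reads),
         frequency = as.numeric(tb$frequency))
}

read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), sample_id = character(),
                  coverage = integer(), alt_reads = integer(),
                  frequency = double()))
  }
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(dp)
  rows <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    purrr::map_dfr(seq_along(samples), function(j) {
      if (is.na(dp[i, j]) || is.na(ad[i, j])) return(NULL)
      ads <- as.integer(strsplit(ad[i, j], ",", fixed = TRUE)[[1]])
      # AD convention: ref then one count per alt allele; multi-allelic rows
      # split into biallelic records
      purrr::map_dfr(seq_along(alts), function(k) {
        ar <- if (length(ads) >= k + 1) ads[k + 1] else NA_integer_
        if (is.na(ar) || ar == 0) return(NULL)
        tibble(contig = fix$CHROM[i], pos = as.integer(fix$POS[i]) - 1L,
               ref = toupper(fix$REF[i]), alt = toupper(alts[k]),
               sample_id = samples[j],
               coverage = as.integer(dp[i, j]), alt_reads = ar,
               frequency = ar / as.integer(dp[i, j]))
      })
    })
  })
  rows
}

# trim shared prefix/suffix to a minimal VCF-style representation and
# left-align indels; SNVs are untouched
normalize_calls <- function(calls, genome = NULL) {
  if (nrow(calls) == 0) {
    calls$variant_class <- character(0)
    return(split_sample_ids(calls))
  }
  norm <- pmap(list(calls$pos, calls$ref, calls$alt, calls$contig),
               function(pos, ref, alt, contig) {
    normalize_allele(pos, ref, alt,
                     if (!is.null(genome)) genome[[contig]] else NULL)
  })
  calls$pos <- map_int(norm, "pos")
  calls$ref <- map_chr(norm, "ref")
  calls$alt <- map_chr(norm, "alt")
  calls$variant_class <- map_chr(norm, "class")
  split_sample_ids(calls)
}

normalize_allele <- function(pos, ref, alt, contig_seq = NULL) {
  if (ref == alt) abort("ref and alt alleles identical")
  # trim common suffix
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  # trim common prefix, advancing pos
  while (nchar(ref) > 1 && nchar(alt) > 1 && substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    return(list(pos = as.integer(pos), ref = ref, alt = alt, class = "SNV"))
  }
  cls <- if (nchar(ref) > nchar(alt)) "deletion" else if (nchar(ref) < nchar(alt)) "insertion" else NA
  if (is.na(cls)) abort("multi-nucleotide substitutions are not supported")
  # left-align through repeats when the reference sequence is available: an
  # anchored indel (anchor a, inserted/deleted sequence D) shifts one base
  # left exactly when the last base of D equals a
  if (!is.null(contig_seq)) {
    repeat {
      longer <- if (cls == "deletion") ref else alt
      n <- nchar(longer)
      if (pos <= 0 || substr(longer, n, n) != substr(longer, 1, 1)) break
      prev <- substr(contig_seq, pos, pos)  # base at 0-based pos-1
      shifted <- paste0(prev, substr(longer, 1, n - 1))
      if (cls == "deletion") {
        ref <- shifted; alt <- prev
      } else {
        alt <- shifted; ref <- prev
      }
      pos <- pos - 1L
    }
  }
  list(pos = as.integer(pos), ref = ref, alt = alt, class = cls)
}

split_sample_ids <- function(calls) {
  # sample ids follow "<population>.<timepoint>"; bare ids get NA timepoint
  parts <- stringr::str_match(calls$sample_id, "^(.*)\\.([0-9]+)$")
  calls$population <- ifelse(is.na(parts[, 2]), calls$sample_id, parts[, 2])
  calls$timepoint <- suppressWarnings(as.integer(parts[, 3]))
  calls[, c("contig", "pos", "ref", "alt", "variant_class", "sample_id",
            "population", "timepoint", "coverage", "alt_reads", "frequency")]
}

validate_calls <- function(calls, freq_tol = 0.01) {
  if (nrow(calls) == 0) return(calls)
  if (any(calls$alt_reads > calls$coverage)) {
    bad <- which(calls$alt_reads > calls$coverage)[1]
    abort(paste0("alt_reads > coverage at ", calls$contig[bad], ":",
                 calls$pos[bad] + 1, " sample ", calls$sample_id[bad]))
  }
  implied <- ifelse(calls$coverage > 0, calls$alt_reads / calls$coverage, NA)
  off <- !is.na(implied) & abs(calls$frequency - implied) > freq_tol
  if (any(off)) {
    bad <- which(off)[1]
    abort(paste0("frequency inconsistent with alt_reads/coverage at ",
                 calls$contig[bad], ":", calls$pos[bad] + 1,
                 " sample ", calls$sample_id[bad]))
  }
  snv <- calls$variant_class == "SNV"
  stopifnot(all(nchar(calls$ref[snv]) == 1 & nchar(calls$alt[snv]) == 1))
  calls
}

#' Write variant calls to a plain-text VCF
#'
#' @param calls Call tibble as returned by [read_variants()].
#' @param path Output path (`.vcf`).
#' @param contig_lengths Optional named integer vector for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(calls, path, contig_lengths = NULL) {
  samples <- sort(unique(calls$sample_id))
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, paste0("##contig=<ID=", names(contig_lengths),
                         ",length=", contig_lengths, ">"))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", samples), collapse = "\t"))
  sites <- calls |>
    distinct(.data$contig, .data$pos, .data$ref, .data$alt) |>
    arrange(.data$contig, .data$pos)
  body <- map_chr(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    here <- calls[calls$contig == s$contig & calls$pos == s$pos &
                  calls$ref == s$ref & calls$alt == s$alt, ]
    cells <- map_chr(samples, function(sm) {
      r <- here[here$sample_id == sm, ]
      if (nrow(r) == 0) return(".:.")
      paste0(r$coverage[1], ":", r$coverage[1] - r$alt_reads[1], ",",
             r$alt_reads[1])
    })
    paste(c(s$contig, s$pos + 1, ".", s$ref, s$alt, ".", "PASS", ".",
            "DP:AD", cells), collapse = "\t")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write variant calls to the TSV dialect
#'
#' @param calls Call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(calls, path) {
  out <- tibble(contig = calls$contig, pos_1based = calls$pos + 1L,
                ref = calls$ref, alt = calls$alt, sample = calls$sample_id,
                coverage = calls$coverage, alt_reads = calls$alt_reads,
                frequency = calls$frequency)
  readr::write_tsv(out, path)
  invisible(path)
}
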