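#' Read gene models from GFF3
#'
#' Parses CDS features, groups them by their `Parent` (falling back to `ID` or
#' `gene_id`), converts 1-based inclusive GFF coordinates to the package's
#' internal 0-based half-open convention, and evaluates completeness of every
#' gene against the genome: a gene is complete when its spliced CDS has length
#' divisible by 3, begins with ATG, ends with a stop codon, and contains no
#' internal in-frame stop.
#'
#' @param path Path to a GFF3 file containing CDS features.
#' @param genome A `podevol_genome`.
#' @return A tibble of gene models, one row per gene: `gene_id`, `contig`,
#'   `strand`, `complete`, and a `cds` list-column of two-column matrices of
#'   0-based half-open `(start, end)` segments sorted in transcription order.
#' @export
read_gene_models <- function(path, genome) {
  gff <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) return(empty_gene_models())
  attr_field <- function(attrs, key) {
    m <- regexpr(paste0("(^|;)", key, "=[^;]+"), attrs)
    out <- rep(NA_character_, length(attrs))
    out[m != -1] <- sub(paste0("^;?", key, "="), "", regmatches(attrs, m))
    out
  }
  gene_id <- attr_field(cds$attributes, "Parent")
  gene_id <- ifelse(is.na(gene_id), attr_field(cds$attributes, "gene_id"), gene_id)
  gene_id <- ifelse(is.na(gene_id), attr_field(cds$attributes, "ID"), gene_id)
  if (anyNA(gene_id)) abort("CDS feature without Parent/gene_id/ID attribute")
  seg <- tibble(
    gene_id = gene_id,
    contig  = as.character(cds$seqid),
    strand  = as.character(cds$strand),
    start   = cds$start - 1L,  # GFF 1-based inclusive -> 0-based half-open
    end     = as.integer(cds$end)
  )
  gene_models(seg, genome)
}

empty_gene_models <- function() {
  tibble(gene_id = character(), contig = character(), strand = character(),
         complete = logical(), cds = list())
}

#' Build gene models from a CDS segment table
#'
#' @param segments Tibble with columns `gene_id`, `contig`, `strand`, `start`,
#'   `end` (0-based half-open), one row per CDS segment.
#' @param genome A `podevol_genome` used to evaluate completeness and bounds.
#' @return Gene-model tibble as described in [read_gene_models()].
#' @export
gene_models <- function(segments, genome) {
  if (nrow(segments) == 0) return(empty_gene_models())
  if (!all(segments$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  bad <- !(segments$contig %in% names(genome))
  if (any(bad)) abort(paste0("CDS on unknown contig: ", segments$contig[bad][1]))
  lens <- nchar(genome)[segments$contig]
  if (any(segments$start < 0 | segments$end > lens)) {
    abort("CDS segment beyond contig bounds")
  }
  segments |>
    group_by(.data$gene_id) |>
    dplyr::group_map(function(g, key) {
      if (length(unique(g$strand)) != 1 || length(unique(g$contig)) != 1) {
        abort(paste0("strand/contig-inconsistent CDS segments in gene ",
                     key$gene_id))
      }
      g <- g[order(g$start), ]
      if (any(g$start[-1] < g$end[-nrow(g)])) {
        abort(paste0("overlapping CDS segments in gene ", key$gene_id))
      }
      strand <- g$strand[1]
      m <- cbind(start = g$start, end = g$end)
      if (strand == "-") m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
      tibble(gene_id = key$gene_id, contig = g$contig[1], strand = strand,
             cds = list(m))
    }) |>
    bind_rows() |>
    mutate(complete = map_lgl(seq_len(dplyr::n()), function(i) {
      is_complete_cds(spliced_cds(genome, .data$contig[i], .data$strand[i],
                                  .data$cds[[i]]))
    })) |>
    select("gene_id", "contig", "strand", "complete", "cds") |>
    arrange(.data$contig, map_int(.data$cds, ~ as.integer(min(.x[, "start"]))))
}

# spliced CDS sequence in transcription order (reverse-complemented on '-')
spliced_cds <- function(genome, contig, strand, cds) {
  seq <- genome[[contig]]
  fwd <- cds[order(cds[, "start"]), , drop = FALSE]
  parts <- substring(seq, fwd[, "start"] + 1, fwd[, "end"])
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}

is_complete_cds <- function(s) {
  n <- nchar(s)
  if (n < 6 || n %% 3 != 0) return(FALSE)
  if (substr(s, 1, 3) != "ATG") return(FALSE)
  prot <- translate_dna(s)
  np <- nchar(prot)
  substr(prot, np, np) == "*" && !grepl("*", substr(prot, 1, np - 1), fixed = TRUE)
}

#' Write gene models to GFF3
#'
#' Emits one `gene` feature spanning each model plus its `CDS` features, with
#' coordinates converted back to the 1-based inclusive GFF convention.
#'
#' @param models Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    cds <- m$cds[[1]]
    cds <- cds[order(cds[, "start"]), , drop = FALSE]
    span <- c(min(cds[, "start"]) + 1, max(cds[, "end"]))
    lines <- c(lines,
      paste(m$contig, "podevol", "gene", span[1], span[2], ".", m$strand, ".",
            paste0("ID=", m$gene_id), sep = "\t"),
      paste(m$contig, "podevol", "CDS", cds[, "start"] + 1, cds[, "end"], ".",
            m$strand, "0", paste0("ID=", m$gene_id, ".cds;Parent=", m$gene_id),
            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read mask intervals from BED
#'
#' @param path Path to a 3+-column BED file (0-based half-open, as standard).
#' @return Tibble with `contig`, `start`, `end`.
#' @export
read_mask <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (nrow(bed) == 0) return(tibble(contig = character(), start = integer(), end = integer()))
  out <- tibble(contig = as.character(bed[[1]]),
                start = as.integer(bed[[2]]), end = as.integer(bed[[3]]))
  if (any(out$end <= out$start)) abort("BED interval with end <= start")
  out
}

#' Write mask intervals to BED
#'
#' @param mask Tibble with `contig`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  readr::write_tsv(mask[, c("contig", "start", "end")], path, col_names = FALSE)
  invisible(path)
}
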