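# --- tiny hand-built fixtures -------------------------------------------------

# one-contig genome with a single complete plus-strand gene: ATG AAA TAA at 3..12
tiny_genome <- function() genome(c(c1 = "AAATGAAATAAAA"))

tiny_models <- function(g = tiny_genome()) {
  gene_models(tibble::tibble(gene_id = "g1", contig = "c1", strand = "+",
                             start = 2L, end = 11L), g)
}

# minus-strand twin: reverse complement of the tiny genome, gene coordinates
# mirrored, so the homologous site must classify identically
tiny_genome_minus <- function() {
  genome(c(c1 = paste(rev(strsplit(chartr("ACGT", "TGCA", "AAATGAAATAAAA"),
                                   NULL)[[1]]), collapse = "")))
}

tiny_models_minus <- function(g = tiny_genome_minus()) {
  L <- nchar(g[["c1"]])
  gene_models(tibble::tibble(gene_id = "g1", contig = "c1", strand = "-",
                             start = L - 11L, end = L - 2L), g)
}

make_call <- function(contig = "c1", pos = 5L, ref = "A", alt = "G",
                      variant_class = "SNV", sample_id = "A1.268",
                      coverage = 30L, alt_reads = 28L,
                      frequency = alt_reads / coverage) {
  tibble::tibble(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
                 variant_class = variant_class, sample_id = sample_id,
                 population = sub("\\..*$", "", sample_id),
                 timepoint = as.integer(sub("^.*\\.", "", sample_id)),
                 coverage = as.integer(coverage),
                 alt_reads = as.integer(alt_reads), frequency = frequency)
}

# --- Table-1-shaped fixation fixture -------------------------------------------
# Encodes the published per-lineage tallies: A = 62 ts + 23 tv SNVs
# (31 missense, 6 synonymous, 8 nonsense, 26 intergenic, 9 unaligned,
# 3 intronic, 2 incomplete) + 13 indels (9 frameshift, 4 in-frame);
# B = 21 ts + 19 tv (21/7/3/5/4/0/0) + 10 indels (4 frameshift, 6 in-frame).
table1_records <- function() {
  snv_block <- function(lineage, n_ts, n_tv, effects) {
    stopifnot(length(effects) == n_ts + n_tv)
    tibble::tibble(
      lineage = lineage, variant_class = "SNV",
      ref = c(rep("A", n_ts), rep("A", n_tv)),
      alt = c(rep("G", n_ts), rep("C", n_tv)),
      effect = effects)
  }
  effs <- function(n_mis, n_syn, n_non, n_int, n_unal, n_intron, n_inc) {
    c(rep("missense", n_mis), rep("synonymous", n_syn), rep("nonsense", n_non),
      rep("intergenic", n_int), rep("unaligned", n_unal),
      rep("intronic", n_intron), rep("incomplete_gene", n_inc))
  }
  indel_block <- function(lineage, n_fs, n_if) {
    tibble::tibble(lineage = lineage, variant_class = "deletion",
                   ref = "AT", alt = "A",
                   effect = c(rep("frameshift", n_fs),
                              rep("inframe_indel", n_if)))
  }
  dplyr::bind_rows(
    snv_block("A", 62, 23, effs(31, 6, 8, 26, 9, 3, 2)),
    indel_block("A", 9, 4),
    snv_block("B", 21, 19, effs(21, 7, 3, 5, 4, 0, 0)),
    indel_block("B", 4, 6))
}

# --- independent oracles --------------------------------------------------------

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), NULL)[[1]]), collapse = "")
}

oracle_translate <- function(s) {
  n <- nchar(s) %/% 3
  paste(Biostrings::GENETIC_CODE[substring(s, 3 * seq_len(n) - 2,
                                           3 * seq_len(n))], collapse = "")
}

# rebuild the whole mutant contig, re-extract and translate every gene's CDS,
# and classify the SNV from the protein diff (independent of the codon path)
oracle_classify_snv <- function(genome, models, contig, pos, alt) {
  seqs <- unclass(genome)
  mut <- seqs
  substr(mut[[contig]], pos + 1, pos + 1) <- alt
  cls <- "intergenic"
  best <- 0
  severity <- c(intergenic = 1, intronic = 2, incomplete_gene = 2.5,
                synonymous = 3, missense = 5, nonsense = 7)
  for (i in which(models$contig == contig)) {
    m <- models[i, ]
    cds <- m$cds[[1]]
    span <- c(min(cds[, "start"]), max(cds[, "end"]))
    if (pos < span[1] || pos >= span[2]) next
    in_cds <- any(pos >= cds[, "start"] & pos < cds[, "end"])
    this <- if (!in_cds) {
      "intronic"
    } else if (!m$complete) {
      "incomplete_gene"
    } else {
      extract <- function(sq) {
        fwd <- cds[order(cds[, "start"]), , drop = FALSE]
        s <- paste(substring(sq, fwd[, "start"] + 1, fwd[, "end"]),
                   collapse = "")
        if (m$strand == "-") oracle_revcomp(s) else s
      }
      p_ref <- oracle_translate(extract(seqs[[contig]]))
      p_mut <- oracle_translate(extract(mut[[contig]]))
      if (p_ref == p_mut) {
        "synonymous"
      } else {
        d <- which(strsplit(p_ref, NULL)[[1]] != strsplit(p_mut, NULL)[[1]])[1]
        if (substr(p_mut, d, d) == "*") "nonsense" else "missense"
      }
    }
    if (severity[this] > best) {
      best <- severity[this]
      cls <- this
    }
  }
  cls
}

# random genome with a handful of complete genes, for oracle-equivalence tests
random_annotated_genome <- function(seed, length = 2000, n_genes = 3) {
  set.seed(seed)
  cfg <- experiment_config(seed = seed, n_contigs = 1, contig_length = length,
                           gene_density = 0.6, mean_cds_length = 300,
                           intron_fraction = 0.3, intron_length = 30,
                           n_masks = 0)
  generate_genome_annotation(cfg)
}
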