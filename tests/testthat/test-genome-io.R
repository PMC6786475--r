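test_that("FASTA reading parses, uppercases, and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1 description", "acgt", ">c2", "NNAA"), fa)
  g <- read_genome(fa)
  expect_equal(unname(nchar(g)), c(4L, 4L))
  expect_named(g, c("c1", "c2"))
  expect_equal(g[["c1"]], "ACGT")

  writeLines(c(">c1", "ACXT"), fa)
  expect_error(read_genome(fa), "c1")
  writeLines(c(">c1", "AC", ">c1", "GG"), fa)
  expect_error(read_genome(fa), "duplicate")
  writeLines(character(0), fa)
  expect_error(read_genome(fa))
})

test_that("genome write/read round-trips up to line wrapping", {
  g <- genome(c(a = paste(rep("ACGTN", 40), collapse = ""), b = "GGGCCC"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_genome(g, fa, width = 17)
  expect_equal(unclass(read_genome(fa)), unclass(g))
})

test_that("GFF3 gene models convert coordinates and evaluate completeness", {
  g <- tiny_genome()
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tx\tgene\t3\t11\t.\t+\t.\tID=g1",
               "c1\tx\tCDS\t3\t11\t.\t+\t0\tID=g1.c;Parent=g1"), gff)
  m <- read_gene_models(gff, g)
  expect_equal(m$gene_id, "g1")
  expect_equal(m$cds[[1]][, "start"], 2L, ignore_attr = TRUE)
  expect_equal(m$cds[[1]][, "end"], 11L, ignore_attr = TRUE)
  expect_true(m$complete)   # ATG AAA TAA

  # same span but the terminal stop broken -> incomplete
  g2 <- genome(c(c1 = "AAATGAAATACAA"))
  expect_false(read_gene_models(gff, g2)$complete)

  # CDS beyond contig bounds
  writeLines(c("c1\tx\tCDS\t3\t99\t.\t+\t0\tParent=g1"), gff)
  expect_error(read_gene_models(gff, g), "bounds")
})

test_that("minus-strand completeness matches a reverse-complement oracle", {
  g <- tiny_genome_minus()
  m <- tiny_models_minus(g)
  cds <- m$cds[[1]]
  fwd <- cds[order(cds[, "start"]), , drop = FALSE]
  s <- oracle_revcomp(substring(g[["c1"]], fwd[1, "start"] + 1, fwd[1, "end"]))
  expect_equal(substr(s, 1, 3), "ATG")
  expect_equal(oracle_translate(s), "MK*")
  expect_true(m$complete)
})

test_that("gene model GFF round-trip is the identity on coordinates", {
  ga <- random_annotated_genome(seed = 21)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(ga$models, gff)
  back <- read_gene_models(gff, ga$genome)
  back <- back[match(ga$models$gene_id, back$gene_id), ]
  expect_equal(back$strand, ga$models$strand)
  expect_equal(back$complete, ga$models$complete)
  for (i in seq_len(nrow(back))) {
    expect_equal(back$cds[[i]], ga$models$cds[[i]], ignore_attr = TRUE)
  }
})

test_that("complete genes translate to a single terminal stop", {
  ga <- random_annotated_genome(seed = 8, length = 5000, n_genes = 6)
  for (i in which(ga$models$complete)) {
    m <- ga$models[i, ]
    s <- podevol:::spliced_cds(ga$genome, m$contig, m$strand, m$cds[[1]])
    prot <- oracle_translate(s)
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_equal(lengths(regmatches(prot, gregexpr("\\*", prot))), 1L)
  }
})

test_that("trinucleotide context reads the forward strand and flags undefined windows", {
  g <- genome(c(c1 = "ACGTA", c2 = "ANGTC"))
  expect_equal(trinucleotide_context(g, "c1", 2L), "CGT")
  expect_equal(trinucleotide_context(g, "c1", 1L), "ACG")
  expect_true(is.na(trinucleotide_context(g, "c1", 0L)))        # edge
  expect_true(is.na(trinucleotide_context(g, "c1", 4L)))        # edge
  expect_true(is.na(trinucleotide_context(g, "c2", 1L)))        # N in window
  expect_equal(trinucleotide_context(g, "c2", 3L), "GTC")
})

test_that("variant TSV reading shifts coordinates and validates evidence", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tpos_1based\tref\talt\tsample\tcoverage\talt_reads\tfrequency",
               "c1\t7\tA\tG\tA1.75\t15\t14\t0.933"), tsv)
  v <- read_variants(tsv)
  expect_equal(v$pos, 6L)
  expect_equal(v$variant_class, "SNV")
  expect_equal(v$population, "A1")
  expect_equal(v$timepoint, 75L)

  writeLines(c("contig\tpos_1based\tref\talt\tsample\tcoverage\talt_reads\tfrequency",
               "c1\t7\tA\tG\tA1.75\t15\t16\t1.0"), tsv)
  expect_error(read_variants(tsv), "alt_reads > coverage")
  writeLines(c("contig\tpos_1based\tref\talt\tsample\tcoverage\talt_reads\tfrequency",
               "c1\t7\tA\tG\tA1.75\t15\t14\t0.5"), tsv)
  expect_error(read_variants(tsv), "frequency inconsistent")
})

test_that("indel normalisation trims and left-aligns to a representation-invariant form", {
  # 'ATT' -> 'A' is a minimal anchored deletion already
  n1 <- podevol:::normalize_allele(10L, "ATT", "A", NULL)
  expect_equal(n1, list(pos = 10L, ref = "ATT", alt = "A", class = "deletion"))
  # shared suffix is trimmed: 'ATTG' -> 'AG' is the same deletion
  n2 <- podevol:::normalize_allele(10L, "ATTG", "AG", NULL)
  expect_equal(n2[c("pos", "ref", "alt")], n1[c("pos", "ref", "alt")])
  # a homopolymer deletion shifts to the leftmost representation
  seq <- "TTAAAAG"
  shifted <- lapply(1:4, function(p) {   # anchors whose deleted base is an A
    podevol:::normalize_allele(as.integer(p), substr(seq, p + 1, p + 2),
                               substr(seq, p + 1, p + 1), seq)
  })
  expect_true(all(vapply(shifted, function(x) x$pos, integer(1)) == 1L))
  expect_true(all(vapply(shifted, function(x) x$ref, character(1)) == "TA"))
  # SNVs pass through untouched
  expect_equal(podevol:::normalize_allele(3L, "C", "T", seq)$class, "SNV")
})

test_that("VCF round-trip preserves calls and their evidence", {
  calls <- dplyr::bind_rows(
    make_call(pos = 5L, sample_id = "A1.75"),
    make_call(pos = 5L, sample_id = "B1.75", coverage = 20L, alt_reads = 18L),
    make_call(pos = 8L, ref = "AT", alt = "A", variant_class = "deletion",
              sample_id = "A1.130"))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(calls, vcf, contig_lengths = c(c1 = 100L))
  back <- read_variants(vcf)
  key <- function(x) paste(x$contig, x$pos, x$ref, x$alt, x$sample_id)
  expect_setequal(key(back), key(calls))
  merged <- dplyr::inner_join(back, calls, by = c("contig", "pos", "sample_id"))
  expect_equal(merged$coverage.x, merged$coverage.y)
  expect_equal(merged$alt_reads.x, merged$alt_reads.y)
})
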