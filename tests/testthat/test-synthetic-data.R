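small_cfg <- function(seed = 1, ...) {
  experiment_config(seed = seed, contig_length = 15000, ...)
}

test_that("generation is byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  e1 <- generate_experiment(small_cfg(seed = 5))
  e2 <- generate_experiment(small_cfg(seed = 5))
  write_experiment(e1, d1); write_experiment(e2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("config validation rejects impossible settings", {
  expect_error(experiment_config(fixation_rate = 0.1, snv_fraction = 1.5),
               "rates")
  expect_error(experiment_config(timepoints = c(75, 75)), "increasing")
  expect_error(experiment_config(gene_density = 0.95), "packable")
})

test_that("zero gene density yields a genome without gene models", {
  ga <- generate_genome_annotation(small_cfg(seed = 2, gene_density = 0,
                                             n_masks = 0))
  expect_equal(nrow(ga$models), 0L)
  expect_gt(sum(nchar(ga$genome)), 0)
})

test_that("zero rates yield an empty experiment", {
  e <- generate_experiment(small_cfg(
    seed = 3, fixation_rate = 0, parallel_targets = NULL,
    artifact_low_coverage = 0, artifact_founder = 0, artifact_adjacent = 0,
    artifact_masked_indel = 0, artifact_multipop = 0))
  expect_equal(nrow(e$calls), 0L)
  expect_equal(nrow(e$truth), 0L)
})

test_that("generated genes are complete and masks sit inside contigs", {
  ga <- generate_genome_annotation(small_cfg(seed = 7))
  expect_true(all(ga$models$complete))
  lens <- nchar(ga$genome)[ga$mask$contig]
  expect_true(all(ga$mask$start > 0 & ga$mask$end < lens))
})

test_that("planted fixations appear monotonically and with fixation-grade evidence", {
  e <- generate_experiment(small_cfg(seed = 9))
  tps <- sort(e$config$timepoints)
  per_mut <- split(e$calls, paste(e$calls$population, e$calls$contig,
                                  e$calls$pos, e$calls$alt))
  for (mt in per_mut) {
    seen <- sort(unique(mt$timepoint))
    expect_equal(seen, tps[tps >= min(seen)])  # presence is monotone
  }
  fixed <- e$calls[!paste(e$calls$population, e$calls$contig, e$calls$pos,
                          e$calls$ref, e$calls$alt, sep = "|") %in%
                     e$truth$mutation_id[e$truth$evidence == "low_coverage"], ]
  expect_true(all(fixed$frequency >= 0.95))
  expect_true(all(fixed$coverage >= e$config$fixed_depth))
})

test_that("six planted frameshifts in one gene give a parallelism count of six", {
  cfg <- small_cfg(seed = 4, fixation_rate = 0,
                   parallel_targets = list(rep("frameshift", 6)),
                   artifact_low_coverage = 0, artifact_founder = 0,
                   artifact_adjacent = 0, artifact_masked_indel = 0,
                   artifact_multipop = 0)
  e <- generate_experiment(cfg)
  expect_equal(nrow(e$truth), 6L)
  expect_equal(length(unique(e$truth$population)), 6L)
  rep <- filter_variants(e$calls, e$founder, e$mask)
  muts <- dplyr::distinct(rep$kept, contig, pos, ref, alt, population,
                          .keep_all = TRUE)
  ann <- classify_variants(muts, e$models, e$genome)
  expect_true(all(ann$effect == "frameshift"))
  expect_equal(length(unique(ann$gene_id)), 1L)
  expect_equal(parallel_gene_count(ann, min_hits = 6,
                                   classes = "frameshift"), 1L)
})

test_that("fixation counts track rate x passages within sampling error", {
  rate <- 0.05
  tot <- numeric(6)
  for (i in seq_along(tot)) {
    e <- generate_experiment(small_cfg(
      seed = 100 + i, fixation_rate = rate, parallel_targets = NULL,
      artifact_low_coverage = 0, artifact_founder = 0, artifact_adjacent = 0,
      artifact_masked_indel = 0, artifact_multipop = 0))
    tot[i] <- sum(!e$truth$is_artifact)
  }
  n_pops <- 8
  expected <- rate * 268 * n_pops
  # pooled Poisson: 6 experiments x expected each
  se <- sqrt(length(tot) * expected)
  expect_lt(abs(sum(tot) - length(tot) * expected), 4 * se)
})

test_that("synthetic ortholog alignments hit the configured background rates", {
  e <- generate_experiment(experiment_config(seed = 6, contig_length = 60000))
  pairs <- generate_ortholog_pairs(e)
  expect_gt(nrow(pairs), 20)
  # conserved fraction of reliable pairs clusters near the configured rate
  cf <- pairs$conserved_fraction[pairs$reliable]
  expect_lt(abs(mean(cf) - e$config$conserved_rate * (1 - 0.085)), 0.08)
  expect_true(any(pairs$reliable) && any(!pairs$reliable))
  # ungapped protein equals the gene translation
  i <- which(pairs$reliable)[1]
  gid <- pairs$focal_id[i]
  m <- e$models[e$models$gene_id == gid, ]
  prot <- sub("\\*$", "", podevol:::translate_dna(
    podevol:::spliced_cds(e$genome, m$contig, m$strand, m$cds[[1]])))
  expect_equal(gsub("-", "", pairs$aln_focal[i]), prot)
})

test_that("unverifiable and time-unknown cases flow through reconciliation", {
  e <- generate_experiment(small_cfg(seed = 15, unverifiable_rate = 0.2,
                                     validation_na_rate = 0.3))
  rep <- filter_variants(e$calls, e$founder, e$mask)
  presence <- rep$kept |>
    dplyr::mutate(mutation_id = paste(population, contig, pos, ref, alt,
                                      sep = "|")) |>
    dplyr::distinct(mutation_id, population, timepoint) |>
    dplyr::mutate(present = TRUE)
  rec <- reconcile_timepoints(presence, e$validation)
  expect_true(all(rec$validation_status %in%
                    c("verified", "unverifiable", "time_unknown")))
  expect_true(all(c("verified", "unverifiable") %in% rec$validation_status))
  marked <- e$truth$mutation_id[e$truth$unverifiable]
  expect_true(all(rec$validation_status[rec$mutation_id %in% marked] ==
                    "unverifiable"))
  # time-unknown mutations stay in totals but carry no ordering information
  tu <- rec[rec$validation_status == "time_unknown", ]
  expect_true(all(is.na(tu$first_seen_timepoint)))
})
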