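cfg <- filter_config()

test_that("quality filter is boundary-inclusive on coverage and frequency", {
  calls <- dplyr::bind_rows(
    make_call(pos = 1L, coverage = 10L, alt_reads = 8L),   # 10x, 0.80 -> kept
    make_call(pos = 2L, coverage = 9L, alt_reads = 9L),    # 9x -> removed
    make_call(pos = 3L, coverage = 100L, alt_reads = 79L)) # 0.79 -> removed
  kept <- apply_quality_filter(calls, cfg)
  expect_equal(kept$pos, 1L)
})

test_that("founder filter removes ancestral variants but leaves uncovered sites alone", {
  calls <- dplyr::bind_rows(make_call(pos = 1L), make_call(pos = 2L),
                            make_call(pos = 3L))
  founder <- tibble::tibble(
    contig = "c1", pos = c(1L, 2L, 3L), ref = "A", alt = "G",
    coverage = c(30L, 30L, 0L), alt_reads = c(2L, 1L, 0L))
  kept <- apply_founder_filter(calls, founder, cfg)
  expect_setequal(kept$pos, c(2L, 3L))  # 2 founder reads -> out; 1 read / uncovered -> kept
})

test_that("multi-population filter needs sharing AND a founder-uncovered site", {
  shared <- dplyr::bind_rows(
    make_call(pos = 1L, sample_id = "A1.268", alt_reads = 25L),
    make_call(pos = 1L, sample_id = "A2.268", alt_reads = 24L))
  single <- make_call(pos = 2L, sample_id = "A1.268")
  calls <- dplyr::bind_rows(shared, single)
  founder0 <- tibble::tibble(contig = "c1", pos = 1L, ref = "A", alt = "G",
                             coverage = 0L, alt_reads = 0L)
  kept <- apply_multipopulation_filter(calls, founder0, cfg)
  expect_equal(kept$pos, 2L)  # both shared calls removed
  # founder covers the site (0 alt reads): retained even though shared
  founder30 <- dplyr::mutate(founder0, coverage = 30L)
  expect_equal(nrow(apply_multipopulation_filter(calls, founder30, cfg)), 3L)
})

test_that("mask filter removes indels within the 10 bp flank, inclusive, and never SNVs", {
  masks <- tibble::tibble(contig = "c1", start = 100L, end = 120L)
  calls <- dplyr::bind_rows(
    make_call(pos = 129L, ref = "AT", alt = "A", variant_class = "deletion"),
    make_call(pos = 130L, ref = "AT", alt = "A", variant_class = "deletion"),
    make_call(pos = 110L))  # SNV inside the mask
  kept <- apply_mask_filter(calls, masks, cfg)
  # last masked base is 119; flank reaches 129 inclusive
  expect_setequal(kept$pos, c(130L, 110L))
  expect_true(all(kept$variant_class[kept$pos == 110L] == "SNV"))
})

test_that("adjacency filter drops same-population SNV pairs only", {
  calls <- dplyr::bind_rows(
    make_call(pos = 100L, sample_id = "A1.268"),
    make_call(pos = 101L, sample_id = "A1.268"),
    make_call(pos = 200L, sample_id = "A1.268"),
    make_call(pos = 202L, sample_id = "A1.268"),
    make_call(pos = 300L, sample_id = "A1.268"),
    make_call(pos = 301L, sample_id = "A2.268"))
  kept <- apply_adjacency_filter(calls, cfg)
  expect_setequal(paste(kept$population, kept$pos),
                  c("A1 200", "A1 202", "A1 300", "A2 301"))
})

test_that("rules are subset-monotone, order-stable, and the cascade is idempotent", {
  e <- generate_experiment(experiment_config(seed = 13, contig_length = 15000))
  calls <- e$calls
  stages <- list(
    function(x) apply_quality_filter(x, cfg),
    function(x) apply_founder_filter(x, e$founder, cfg),
    function(x) apply_multipopulation_filter(x, e$founder, cfg),
    function(x) apply_mask_filter(x, e$mask, cfg),
    function(x) apply_adjacency_filter(x, cfg))
  key <- function(x) sort(paste(x$sample_id, x$contig, x$pos, x$ref, x$alt))
  # subset property per rule
  for (f in stages) expect_true(all(key(f(calls)) %in% key(calls)))
  # surviving set identical under a permuted rule order
  apply_order <- function(ord) {
    out <- calls
    for (f in stages[ord]) out <- f(out)
    key(out)
  }
  base <- apply_order(1:5)
  expect_identical(apply_order(c(5, 3, 1, 4, 2)), base)
  expect_identical(apply_order(c(2, 4, 5, 1, 3)), base)
  # idempotence of the composite
  rep1 <- filter_variants(calls, e$founder, e$mask, cfg)
  rep2 <- filter_variants(rep1$kept, e$founder, e$mask, cfg)
  expect_identical(key(rep2$kept), key(rep1$kept))
  expect_equal(nrow(rep2$removed), 0L)
  # audit bookkeeping: removals + survivors = input
  expect_equal(nrow(rep1$kept) + nrow(rep1$removed), nrow(calls))
})

test_that("each planted artifact class is removed by exactly its designated rule", {
  e <- generate_experiment(experiment_config(seed = 17, contig_length = 15000))
  rep <- filter_variants(e$calls, e$founder, e$mask)
  removed_key <- paste(rep$removed$population, rep$removed$contig,
                       rep$removed$pos, rep$removed$ref, rep$removed$alt,
                       sep = "|")
  audit <- tibble::tibble(mutation_id = removed_key, rule = rep$removed$rule) |>
    dplyr::distinct()
  art <- e$truth[e$truth$is_artifact, c("mutation_id", "artifact_rule")] |>
    dplyr::distinct()
  expect_gt(nrow(art), 0)
  joined <- dplyr::left_join(art, audit, by = "mutation_id")
  expect_true(all(!is.na(joined$rule)))
  expect_equal(joined$rule, joined$artifact_rule)
  # and no true fixation was touched
  kept_key <- paste(rep$kept$population, rep$kept$contig, rep$kept$pos,
                    rep$kept$ref, rep$kept$alt, sep = "|")
  true_ids <- e$truth$mutation_id[!e$truth$is_artifact]
  expect_true(all(true_ids %in% kept_key))
})

test_that("timepoint reconciliation verifies, imputes monotone presence, and flags the rest", {
  tps <- c(75, 130, 200, 268)
  presence <- tibble::tibble(
    mutation_id = c("m1", "m1", "m2", "m3", "m3"),
    population = "A1",
    timepoint = c(130, 268, 268, 75, 268),
    present = TRUE)
  validation <- dplyr::bind_rows(
    tibble::tibble(mutation_id = "m1", timepoint = tps,
                   confirmed = c(FALSE, TRUE, NA, TRUE)),
    tibble::tibble(mutation_id = "m2", timepoint = tps, confirmed = NA),
    tibble::tibble(mutation_id = "m3", timepoint = tps,
                   confirmed = c(NA, NA, NA, TRUE)),
    tibble::tibble(mutation_id = "m4", timepoint = tps,
                   confirmed = c(NA, TRUE, TRUE, TRUE)))
  presence <- dplyr::bind_rows(presence,
                               tibble::tibble(mutation_id = "m4",
                                              population = "A2",
                                              timepoint = 268, present = TRUE))
  # m3's sequencing presence is non-monotone (75 yes, 130/200 no, 268 yes)
  expect_warning(rec <- reconcile_timepoints(presence, validation),
                 "non-monotone")
  rec <- rec[match(c("m1", "m2", "m3", "m4"), rec$mutation_id), ]
  # m1: confirmed at 130 -> verified, present 130..268
  expect_equal(rec$validation_status[1], "verified")
  expect_equal(rec$first_seen_timepoint[1], 130)
  expect_equal(rec$present_at[[1]], c(130, 200, 268))
  # m2: confirmed nowhere -> unverifiable
  expect_equal(rec$validation_status[2], "unverifiable")
  # m3: sequencing sees it at 75 -> ordered, verified despite NA assays
  expect_equal(rec$validation_status[3], "verified")
  expect_equal(rec$first_seen_timepoint[3], 75)
  expect_true(rec$monotonicity_warning[3])
  # m4: first confirmation at 130, timepoint 75 uninformative -> time unknown
  expect_equal(rec$validation_status[4], "time_unknown")
  expect_true(is.na(rec$first_seen_timepoint[4]))
})

test_that("a mutation confirmed only at the final timepoint of a fully assayed series is verified", {
  tps <- c(75, 130, 200, 268)
  presence <- tibble::tibble(mutation_id = "m", population = "B1",
                             timepoint = 268, present = TRUE)
  validation <- tibble::tibble(mutation_id = "m", timepoint = tps,
                               confirmed = c(FALSE, FALSE, FALSE, TRUE))
  rec <- reconcile_timepoints(presence, validation)
  expect_equal(rec$validation_status, "verified")
  expect_equal(rec$first_seen_timepoint, 268)
  expect_equal(rec$present_at[[1]], 268)
})
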