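#' Pipeline run configuration
#'
#' One global seed deterministically derives a seed per stage, so any stage
#' can be re-run in isolation and reproduce the full run's output.
#'
#' @param experiment An [experiment_config()] for the synthetic generator
#'   stage.
#' @param filter A [filter_config()].
#' @param n_reps Permutation replicates.
#' @param seed Global seed.
#' @param variant_format `"tsv"` or `"vcf"` for the generated variant tables.
#' @param min_hits Parallelism statistic threshold.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(experiment = experiment_config(),
                            filter = filter_config(),
                            n_reps = 10000, seed = 1,
                            variant_format = c("tsv", "vcf"),
                            min_hits = 2) {
  structure(list(experiment = experiment, filter = filter, n_reps = n_reps,
                 seed = seed, variant_format = match.arg(variant_format),
                 min_hits = min_hits),
            class = "pipeline_config")
}

# stage seed = global seed + stable hash of the stage name, inside 32 bits
derive_seed <- function(seed, stage) {
  h <- sum(as.numeric(utf8ToInt(stage)) * seq_along(utf8ToInt(stage)) * 2654435)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Stages: generate inputs -> write and re-read them through the file formats
#' -> filter -> reconcile timepoints -> annotate effects -> permutation nulls
#' -> conservation tests -> evolutionary summary. All stage outputs plus a
#' manifest (input checksums, stage seeds, row counts) are written under
#' `dir`; re-running with the same config and seed reproduces every output.
#'
#' @param config A [pipeline_config()].
#' @param dir Run directory (created).
#' @return A list of class `pipeline_run` with all stage results and `dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), dir = tempfile("podevol_run_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  in_dir <- file.path(dir, "inputs")
  # --- generate ---------------------------------------------------------------
  exp_cfg <- config$experiment
  exp_cfg$seed <- derive_seed(config$seed, "generate")
  experiment <- generate_experiment(exp_cfg)
  paths <- write_experiment(experiment, in_dir, config$variant_format)
  # --- read back through the standard formats ---------------------------------
  genome <- read_genome(paths$genome)
  models <- read_gene_models(paths$models, genome)
  mask <- read_mask(paths$mask)
  calls <- read_variants(paths$calls, genome = genome)
  founder <- read_founder_evidence(paths$founder)
  validation <- readr::read_tsv(paths$validation, show_col_types = FALSE,
                                progress = FALSE)
  pairs <- read_ortholog_pairs(paths$orthologs)
  # --- filter -----------------------------------------------------------------
  filt <- filter_variants(calls, founder, mask, config$filter)
  readr::write_tsv(filt$kept, file.path(dir, "filtered_calls.tsv"))
  readr::write_tsv(bind_rows(filt$removed), file.path(dir, "filter_report.tsv"))
  # --- reconcile --------------------------------------------------------------
  presence <- filt$kept |>
    mutate(mutation_id = paste(.data$population, .data$contig, .data$pos,
                               .data$ref, .data$alt, sep = "|")) |>
    distinct(.data$mutation_id, .data$population, .data$timepoint) |>
    mutate(present = TRUE)
  recon <- reconcile_timepoints(presence, validation)
  # --- annotate ---------------------------------------------------------------
  muts <- filt$kept |>
    mutate(mutation_id = paste(.data$population, .data$contig, .data$pos,
                               .data$ref, .data$alt, sep = "|")) |>
    group_by(.data$mutation_id) |>
    dplyr::slice_min(.data$timepoint, n = 1, with_ties = FALSE) |>
    ungroup()
  records <- classify_variants(muts, models, genome) |>
    left_join(select(recon, "mutation_id", "validation_status",
                     "first_seen_timepoint"),
              by = "mutation_id") |>
    mutate(lineage = substr(.data$population, 1, 1)) |>
    filter(.data$validation_status != "unverifiable")
  readr::write_tsv(records, file.path(dir, "fixation_records.tsv"))
  # --- permutation ------------------------------------------------------------
  snvs <- records[records$variant_class == "SNV", ]
  by_lineage <- split(snvs, snvs$lineage)
  perms <- imap(by_lineage, function(s, lin) {
    null_effect_counts(genome, models, select(s, "contig", "pos", "alt",
                                              "context"),
                       n_reps = config$n_reps,
                       seed = derive_seed(config$seed, paste0("permute_", lin)))
  })
  parallel <- null_parallel_genes(
    genome, models, select(by_lineage[["A"]] %||% snvs[0, ],
                           "contig", "pos", "alt", "context"),
    genome, models, select(by_lineage[["B"]] %||% snvs[0, ],
                           "contig", "pos", "alt", "context"),
    n_reps = config$n_reps, min_hits = config$min_hits,
    seed = derive_seed(config$seed, "permute_parallel"))
  perm_summary <- bind_rows(c(
    purrr::flatten(map(perms, ~ map(.x, glance))),
    list(glance(parallel))))
  jsonlite::write_json(perm_summary, file.path(dir, "permutation.json"),
                       auto_unbox = TRUE, digits = NA)
  # --- conservation -----------------------------------------------------------
  conservation <- conservation_stage(records, pairs, models)
  jsonlite::write_json(conservation, file.path(dir, "conservation.json"),
                       auto_unbox = TRUE, digits = NA)
  # --- summary ----------------------------------------------------------------
  summary_res <- summary_stage(records, models, genome,
                               experiment$populations, config)
  readr::write_tsv(tidy(summary_res$fixation_summary),
                   file.path(dir, "table1.tsv"))
  jsonlite::write_json(summary_res$headline, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  # --- manifest ---------------------------------------------------------------
  manifest <- list(
    schema_version = "1.0",
    seed = config$seed,
    stage_seeds = list(generate = derive_seed(config$seed, "generate"),
                       permute_A = derive_seed(config$seed, "permute_A"),
                       permute_B = derive_seed(config$seed, "permute_B"),
                       permute_parallel = derive_seed(config$seed,
                                                      "permute_parallel")),
    input_md5 = as.list(tools::md5sum(unlist(paths))),
    rows = list(raw_calls = nrow(calls), kept_calls = nrow(filt$kept),
                removed_calls = nrow(filt$removed),
                fixation_records = nrow(records),
                ortholog_pairs = nrow(pairs)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(dir = dir, experiment = experiment, genome = genome,
                 models = models, mask = mask, filter = filt,
                 reconciled = recon, records = records, perms = perms,
                 parallel = parallel, conservation = conservation,
                 summary = summary_res, manifest = manifest),
            class = "pipeline_run")
}

conservation_stage <- function(records, pairs, models) {
  n_complete <- sum(models$complete)
  n_reliable <- sum(pairs$reliable)
  background <- n_reliable / n_complete
  gene_has_reliable <- function(gids) gids %in% pairs$focal_id[pairs$reliable]
  genes_non <- unique(records$gene_id[records$effect == "nonsense"])
  genes_mis <- unique(records$gene_id[records$effect == "missense"])
  genes_non <- genes_non[!is.na(genes_non)]
  genes_mis <- genes_mis[!is.na(genes_mis)]
  k_non <- sum(gene_has_reliable(genes_non))
  k_mis <- sum(gene_has_reliable(genes_mis))
  # site conservation over missense sites in reliable-ortholog proteins
  mis <- records[records$effect == "missense" & !is.na(records$gene_id) &
                   gene_has_reliable(records$gene_id), ]
  site_cons <- map_lgl(seq_len(nrow(mis)), function(i) {
    p <- pairs[pairs$focal_id == mis$gene_id[i] & pairs$reliable, ][1, ]
    # the terminal stop codon (stop-loss missense) has no alignment column
    if (mis$residue_index[i] > nchar(gsub("-", "", p$aln_focal))) {
      return(NA)
    }
    site_is_conserved(p$aln_focal, p$aln_ortholog, mis$residue_index[i])
  })
  site_cons <- site_cons[!is.na(site_cons)]
  bg_sites <- if (n_reliable > 0) {
    mean(map_dbl(which(pairs$reliable), function(i) {
      conserved_fraction(pairs$aln_focal[i], pairs$aln_ortholog[i])
    }), na.rm = TRUE)
  } else {
    NA_real_
  }
  list(
    background_reliable_fraction = background,
    n_complete_proteins = n_complete, n_reliable_orthologs = n_reliable,
    nonsense = list(k = k_non, n = length(genes_non),
                    p = if (length(genes_non) > 0 && background > 0 && background < 1)
                      ortholog_enrichment_test(k_non, length(genes_non), background)
                    else NA_real_),
    missense = list(k = k_mis, n = length(genes_mis),
                    p = if (length(genes_mis) > 0 && background > 0 && background < 1)
                      ortholog_enrichment_test(k_mis, length(genes_mis), background)
                    else NA_real_),
    sites = list(k = sum(site_cons), n = length(site_cons),
                 background = bg_sites,
                 p = if (length(site_cons) > 0 && !is.na(bg_sites) &&
                         bg_sites > 0 && bg_sites < 1)
                   site_conservation_test(sum(site_cons), length(site_cons),
                                          bg_sites)
                 else NA_real_))
}

summary_stage <- function(records, models, genome, populations, config) {
  fs <- summarize_fixations(records)
  dn <- dnds(records[records$variant_class == "SNV", ], models, genome)
  tps <- sort(config$experiment$timepoints)
  grid <- tidyr::expand_grid(population = populations$population,
                             timepoint = tps)
  timed <- records[!is.na(records$first_seen_timepoint), ]
  counts <- grid |>
    left_join(timed |>
                dplyr::count(.data$population,
                             timepoint = .data$first_seen_timepoint),
              by = c("population", "timepoint")) |>
    mutate(new_fixations = dplyr::coalesce(.data$n, 0L)) |>
    select("population", "timepoint", "new_fixations") |>
    left_join(populations, by = "population")
  fit <- accumulation_regression(counts, tps)
  ppf <- passages_per_fixation(nrow(populations), max(tps), nrow(records))
  mut <- mutator_test(counts)
  headline <- list(
    schema_version = "1.0",
    n_fixations = nrow(records),
    n_snv = sum(records$variant_class == "SNV"),
    shares = as.list(fs$shares),
    transition_share = setNames(as.list(fs$transition_share$pct),
                                fs$transition_share$lineage),
    dnds = glance(dn)$dnds, dnds_p = glance(dn)$p,
    accumulation_slope = fit$slope, accumulation_slope_p = fit$slope_p,
    passages_per_fixation = ppf$raw,
    passages_per_fixation_rounded = ppf$rounded,
    mutator_p_lineage = mut$p_lineage, mutator_p_population = mut$p_population)
  list(fixation_summary = fs, dnds = dn, accumulation = fit,
       passages_per_fixation = ppf, mutator = mut, counts = counts,
       headline = headline)
}

#' Render a human-readable report for a pipeline run
#'
#' Collects the fixation summary, permutation p-values, parallelism result,
#' conservation tests and headline statistics from a run directory into one
#' markdown document. Re-rendering is idempotent.
#'
#' @param dir A [run_pipeline()] output directory.
#' @param path Output file (default `report.md` inside `dir`).
#' @return `path`, invisibly.
#' @export
make_report <- function(dir, path = file.path(dir, "report.md")) {
  need <- file.path(dir, c("summary.json", "permutation.json",
                           "conservation.json", "table1.tsv"))
  if (!all(file.exists(need))) {
    abort(paste0("not a complete run directory: ", dir))
  }
  summ <- jsonlite::read_json(file.path(dir, "summary.json"))
  perm <- jsonlite::read_json(file.path(dir, "permutation.json"))
  cons <- jsonlite::read_json(file.path(dir, "conservation.json"))
  tab1 <- readr::read_tsv(file.path(dir, "table1.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  fmt <- function(x, d = 4) if (is.null(x) || is.na(x)) "NA" else signif(as.numeric(x), d)
  lines <- c(
    "# Serial-passage fixation analysis",
    "",
    "## Fixation summary",
    paste0("Total fixations: ", summ$n_fixations, " (", summ$n_snv, " SNVs)"),
    paste0("Shares: missense ", fmt(summ$shares$missense_pct), "%, nonsense ",
           fmt(summ$shares$nonsense_pct), "%, frameshift ",
           fmt(summ$shares$frameshift_pct), "%"),
    paste0("Transition shares: ",
           paste(names(summ$transition_share),
                 unlist(summ$transition_share), sep = " = ",
                 collapse = "%, "), "%"),
    "", knit_table(tab1), "",
    "## Permutation tests",
    map_chr(perm, function(p) paste0("- ", p$statistic, ": observed ",
                                     p$observed, ", empirical p = ",
                                     fmt(p$p), " (", p$n_reps, " reps)")),
    "",
    "## Parallel evolution",
    paste0("Genes with parallel protein-altering fixations: see the last ",
           "permutation row above."),
    "",
    "## Conservation",
    paste0("- Reliable-ortholog background: ",
           fmt(cons$background_reliable_fraction), " (",
           cons$n_reliable_orthologs, "/", cons$n_complete_proteins, ")"),
    paste0("- Nonsense proteins with ortholog: ", cons$nonsense$k, "/",
           cons$nonsense$n, ", binomial p = ", fmt(cons$nonsense$p)),
    paste0("- Missense proteins with ortholog: ", cons$missense$k, "/",
           cons$missense$n, ", binomial p = ", fmt(cons$missense$p)),
    paste0("- Conserved mutated sites: ", cons$sites$k, "/", cons$sites$n,
           " vs background ", fmt(cons$sites$background),
           ", binomial p = ", fmt(cons$sites$p)),
    "",
    "## Headline statistics",
    paste0("- dN/dS = ", fmt(summ$dnds), " (binomial p = ", fmt(summ$dnds_p), ")"),
    paste0("- Accumulation slope = ", fmt(summ$accumulation_slope),
           " per passage^2 (p = ", fmt(summ$accumulation_slope_p), ")"),
    paste0("- Passages per fixation = ", fmt(summ$passages_per_fixation),
           " (rounded: ", summ$passages_per_fixation_rounded, ")"),
    paste0("- Mutator test: lineage p = ", fmt(summ$mutator_p_lineage),
           ", population p = ", fmt(summ$mutator_p_population)))
  writeLines(unlist(lines), path)
  invisible(path)
}

knit_table <- function(tb) {
  header <- paste0("| ", paste(names(tb), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tb)), collapse = "|"), "|")
  rows <- apply(tb, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
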