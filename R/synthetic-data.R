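#' Configuration of a synthetic serial-passage experiment
#'
#' Defaults emulate the experiment this package models: eight clonal
#' populations from two founder lineages (five A, three B) sampled at passages
#' 75, 130, 200 and 268; fixations arrive as a Poisson process at 0.07 per
#' passage per population (about 150 over the experiment), ~85% of them SNVs
#' with a 2:1 transition:transversion ratio; six parallel-target genes carry
#' the planted hit pattern (2 nonsense / 1 nonsense + 2 missense / 6
#' frameshifts / 2 missense / 2 nonsense + 1 missense / 7 missense); and each
#' exclusion filter gets planted artifacts that only it removes.
#'
#' @param seed Integer seed; the whole experiment is a deterministic function
#'   of the configuration.
#' @param n_contigs,contig_length Genome shape.
#' @param gene_density Target fraction of each contig covered by gene loci.
#' @param mean_cds_length Mean CDS length (bp; forced to a multiple of 3).
#' @param intron_fraction Fraction of genes with one intron.
#' @param intron_length Intron length (bp).
#' @param minus_strand_fraction Fraction of genes on the minus strand.
#' @param n_populations_a,n_populations_b Populations per founder lineage.
#' @param timepoints Sampling passages, strictly increasing.
#' @param fixation_rate Fixations per passage per population.
#' @param snv_fraction Fraction of fixations that are SNVs (rest indels).
#' @param tstv Transition:transversion odds for SNV alt draws.
#' @param fixed_depth Mean sequencing depth of fixed variants.
#' @param min_fixed_frequency Lower bound of a fixed variant's frequency.
#' @param parallel_targets List of character vectors; each vector is one
#'   target gene's planted hits (one per distinct population), entries in
#'   `missense`, `nonsense`, `frameshift`. `NULL` disables planting.
#' @param artifact_low_coverage,artifact_founder,artifact_adjacent,artifact_masked_indel
#'   Expected planted artifacts per population (Poisson).
#' @param artifact_multipop Expected founder-uncovered multi-population
#'   artifact sites per experiment.
#' @param n_masks,mask_length Low-complexity mask intervals per contig and
#'   their length.
#' @param validation_na_rate Probability that a validation assay before a
#'   mutation's first confirmation is uninformative (creates `time_unknown`
#'   cases).
#' @param unverifiable_rate Probability that a planted fixation is confirmed
#'   nowhere (creates `unverifiable` cases).
#' @param ortholog_fraction,reliable_given_ortholog Probability a gene has an
#'   ortholog, and that the pair's alignment is low-gap given it has one.
#' @param conserved_rate Per-site conservation of ortholog alignments (the
#'   background conserved fraction).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(seed = 1,
                              n_contigs = 2, contig_length = 60000,
                              gene_density = 0.5, mean_cds_length = 900,
                              intron_fraction = 0.2, intron_length = 60,
                              minus_strand_fraction = 0.5,
                              n_populations_a = 5, n_populations_b = 3,
                              timepoints = c(75, 130, 200, 268),
                              fixation_rate = 0.07,
                              snv_fraction = 125 / 148,
                              tstv = 2,
                              fixed_depth = 30,
                              min_fixed_frequency = 0.95,
                              parallel_targets = default_parallel_targets(),
                              artifact_low_coverage = 1,
                              artifact_founder = 1,
                              artifact_adjacent = 1,
                              artifact_masked_indel = 1,
                              artifact_multipop = 1,
                              n_masks = 3, mask_length = 300,
                              validation_na_rate = 0,
                              unverifiable_rate = 0,
                              ortholog_fraction = 0.8,
                              reliable_given_ortholog = 0.575,
                              conserved_rate = 0.62) {
  cfg <- as.list(environment())
  rates <- c(gene_density, intron_fraction, minus_strand_fraction,
             snv_fraction, min_fixed_frequency, validation_na_rate,
             unverifiable_rate, ortholog_fraction, reliable_given_ortholog,
             conserved_rate)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (any(diff(timepoints) <= 0)) abort("timepoints must be strictly increasing")
  if (gene_density > 0.85) {
    abort("gene_density above 0.85 is not packable with intergenic spacers")
  }
  structure(cfg, class = "experiment_config")
}

default_parallel_targets <- function() {
  list(c("nonsense", "nonsense"),
       c("nonsense", "missense", "missense"),
       rep("frameshift", 6),
       c("missense", "missense"),
       c("nonsense", "nonsense", "missense"),
       rep("missense", 7))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codons <- function(n) {
  pool <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  sample(pool, n, replace = TRUE)
}

#' Generate a founder genome, gene models, and mask
#'
#' Genes are packed along each contig with random intergenic spacers sized to
#' the target density; every gene is complete by construction (ATG, non-stop
#' codons, one terminal stop), a configurable fraction carries one intron, and
#' strands are drawn at random. Mask intervals are placed inside intergenic
#' spacers away from contig edges. Deterministic for a fixed seed.
#'
#' @param config An [experiment_config()].
#' @return List: `genome`, `models` (gene-model tibble), `mask` (BED-style
#'   tibble).
#' @export
generate_genome_annotation <- function(config) {
  set.seed(config$seed)
  contig_ids <- paste0("ctg", seq_len(config$n_contigs))
  seqs <- character(0)
  seg_rows <- list()
  mask_rows <- list()
  mean_gene <- max(150, round(config$mean_cds_length / 3) * 3)
  for (ct in contig_ids) {
    L <- config$contig_length
    spacer_mean <- if (config$gene_density > 0) {
      max(30, mean_gene * (1 - config$gene_density) / config$gene_density)
    } else {
      Inf
    }
    pieces <- character(0)
    cursor <- 0L
    gi <- 0L
    spacers <- list()  # candidate mask locations
    repeat {
      sp_len <- if (is.finite(spacer_mean)) {
        max(20L, as.integer(rpois(1, spacer_mean)))
      } else {
        as.integer(L - cursor)
      }
      sp_len <- min(sp_len, L - cursor)
      if (sp_len > 0) {
        pieces <- c(pieces, paste(sample(BASES, sp_len, replace = TRUE),
                                  collapse = ""))
        spacers[[length(spacers) + 1]] <- c(cursor, cursor + sp_len)
        cursor <- cursor + sp_len
      }
      if (!is.finite(spacer_mean)) break
      n_codons <- max(50, round(rpois(1, mean_gene) / 3))
      glen <- n_codons * 3L
      has_intron <- runif(1) < config$intron_fraction
      total <- glen + if (has_intron) config$intron_length else 0L
      if (cursor + total > L - 20) {
        pad <- L - cursor
        if (pad > 0) {
          pieces <- c(pieces, paste(sample(BASES, pad, replace = TRUE),
                                    collapse = ""))
          spacers[[length(spacers) + 1]] <- c(cursor, cursor + pad)
        }
        break
      }
      gi <- gi + 1L
      gene_id <- paste0(ct, "_g", gi)
      cds <- paste0("ATG", paste(random_codons(n_codons - 2), collapse = ""),
                    sample(STOP_CODONS, 1))
      strand <- if (runif(1) < config$minus_strand_fraction) "-" else "+"
      if (has_intron) {
        # split at a codon boundary strictly inside the CDS
        cut <- 3L * sample(seq_len(n_codons - 1L), 1)
        intron <- paste(sample(BASES, config$intron_length, replace = TRUE),
                        collapse = "")
        locus_tx <- paste0(substr(cds, 1, cut), intron,
                           substr(cds, cut + 1, glen))
        seg_tx <- rbind(c(0L, cut), c(cut + config$intron_length,
                                      nchar(locus_tx)))
      } else {
        locus_tx <- cds
        seg_tx <- rbind(c(0L, glen))
      }
      locus <- if (strand == "-") revcomp(locus_tx) else locus_tx
      nl <- nchar(locus)
      segs <- if (strand == "-") {
        cbind(start = cursor + nl - seg_tx[, 2], end = cursor + nl - seg_tx[, 1])
      } else {
        cbind(start = cursor + seg_tx[, 1], end = cursor + seg_tx[, 2])
      }
      seg_rows[[length(seg_rows) + 1]] <-
        tibble(gene_id = gene_id, contig = ct, strand = strand,
               start = as.integer(segs[, "start"]),
               end = as.integer(segs[, "end"]))
      pieces <- c(pieces, locus)
      cursor <- cursor + nl
      if (cursor >= L - 20) break
    }
    seqs[ct] <- paste(pieces, collapse = "")
    # masks inside roomy spacers, away from contig edges
    roomy <- Filter(function(iv) {
      iv[2] - iv[1] >= config$mask_length + 4 && iv[1] > 200 && iv[2] < L - 200
    }, spacers)
    if (config$n_masks > 0 && length(roomy) > 0) {
      pick <- sample(seq_along(roomy), min(config$n_masks, length(roomy)))
      for (iv in roomy[pick]) {
        start <- iv[1] + sample.int(iv[2] - iv[1] - config$mask_length, 1)
        mask_rows[[length(mask_rows) + 1]] <-
          tibble(contig = ct, start = as.integer(start),
                 end = as.integer(start + config$mask_length))
      }
    }
  }
  gen <- genome(seqs)
  models <- if (length(seg_rows)) gene_models(bind_rows(seg_rows), gen) else
    empty_gene_models()
  if (nrow(models) > 0 && !all(models$complete)) {
    abort("internal error: generated gene is not complete")
  }
  mask <- if (length(mask_rows)) bind_rows(mask_rows) else
    tibble(contig = character(), start = integer(), end = integer())
  list(genome = gen, models = models, mask = mask)
}

# sample alt base with the configured transition:transversion outcome odds
# (tstv = 2 means two transitions are drawn per transversion)
draw_alt <- function(ref, tstv) {
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  if (runif(1) < tstv / (tstv + 1)) {
    unname(ts_of[ref])
  } else {
    sample(setdiff(BASES, c(ref, ts_of[ref])), 1)
  }
}

in_masked_region <- function(mask, contig, pos, flank) {
  m <- mask[mask$contig == contig, , drop = FALSE]
  nrow(m) > 0 && any(pos >= m$start - flank & pos <= m$end - 1 + flank)
}

#' Simulate the serial-passage experiment on a generated genome
#'
#' Background fixations arrive per population as a Poisson process over
#' passages and persist at every later timepoint (clonal monotone presence);
#' fixed calls carry high depth and frequency >= the configured floor.
#' Parallel-target hits are planted as protein-altering mutations in distinct
#' populations of the designated genes. Planted artifacts carry evidence
#' patterns that violate exactly one exclusion filter each. Founder evidence
#' covers every true site with zero alternative reads.
#'
#' @param genome,models,mask Output of [generate_genome_annotation()].
#' @param config The same [experiment_config()].
#' @return List of class `experiment`: `calls` (raw per-sample variant
#'   tibble), `founder` (founder read support), `validation` (assay matrix in
#'   long form), `truth` (planted-mutation ledger), `populations`, `config`,
#'   plus the inputs (`genome`, `models`, `mask`).
#' @export
simulate_experiment <- function(genome, models, mask, config) {
  set.seed(config$seed + 1L)
  pops <- tibble(
    population = c(paste0("A", seq_len(config$n_populations_a)),
                   paste0("B", seq_len(config$n_populations_b))),
    lineage = c(rep("A", config$n_populations_a),
                rep("B", config$n_populations_b)))
  tps <- sort(config$timepoints)
  widths <- diff(c(0, tps))
  used <- list()  # per population: positions taken (with a safety margin)
  for (p in pops$population) used[[p]] <- tibble(contig = character(),
                                                 pos = integer())
  flank <- 10
  margin <- 5
  free_site <- function(pop, contig, pos) {
    u <- used[[pop]]
    !any(u$contig == contig & abs(u$pos - pos) <= margin)
  }
  claim <- function(pop, contig, pos) {
    used[[pop]] <<- bind_rows(used[[pop]], tibble(contig = contig,
                                                  pos = as.integer(pos)))
  }
  contig_ids <- names(genome)
  clens <- nchar(genome)
  draw_snv_site <- function(pop) {
    repeat {
      ct <- sample(contig_ids, 1, prob = clens)
      pos <- sample.int(clens[[ct]] - 20L, 1) + 9L
      if (free_site(pop, ct, pos)) return(list(contig = ct, pos = pos))
    }
  }
  draw_indel_site <- function(pop) {
    repeat {
      s <- draw_snv_site(pop)
      if (!in_masked_region(mask, s$contig, s$pos, flank + 5)) return(s)
    }
  }
  truth <- list()
  add_truth <- function(pop, lineage, contig, pos, ref, alt, vclass,
                        appearance, planted_class = NA_character_,
                        is_artifact = FALSE, artifact_rule = NA_character_,
                        evidence = "fixed") {
    truth[[length(truth) + 1]] <<- tibble(
      population = pop, lineage = lineage, contig = contig,
      pos = as.integer(pos), ref = ref, alt = alt, variant_class = vclass,
      appearance_passage = appearance,
      first_seen_timepoint = if (is.na(appearance)) NA_real_ else
        tps[which(tps >= appearance)[1]],
      planted_class = planted_class, is_artifact = is_artifact,
      artifact_rule = artifact_rule, evidence = evidence)
  }
  make_indel <- function(contig, pos) {
    seq <- genome[[contig]]
    len <- sample(1:3, 1)
    anchor <- substr(seq, pos + 1, pos + 1)
    if (runif(1) < 0.5 && pos + 1 + len <= nchar(seq)) {
      ref <- substr(seq, pos + 1, pos + 1 + len)
      alt <- anchor
    } else {
      ref <- anchor
      alt <- paste0(anchor, paste(sample(BASES, len, replace = TRUE),
                                  collapse = ""))
    }
    nm <- normalize_allele(pos, ref, alt, seq)
    nm
  }
  # --- background fixations -------------------------------------------------
  for (pi in seq_len(nrow(pops))) {
    pop <- pops$population[pi]; lin <- pops$lineage[pi]
    for (iv in seq_along(tps)) {
      n_new <- rpois(1, config$fixation_rate * widths[iv])
      for (k in seq_len(n_new)) {
        appearance <- (tps[iv] - widths[iv]) + sample.int(widths[iv], 1)
        if (runif(1) < config$snv_fraction) {
          s <- draw_snv_site(pop)
          ref <- substr(genome[[s$contig]], s$pos + 1, s$pos + 1)
          alt <- draw_alt(ref, config$tstv)
          claim(pop, s$contig, s$pos)
          add_truth(pop, lin, s$contig, s$pos, ref, alt, "SNV", appearance)
        } else {
          repeat {
            s <- draw_indel_site(pop)
            nm <- make_indel(s$contig, s$pos)
            # left-alignment may shift the indel; re-check mask clearance
            if (free_site(pop, s$contig, nm$pos) &&
                !in_masked_region(mask, s$contig, nm$pos, flank + 2)) break
          }
          claim(pop, s$contig, nm$pos)
          add_truth(pop, lin, s$contig, nm$pos, nm$ref, nm$alt, nm$class,
                    appearance)
        }
      }
    }
  }
  # --- planted parallel-target hits ----------------------------------------
  if (!is.null(config$parallel_targets) && length(config$parallel_targets) &&
      nrow(models) > 0) {
    eligible <- models[models$complete &
                         map_int(models$cds, ~ sum(.x[, "end"] - .x[, "start"])) >= 300, ]
    if (nrow(eligible) < length(config$parallel_targets)) {
      abort("not enough complete genes to host the parallel targets")
    }
    target_rows <- sample.int(nrow(eligible), length(config$parallel_targets))
    tabs <- prepare_gene_tables(genome, eligible)
    for (ti in seq_along(config$parallel_targets)) {
      classes <- config$parallel_targets[[ti]]
      row <- eligible[target_rows[ti], ]
      tab <- tabs[[target_rows[ti]]]
      hit_pops <- sample(pops$population, length(classes))
      for (hi in seq_along(classes)) {
        pop <- hit_pops[hi]
        lin <- pops$lineage[match(pop, pops$population)]
        appearance <- sample.int(max(tps), 1)
        if (classes[hi] == "frameshift") {
          # 1 bp deletion inside the CDS, away from masks; the normalised
          # (left-aligned) form must still hit the CDS
          seq <- genome[[row$contig]]
          repeat {
            ci <- sample.int(length(tab$gpos) - 4L, 1) + 2L
            gp <- sort(tab$gpos)[ci]
            if (!free_site(pop, row$contig, gp - 1) ||
                in_masked_region(mask, row$contig, gp, flank + 2)) next
            nm <- normalize_allele(gp - 1L, substr(seq, gp, gp + 1),
                                   substr(seq, gp, gp), seq)
            if ((nm$pos + 1L) %in% tab$gpos && free_site(pop, row$contig, nm$pos)) break
          }
          claim(pop, row$contig, nm$pos)
          add_truth(pop, lin, row$contig, nm$pos, nm$ref, nm$alt, "deletion",
                    appearance, planted_class = "frameshift")
        } else {
          site <- find_effect_site(genome, row, tab, classes[hi],
                                   function(ct, p) free_site(pop, ct, p))
          claim(pop, row$contig, site$pos)
          add_truth(pop, lin, row$contig, site$pos, site$ref, site$alt, "SNV",
                    appearance, planted_class = classes[hi])
        }
      }
    }
    attr(truth, "target_genes") <- eligible$gene_id[target_rows]
  }
  target_genes <- attr(truth, "target_genes") %||% character(0)
  # --- planted artifacts ----------------------------------------------------
  for (pi in seq_len(nrow(pops))) {
    pop <- pops$population[pi]; lin <- pops$lineage[pi]
    for (k in seq_len(rpois(1, config$artifact_low_coverage))) {
      s <- draw_snv_site(pop); claim(pop, s$contig, s$pos)
      ref <- substr(genome[[s$contig]], s$pos + 1, s$pos + 1)
      add_truth(pop, lin, s$contig, s$pos, ref, draw_alt(ref, config$tstv),
                "SNV", sample.int(max(tps), 1), is_artifact = TRUE,
                artifact_rule = "quality", evidence = "low_coverage")
    }
    for (k in seq_len(rpois(1, config$artifact_founder))) {
      s <- draw_snv_site(pop); claim(pop, s$contig, s$pos)
      ref <- substr(genome[[s$contig]], s$pos + 1, s$pos + 1)
      add_truth(pop, lin, s$contig, s$pos, ref, draw_alt(ref, config$tstv),
                "SNV", sample.int(max(tps), 1), is_artifact = TRUE,
                artifact_rule = "founder", evidence = "founder_supported")
    }
    for (k in seq_len(rpois(1, config$artifact_adjacent))) {
      repeat {
        s <- draw_snv_site(pop)
        if (free_site(pop, s$contig, s$pos + 1L)) break
      }
      claim(pop, s$contig, s$pos); claim(pop, s$contig, s$pos + 1L)
      app <- sample.int(max(tps), 1)
      for (off in 0:1) {
        ref <- substr(genome[[s$contig]], s$pos + 1 + off, s$pos + 1 + off)
        add_truth(pop, lin, s$contig, s$pos + off, ref,
                  draw_alt(ref, config$tstv), "SNV", app,
                  is_artifact = TRUE, artifact_rule = "adjacency",
                  evidence = "adjacent_pair")
      }
    }
    for (k in seq_len(rpois(1, config$artifact_masked_indel))) {
      if (nrow(mask) == 0) break
      m <- mask[sample.int(nrow(mask), 1), ]
      pos <- as.integer(m$start + (m$end - m$start) %/% 2)
      if (!free_site(pop, m$contig, pos)) next
      nm <- make_indel(m$contig, pos)
      if (!free_site(pop, m$contig, nm$pos)) next
      claim(pop, m$contig, nm$pos)
      add_truth(pop, lin, m$contig, nm$pos, nm$ref, nm$alt, nm$class,
                sample.int(max(tps), 1), is_artifact = TRUE,
                artifact_rule = "mask", evidence = "masked_indel")
    }
  }
  for (k in seq_len(rpois(1, config$artifact_multipop))) {
    pair <- sample(pops$population, 2)
    repeat {
      s <- draw_snv_site(pair[1])
      if (free_site(pair[2], s$contig, s$pos)) break
    }
    ref <- substr(genome[[s$contig]], s$pos + 1, s$pos + 1)
    alt <- draw_alt(ref, config$tstv)
    app <- sample.int(max(tps), 1)
    for (pop in pair) {
      claim(pop, s$contig, s$pos)
      add_truth(pop, pops$lineage[match(pop, pops$population)], s$contig,
                s$pos, ref, alt, "SNV", app, is_artifact = TRUE,
                artifact_rule = "multi_population", evidence = "multipop_shared")
    }
  }
  truth_tb <- if (length(truth)) {
    bind_rows(truth) |>
      mutate(mutation_id = paste(.data$population, .data$contig, .data$pos,
                                 .data$ref, .data$alt, sep = "|"))
  } else {
    tibble(population = character(), lineage = character(),
           contig = character(), pos = integer(), ref = character(),
           alt = character(), variant_class = character(),
           appearance_passage = double(), first_seen_timepoint = double(),
           planted_class = character(), is_artifact = logical(),
           artifact_rule = character(), evidence = character(),
           mutation_id = character())
  }
  # --- evidence tables -------------------------------------------------------
  calls <- make_calls(truth_tb, tps, config)
  founder <- make_founder_evidence(truth_tb, config)
  validation <- make_validation(truth_tb, tps, config)
  truth_tb <- mark_unverifiable(truth_tb, validation)
  structure(list(calls = calls, founder = founder, validation = validation,
                 truth = truth_tb, populations = pops,
                 target_genes = target_genes,
                 genome = genome, models = models, mask = mask,
                 config = config),
            class = "experiment")
}

# scan a complete gene for a substitution with the requested effect class
find_effect_site <- function(genome, model_row, tab, wanted, site_ok) {
  n <- nchar(tab$cds_seq)
  order_try <- sample.int(n - 6L) + 3L  # skip start codon / terminal stop
  for (ci in order_try) {
    gp <- tab$gpos[ci]
    if (!site_ok(model_row$contig, gp)) next
    for (alt_tx in sample(BASES)) {
      base_tx <- substr(tab$cds_seq, ci, ci)
      if (alt_tx == base_tx) next
      cc <- classify_codon_change(tab$cds_seq, ci, alt_tx)
      if (cc$effect == wanted) {
        alt_gen <- if (tab$strand == "-") complement_base(alt_tx) else alt_tx
        ref_gen <- substr(genome[[model_row$contig]], gp + 1, gp + 1)
        return(list(pos = gp, ref = ref_gen, alt = alt_gen))
      }
    }
  }
  abort(paste0("no ", wanted, " site available in gene ", model_row$gene_id))
}

make_calls <- function(truth, tps, config) {
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    seen_at <- tps[tps >= t$appearance_passage]
    for (tp in seen_at) {
      if (t$evidence == "low_coverage") {
        cov <- sample(3:9, 1)
      } else {
        cov <- config$fixed_depth + rpois(1, 5)  # never below the floor depth
      }
      freq <- runif(1, config$min_fixed_frequency, 1)
      ar <- min(cov, as.integer(ceiling(freq * cov)))
      rows[[length(rows) + 1]] <- tibble(
        contig = t$contig, pos = t$pos, ref = t$ref, alt = t$alt,
        variant_class = t$variant_class,
        sample_id = paste0(t$population, ".", tp),
        population = t$population, timepoint = tp,
        coverage = as.integer(cov), alt_reads = ar,
        frequency = round(ar / cov, 4))
    }
  }
  if (!length(rows)) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), variant_class = character(),
                  sample_id = character(), population = character(),
                  timepoint = integer(), coverage = integer(),
                  alt_reads = integer(), frequency = double()))
  }
  bind_rows(rows) |> arrange(.data$contig, .data$pos, .data$sample_id)
}

make_founder_evidence <- function(truth, config) {
  truth |>
    distinct(.data$contig, .data$pos, .data$ref, .data$alt, .data$evidence) |>
    mutate(
      coverage = dplyr::case_when(
        .data$evidence == "multipop_shared" ~ 0L,
        TRUE ~ as.integer(config$fixed_depth)),
      alt_reads = dplyr::case_when(
        .data$evidence == "founder_supported" ~ 2L,
        TRUE ~ 0L)) |>
    select("contig", "pos", "ref", "alt", "coverage", "alt_reads")
}

make_validation <- function(truth, tps, config) {
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    if (t$is_artifact) next  # artifacts never reach the validation assay
    unverifiable <- runif(1) < config$unverifiable_rate
    for (tp in tps) {
      confirmed <- if (unverifiable) NA else tp >= t$first_seen_timepoint
      if (!unverifiable && isFALSE(confirmed) &&
          runif(1) < config$validation_na_rate) {
        confirmed <- NA
      }
      rows[[length(rows) + 1]] <- tibble(mutation_id = t$mutation_id,
                                         timepoint = tp,
                                         confirmed = confirmed)
    }
  }
  if (!length(rows)) {
    return(tibble(mutation_id = character(), timepoint = double(),
                  confirmed = logical()))
  }
  bind_rows(rows)
}

mark_unverifiable <- function(truth, validation) {
  if (nrow(validation) == 0) return(mutate(truth, unverifiable = FALSE))
  conf <- validation |>
    group_by(.data$mutation_id) |>
    summarise(any_confirmed = any(!is.na(.data$confirmed) & .data$confirmed),
              .groups = "drop")
  truth |>
    left_join(conf, by = "mutation_id") |>
    mutate(unverifiable = !.data$is_artifact &
             !dplyr::coalesce(.data$any_confirmed, FALSE)) |>
    select(-"any_confirmed")
}

#' Generate a complete synthetic experiment
#'
#' Convenience wrapper: [generate_genome_annotation()] then
#' [simulate_experiment()].
#'
#' @param config An [experiment_config()].
#' @return An `experiment` list (see [simulate_experiment()]).
#' @export
generate_experiment <- function(config = experiment_config()) {
  ga <- generate_genome_annotation(config)
  simulate_experiment(ga$genome, ga$models, ga$mask, config)
}

#' Simulate ortholog protein alignments for the generated genes
#'
#' Each complete gene's protein gets an ortholog with the configured
#' probability; the ortholog diverges by independent residue substitutions at
#' rate `1 - conserved_rate` and carries a gap block sized to land under (or,
#' for unreliable pairs, over) the 20% gap threshold.
#'
#' @param experiment An `experiment` (or the output of
#'   [generate_genome_annotation()] plus a config).
#' @return Ortholog-pair tibble ([ortholog_pairs()] layout).
#' @export
generate_ortholog_pairs <- function(experiment) {
  config <- experiment$config
  models <- experiment$models
  genome <- experiment$genome
  set.seed(config$seed + 2L)
  aas <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
  rows <- list()
  complete <- models[models$complete, , drop = FALSE]
  for (i in seq_len(nrow(complete))) {
    if (runif(1) >= config$ortholog_fraction) next
    prot <- translate_dna(spliced_cds(genome, complete$contig[i],
                                      complete$strand[i], complete$cds[[i]]))
    prot <- sub("\\*$", "", prot)
    res <- strsplit(prot, NULL)[[1]]
    orth <- res
    swap <- runif(length(res)) >= config$conserved_rate
    orth[swap] <- vapply(orth[swap], function(a) sample(setdiff(aas, a), 1),
                         character(1))
    reliable <- runif(1) < config$reliable_given_ortholog
    gap_target <- if (reliable) runif(1, 0.02, 0.15) else runif(1, 0.25, 0.45)
    g <- max(1L, round(gap_target * length(res)))
    start <- sample.int(length(res) - g + 1L, 1)
    orth[start:(start + g - 1L)] <- "-"
    rows[[length(rows) + 1]] <- tibble(
      focal_id = complete$gene_id[i],
      ortholog_id = paste0("Nc_", complete$gene_id[i]),
      aln_focal = prot, aln_ortholog = paste(orth, collapse = ""))
  }
  if (!length(rows)) {
    return(ortholog_pairs(character(0), character(0), character(0),
                          character(0)))
  }
  tb <- bind_rows(rows)
  ortholog_pairs(tb$focal_id, tb$ortholog_id, tb$aln_focal, tb$aln_ortholog)
}

#' Write a synthetic experiment's inputs to disk
#'
#' Emits FASTA (genome), GFF3 (gene models), BED (mask), the variant calls
#' (VCF or TSV dialect), founder evidence, validation matrix, truth ledger and
#' ortholog alignments under one directory.
#'
#' @param experiment An `experiment`.
#' @param dir Output directory (created if needed).
#' @param variant_format `"tsv"` or `"vcf"`.
#' @return Named list of written paths, invisibly.
#' @export
write_experiment <- function(experiment, dir, variant_format = c("tsv", "vcf")) {
  variant_format <- match.arg(variant_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "founder.fasta"),
    models = file.path(dir, "genes.gff3"),
    mask = file.path(dir, "mask.bed"),
    calls = file.path(dir, paste0("calls.", variant_format)),
    founder = file.path(dir, "founder_evidence.tsv"),
    validation = file.path(dir, "validation.tsv"),
    truth = file.path(dir, "truth.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"))
  write_genome(experiment$genome, paths$genome)
  write_gene_models(experiment$models, paths$models)
  write_mask(experiment$mask, paths$mask)
  if (variant_format == "vcf") {
    write_variants_vcf(experiment$calls, paths$calls,
                       contig_lengths = nchar(experiment$genome))
  } else {
    write_variants_tsv(experiment$calls, paths$calls)
  }
  founder_out <- mutate(experiment$founder, pos_1based = .data$pos + 1L) |>
    select("contig", "pos_1based", "ref", "alt", "coverage", "alt_reads")
  readr::write_tsv(founder_out, paths$founder)
  readr::write_tsv(experiment$validation, paths$validation)
  readr::write_tsv(select(experiment$truth, -dplyr::any_of("evidence")),
                   paths$truth)
  write_ortholog_pairs(generate_ortholog_pairs(experiment), paths$orthologs)
  invisible(paths)
}

#' Read founder evidence written by [write_experiment()]
#'
#' @param path TSV with columns `contig, pos_1based, ref, alt, coverage,
#'   alt_reads`.
#' @return Tibble with 0-based `pos`.
#' @export
read_founder_evidence <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tibble(contig = as.character(tb$contig), pos = as.integer(tb$pos_1based) - 1L,
         ref = tb$ref, alt = tb$alt, coverage = as.integer(tb$coverage),
         alt_reads = as.integer(tb$alt_reads))
}
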