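#' Filtering thresholds for candidate fixations
#'
#' Defaults follow the study design this package models: calls must reach 10x
#' coverage and 80% allele frequency; a variant supported by >= 2 reads in the
#' population's founder is ancestral; a variant shared (>= 2 supporting reads)
#' by more than one population at a site the founder does not cover at all is
#' a mapping artifact; indels within 10 bp of a low-complexity mask are
#' discarded; same-population SNVs at adjacent sites are treated as one
#' dinucleotide event and dropped.
#'
#' @param min_coverage Minimum read depth (inclusive).
#' @param min_frequency Minimum allele frequency (inclusive).
#' @param founder_support_reads Founder alt reads at/above which a call is
#'   ancestral.
#' @param multi_population_support_reads Alt reads defining "supported" in the
#'   multi-population rule.
#' @param mask_flank Flank (bp) added to each mask interval, inclusive.
#' @param adjacency_distance Maximum distance (bp) defining adjacent SNVs.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_coverage = 10, min_frequency = 0.80,
                          founder_support_reads = 2,
                          multi_population_support_reads = 2,
                          mask_flank = 10, adjacency_distance = 1) {
  cfg <- list(min_coverage = min_coverage, min_frequency = min_frequency,
              founder_support_reads = founder_support_reads,
              multi_population_support_reads = multi_population_support_reads,
              mask_flank = mask_flank, adjacency_distance = adjacency_distance)
  if (any(unlist(cfg) < 0)) abort("filter thresholds must be >= 0")
  structure(cfg, class = "filter_config")
}

site_key <- function(x) paste(x$contig, x$pos, x$ref, x$alt, sep = "|")

#' Coverage and frequency filter
#'
#' Keeps calls with `coverage >= min_coverage` and
#' `frequency >= min_frequency`, both boundaries inclusive.
#'
#' @param calls Call tibble ([read_variants()] layout).
#' @param config A [filter_config()].
#' @return The surviving calls.
#' @export
apply_quality_filter <- function(calls, config = filter_config()) {
  calls[calls$coverage >= config$min_coverage &
        calls$frequency >= config$min_frequency, , drop = FALSE]
}

#' Founder-support filter
#'
#' Removes calls whose site and allele are supported by at least
#' `founder_support_reads` alt reads in the corresponding founder genotype
#' (such variants are ancestral, not fixations). Sites the founder does not
#' cover are left to the multi-population rule.
#'
#' @param calls Call tibble.
#' @param founder_evidence Tibble `contig, pos, ref, alt, population (optional
#'   lineage column), coverage, alt_reads` describing founder read support.
#' @param config A [filter_config()].
#' @return The surviving calls.
#' @export
apply_founder_filter <- function(calls, founder_evidence,
                                 config = filter_config()) {
  if (nrow(calls) == 0 || nrow(founder_evidence) == 0) return(calls)
  supported <- founder_evidence[founder_evidence$alt_reads >=
                                  config$founder_support_reads, , drop = FALSE]
  calls[!(site_key(calls) %in% site_key(supported)), , drop = FALSE]
}

#' Multi-population sharing filter
#'
#' Removes every call at a site+allele that is supported by at least
#' `multi_population_support_reads` alt reads in more than one experimental
#' population while the founder has zero coverage there (founder-uncovered
#' shared variants are treated as systematic artifacts). Shared sites that the
#' founder does cover are untouched by this rule.
#'
#' @param calls Call tibble pooled across all populations.
#' @param founder_evidence Founder read-support tibble; sites absent from it
#'   are taken as founder coverage 0.
#' @param config A [filter_config()].
#' @return The surviving calls.
#' @export
apply_multipopulation_filter <- function(calls, founder_evidence,
                                         config = filter_config()) {
  if (nrow(calls) == 0) return(calls)
  thr <- config$multi_population_support_reads
  shared <- calls |>
    filter(.data$alt_reads >= thr) |>
    distinct(.data$contig, .data$pos, .data$ref, .data$alt, .data$population) |>
    dplyr::count(.data$contig, .data$pos, .data$ref, .data$alt) |>
    filter(.data$n > 1)
  if (nrow(shared) == 0) return(calls)
  covered <- founder_evidence[founder_evidence$coverage > 0, , drop = FALSE]
  shared <- shared[!(site_key(shared) %in% site_key(covered)), , drop = FALSE]
  calls[!(site_key(calls) %in% site_key(shared)), , drop = FALSE]
}

#' Low-complexity mask filter
#'
#' Removes indels whose normalised position falls inside a mask interval
#' expanded by `mask_flank` bp on both sides (inclusive). SNVs are never
#' removed by this rule.
#'
#' @param calls Call tibble.
#' @param masks Mask tibble (`contig`, `start`, `end`; 0-based half-open).
#' @param config A [filter_config()].
#' @return The surviving calls.
#' @export
apply_mask_filter <- function(calls, masks, config = filter_config()) {
  if (nrow(calls) == 0 || nrow(masks) == 0) return(calls)
  indel <- calls$variant_class != "SNV"
  if (!any(indel)) return(calls)
  hit <- rep(FALSE, nrow(calls))
  for (i in which(indel)) {
    m <- masks[masks$contig == calls$contig[i], , drop = FALSE]
    if (nrow(m) == 0) next
    # expanded interval [start - flank, end - 1 + flank], inclusive
    hit[i] <- any(calls$pos[i] >= m$start - config$mask_flank &
                  calls$pos[i] <= m$end - 1 + config$mask_flank)
  }
  calls[!hit, , drop = FALSE]
}

#' Adjacent-SNV (dinucleotide) filter
#'
#' Within each population, removes both members of any SNV pair on the same
#' contig at distance `<= adjacency_distance` — such pairs are treated as a
#' single dinucleotide mutation event rather than two independent fixations.
#'
#' @param calls Call tibble.
#' @param config A [filter_config()].
#' @return The surviving calls.
#' @export
apply_adjacency_filter <- function(calls, config = filter_config()) {
  if (nrow(calls) == 0) return(calls)
  drop_key <- calls |>
    filter(.data$variant_class == "SNV") |>
    distinct(.data$population, .data$contig, .data$pos) |>
    group_by(.data$population, .data$contig) |>
    arrange(.data$pos, .by_group = TRUE) |>
    mutate(d_prev = .data$pos - dplyr::lag(.data$pos),
           d_next = dplyr::lead(.data$pos) - .data$pos,
           adj = (!is.na(.data$d_prev) & .data$d_prev <= config$adjacency_distance) |
                 (!is.na(.data$d_next) & .data$d_next <= config$adjacency_distance)) |>
    ungroup() |>
    filter(.data$adj)
  if (nrow(drop_key) == 0) return(calls)
  key <- paste(calls$population, calls$contig, calls$pos)
  bad <- paste(drop_key$population, drop_key$contig, drop_key$pos)
  calls[!(calls$variant_class == "SNV" & key %in% bad), , drop = FALSE]
}

#' Run the full exclusion cascade with an audit trail
#'
#' Applies the rules in the fixed order quality -> founder ->
#' multi-population -> mask -> adjacency. Each rule's predicate is independent
#' of the others' outcomes, so the surviving set does not depend on the order;
#' the order only decides which rule an excluded call is attributed to.
#'
#' @param calls Raw call tibble across all populations and timepoints.
#' @param founder_evidence Founder read-support tibble (see
#'   [apply_founder_filter()]).
#' @param masks Mask tibble.
#' @param config A [filter_config()].
#' @return A list of class `filter_report`: `kept` (surviving calls),
#'   `removed` (excluded calls with a `rule` column), `counts` (per-rule
#'   removal tallies).
#' @export
filter_variants <- function(calls, founder_evidence = NULL, masks = NULL,
                            config = filter_config()) {
  founder_evidence <- founder_evidence %||%
    tibble(contig = character(), pos = integer(), ref = character(),
           alt = character(), coverage = integer(), alt_reads = integer())
  masks <- masks %||%
    tibble(contig = character(), start = integer(), end = integer())
  stages <- list(
    quality = function(x) apply_quality_filter(x, config),
    founder = function(x) apply_founder_filter(x, founder_evidence, config),
    multi_population = function(x)
      apply_multipopulation_filter(x, founder_evidence, config),
    mask = function(x) apply_mask_filter(x, masks, config),
    adjacency = function(x) apply_adjacency_filter(x, config)
  )
  kept <- calls
  removed <- list()
  for (rule in names(stages)) {
    out <- stages[[rule]](kept)
    gone <- anti_join(kept, out,
                      by = c("contig", "pos", "ref", "alt", "sample_id"))
    if (nrow(gone) > 0) removed[[rule]] <- mutate(gone, rule = rule)
    kept <- out
  }
  removed <- if (length(removed)) bind_rows(removed) else
    mutate(calls[0, ], rule = character(0))
  counts <- tibble(rule = names(stages),
                   removed = map_int(names(stages),
                                     ~ sum(removed$rule == .x)))
  stopifnot(nrow(kept) + nrow(removed) == nrow(calls))
  structure(list(kept = kept, removed = removed, counts = counts,
                 config = config),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> ", nrow(x$kept), " kept, ", nrow(x$removed),
      " removed\n", sep = "")
  print(x$counts)
  invisible(x)
}
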