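TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

# round-half-up, the convention used for reported percentages
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Tabulate fixations by mutation type and effect class
#'
#' Produces the per-lineage summary: transition/transversion counts among
#' SNVs, per-effect counts, totals, and the derived percentage shares of
#' missense, nonsense and frameshift fixations among all fixations
#' (percentages rounded to 1 decimal; transition shares to whole percent,
#' half-up).
#'
#' @param records Fixation tibble with columns `lineage`, `variant_class`,
#'   `ref`, `alt`, `effect`.
#' @return A list of class `fixation_summary`: `by_lineage` (counts tibble),
#'   `totals`, `shares` (named percentages, `NA` when there are no
#'   fixations).
#' @export
summarize_fixations <- function(records) {
  if (nrow(records) == 0) {
    return(structure(list(
      by_lineage = tibble(lineage = character(), category = character(),
                          n = integer()),
      totals = tibble(n_fixations = 0L, n_snv = 0L, n_indel = 0L),
      shares = c(missense_pct = NA_real_, nonsense_pct = NA_real_,
                 frameshift_pct = NA_real_),
      transition_share = tibble(lineage = character(), n_snv = integer(),
                                n_transitions = integer(), pct = numeric())),
      class = "fixation_summary"))
  }
  records <- mutate(records,
    mutation_type = dplyr::case_when(
      .data$variant_class != "SNV" ~ "indel",
      paste0(.data$ref, ">", .data$alt) %in% TRANSITIONS ~ "transition",
      TRUE ~ "transversion"))
  by_lineage <- bind_rows(
    records |>
      filter(.data$variant_class == "SNV") |>
      dplyr::count(.data$lineage, category = .data$mutation_type),
    records |> dplyr::count(.data$lineage, category = .data$effect)
  ) |> arrange(.data$lineage)
  n_tot <- nrow(records)
  n_snv <- sum(records$variant_class == "SNV")
  shares <- c(
    missense_pct = round_half_up(100 * sum(records$effect == "missense") / n_tot, 1),
    nonsense_pct = round_half_up(100 * sum(records$effect == "nonsense") / n_tot, 1),
    frameshift_pct = round_half_up(100 * sum(records$effect == "frameshift") / n_tot, 1))
  transition_share <- records |>
    filter(.data$variant_class == "SNV") |>
    group_by(.data$lineage) |>
    summarise(n_snv = dplyr::n(),
              n_transitions = sum(.data$mutation_type == "transition"),
              .groups = "drop") |>
    mutate(pct = round_half_up(100 * .data$n_transitions / .data$n_snv))
  structure(list(by_lineage = by_lineage,
                 totals = tibble(n_fixations = n_tot, n_snv = n_snv,
                                 n_indel = n_tot - n_snv),
                 shares = shares, transition_share = transition_share),
            class = "fixation_summary")
}

#' @export
print.fixation_summary <- function(x, ...) {
  cat("<fixation_summary> ", x$totals$n_fixations, " fixations (",
      x$totals$n_snv, " SNVs, ", x$totals$n_indel, " indels)\n", sep = "")
  cat("  shares: missense ", x$shares[["missense_pct"]], "%, nonsense ",
      x$shares[["nonsense_pct"]], "%, frameshift ",
      x$shares[["frameshift_pct"]], "%\n", sep = "")
  print(x$transition_share)
  invisible(x)
}

#' @export
tidy.fixation_summary <- function(x, ...) x$by_lineage

#' @export
glance.fixation_summary <- function(x, ...) {
  dplyr::bind_cols(x$totals, tibble(missense_pct = x$shares[["missense_pct"]],
                                    nonsense_pct = x$shares[["nonsense_pct"]],
                                    frameshift_pct = x$shares[["frameshift_pct"]]))
}

#' Nei-Gojobori-style site counts for a CDS sequence
#'
#' Every position contributes total weight 1, split between synonymous and
#' nonsynonymous according to its three possible substitutions under equal
#' mutation rates (optionally transition/transversion-weighted: a transition
#' then carries weight `tstv` against 1 per transversion).
#'
#' @param cds_seq In-frame coding sequence (character scalar).
#' @param tstv Transition/transversion rate ratio for the weighting (1 =
#'   equal-rates NG86 variant).
#' @return Named numeric: `sites_N`, `sites_S` (sum = `nchar(cds_seq)`).
#' @export
ng_site_counts <- function(cds_seq, tstv = 1) {
  n <- nchar(cds_seq)
  stopifnot(n %% 3 == 0)
  bases <- strsplit(cds_seq, NULL)[[1]]
  codon_index <- (seq_len(n) - 1L) %/% 3L
  pos_in_codon <- (seq_len(n) - 1L) %% 3L
  cstart <- codon_index * 3L + 1L
  codons <- substring(cds_seq, cstart, cstart + 2L)
  aa0 <- unname(Biostrings::GENETIC_CODE[codons])
  syn_w <- tot_w <- numeric(n)
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  for (b in BASES) {
    differ <- bases != b
    if (!any(differ)) next
    pic <- pos_in_codon[differ]
    cd <- codons[differ]
    mut <- paste0(substr(cd, 1, pic), b, substr(cd, pic + 2L, 3L))
    aa1 <- unname(Biostrings::GENETIC_CODE[mut])
    w <- ifelse(ts_of[bases[differ]] == b, tstv, 1)
    tot_w[differ] <- tot_w[differ] + w
    syn_w[differ] <- syn_w[differ] + w * (aa1 == aa0[differ])
  }
  sites_S <- sum(syn_w / tot_w)
  c(sites_N = n - sites_S, sites_S = sites_S)
}

#' dN/dS over the experiment's coding SNVs
#'
#' Expected nonsynonymous/synonymous site counts are obtained by enumerating
#' all single-base substitutions over the complete-gene CDS set (equal
#' mutation rates by default); `dN/dS = (obs_N / sites_N) / (obs_S /
#' sites_S)`. The neutral-expectation test is an exact binomial test of
#' `obs_N` among `obs_N + obs_S` against `sites_N / (sites_N + sites_S)`.
#'
#' @param coding_snvs Annotated SNV tibble (`effect` in missense / nonsense /
#'   synonymous; other rows are ignored).
#' @param models Gene-model tibble (complete genes define the site universe).
#' @param genome A `podevol_genome`.
#' @param tstv Transition/transversion weighting for site counts (default 1).
#' @param alternative Binomial-test sidedness (default two-sided).
#' @return A list of class `dnds_result`: `obs_N`, `obs_S`, `sites_N`,
#'   `sites_S`, `dnds` (`Inf` with `infinite = TRUE` when `obs_S = 0`), `p`.
#' @export
dnds <- function(coding_snvs, models, genome, tstv = 1,
                 alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  complete <- models[models$complete, , drop = FALSE]
  if (nrow(complete) == 0) abort("no complete genes in the CDS set")
  sites <- rowSums(vapply(seq_len(nrow(complete)), function(i) {
    ng_site_counts(spliced_cds(genome, complete$contig[i],
                               complete$strand[i], complete$cds[[i]]), tstv)
  }, numeric(2)))
  obs_N <- sum(coding_snvs$effect %in% c("missense", "nonsense"))
  obs_S <- sum(coding_snvs$effect == "synonymous")
  ratio <- if (obs_S == 0) Inf else
    (obs_N / sites[["sites_N"]]) / (obs_S / sites[["sites_S"]])
  p <- if (obs_N + obs_S == 0) NA_real_ else {
    pn <- sites[["sites_N"]] / sum(sites)
    if (alternative == "greater") {
      pbinom(obs_N - 1, obs_N + obs_S, pn, lower.tail = FALSE)
    } else {
      binom.test(obs_N, obs_N + obs_S, pn)$p.value
    }
  }
  structure(list(obs_N = obs_N, obs_S = obs_S,
                 sites_N = sites[["sites_N"]], sites_S = sites[["sites_S"]],
                 dnds = ratio, infinite = is.infinite(ratio), p = p),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat("<dnds_result> dN/dS = ", format(x$dnds), " (", x$obs_N, " N / ",
      x$obs_S, " S over ", round(x$sites_N, 1), " / ", round(x$sites_S, 1),
      " sites), binomial p = ", format(x$p), "\n", sep = "")
  invisible(x)
}

#' @export
glance.dnds_result <- function(x, ...) {
  tibble(dnds = x$dnds, obs_N = x$obs_N, obs_S = x$obs_S,
         sites_N = x$sites_N, sites_S = x$sites_S, p = x$p)
}

#' Regression of fixation rate on time
#'
#' Converts per-population, per-timepoint counts of newly appeared fixations
#' into per-interval rates (new fixations / passages in the interval) and fits
#' ordinary least squares of rate on the interval midpoint passage, pooled
#' across populations. A declining rate shows as a negative slope.
#'
#' @param counts Tibble `population`, `timepoint` (passage number of the
#'   sampling point), `new_fixations`.
#' @param passage_numbers The experiment's sampling passages, sorted; interval
#'   `i` runs from the previous passage (0 before the first) to passage `i`.
#' @return List of class `accumulation_fit`: `rates` (tibble with
#'   `population`, `midpoint`, `rate`), `slope`, `intercept`, `slope_p`,
#'   `model` (the `lm` fit).
#' @export
accumulation_regression <- function(counts, passage_numbers) {
  passage_numbers <- sort(passage_numbers)
  if (length(passage_numbers) < 2) {
    abort("at least two timepoints are needed to fit an accumulation trend")
  }
  widths <- diff(c(0, passage_numbers))
  mids <- passage_numbers - widths / 2
  rates <- counts |>
    mutate(idx = match(.data$timepoint, passage_numbers)) |>
    filter(!is.na(.data$idx)) |>
    mutate(rate = .data$new_fixations / widths[.data$idx],
           midpoint = mids[.data$idx]) |>
    select("population", "midpoint", "rate")
  if (nrow(distinct(rates, .data$midpoint)) < 2) {
    abort("accumulation fit undefined: fewer than two distinct intervals")
  }
  fit <- lm(rate ~ midpoint, data = rates)
  # noise-free constructed inputs fit exactly; the warning is expected there
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(rates = rates, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 slope_p = if (nrow(sm) > 1) sm["midpoint", 4] else NA_real_,
                 model = fit),
            class = "accumulation_fit")
}

#' @export
print.accumulation_fit <- function(x, ...) {
  cat("<accumulation_fit> slope = ", format(x$slope), " fixations/passage^2",
      ", p = ", format(x$slope_p), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.accumulation_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "midpoint"),
         estimate = c(x$intercept, x$slope),
         p.value = c(suppressWarnings(summary(x$model))$coefficients[1, 4], x$slope_p))
}

#' @export
glance.accumulation_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, slope_p = x$slope_p,
         r.squared = suppressWarnings(summary(x$model))$r.squared, n = nrow(x$rates))
}

#' @export
autoplot.accumulation_fit <- function(object, ...) {
  ggplot2::ggplot(object$rates,
                  ggplot2::aes(x = .data$midpoint, y = .data$rate)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$population)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "blue") +
    ggplot2::labs(x = "passage (interval midpoint)",
                  y = "fixations per passage per population") +
    ggplot2::theme_minimal()
}

#' Average passages per fixation
#'
#' @param n_populations Number of experimental populations.
#' @param total_passages Passages elapsed per population.
#' @param total_fixations Total fixations across populations.
#' @return Tibble: `raw` and `rounded` (half-up) passages per fixation; both
#'   `NA` with a warning when no fixations occurred.
#' @export
passages_per_fixation <- function(n_populations, total_passages,
                                  total_fixations) {
  if (total_fixations == 0) {
    warn("no fixations: passages-per-fixation undefined")
    return(tibble(raw = NA_real_, rounded = NA_real_))
  }
  raw <- (n_populations * total_passages) / total_fixations
  tibble(raw = raw, rounded = round_half_up(raw))
}

#' Two-way ANOVA for mutation-count homogeneity (mutator check)
#'
#' Tests per-timepoint fixation counts for differences between founder
#' lineages and between populations within a lineage (fixed-effects two-way
#' ANOVA with population nested in lineage). A population acquiring mutations
#' much faster than its peers (a mutator) shows as a small
#' within-lineage population p-value. With zero variance everywhere both
#' p-values are 1 by convention.
#'
#' @param counts Tibble `population`, `lineage`, `timepoint`,
#'   `new_fixations`.
#' @return Tibble: `p_lineage`, `p_population`.
#' @export
mutator_test <- function(counts) {
  counts <- mutate(counts, lineage = factor(.data$lineage),
                   population = factor(.data$population))
  if (sd(counts$new_fixations) == 0) {
    return(tibble(p_lineage = 1, p_population = 1))
  }
  fit <- aov(new_fixations ~ lineage + lineage:population, data = counts)
  sm <- summary(fit)[[1]]
  rn <- trimws(rownames(sm))
  tibble(p_lineage = sm[match("lineage", rn), "Pr(>F)"],
         p_population = sm[match("lineage:population", rn), "Pr(>F)"])
}
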