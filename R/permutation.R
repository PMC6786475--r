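#' Build a trinucleotide-context index of a genome
#'
#' Indexes every internal position of every contig (no `N` in the 3-bp
#' window) under its forward-strand 3-mer, for context-matched re-throwing of
#' observed SNVs. Positions are stored in a single encoded coordinate
#' (contig offset + 0-based position).
#'
#' @param genome A `podevol_genome`.
#' @param collapse_strand Collapse each 3-mer with its reverse complement
#'   (pyrimidine-centred equivalence classes). Default `FALSE`: contexts are
#'   read on the forward strand only.
#' @return A `context_index` list: `index` (named list 3-mer -> encoded
#'   positions), `all_pool` (every eligible encoded position), `offsets`,
#'   `contigs`, `central` (central base per encoded position, as the pool
#'   order), `n_eligible`.
#' @export
build_context_index <- function(genome, collapse_strand = FALSE) {
  contigs <- names(genome)
  lens <- nchar(genome)
  offsets <- c(0, cumsum(as.numeric(lens)))[seq_along(contigs)]
  names(offsets) <- contigs
  enc_all <- integer(0)
  kmer_all <- character(0)
  for (ct in contigs) {
    L <- lens[[ct]]
    if (L < 3) next
    p <- seq.int(1L, L - 2L)                      # 0-based internal positions
    k <- substring(genome[[ct]], p, p + 2L)       # 1-based p..p+2 == window
    ok <- !grepl("N", k, fixed = TRUE)
    enc_all <- c(enc_all, as.integer(offsets[[ct]]) + p[ok])
    kmer_all <- c(kmer_all, k[ok])
  }
  if (collapse_strand) {
    central <- substr(kmer_all, 2, 2)
    flip <- central %in% c("A", "G")              # centre on pyrimidines
    kmer_all[flip] <- revcomp(kmer_all[flip])
  }
  structure(list(index = split(enc_all, kmer_all),
                 all_pool = enc_all,
                 offsets = offsets, contigs = contigs,
                 contig_lengths = lens,
                 collapse_strand = collapse_strand,
                 n_eligible = length(enc_all)),
            class = "context_index")
}

decode_positions <- function(index, enc) {
  ci <- findInterval(enc, unname(index$offsets))
  tibble(contig = index$contigs[ci],
         pos = as.integer(enc - index$offsets[ci]))
}

# sample one encoded position per (mutation, replicate); observed must carry
# columns context (NA = undefined) and alt
sample_placements <- function(index, observed, n_reps) {
  m <- nrow(observed)
  enc <- matrix(0L, nrow = m, ncol = n_reps)
  grp <- ifelse(is.na(observed$context), ".nocontext", observed$context)
  for (g in unique(grp)) {
    rows <- which(grp == g)
    pool <- if (g == ".nocontext") index$all_pool else index$index[[g]]
    if (is.null(pool) || length(pool) == 0) {
      inform(paste0("context ", g,
                    " has no eligible genomic position; using the uniform pool"))
      pool <- index$all_pool
    }
    k <- length(rows) * n_reps
    enc[rows, ] <- pool[sample.int(length(pool), k, replace = TRUE)]
  }
  enc
}

# alt base per placement: preserved where the central base stays the ref,
# redrawn uniformly among the other three bases where a uniform-pool placement
# landed on a central base equal to the alt allele
placement_alts <- function(genome, index, enc, observed) {
  dec <- decode_positions(index, as.vector(enc))
  central <- character(nrow(dec))
  for (ct in unique(dec$contig)) {
    sel <- dec$contig == ct
    central[sel] <- substring(genome[[ct]], dec$pos[sel] + 1L, dec$pos[sel] + 1L)
  }
  alt <- rep(observed$alt, times = ncol(enc))
  clash <- alt == central
  if (any(clash)) {
    alt[clash] <- vapply(central[clash], function(b) {
      sample(setdiff(BASES, b), 1)
    }, character(1))
  }
  list(contig = dec$contig, pos = dec$pos, ref = central, alt = alt)
}

#' Throw the observed SNV set onto the genome once
#'
#' One permutation replicate: each observed SNV is placed uniformly at random
#' on a genomic position matching its trinucleotide context (mutations with
#' undefined context use the uniform pool), keeping its substituted base.
#' Collisions between mutations are allowed. Uses the current RNG state.
#'
#' @param observed Tibble of observed SNVs with columns `context` and `alt`.
#' @param index A [build_context_index()] object.
#' @param genome The `podevol_genome` the index was built from.
#' @return Tibble of placements: `contig`, `pos`, `ref`, `alt`, `context`.
#' @export
permute_once <- function(observed, index, genome) {
  enc <- sample_placements(index, observed, 1L)
  pl <- placement_alts(genome, index, enc, observed)
  out <- tibble(contig = pl$contig, pos = pl$pos, ref = pl$ref, alt = pl$alt)
  out$context <- NA_character_
  for (ct in unique(out$contig)) {
    sel <- out$contig == ct
    out$context[sel] <- trinucleotide_context(genome, ct, out$pos[sel])
  }
  out
}

empirical_p <- function(null, observed, estimator = c("plugin", "add_one")) {
  estimator <- match.arg(estimator)
  if (estimator == "plugin") {
    sum(null >= observed) / length(null)
  } else {
    (sum(null >= observed) + 1) / (length(null) + 1)
  }
}

new_perm_test <- function(statistic, observed, null, estimator, seed) {
  structure(list(statistic = statistic, observed = observed, null = null,
                 n_reps = length(null),
                 p = empirical_p(null, observed, estimator),
                 estimator = estimator, seed = seed),
            class = "perm_test")
}

# class-code counts per replicate for one placed matrix
replicate_class_counts <- function(index, map, enc, alts, code) {
  dec <- decode_positions(index, as.vector(enc))
  alt_idx <- match(alts, BASES)
  hit <- logical(length(alt_idx))
  for (ct in unique(dec$contig)) {
    sel <- dec$contig == ct
    cl <- map$maps[[ct]]$class
    hit[sel] <- cl[cbind(alt_idx[sel], dec$pos[sel] + 1L)] == code
  }
  rep_id <- rep(seq_len(ncol(enc)), each = nrow(enc))
  tabulate(rep_id[hit], nbins = ncol(enc))
}

#' Permutation null for protein-altering SNV counts
#'
#' Re-throws the observed SNV set onto the genome `n_reps` times (context
#' matched by default), annotates every replicate with the effect classifier,
#' and returns the null distribution of the nonsense and missense counts with
#' empirical right-tail p-values for the observed counts
#' (`p = #\{null >= observed\} / n_reps`; the area to the right of the
#' observed value, inclusive).
#'
#' @param genome A `podevol_genome`.
#' @param models Gene-model tibble.
#' @param observed Tibble of observed SNVs with columns `contig`, `pos`,
#'   `alt`, and (unless recomputed here) `context`; typically the SNV rows of
#'   [classify_variants()] output.
#' @param n_reps Number of permutation replicates.
#' @param seed Integer seed (RNG restored on exit).
#' @param context_matched Match trinucleotide contexts (default) or place
#'   uniformly.
#' @param collapse_strand See [build_context_index()].
#' @param estimator `"plugin"` (`#\{>=\}/n`) or `"add_one"`
#'   (Davison-Hinkley `(#\{>=\}+1)/(n+1)`).
#' @param unaligned_contigs Contigs without annotation (hits count as
#'   `unaligned`, never protein-altering).
#' @return Named list of two `perm_test` objects: `nonsense`, `missense`.
#' @export
null_effect_counts <- function(genome, models, observed, n_reps = 10000,
                               seed = 1, context_matched = TRUE,
                               collapse_strand = FALSE,
                               estimator = c("plugin", "add_one"),
                               unaligned_contigs = character()) {
  estimator <- match.arg(estimator)
  observed <- prepare_observed(observed, genome, context_matched)
  index <- build_context_index(genome, collapse_strand)
  map <- effect_map(genome, models, unaligned_contigs)
  obs_ann <- classify_variants(
    mutate(observed, variant_class = "SNV",
           ref = central_base(genome, observed)),
    models, genome, unaligned_contigs)
  code_non <- match("nonsense", EFFECT_LEVELS)
  code_mis <- match("missense", EFFECT_LEVELS)
  withr_seed(seed)
  enc <- sample_placements(index, observed, n_reps)
  pl <- placement_alts(genome, index, enc, observed)
  null_non <- replicate_class_counts(index, map, enc, pl$alt, code_non)
  null_mis <- replicate_class_counts(index, map, enc, pl$alt, code_mis)
  list(
    nonsense = new_perm_test("nonsense count",
                             sum(obs_ann$effect == "nonsense"),
                             null_non, estimator, seed),
    missense = new_perm_test("missense count",
                             sum(obs_ann$effect == "missense"),
                             null_mis, estimator, seed)
  )
}

central_base <- function(genome, observed) {
  out <- character(nrow(observed))
  for (ct in unique(observed$contig)) {
    sel <- observed$contig == ct
    out[sel] <- substring(genome[[ct]], observed$pos[sel] + 1L,
                          observed$pos[sel] + 1L)
  }
  out
}

prepare_observed <- function(observed, genome, context_matched) {
  if (!("context" %in% names(observed)) && context_matched) {
    observed$context <- NA_character_
    for (ct in unique(observed$contig)) {
      sel <- observed$contig == ct
      observed$context[sel] <- trinucleotide_context(genome, ct,
                                                     observed$pos[sel])
    }
  }
  if (!context_matched) observed$context <- NA_character_
  observed
}

#' Permutation null for the gene-level parallelism statistic
#'
#' Statistic: the number of genes that carry at least `min_hits`
#' protein-altering (missense or nonsense) single-nucleotide mutations, pooled
#' over both founder lineages. Per replicate, the A set is thrown onto genome
#' A and the B set onto genome B (context matched), hits are pooled by
#' `gene_id`, and the statistic recomputed; the empirical p is right-tailed.
#'
#' @param genome_a,genome_b Founder genomes (may be the same object).
#' @param models_a,models_b Gene models sharing a `gene_id` namespace.
#' @param observed_a,observed_b Observed SNV tibbles (`contig`, `pos`, `alt`,
#'   optionally `context`).
#' @param observed_statistic Optionally override the observed value (default:
#'   computed from the observed sets via the effect classifier).
#' @param min_hits Minimum protein-altering hits for a gene to count.
#' @inheritParams null_effect_counts
#' @return A `perm_test` object.
#' @export
null_parallel_genes <- function(genome_a, models_a, observed_a,
                                genome_b, models_b, observed_b,
                                n_reps = 10000, seed = 1, min_hits = 2,
                                context_matched = TRUE,
                                collapse_strand = FALSE,
                                estimator = c("plugin", "add_one"),
                                observed_statistic = NULL,
                                unaligned_contigs = character()) {
  estimator <- match.arg(estimator)
  observed_a <- prepare_observed(observed_a, genome_a, context_matched)
  observed_b <- prepare_observed(observed_b, genome_b, context_matched)
  index_a <- build_context_index(genome_a, collapse_strand)
  index_b <- build_context_index(genome_b, collapse_strand)
  map_a <- effect_map(genome_a, models_a, unaligned_contigs)
  map_b <- effect_map(genome_b, models_b, unaligned_contigs)
  if (is.null(observed_statistic)) {
    ann <- bind_rows(
      classify_variants(mutate(observed_a, variant_class = "SNV",
                               ref = central_base(genome_a, observed_a)),
                        models_a, genome_a, unaligned_contigs),
      classify_variants(mutate(observed_b, variant_class = "SNV",
                               ref = central_base(genome_b, observed_b)),
                        models_b, genome_b, unaligned_contigs))
    observed_statistic <- parallel_gene_count(ann, min_hits)
  }
  withr_seed(seed)
  null <- parallel_null_counts(index_a, map_a, models_a, observed_a, genome_a,
                               index_b, map_b, models_b, observed_b, genome_b,
                               n_reps, min_hits)
  new_perm_test(paste0("genes with >=", min_hits, " protein-altering SNVs"),
                observed_statistic, null, estimator, seed)
}

#' Count genes hit by protein-altering mutations in several populations
#'
#' @param annotated Annotated fixation tibble (needs `gene_id`, `effect`).
#' @param min_hits Minimum number of qualifying mutations.
#' @param classes Effect classes that qualify (default: protein-altering
#'   SNV classes).
#' @return Number of genes with at least `min_hits` qualifying mutations.
#' @export
parallel_gene_count <- function(annotated, min_hits = 2,
                                classes = c("missense", "nonsense")) {
  hits <- annotated[annotated$effect %in% classes & !is.na(annotated$gene_id), ]
  sum(table(hits$gene_id) >= min_hits)
}

parallel_null_counts <- function(index_a, map_a, models_a, obs_a, genome_a,
                                 index_b, map_b, models_b, obs_b, genome_b,
                                 n_reps, min_hits) {
  gene_keys <- function(index, map, models, obs, genome, lineage) {
    if (nrow(obs) == 0) {
      return(list(rep_id = integer(0), gene = character(0)))
    }
    enc <- sample_placements(index, obs, n_reps)
    pl <- placement_alts(genome, index, enc, obs)
    dec_pos <- pl$pos
    alt_idx <- match(pl$alt, BASES)
    code_non <- match("nonsense", EFFECT_LEVELS)
    code_mis <- match("missense", EFFECT_LEVELS)
    keep <- logical(length(alt_idx))
    gene <- integer(length(alt_idx))
    for (ct in unique(pl$contig)) {
      sel <- pl$contig == ct
      cl <- map$maps[[ct]]$class[cbind(alt_idx[sel], dec_pos[sel] + 1L)]
      keep[sel] <- cl == code_non | cl == code_mis
      gene[sel] <- map$maps[[ct]]$gene[dec_pos[sel] + 1L]
    }
    rep_id <- rep(seq_len(n_reps), each = nrow(obs))
    list(rep_id = rep_id[keep],
         gene = paste0(lineage, models$gene_id[gene[keep]]))
  }
  a <- gene_keys(index_a, map_a, models_a, obs_a, genome_a, "")
  b <- gene_keys(index_b, map_b, models_b, obs_b, genome_b, "")
  rep_id <- c(a$rep_id, b$rep_id)
  key <- paste0(rep_id, "|", c(a$gene, b$gene))
  if (length(key) == 0) return(integer(n_reps))
  cnt <- table(key)
  multi <- cnt[cnt >= min_hits]
  reps <- as.integer(sub("\\|.*$", "", names(multi)))
  tabulate(reps, nbins = n_reps)
}

# set the RNG deterministically without clobbering the caller's stream
withr_seed <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> ", x$statistic, "\n  observed = ", x$observed,
      ", reps = ", x$n_reps, ", empirical p = ", format(x$p), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.perm_test <- function(x, ...) {
  tb <- table(x$null)
  tibble(value = as.integer(names(tb)), n = as.integer(tb),
         statistic = x$statistic)
}

#' @export
glance.perm_test <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed, p = x$p,
         n_reps = x$n_reps, estimator = x$estimator)
}

#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$n)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = object$statistic, y = "replicates",
                  title = paste0("Permutation null (", object$n_reps,
                                 " reps), empirical p = ",
                                 signif(object$p, 3))) +
    ggplot2::theme_minimal()
}
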