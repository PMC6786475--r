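EFFECT_LEVELS <- c("missense", "nonsense", "synonymous", "intronic",
                   "intergenic", "frameshift", "inframe_indel",
                   "incomplete_gene", "unaligned")

# severity used when a variant hits overlapping genes (most severe reported)
EFFECT_SEVERITY <- c(nonsense = 7, frameshift = 6, missense = 5,
                     inframe_indel = 4, synonymous = 3, incomplete_gene = 2.5,
                     intronic = 2, intergenic = 1, unaligned = 0)

complement_base <- function(b) chartr("ACGTN", "TGCAN", b)

prepare_gene_tables <- function(genome, models) {
  lapply(seq_len(nrow(models)), function(i) gene_cds_table(genome, models[i, ]))
}

# per-gene lookup tables: genomic position (0-based) -> CDS index, codon, etc.
gene_cds_table <- function(genome, model_row) {
  cds <- model_row$cds[[1]]
  strand <- model_row$strand
  fwd <- cds[order(cds[, "start"]), , drop = FALSE]
  gpos <- unlist(lapply(seq_len(nrow(fwd)),
                        function(i) seq.int(fwd[i, "start"], fwd[i, "end"] - 1L)))
  if (strand == "-") gpos <- rev(gpos)
  s <- spliced_cds(genome, model_row$contig, strand, cds)
  list(gpos = gpos, cds_seq = s, strand = strand,
       span = c(min(fwd[, "start"]), max(fwd[, "end"])))
}

classify_codon_change <- function(cds_seq, cds_index, alt_tx) {
  codon_index <- (cds_index - 1L) %/% 3L
  pos_in_codon <- (cds_index - 1L) %% 3L
  cstart <- codon_index * 3L + 1L
  codon <- substr(cds_seq, cstart, cstart + 2L)
  mutant <- codon
  substr(mutant, pos_in_codon + 1L, pos_in_codon + 1L) <- alt_tx
  aa_ref <- unname(Biostrings::GENETIC_CODE[codon])
  aa_alt <- unname(Biostrings::GENETIC_CODE[mutant])
  effect <- if (aa_alt == aa_ref) {
    "synonymous"              # includes stop -> stop at the terminal codon
  } else if (aa_alt == "*") {
    "nonsense"
  } else {
    "missense"                # includes stop-loss (no separate category)
  }
  list(effect = effect, codon_index = codon_index,
       residue_index = codon_index + 1L, aa_ref = aa_ref, aa_alt = aa_alt)
}

#' Classify a single SNV against the gene models
#'
#' Translates the affected codon before and after the substitution
#' (reverse-complementing for minus-strand genes). SNVs in the CDS of a
#' complete gene become `missense` / `nonsense` / `synonymous`; in an
#' incomplete gene's exon, `incomplete_gene`; between CDS segments of a gene,
#' `intronic`; outside all genes, `intergenic`; on a contig flagged as lacking
#' annotation, `unaligned`. With overlapping genes the most severe effect is
#' reported and all hits are returned in `all_hits`.
#'
#' @param genome A `podevol_genome`.
#' @param models Gene-model tibble.
#' @param contig,pos,ref,alt The SNV (0-based `pos`; single-base alleles).
#' @param unaligned_contigs Contigs to tag `unaligned`.
#' @param tabs Precomputed per-gene CDS tables (internal; built automatically
#'   when `NULL`).
#' @return A list: `effect`, `gene_id`, `residue_index`, `aa_ref`, `aa_alt`,
#'   `all_hits` (tibble of every overlapping-gene classification).
#' @export
classify_snv <- function(genome, models, contig, pos, ref, alt,
                         unaligned_contigs = character(), tabs = NULL) {
  stopifnot(nchar(ref) == 1, nchar(alt) == 1)
  tabs <- tabs %||% prepare_gene_tables(genome, models)
  gbase <- substr(genome[[contig]], pos + 1, pos + 1)
  if (gbase != ref) {
    abort(paste0("ref allele mismatch at ", contig, ":", pos + 1,
                 " (genome has ", gbase, ", call says ", ref, ")"))
  }
  if (contig %in% unaligned_contigs) {
    return(list(effect = "unaligned", gene_id = NA_character_,
                residue_index = NA_integer_, aa_ref = NA_character_,
                aa_alt = NA_character_, all_hits = NULL))
  }
  hits <- list()
  for (i in which(models$contig == contig)) {
    tab <- tabs[[i]]
    if (pos < tab$span[1] || pos >= tab$span[2]) next
    ci <- match(pos, tab$gpos)
    if (is.na(ci)) {
      hits[[length(hits) + 1]] <- tibble(gene_id = models$gene_id[i],
                                         effect = "intronic",
                                         residue_index = NA_integer_,
                                         aa_ref = NA_character_,
                                         aa_alt = NA_character_)
    } else if (!models$complete[i]) {
      hits[[length(hits) + 1]] <- tibble(gene_id = models$gene_id[i],
                                         effect = "incomplete_gene",
                                         residue_index = NA_integer_,
                                         aa_ref = NA_character_,
                                         aa_alt = NA_character_)
    } else {
      alt_tx <- if (tab$strand == "-") complement_base(alt) else alt
      cc <- classify_codon_change(tab$cds_seq, ci, alt_tx)
      hits[[length(hits) + 1]] <- tibble(gene_id = models$gene_id[i],
                                         effect = cc$effect,
                                         residue_index = cc$residue_index,
                                         aa_ref = cc$aa_ref,
                                         aa_alt = cc$aa_alt)
    }
  }
  if (length(hits) == 0) {
    return(list(effect = "intergenic", gene_id = NA_character_,
                residue_index = NA_integer_, aa_ref = NA_character_,
                aa_alt = NA_character_, all_hits = NULL))
  }
  hits <- bind_rows(hits)
  best <- hits[which.max(EFFECT_SEVERITY[hits$effect]), ]
  list(effect = best$effect, gene_id = best$gene_id,
       residue_index = best$residue_index, aa_ref = best$aa_ref,
       aa_alt = best$aa_alt, all_hits = hits)
}

#' Classify a single indel against the gene models
#'
#' Indels are classified by their leftmost affected base (the base after the
#' VCF anchor). Within the CDS of a complete gene an indel whose length is not
#' divisible by 3 is a `frameshift`, otherwise an `inframe_indel`; intronic /
#' intergenic / incomplete-gene / unaligned cases follow the SNV rules.
#'
#' @inheritParams classify_snv
#' @param ref,alt Anchored, normalised alleles (unequal lengths).
#' @return A list: `effect`, `gene_id`, `all_hits`.
#' @export
classify_indel <- function(genome, models, contig, pos, ref, alt,
                           unaligned_contigs = character(), tabs = NULL) {
  stopifnot(nchar(ref) != nchar(alt))
  tabs <- tabs %||% prepare_gene_tables(genome, models)
  if (contig %in% unaligned_contigs) {
    return(list(effect = "unaligned", gene_id = NA_character_, all_hits = NULL))
  }
  affected <- pos + 1L   # first inserted/deleted base after the anchor
  len <- abs(nchar(ref) - nchar(alt))
  hits <- list()
  for (i in which(models$contig == contig)) {
    tab <- tabs[[i]]
    if (affected < tab$span[1] || affected >= tab$span[2]) next
    in_cds <- affected %in% tab$gpos
    eff <- if (!in_cds) {
      "intronic"
    } else if (!models$complete[i]) {
      "incomplete_gene"
    } else if (len %% 3L != 0L) {
      "frameshift"
    } else {
      "inframe_indel"
    }
    hits[[length(hits) + 1]] <- tibble(gene_id = models$gene_id[i], effect = eff)
  }
  if (length(hits) == 0) {
    return(list(effect = "intergenic", gene_id = NA_character_, all_hits = NULL))
  }
  hits <- bind_rows(hits)
  best <- hits[which.max(EFFECT_SEVERITY[hits$effect]), ]
  list(effect = best$effect, gene_id = best$gene_id, all_hits = hits)
}

#' Annotate a table of variants with their effects
#'
#' Vectorised wrapper over [classify_snv()] / [classify_indel()]; also attaches
#' the forward-strand trinucleotide context of every SNV.
#'
#' @param variants Call tibble ([read_variants()] layout).
#' @param models Gene-model tibble.
#' @param genome A `podevol_genome`.
#' @param unaligned_contigs Contigs whose variants are tagged `unaligned`.
#' @return The input tibble with added columns `effect`, `gene_id`,
#'   `residue_index`, `aa_ref`, `aa_alt`, `context`.
#' @export
classify_variants <- function(variants, models, genome,
                              unaligned_contigs = character()) {
  n <- nrow(variants)
  tabs <- prepare_gene_tables(genome, models)
  effect <- gene_id <- aa_ref <- aa_alt <- rep(NA_character_, n)
  residue_index <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    if (v$variant_class == "SNV") {
      r <- classify_snv(genome, models, v$contig, v$pos, v$ref, v$alt,
                        unaligned_contigs, tabs = tabs)
      residue_index[i] <- r$residue_index
      aa_ref[i] <- r$aa_ref
      aa_alt[i] <- r$aa_alt
    } else {
      r <- classify_indel(genome, models, v$contig, v$pos, v$ref, v$alt,
                          unaligned_contigs, tabs = tabs)
    }
    effect[i] <- r$effect
    gene_id[i] <- r$gene_id
  }
  variants$effect <- effect
  variants$gene_id <- gene_id
  variants$residue_index <- residue_index
  variants$aa_ref <- aa_ref
  variants$aa_alt <- aa_alt
  ctx <- rep(NA_character_, n)
  snv <- variants$variant_class == "SNV"
  for (ct in unique(variants$contig[snv])) {
    sel <- snv & variants$contig == ct
    ctx[sel] <- trinucleotide_context(genome, ct, variants$pos[sel])
  }
  variants$context <- ctx
  variants
}

BASES <- c("A", "C", "G", "T")

# Precomputed per-position effect arrays used by the permutation engine.
# For every contig: class_code[alt_base 1..4, pos 1..L] (codes into
# EFFECT_LEVELS; 0 where alt == ref base) and gene_idx[pos] (row index into
# `models` owning the coding/intronic classification; 0 in intergenic runs).
effect_map <- function(genome, models, unaligned_contigs = character()) {
  maps <- list()
  code_of <- setNames(seq_along(EFFECT_LEVELS), EFFECT_LEVELS)
  for (ct in names(genome)) {
    L <- nchar(genome[[ct]])
    cls <- matrix(0L, nrow = 4, ncol = L)
    gidx <- integer(L)
    if (ct %in% unaligned_contigs) {
      cls[] <- code_of[["unaligned"]]
      maps[[ct]] <- list(class = cls, gene = gidx)
      next
    }
    cls[] <- code_of[["intergenic"]]
    prio <- matrix(EFFECT_SEVERITY[["intergenic"]], nrow = 4, ncol = L)
    rows <- which(models$contig == ct)
    # lower-severity layers first so coding information wins at overlaps
    for (i in rows) {
      tab <- gene_cds_table(genome, models[i, ])
      span_pos <- seq.int(tab$span[1], tab$span[2] - 1L)
      intron <- setdiff(span_pos, tab$gpos)
      if (length(intron)) {
        lay <- EFFECT_SEVERITY[["intronic"]]
        upd <- intron[prio[1, intron + 1] < lay]
        if (length(upd)) {
          cls[, upd + 1] <- code_of[["intronic"]]
          prio[, upd + 1] <- lay
          gidx[upd + 1] <- i
        }
      }
      if (!models$complete[i]) {
        lay <- EFFECT_SEVERITY[["incomplete_gene"]]
        upd <- tab$gpos[prio[1, tab$gpos + 1] < lay]
        if (length(upd)) {
          cls[, upd + 1] <- code_of[["incomplete_gene"]]
          prio[, upd + 1] <- lay
          gidx[upd + 1] <- i
        }
        next
      }
      # complete gene: classify all 3 substitutions at every CDS position
      s <- tab$cds_seq
      nc <- nchar(s)
      bases_tx <- strsplit(s, NULL)[[1]]
      codon_index <- (seq_len(nc) - 1L) %/% 3L
      pos_in_codon <- (seq_len(nc) - 1L) %% 3L
      cstart <- codon_index * 3L + 1L
      codons <- substring(s, cstart, cstart + 2L)
      aa_ref_v <- unname(Biostrings::GENETIC_CODE[codons])
      for (b in BASES) {
        alt_tx <- b
        differ <- bases_tx != alt_tx
        if (!any(differ)) next
        pic <- pos_in_codon[differ]
        cd <- codons[differ]
        mut <- paste0(substr(cd, 1, pic), alt_tx, substr(cd, pic + 2L, 3L))
        aa_alt_v <- unname(Biostrings::GENETIC_CODE[mut])
        aa0 <- aa_ref_v[differ]
        eff <- ifelse(aa_alt_v == aa0, "synonymous",
                      ifelse(aa_alt_v == "*", "nonsense", "missense"))
        # genomic alt base: complement back on the minus strand
        alt_gen <- if (tab$strand == "-") complement_base(b) else b
        bi <- match(alt_gen, BASES)
        gp <- tab$gpos[differ]
        lay <- EFFECT_SEVERITY[eff]
        upd <- lay > prio[bi, gp + 1]
        if (any(upd)) {
          cls[bi, gp[upd] + 1] <- code_of[eff[upd]]
          prio[bi, gp[upd] + 1] <- lay[upd]
          gidx[gp[upd] + 1] <- i
        }
      }
    }
    maps[[ct]] <- list(class = cls, gene = gidx)
  }
  structure(list(maps = maps, models = models, levels = EFFECT_LEVELS),
            class = "podevol_effect_map")
}
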