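# Amino-acid polarity and volume constants (Grantham 1974), the inputs of the
# Miyata, Miyazawa & Yasunaga (1979) physicochemical distance.
AA_POLARITY <- c(A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5,
                 E = 12.3, G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3,
                 M = 5.7, F = 5.2, P = 8.0, S = 9.2, T = 8.6, W = 5.4,
                 Y = 6.2, V = 5.9)
AA_VOLUME <- c(A = 31, R = 124, N = 56, D = 54, C = 55, Q = 85, E = 83,
               G = 3, H = 96, I = 111, L = 111, K = 119, M = 105, F = 132,
               P = 32.5, S = 32, T = 61, W = 170, Y = 136, V = 84)

#' The Miyata physicochemical distance matrix
#'
#' Recomputes the 20x20 amino-acid distance matrix
#' `d(a, b) = sqrt((dp / sd_p)^2 + (dv / sd_v)^2)` where `dp`, `dv` are the
#' polarity and volume differences and `sd_p`, `sd_v` the standard deviations
#' of the 20 polarity and volume values.
#'
#' @return A symmetric 20x20 numeric matrix with zero diagonal, dimnames are
#'   one-letter amino-acid codes.
#' @export
miyata_matrix <- function() {
  sp <- sd(AA_POLARITY)
  sv <- sd(AA_VOLUME)
  dp <- outer(AA_POLARITY, AA_POLARITY, "-") / sp
  dv <- outer(AA_VOLUME, AA_VOLUME, "-") / sv
  sqrt(dp^2 + dv^2)
}

#' Miyata distance between two amino acids
#'
#' @param residue_a,residue_b One-letter amino-acid codes (vectorised).
#' @param table Distance matrix, by default [miyata_matrix()].
#' @return Numeric distances.
#' @export
miyata_distance <- function(residue_a, residue_b, table = miyata_matrix()) {
  a <- toupper(residue_a); b <- toupper(residue_b)
  bad <- !(a %in% rownames(table)) | !(b %in% rownames(table))
  if (any(bad)) {
    abort(paste0("unknown amino acid code(s): ",
                 paste(unique(c(a[bad], b[bad])), collapse = ", ")))
  }
  table[cbind(a, b)]
}

#' Compare Miyata distances of two substitution sets
#'
#' Computes per-substitution Miyata distances for the amino-acid changes fixed
#' during the experiment and for those accumulated in long-term divergence,
#' and compares the group means with a two-sample two-tailed t-test (pooled
#' variance by default; Welch behind `welch = TRUE`). With both groups
#' degenerate (zero variance) and equal means, `p = 1` by convention.
#'
#' @param experimental_changes,divergence_changes Tibbles (or data frames)
#'   with columns `aa_ref` and `aa_alt`, one row per substitution.
#' @param welch Use Welch's unequal-variance t-test.
#' @param table Distance matrix, by default [miyata_matrix()].
#' @return A tibble: `mean_experimental`, `mean_divergence`, `n_experimental`,
#'   `n_divergence`, `t`, `p`.
#' @export
compare_miyata_means <- function(experimental_changes, divergence_changes,
                                 welch = FALSE, table = miyata_matrix()) {
  if (nrow(experimental_changes) == 0 || nrow(divergence_changes) == 0) {
    abort("both substitution lists must be nonempty")
  }
  d1 <- miyata_distance(experimental_changes$aa_ref,
                        experimental_changes$aa_alt, table)
  d2 <- miyata_distance(divergence_changes$aa_ref,
                        divergence_changes$aa_alt, table)
  out <- tibble(mean_experimental = mean(d1), mean_divergence = mean(d2),
                n_experimental = length(d1), n_divergence = length(d2),
                t = NA_real_, p = NA_real_)
  if (length(d1) < 2 || length(d2) < 2) {
    warn("a substitution list has fewer than 2 entries; t-test undefined")
    return(out)
  }
  if (sd(d1) == 0 && sd(d2) == 0) {
    out$t <- if (mean(d1) == mean(d2)) 0 else Inf
    out$p <- if (mean(d1) == mean(d2)) 1 else 0
    return(out)
  }
  tt <- t.test(d1, d2, var.equal = !welch)
  out$t <- unname(tt$statistic)
  out$p <- tt$p.value
  out
}
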