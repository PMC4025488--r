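#' Per-locus allele frequencies from non-missing genotypes
#'
#' Frequency of allele A at each locus, estimated only from the lines with
#' a genotype call there: with `N1, N2, N3` counts of codes 1/2/3 among
#' non-missing cells, `p = (2*N1 + N2) / (2*(N1 + N2 + N3))`. Loci with no
#' valid genotype are flagged (`p = NA`).
#'
#' @param g a [genotype_matrix()].
#' @return data.frame with columns `marker_id`, `p`, `n_valid`.
#' @export
allele_freqs <- function(g) {
  validate_genotype_matrix(g)
  x <- unclass(g)
  n1 <- colSums(x == 1L, na.rm = TRUE)
  n2 <- colSums(x == 2L, na.rm = TRUE)
  n3 <- colSums(x == 3L, na.rm = TRUE)
  n_valid <- n1 + n2 + n3
  p <- ifelse(n_valid > 0, (2 * n1 + n2) / (2 * n_valid), NA_real_)
  data.frame(marker_id = colnames(g), p = p, n_valid = as.integer(n_valid),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Observed/expected heterozygosity and inbreeding coefficient
#'
#' Missing-aware per-locus diversity statistics with all lines pooled (no
#' group stratification): `Ho_l = N2 / n_valid_l`,
#' `He_l = 1 - p_l^2 - (1-p_l)^2`, and `F_l = (He_l - Ho_l) / He_l` where
#' `He_l > 0`. The summary values are the means of `Ho_l` and `He_l` over
#' loci with at least one valid genotype, and the mean of `F_l` over loci
#' with `He_l > 0` (the primary F summary). The ratio-of-means form
#' `1 - mean(Ho)/mean(He)` is also reported as `f_ratio` for comparison.
#'
#' @param g a [genotype_matrix()].
#' @return object of class `diversity_summary`: list with `ho`, `he`, `f`,
#'   `f_ratio`, `n_loci_used`, `n_loci_f`, and a `per_locus` data.frame.
#' @export
het_stats <- function(g) {
  validate_genotype_matrix(g)
  af <- allele_freqs(g)
  n2 <- colSums(unclass(g) == 2L, na.rm = TRUE)
  ho_l <- ifelse(af$n_valid > 0, n2 / af$n_valid, NA_real_)
  he_l <- ifelse(af$n_valid > 0, 1 - af$p^2 - (1 - af$p)^2, NA_real_)
  f_l <- ifelse(!is.na(he_l) & he_l > 0, (he_l - ho_l) / he_l, NA_real_)
  used <- af$n_valid > 0
  if (!any(used)) stop("no locus with a valid genotype")
  f_ok <- !is.na(f_l)
  if (!any(f_ok))
    warning("no polymorphic locus: inbreeding coefficient undefined")
  structure(list(
    ho = mean(ho_l[used]),
    he = mean(he_l[used]),
    f = if (any(f_ok)) mean(f_l[f_ok]) else NA_real_,
    f_ratio = if (mean(he_l[used]) > 0)
      1 - mean(ho_l[used]) / mean(he_l[used]) else NA_real_,
    n_loci_used = sum(used),
    n_loci_f = sum(f_ok),
    per_locus = data.frame(marker_id = af$marker_id, ho = ho_l, he = he_l,
                           f = f_l, p = af$p, n_valid = af$n_valid,
                           stringsAsFactors = FALSE)),
    class = "diversity_summary")
}

#' @method print diversity_summary
#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf(
    "diversity_summary over %d loci: Ho = %.4f (%.2f%%), He = %.4f, F = %.4f\n",
    x$n_loci_used, x$ho, 100 * x$ho, x$he, x$f))
  invisible(x)
}

# pairwise squared genotypic distances on the allele-count scale, with
# missing loci compensated by the L / L_valid(i,j) rescaling
pairwise_sq_dist <- function(g, rescale_missing = TRUE,
                             pair_fallback = c("error", "mean")) {
  pair_fallback <- match.arg(pair_fallback)
  x <- as_allele_counts(g)
  L <- ncol(x)
  m <- (!is.na(x)) * 1.0
  x0 <- ifelse(is.na(x), 0, x)
  cross <- tcrossprod(x0)
  ssq <- tcrossprod(x0^2, m)
  d2 <- ssq + t(ssq) - 2 * cross
  lv <- tcrossprod(m)
  if (rescale_missing) d2 <- d2 * (L / lv) else d2 <- d2
  diag(d2) <- 0
  und <- lv == 0 & row(lv) != col(lv)
  if (any(und)) {
    if (pair_fallback == "error")
      stop("line pair(s) with zero co-observed loci; set pair_fallback = ",
           "'mean' to substitute the mean distance")
    warning(sum(und) / 2, " line pair(s) with zero co-observed loci ",
            "assigned the mean defined distance")
    d2[und] <- mean(d2[!und & row(lv) != col(lv)])
  }
  list(d2 = d2, valid = lv)
}

#' AMOVA-based Phi-ST for grouped genotypes
#'
#' One-level analysis of molecular variance on pairwise squared genotypic
#' distances for codominant biallelic data. Distances use the allele-count
#' view (`code 1 -> 2, 2 -> 1, 3 -> 0` copies of allele A):
#' `d2(i,j) = (L / L_valid(i,j)) * sum over co-observed loci (x_i - x_j)^2`,
#' where the `L / L_valid` rescaling compensates missing loci (disable with
#' `rescale_missing = FALSE`). Then `SS_total = sum(d2_pairs) / N`,
#' `SS_within = sum over groups of within-pair d2 / n_g`,
#' `SS_among = SS_total - SS_within`, mean squares on `K - 1` and `N - K`
#' degrees of freedom, `n0 = (N - sum(n_g^2)/N) / (K - 1)`,
#' `Va = (MS_among - MS_within) / n0`, `Vw = MS_within`, and
#' `Phi_ST = Va / (Va + Vw)`, reported unclipped (it may be negative).
#'
#' @param g a [genotype_matrix()].
#' @param groups a [group_assignment()] with K >= 2 groups over the lines
#'   of `g`.
#' @param rescale_missing apply the `L / L_valid` missing-loci rescaling?
#' @param pair_fallback what to do with a line pair sharing no co-observed
#'   locus: `"error"` (default) or `"mean"` (substitute the mean defined
#'   distance, with a warning).
#' @return object of class `amova_result`.
#' @export
amova_phi <- function(g, groups, rescale_missing = TRUE,
                      pair_fallback = c("error", "mean")) {
  validate_genotype_matrix(g)
  groups <- align_groups(g, groups)
  K <- nlevels(groups)
  if (K < 2L) stop("AMOVA needs K >= 2 groups")
  N <- nrow(g)
  ng <- as.integer(table(groups))
  pd <- pairwise_sq_dist(g, rescale_missing, pair_fallback)
  d2 <- pd$d2
  upper <- upper.tri(d2)
  ss_total <- sum(d2[upper]) / N
  ss_within <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    if (length(idx) > 1L) {
      dg <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(dg[upper.tri(dg)]) / length(idx)
    }
  }
  ss_among <- ss_total - ss_within
  df_among <- K - 1L
  df_within <- N - K
  ms_among <- ss_among / df_among
  ms_within <- if (df_within > 0) ss_within / df_within else NA_real_
  n0 <- (N - sum(ng^2) / N) / df_among
  va <- (ms_among - ms_within) / n0
  vw <- ms_within
  structure(list(ss_total = ss_total, ss_among = ss_among,
                 ss_within = ss_within, df_among = df_among,
                 df_within = df_within, ms_among = ms_among,
                 ms_within = ms_within, n0 = n0, va = va, vw = vw,
                 phi_st = va / (va + vw), n_lines = N, k = K,
                 group_sizes = stats::setNames(ng, levels(groups))),
            class = "amova_result")
}

#' @method print amova_result
#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA: %d lines in %d groups\n", x$n_lines, x$k))
  cat(sprintf("  SS among  = %10.3f (df = %d)\n", x$ss_among, x$df_among))
  cat(sprintf("  SS within = %10.3f (df = %d)\n", x$ss_within, x$df_within))
  cat(sprintf("  Va = %.4f, Vw = %.4f, Phi_ST = %.4f (%.2f%%)\n",
              x$va, x$vw, x$phi_st, 100 * x$phi_st))
  invisible(x)
}
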