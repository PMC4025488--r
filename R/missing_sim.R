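#' Mask a prescribed fraction of genotype cells at random
#'
#' Draws exactly `round(m * lines * markers)` distinct cells uniformly
#' without replacement from all cells of the matrix — ignoring pre-existing
#' missingness, line and marker structure — and sets them to missing. Cells
#' that were already missing may be drawn and simply remain missing, so on
#' data with pre-existing missingness the realized missing fraction can be
#' slightly below `m` plus the baseline; on complete data it equals `m`
#' exactly (to rounding).
#'
#' @param g a [genotype_matrix()].
#' @param m target missing level in `[0, 1]`.
#' @param seed optional RNG seed (caller's RNG state is preserved).
#' @return list with `genotypes` (masked matrix) and `mask` (class
#'   `missing_mask`): a two-column integer matrix of (line, marker) indices
#'   of the drawn cells, with attribute `missing_level = m`.
#' @export
apply_random_missing <- function(g, m, seed = NULL) {
  validate_genotype_matrix(g)
  stopifnot(m >= 0, m <= 1)
  N <- length(g)
  k <- round(m * N)
  cells <- with_seed(seed, sample.int(N, k))
  out <- g
  out[cells] <- NA_integer_
  mask <- arrayInd(cells, dim(g))
  colnames(mask) <- c("line", "marker")
  mask <- structure(mask, missing_level = m,
                    class = c("missing_mask", "matrix", "array"))
  list(genotypes = out, mask = mask)
}

#' @method print missing_mask
#' @export
print.missing_mask <- function(x, ...) {
  cat(sprintf("missing_mask: %d cells at missing level %.3f\n",
              nrow(x), attr(x, "missing_level")))
  invisible(x)
}

#' Random subsample of lines and markers
#'
#' Simple random sample without replacement of `n_lines` lines and
#' `n_markers` markers, as taken before every assessment run (the study
#' design uses 130 lines x 1000 markers). When `require_all_groups` is
#' `TRUE`, line draws are retried (up to `max_retries`, logged via a
#' message) until every group is represented. The returned index record
#' extracts the same cells from any matrix aligned with `g`, so a masked
#' subset can be paired with its original genotypes.
#'
#' @param g a [genotype_matrix()].
#' @param groups a [group_assignment()] covering the lines of `g`.
#' @param n_lines,n_markers subsample dimensions.
#' @param seed optional RNG seed.
#' @param require_all_groups resample until every group is represented?
#' @param max_retries bound on resampling attempts.
#' @return list with `genotypes`, `groups` (both subset), and the index
#'   record `line_idx`, `marker_idx`.
#' @export
subsample_genotypes <- function(g, groups, n_lines, n_markers, seed = NULL,
                                require_all_groups = TRUE, max_retries = 100L) {
  validate_genotype_matrix(g)
  groups <- align_groups(g, groups)
  stopifnot(n_lines >= 1, n_lines <= nrow(g),
            n_markers >= 1, n_markers <= ncol(g))
  K <- nlevels(groups)
  if (require_all_groups && n_lines < K)
    stop("cannot represent all ", K, " groups with ", n_lines, " lines")
  with_seed(seed, {
    line_idx <- sample.int(nrow(g), n_lines)
    if (require_all_groups) {
      tries <- 0L
      while (length(unique(groups[line_idx])) < K) {
        tries <- tries + 1L
        if (tries > max_retries)
          stop("a group could not be represented after ", max_retries,
               " retries")
        line_idx <- sample.int(nrow(g), n_lines)
      }
      if (tries > 0L)
        message("line subsample redrawn ", tries,
                " time(s) to represent every group")
    }
    marker_idx <- sample.int(ncol(g), n_markers)
    sub <- g[line_idx, marker_idx]
    list(genotypes = sub,
         groups = align_groups(sub, groups),
         line_idx = line_idx, marker_idx = marker_idx)
  })
}
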