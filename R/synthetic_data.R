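# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Configuration for the synthetic genotype generator
#'
#' Describes a structured inbred population: `n_groups` groups of
#' `lines_per_group` diploid lines genotyped at `n_markers` independent
#' biallelic SNPs. Ancestral minor-allele frequencies follow one of three
#' regimes; group frequencies drift from the ancestral ones under the
#' Balding-Nichols model with differentiation parameter `fst_target`;
#' genotypes within a group are drawn with within-group inbreeding
#' coefficient `f_is`.
#'
#' @param n_groups number of groups K (>= 1; AMOVA needs K >= 2).
#' @param lines_per_group diploid lines per group.
#' @param n_markers number of independent SNP markers L.
#' @param maf_regime ancestral minor-allele-frequency regime:
#'   `"uniform"` (Uniform(0.05, 0.5); maize-like flat spectrum),
#'   `"high_skew"` (Beta(3, 2) rescaled to (0.05, 0.5); excess of common
#'   minor alleles, rice-like), or `"low_skew"` (Beta(0.6, 3) rescaled to
#'   (0.01, 0.5); strong excess of rare minor alleles, wheat-like).
#' @param fst_target Balding-Nichols theta in `[0, 1)`; 0 means no
#'   differentiation.
#' @param f_is within-group inbreeding coefficient in `[0, 1]`.
#' @param baseline_missing fraction of cells masked at random in the
#'   generated matrix (pre-existing missingness), in `[0, 1)`.
#' @param seed RNG seed making the generated population reproducible.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_groups = 4, lines_per_group = 100,
                             n_markers = 5000,
                             maf_regime = c("uniform", "high_skew", "low_skew"),
                             fst_target = 0.05, f_is = 0.7,
                             baseline_missing = 0, seed = 1L) {
  maf_regime <- match.arg(maf_regime)
  stopifnot(n_groups >= 1, lines_per_group >= 1, n_markers >= 1,
            fst_target >= 0, fst_target < 1, f_is >= 0, f_is <= 1,
            baseline_missing >= 0, baseline_missing < 1)
  structure(list(n_groups = as.integer(n_groups),
                 lines_per_group = as.integer(lines_per_group),
                 n_markers = as.integer(n_markers),
                 maf_regime = maf_regime,
                 fst_target = fst_target, f_is = f_is,
                 baseline_missing = baseline_missing,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Crop-style generator presets
#'
#' Ready-made [synthetic_config()]s emulating the three allele-frequency /
#' inbreeding regimes the assessment is designed around: a maize-like
#' outcrossing panel with a flat minor-allele spectrum (Ho ~ 10%), a
#' rice-like selfing panel with an excess of common minor alleles
#' (Ho ~ 0.5%), and a wheat-like selfing panel dominated by rare minor
#' alleles (Ho ~ 0.3%), each with four groups and among-group Phi-ST in the
#' 1.5-5% range.
#'
#' @param crop one of `"corn"`, `"rice"`, `"wheat"`.
#' @param ... overrides passed to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
crop_preset <- function(crop = c("corn", "rice", "wheat"), ...) {
  crop <- match.arg(crop)
  base <- switch(crop,
    corn  = list(n_groups = 4, lines_per_group = 100, n_markers = 5000,
                 maf_regime = "uniform", fst_target = 0.045, f_is = 0.70),
    rice  = list(n_groups = 4, lines_per_group = 99, n_markers = 5000,
                 maf_regime = "high_skew", fst_target = 0.044, f_is = 0.985),
    wheat = list(n_groups = 4, lines_per_group = 85, n_markers = 5000,
                 maf_regime = "low_skew", fst_target = 0.015, f_is = 0.98))
  over <- list(...)
  base[names(over)] <- over
  do.call(synthetic_config, base)
}

#' Sample ancestral minor-allele frequencies
#'
#' Draws per-marker ancestral minor-allele frequencies under one of the
#' three regimes (see [synthetic_config()]). Uses the current RNG state.
#'
#' @param regime `"uniform"`, `"high_skew"` or `"low_skew"`.
#' @param L number of markers.
#' @return numeric vector of length `L` with values in (0, 0.5].
#' @export
sample_maf <- function(regime = c("uniform", "high_skew", "low_skew"), L) {
  regime <- match.arg(regime)
  stopifnot(L >= 1)
  switch(regime,
    uniform   = stats::runif(L, 0.05, 0.5),
    high_skew = 0.05 + 0.45 * stats::rbeta(L, 3, 2),
    low_skew  = 0.01 + 0.49 * stats::rbeta(L, 0.6, 3))
}

#' Generate a structured synthetic genotype population
#'
#' For each marker an ancestral minor-allele frequency is drawn by
#' [sample_maf()]; each group's frequency drifts under the Balding-Nichols
#' model `p_g ~ Beta(p(1-theta)/theta, (1-p)(1-theta)/theta)` with
#' `theta = fst_target` (`p_g = p` when `theta = 0`). Writing `q` for the
#' within-group frequency of allele A (the major allele at the ancestral
#' level), genotypes follow the inbreeding F-model
#' `P(AA) = q^2 + f_is*q*(1-q)`, `P(Aa) = 2q(1-q)(1-f_is)`,
#' `P(aa) = (1-q)^2 + f_is*q*(1-q)`. Finally `baseline_missing` of cells are
#' masked uniformly at random. Deterministic given `cfg` (including its
#' seed).
#'
#' @param cfg a [synthetic_config()].
#' @return list with elements `genotypes` (a [genotype_matrix()]), `groups`
#'   (a [group_assignment()]), and `maf` (the ancestral frequencies).
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    K <- cfg$n_groups; n <- cfg$lines_per_group; L <- cfg$n_markers
    theta <- cfg$fst_target; f <- cfg$f_is
    p <- sample_maf(cfg$maf_regime, L)        # ancestral minor-allele freq
    codes <- matrix(NA_integer_, nrow = K * n, ncol = L)
    for (g in seq_len(K)) {
      if (theta > 0) {
        pg <- stats::rbeta(L, p * (1 - theta) / theta,
                           (1 - p) * (1 - theta) / theta)
      } else pg <- p
      q <- 1 - pg                              # frequency of allele A
      p_aa <- q^2 + f * q * (1 - q)            # code 1
      p_het <- 2 * q * (1 - q) * (1 - f)       # code 2
      u <- matrix(stats::runif(n * L), nrow = n)
      cg <- matrix(3L, nrow = n, ncol = L)
      cg[sweep(u, 2, p_aa + p_het, "<=")] <- 2L
      cg[sweep(u, 2, p_aa, "<=")] <- 1L
      codes[(g - 1L) * n + seq_len(n), ] <- cg
    }
    if (cfg$baseline_missing > 0) {
      nmiss <- round(cfg$baseline_missing * length(codes))
      codes[sample.int(length(codes), nmiss)] <- NA_integer_
    }
    line_ids <- paste0("G", rep(seq_len(K), each = n), "_L",
                       rep(seq_len(n), times = K))
    gm <- genotype_matrix(codes, line_ids = line_ids,
                          marker_ids = paste0("M", seq_len(L)))
    grp <- group_assignment(paste0("G", rep(seq_len(K), each = n)),
                            line_ids = line_ids)
    list(genotypes = gm, groups = grp, maf = p)
  })
}
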