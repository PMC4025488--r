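#' Relative bias of an estimate against a reference
#'
#' `100 * (est - ref) / ref`, signed: a downward bias is negative.
#'
#' @param est statistic estimated from missing or imputed data.
#' @param ref the same statistic from the original data (non-zero).
#' @return percent bias; `NA` with a warning when `ref == 0`.
#' @export
relative_bias <- function(est, ref) {
  out <- 100 * (est - ref) / ref
  if (any(ref == 0, na.rm = TRUE)) {
    warning("relative bias undefined for zero reference")
    out[ref == 0] <- NA_real_
  }
  out
}

#' Imputation accuracy with genotype-class breakdown
#'
#' Over the masked cells whose original genotype is known, `m_pct` is the
#' percentage whose imputed genotype equals the original; `aa_pct`,
#' `het_pct` and `maj_pct` split the matched cells by the class of the
#' ORIGINAL genotype — minor homozygote, heterozygote, major homozygote —
#' where the major homozygote at a locus is decided by [allele_freqs()] on
#' the original data (frequency ties go to the code-1 homozygote). The four
#' class percentages sum to `m_pct`.
#'
#' @param original the original [genotype_matrix()].
#' @param mask a `missing_mask` (or two-column line/marker index matrix)
#'   aligned with `original`.
#' @param imputed the imputed matrix, aligned with `original`.
#' @return object of class `accuracy_breakdown`: list with `m_pct`,
#'   `aa_pct`, `het_pct`, `maj_pct`, `denominator`.
#' @export
imputation_accuracy <- function(original, mask, imputed) {
  stopifnot(all(dim(original) == dim(imputed)), nrow(mask) > 0L)
  cells <- cbind(mask[, 1L], mask[, 2L])
  orig <- unclass(original)[cells]
  imp <- unclass(imputed)[cells]
  known <- !is.na(orig)
  denom <- sum(known)
  if (denom == 0L) {
    warning("no masked cell with a known original genotype")
    return(structure(list(m_pct = NA_real_, aa_pct = NA_real_,
                          het_pct = NA_real_, maj_pct = NA_real_,
                          denominator = 0L),
                     class = "accuracy_breakdown"))
  }
  p <- allele_freqs(original)$p
  major_code <- ifelse(p >= 0.5, 1L, 3L)     # ties -> code-1 homozygote
  oc <- orig[known]
  cls <- ifelse(oc == 2L, "het",
                ifelse(oc == major_code[cells[known, 2L]], "maj", "aa"))
  matched <- !is.na(imp[known]) & imp[known] == oc
  structure(list(
    m_pct = 100 * sum(matched) / denom,
    aa_pct = 100 * sum(matched & cls == "aa") / denom,
    het_pct = 100 * sum(matched & cls == "het") / denom,
    maj_pct = 100 * sum(matched & cls == "maj") / denom,
    denominator = denom), class = "accuracy_breakdown")
}

#' @method print accuracy_breakdown
#' @export
print.accuracy_breakdown <- function(x, ...) {
  cat(sprintf(
    "imputation accuracy: M = %.1f%% (aa %.1f, Aa %.1f, AA %.1f) over %d cells\n",
    x$m_pct, x$aa_pct, x$het_pct, x$maj_pct, x$denominator))
  invisible(x)
}

#' Assessment configuration
#'
#' Settings for the full simulation loop: missing levels, number of runs,
#' subsample dimensions (the study design is 130 lines x 1000 markers with
#' 100 runs per level), the methods compared (`"NONE"` = missing data
#' without imputation, plus `"RF"`, `"PP"`, `"NI"`), and a master seed from
#' which every per-(level, run) RNG stream is derived deterministically.
#'
#' @param missing_levels fractions in (0, 1] (plus 0 allowed for checks).
#' @param n_runs simulation runs per level.
#' @param n_lines,n_markers subsample dimensions.
#' @param methods subset of `c("NONE", "RF", "PP", "NI")`.
#' @param seed master seed.
#' @param n_pcs,tol,max_iter PCA imputer settings.
#' @param n_trees,mtry,rf_iter RF imputer settings.
#' @param pair_fallback distance fallback for pairs with no co-observed
#'   locus (passed to [smc_distance()] and [amova_phi()]); the harness
#'   default `"mean"` keeps high-missing runs alive.
#' @return an `assessment_config` list.
#' @export
assessment_config <- function(missing_levels = seq(0.1, 0.9, by = 0.1),
                              n_runs = 100, n_lines = 130, n_markers = 1000,
                              methods = c("NONE", "RF", "PP", "NI"),
                              seed = 1L, n_pcs = 2, tol = 1e-5,
                              max_iter = 1000, n_trees = 100, mtry = NULL,
                              rf_iter = 1, pair_fallback = "mean") {
  methods <- match.arg(methods, c("NONE", "RF", "PP", "NI"),
                       several.ok = TRUE)
  stopifnot(all(missing_levels >= 0), all(missing_levels <= 1), n_runs >= 1)
  structure(list(missing_levels = missing_levels,
                 n_runs = as.integer(n_runs),
                 n_lines = as.integer(n_lines),
                 n_markers = as.integer(n_markers),
                 methods = methods, seed = as.integer(seed),
                 n_pcs = n_pcs, tol = tol, max_iter = max_iter,
                 n_trees = n_trees, mtry = mtry, rf_iter = rf_iter,
                 pair_fallback = pair_fallback),
            class = "assessment_config")
}

# diversity + differentiation + representative-sample topology for one
# matrix; quartet with the star tie rule when K = 4, an NJ tree for other
# K >= 3, no topology otherwise
.run_stats <- function(g, groups, rep_lines, pair_fallback) {
  hs <- het_stats(g)
  am <- amova_phi(g, groups, pair_fallback = pair_fallback)
  topo <- if (length(rep_lines) == 4L) {
    quartet_split(smc_distance(g[rep_lines, ], pair_fallback = "mean"))
  } else if (length(rep_lines) >= 3L) {
    nj_tree(smc_distance(g[rep_lines, ], pair_fallback = "mean"))
  } else NULL
  list(ho = hs$ho, he = hs$he, f = hs$f, phi_st = am$phi_st, quartet = topo)
}

#' Run the full assessment loop
#'
#' For every missing level and run: (1) mask the whole input matrix at the
#' level; (2) take the `n_lines` x `n_markers` subsample and the aligned
#' original subset; (3) impute the masked subset with each requested
#' method; (4) compute pooled Ho/He/F and AMOVA Phi-ST on the original,
#' missing, and imputed subsets; (5) draw one representative line per
#' group and score the simple-matching NJ quartet of each dataset against
#' the original subset's quartet; (6) compute the imputation-accuracy
#' breakdown per method. Means, SDs, mean relative biases (versus the
#' run's own original subset), topology accuracy and failure counts are
#' aggregated over runs. Deterministic given the config.
#'
#' @param g the full [genotype_matrix()].
#' @param groups a [group_assignment()] over the lines of `g`.
#' @param cfg an [assessment_config()].
#' @param verbose print progress messages?
#' @return object of class `assessment_table`: list with data.frames
#'   `summary` (one row per level x method, the machine-readable twin of a
#'   results table), `per_run`, and `failures`.
#' @export
run_assessment <- function(g, groups, cfg = assessment_config(),
                           verbose = FALSE) {
  validate_genotype_matrix(g)
  groups <- align_groups(g, groups)
  stopifnot(inherits(cfg, "assessment_config"))
  lv <- cfg$missing_levels
  seed_tab <- with_seed(cfg$seed,
                        array(sample.int(.Machine$integer.max,
                                         length(lv) * cfg$n_runs * 6L),
                              dim = c(length(lv), cfg$n_runs, 6L)))
  rows <- list(); fails <- list(); ri <- 0L; fi <- 0L
  for (li in seq_along(lv)) {
    m <- lv[li]
    for (r in seq_len(cfg$n_runs)) {
      sd6 <- seed_tab[li, r, ]
      res <- tryCatch({
        masked <- apply_random_missing(g, m, seed = sd6[1L])
        sub <- subsample_genotypes(masked$genotypes, groups, cfg$n_lines,
                                   cfg$n_markers, seed = sd6[2L])
        orig_sub <- g[sub$line_idx, sub$marker_idx]
        miss_sub <- sub$genotypes
        sub_groups <- sub$groups
        # representative line per group, same four lines for every dataset
        rep_lines <- with_seed(sd6[3L], vapply(levels(sub_groups),
          function(lev) sample(which(sub_groups == lev), 1L), integer(1L)))
        # masked cells within the subset that have a known original genotype
        mask_sub <- which(is.na(miss_sub) & !is.na(orig_sub))
        mask_idx <- arrayInd(mask_sub, dim(orig_sub))
        ref <- .run_stats(orig_sub, sub_groups, rep_lines, cfg$pair_fallback)
        datasets <- list(ORIGINAL = orig_sub)
        imp_seeds <- stats::setNames(sd6[4:6], c("RF", "PP", "NI"))
        for (meth in cfg$methods) {
          datasets[[meth]] <- switch(meth,
            NONE = miss_sub,
            RF = impute_rf(miss_sub, n_trees = cfg$n_trees, mtry = cfg$mtry,
                           n_iter = cfg$rf_iter,
                           seed = imp_seeds[["RF"]])$imputed,
            PP = suppressWarnings(
              impute_ppca(miss_sub, n_pcs = cfg$n_pcs, tol = cfg$tol,
                          max_iter = cfg$max_iter,
                          seed = imp_seeds[["PP"]]))$imputed,
            NI = suppressWarnings(
              impute_nipals(miss_sub, n_pcs = cfg$n_pcs, tol = cfg$tol,
                            max_iter = cfg$max_iter))$imputed)
        }
        out <- list()
        for (nm in names(datasets)) {
          st <- if (nm == "ORIGINAL") ref else
            suppressWarnings(.run_stats(datasets[[nm]], sub_groups,
                                        rep_lines, cfg$pair_fallback))
          acc <- if (nm %in% c("RF", "PP", "NI") && nrow(mask_idx) > 0L)
            imputation_accuracy(orig_sub, mask_idx, datasets[[nm]])
          else list(m_pct = NA_real_, aa_pct = NA_real_, het_pct = NA_real_,
                    maj_pct = NA_real_, denominator = NA_integer_)
          out[[nm]] <- data.frame(
            missing_level = m, run = r, method = nm,
            ho = st$ho, he = st$he, f = st$f, phi_st = st$phi_st,
            ho_bias = if (nm == "ORIGINAL") NA_real_ else
              suppressWarnings(relative_bias(st$ho, ref$ho)),
            he_bias = if (nm == "ORIGINAL") NA_real_ else
              suppressWarnings(relative_bias(st$he, ref$he)),
            f_bias = if (nm == "ORIGINAL") NA_real_ else
              suppressWarnings(relative_bias(st$f, ref$f)),
            phi_bias = if (nm == "ORIGINAL") NA_real_ else
              suppressWarnings(relative_bias(st$phi_st, ref$phi_st)),
            topo_match = if (nm == "ORIGINAL" || is.null(st$quartet)) NA else
              same_topology(st$quartet, ref$quartet),
            m_pct = acc$m_pct, aa_pct = acc$aa_pct, het_pct = acc$het_pct,
            maj_pct = acc$maj_pct, accuracy_denom = acc$denominator,
            stringsAsFactors = FALSE)
        }
        do.call(rbind, out)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fi <- fi + 1L
        fails[[fi]] <- data.frame(missing_level = m, run = r,
                                  error = conditionMessage(res),
                                  stringsAsFactors = FALSE)
      } else {
        ri <- ri + 1L
        rows[[ri]] <- res
      }
    }
    if (verbose)
      message(sprintf("missing level %.0f%%: %d run(s) done", 100 * m,
                      cfg$n_runs))
  }
  per_run <- do.call(rbind, rows)
  rownames(per_run) <- NULL
  failures <- if (fi > 0L) do.call(rbind, fails) else
    data.frame(missing_level = numeric(0), run = integer(0),
               error = character(0))
  summary <- .summarise_runs(per_run)
  structure(list(summary = summary, per_run = per_run, failures = failures,
                 config = cfg), class = "assessment_table")
}

.summarise_runs <- function(per_run) {
  if (is.null(per_run) || nrow(per_run) == 0L)
    return(data.frame(missing_level = numeric(0), method = character(0),
                      n_runs = integer(0)))
  key <- interaction(per_run$missing_level, per_run$method, drop = TRUE)
  parts <- split(per_run, key)
  msd <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  out <- lapply(parts, function(d) {
    stats_cols <- c("ho", "he", "f", "phi_st", "m_pct", "aa_pct", "het_pct",
                    "maj_pct")
    row <- data.frame(missing_level = d$missing_level[1L],
                      method = d$method[1L], n_runs = nrow(d))
    for (cn in stats_cols) {
      v <- msd(d[[cn]])
      row[[paste0(cn, "_mean")]] <- v[["mean"]]
      row[[paste0(cn, "_sd")]] <- v[["sd"]]
    }
    for (cn in c("ho_bias", "he_bias", "f_bias", "phi_bias"))
      row[[paste0(cn, "_mean")]] <- mean(d[[cn]], na.rm = TRUE)
    row$topology_accuracy <- if (all(is.na(d$topo_match))) NA_real_ else
      100 * mean(d$topo_match, na.rm = TRUE)
    row
  })
  out <- do.call(rbind, out)
  out <- out[order(out$missing_level, out$method), ]
  rownames(out) <- NULL
  out
}

#' @method print assessment_table
#' @export
print.assessment_table <- function(x, ...) {
  cat(sprintf(
    "assessment_table: %d level(s) x %d method(s), %d run(s); %d failed\n",
    length(unique(x$summary$missing_level)),
    length(unique(x$summary$method)) , x$config$n_runs, nrow(x$failures)))
  cols <- c("missing_level", "method", "ho_mean", "he_mean", "f_mean",
            "phi_st_mean", "topology_accuracy", "m_pct_mean")
  print(x$summary[, cols], digits = 4)
  invisible(x)
}

#' Write assessment outputs as CSV
#'
#' Writes `summary.csv` (the level x method table), `per_run.csv`, and
#' `accuracy.csv` (the imputation-accuracy columns of the summary) into a
#' directory.
#'
#' @param at an `assessment_table`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assessment <- function(at, dir) {
  stopifnot(inherits(at, "assessment_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(at$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(at$per_run, file.path(dir, "per_run.csv"),
                   row.names = FALSE)
  acc <- at$summary[at$summary$method %in% c("RF", "PP", "NI"),
                    c("missing_level", "method", "n_runs",
                      grep("_pct_", names(at$summary), value = TRUE))]
  utils::write.csv(acc, file.path(dir, "accuracy.csv"), row.names = FALSE)
  invisible(dir)
}
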