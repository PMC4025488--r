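#' Bin continuous genotype estimates into codes
#'
#' The ad-hoc assignment rule used after PCA-based (and, for a uniform
#' downstream interface, RF-based) imputation on the 1/2/3 code scale:
#' estimates `<= 1.5` become the homozygote `1`, estimates in `(1.5, 2.5]`
#' the heterozygote `2`, and estimates `> 2.5` the other homozygote `3`.
#' Out-of-range values fall into the open tails; the rule is idempotent on
#' `{1,2,3}`.
#'
#' @param values finite numeric estimates.
#' @return integer genotype codes.
#' @export
bin_estimates <- function(values) {
  if (length(values) == 0L) return(integer(0))
  bad <- !is.finite(values)
  if (any(bad))
    stop("non-finite estimate at position ", which(bad)[1L])
  out <- rep(2L, length(values))
  out[values <= 1.5] <- 1L
  out[values > 2.5] <- 3L
  out
}

# assemble an imputation_result: replace masked cells of g by binned
# estimates; cells without an estimate (degenerate markers/lines) stay NA
# and are reported
make_imputation_result <- function(g, fitted, method, params, convergence,
                                   usable_cols) {
  miss <- which(is.na(g))
  est <- fitted[miss]
  have <- is.finite(est)
  imputed <- g
  if (any(have)) imputed[miss[have]] <- bin_estimates(est[have])
  idx <- arrayInd(miss, dim(g))
  continuous <- data.frame(
    line = rownames(g)[idx[, 1L]],
    marker = colnames(g)[idx[, 2L]],
    estimate = est,
    code = ifelse(have, unclass(imputed)[miss], NA_integer_),
    stringsAsFactors = FALSE)
  dropped <- colnames(g)[!usable_cols]
  if (length(dropped) > 0L)
    warning(length(dropped), " marker(s) without observed genotypes left ",
            "unimputed: ", paste(utils::head(dropped, 5L), collapse = ", "))
  dimnames(fitted) <- dimnames(g)
  structure(list(imputed = imputed, continuous = continuous, method = method,
                 params = params, convergence = convergence,
                 fitted = fitted, dropped_markers = dropped),
            class = "imputation_result")
}

#' @method print imputation_result
#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("imputation_result (%s): %d cells imputed", x$method,
              sum(is.finite(x$continuous$estimate))))
  if (!is.null(x$convergence$converged))
    cat(sprintf(", converged = %s in %d iteration(s)",
                x$convergence$converged, x$convergence$iterations))
  cat("\n")
  invisible(x)
}

# observed-mean column centering; returns centered matrix (NA kept), means,
# and the usable-column flag (>=1 observed cell)
center_columns <- function(g) {
  x <- unclass(g) * 1.0
  mu <- colMeans(x, na.rm = TRUE)
  usable <- !is.nan(mu)
  mu[!usable] <- 0
  list(y = sweep(x, 2, mu), mu = mu, usable = usable)
}

#' Probabilistic PCA imputation
#'
#' Fits the Tipping-Bishop probabilistic PCA model with isotropic noise by
#' EM, treating missing cells as latent. Marker columns are centered on
#' their observed means; the E-step computes each line's expected factor
#' scores and second moments from its observed entries only; the M-step
#' updates the loading matrix and noise variance; iteration stops when the
#' relative Frobenius change of the reconstruction drops below `tol` or at
#' `max_iter`. The fitted matrix is the least-squares projection
#' onto the converged principal subspace (scores re-solved per line from
#' observed cells), read out at missing cells and binned with
#' [bin_estimates()]. Observed cells are never altered.
#'
#' @param g a [genotype_matrix()] with missing cells.
#' @param n_pcs number of principal components (>= 1, < min(dim)).
#' @param tol relative-change convergence tolerance.
#' @param max_iter maximum EM iterations; non-convergence yields a warning
#'   and `convergence$converged = FALSE`.
#' @param seed RNG seed for the loading initialization.
#' @return an `imputation_result`.
#' @export
impute_ppca <- function(g, n_pcs = 2, tol = 1e-5, max_iter = 1000,
                        seed = NULL) {
  validate_genotype_matrix(g)
  k <- as.integer(n_pcs)
  stopifnot(k >= 1, k < min(dim(g)))
  cc <- center_columns(g)
  y <- cc$y[, cc$usable, drop = FALSE]
  n <- nrow(y); L <- ncol(y)
  obs <- !is.na(y)
  y0 <- ifelse(obs, y, 0)
  mobs <- obs * 1.0
  W <- with_seed(seed, matrix(stats::rnorm(L * k, sd = 0.1), nrow = L))
  sigma2 <- 1
  Z <- matrix(0, n, k)
  Cmat <- matrix(0, n, k * k)  # row i = vec(E[z_i z_i'])
  R_old <- NULL; it <- 0L; converged <- FALSE; rel <- NA_real_
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(n)) {                       # E-step, observed entries only
      o <- obs[i, ]
      Wo <- W[o, , drop = FALSE]
      Mi <- crossprod(Wo) + diag(sigma2, k)
      Mi_inv <- solve(Mi)
      zi <- Mi_inv %*% crossprod(Wo, y[i, o])
      Z[i, ] <- zi
      Cmat[i, ] <- as.vector(sigma2 * Mi_inv + tcrossprod(zi))
    }
    Nmat <- crossprod(y0, Z)                      # L x k
    Dmat <- crossprod(mobs, Cmat)                 # L x k^2
    for (j in seq_len(L))                         # M-step loadings
      W[j, ] <- solve(matrix(Dmat[j, ], k, k), Nmat[j, ])
    R <- Z %*% t(W)
    # noise variance over observed cells
    Wsq <- t(apply(W, 1L, function(w) as.vector(tcrossprod(w))))
    if (k == 1L) Wsq <- matrix(W^2, ncol = 1L)
    term3 <- sum((mobs %*% Wsq) * Cmat)
    nobs <- sum(obs)
    sigma2 <- max((sum(y0^2) - 2 * sum(y0 * R * obs) + term3) / nobs, 1e-12)
    # relative change of the reconstruction itself: a scalar error change
    # can stall while the principal subspace is still rotating
    if (!is.null(R_old)) {
      rel <- sqrt(sum((R - R_old)^2) / max(sum(R^2), 1e-300))
      if (is.finite(rel) && rel < tol) { converged <- TRUE; break }
    }
    R_old <- R
  }
  if (!converged)
    warning("probabilistic PCA did not converge in ", max_iter,
            " iterations (relative change ", signif(rel, 3), ")")
  # least-squares readout on the orthonormalized principal subspace
  U <- svd(W, nu = k, nv = 0)$u
  Tsc <- matrix(0, n, k)
  for (i in seq_len(n)) {
    o <- obs[i, ]
    Uo <- U[o, , drop = FALSE]
    Tsc[i, ] <- tryCatch(solve(crossprod(Uo), crossprod(Uo, y[i, o])),
                         error = function(e) rep(NA_real_, k))
  }
  fit_sub <- sweep(Tsc %*% t(U), 2, cc$mu[cc$usable], "+")
  fitted <- matrix(NA_real_, nrow(g), ncol(g))
  fitted[, cc$usable] <- fit_sub
  make_imputation_result(g, fitted, "PP",
                         list(n_pcs = k, tol = tol, max_iter = max_iter),
                         list(converged = converged, iterations = it,
                              change = rel, sigma2 = sigma2),
                         cc$usable)
}

#' NIPALS PCA imputation
#'
#' Nonlinear estimation by iterative partial least squares: principal
#' components are extracted one at a time by alternating regressions of
#' scores on loadings and loadings on scores in which every sum runs over
#' observed cells only (missing cells are excluded, never filled), with
#' deflation of the observed residuals after each component. The
#' reconstruction from `n_pcs` components plus the observed-cell column
#' means is read out at missing cells and binned. `n_pcs = 0` reduces to
#' column-mean imputation. Observed cells are never altered.
#'
#' @inheritParams impute_ppca
#' @param n_pcs number of components (>= 0, < min(dim)).
#' @param max_iter maximum alternating iterations per component.
#' @return an `imputation_result`.
#' @export
impute_nipals <- function(g, n_pcs = 2, tol = 1e-5, max_iter = 500) {
  validate_genotype_matrix(g)
  k <- as.integer(n_pcs)
  stopifnot(k >= 0, k < min(dim(g)))
  cc <- center_columns(g)
  y <- cc$y[, cc$usable, drop = FALSE]
  n <- nrow(y); L <- ncol(y)
  obs <- !is.na(y)
  mobs <- obs * 1.0
  no_line_data <- rowSums(obs) == 0L
  R0 <- ifelse(obs, y, 0)
  Tsc <- matrix(0, n, max(k, 1L))[, seq_len(k), drop = FALSE]
  P <- matrix(0, L, max(k, 1L))[, seq_len(k), drop = FALSE]
  iters <- integer(0); converged <- TRUE
  h <- 0L
  while (h < k) {
    h <- h + 1L
    t_vec <- R0[, which.max(colSums(R0^2))]
    it <- 0L; ok <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      den_p <- as.vector(crossprod(mobs, t_vec^2))
      p_vec <- as.vector(crossprod(R0, t_vec)) / ifelse(den_p > 0, den_p, 1)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      den_t <- as.vector(mobs %*% p_vec^2)
      t_new <- as.vector(R0 %*% p_vec) / ifelse(den_t > 0, den_t, 1)
      t_new[no_line_data] <- 0
      d <- sqrt(sum((t_new - t_vec)^2)) / max(sqrt(sum(t_new^2)), 1e-300)
      t_vec <- t_new
      if (d < tol) { ok <- TRUE; break }
    }
    if (!ok) converged <- FALSE
    if (p_vec[which.max(abs(p_vec))] < 0) { p_vec <- -p_vec; t_vec <- -t_vec }
    iters <- c(iters, it)
    Tsc[, h] <- t_vec; P[, h] <- p_vec
    R0 <- R0 - mobs * tcrossprod(t_vec, p_vec)   # deflate observed cells only
  }
  if (!converged)
    warning("NIPALS did not converge for every component in ", max_iter,
            " iterations per component")
  fit_sub <- sweep(if (k > 0) Tsc %*% t(P) else matrix(0, n, L),
                   2, cc$mu[cc$usable], "+")
  fit_sub[no_line_data, ] <- NA_real_            # no observed overlap at all
  if (any(no_line_data))
    warning(sum(no_line_data), " line(s) with no observed cells left ",
            "unimputed")
  fitted <- matrix(NA_real_, nrow(g), ncol(g))
  fitted[, cc$usable] <- fit_sub
  make_imputation_result(g, fitted, "NI",
                         list(n_pcs = k, tol = tol, max_iter = max_iter),
                         list(converged = converged,
                              iterations = if (length(iters)) max(iters) else 0L,
                              change = NA_real_),
                         cc$usable)
}

#' Random-forest regression imputation
#'
#' Missing cells are initialized with their marker's observed mean on the
#' numeric code scale; then, for each marker with masked cells, a
#' random-forest regressor (bootstrap trees via \pkg{ranger}, single
#' thread) is fitted with that marker's observed codes as response and all
#' other, currently filled, markers as predictors, and the masked cells are
#' replaced by its predictions. The sweep over markers is repeated `n_iter`
#' times. Final continuous predictions are binned with [bin_estimates()].
#' Observed cells are never altered; markers with no observed genotype are
#' excluded from both response and predictor roles and reported.
#'
#' @param g a [genotype_matrix()] with >= 2 markers.
#' @param n_trees trees per forest.
#' @param mtry predictors tried per split; default one third of the
#'   available predictors (rounded up).
#' @param n_iter number of sweeps over the markers.
#' @param seed RNG seed (per-forest seeds are derived from it).
#' @return an `imputation_result`.
#' @export
impute_rf <- function(g, n_trees = 100, mtry = NULL, n_iter = 1,
                      seed = NULL) {
  validate_genotype_matrix(g)
  stopifnot(ncol(g) >= 2, n_iter >= 1)
  cc <- center_columns(g)
  usable <- cc$usable
  x <- unclass(g)[, usable, drop = FALSE] * 1.0
  L <- ncol(x)
  if (L < 2L) stop("fewer than 2 markers with observed genotypes")
  obs <- !is.na(x)
  fill <- x
  fill[!obs] <- rep(colMeans(x, na.rm = TRUE), colSums(!obs))
  targets <- which(colSums(!obs) > 0L)
  if (is.null(mtry)) mtry <- ceiling((L - 1) / 3)
  mtry <- min(as.integer(mtry), L - 1L)
  seeds <- with_seed(if (is.null(seed)) 0L else seed,
                     matrix(sample.int(.Machine$integer.max,
                                       n_iter * max(length(targets), 1L)),
                            nrow = n_iter))
  for (it in seq_len(n_iter)) {
    for (s in seq_along(targets)) {
      j <- targets[s]
      oj <- obs[, j]
      if (!any(oj)) next
      fit <- ranger::ranger(x = fill[oj, -j, drop = FALSE], y = x[oj, j],
                            num.trees = n_trees, mtry = mtry,
                            seed = seeds[it, s], num.threads = 1L,
                            verbose = FALSE)
      pred <- stats::predict(fit, data = fill[!oj, -j, drop = FALSE],
                             num.threads = 1L)$predictions
      fill[!oj, j] <- pred
    }
  }
  full <- matrix(NA_real_, nrow(g), ncol(g))
  full[, usable] <- fill
  make_imputation_result(g, full, "RF",
                         list(n_trees = n_trees, mtry = mtry,
                              n_iter = n_iter),
                         list(converged = TRUE, iterations = n_iter,
                              change = NA_real_),
                         usable)
}
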