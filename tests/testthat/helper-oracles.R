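# Independent oracles, deliberately written as plain loops so that they do
# not share code paths with the package implementations they check.

# random genotype matrix with a given missing fraction
rand_geno <- function(n, L, miss = 0, seed = NULL,
                      probs = c(0.4, 0.2, 0.4)) {
  draw <- function() {
    codes <- sample(1:3, n * L, replace = TRUE, prob = probs)
    if (miss > 0)
      codes[sample.int(n * L, round(miss * n * L))] <- NA
    genotype_matrix(matrix(codes, n, L))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# brute-force AMOVA: explicit loops over pairs, loci and groups
brute_amova <- function(g, groups) {
  x <- 3 - unclass(g)   # allele-count view
  n <- nrow(x); L <- ncol(x)
  glab <- as.character(groups[rownames(g)])
  d2 <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- 0; cnt <- 0
      for (l in seq_len(L)) {
        if (!is.na(x[i, l]) && !is.na(x[j, l])) {
          s <- s + (x[i, l] - x[j, l])^2
          cnt <- cnt + 1
        }
      }
      if (cnt == 0) stop("pair without co-observed loci in oracle")
      d2[i, j] <- d2[j, i] <- s * L / cnt
    }
  }
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  for (lab in unique(glab)) {
    idx <- which(glab == lab)
    s <- 0
    if (length(idx) > 1)
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
        s <- s + d2[idx[a], idx[b]]
    ss_within <- ss_within + s / length(idx)
  }
  K <- length(unique(glab))
  ng <- as.numeric(table(glab))
  ss_among <- ss_total - ss_within
  ms_among <- ss_among / (K - 1)
  ms_within <- ss_within / (n - K)
  n0 <- (n - sum(ng^2) / n) / (K - 1)
  va <- (ms_among - ms_within) / n0
  list(ss_total = ss_total, ss_among = ss_among, ss_within = ss_within,
       va = va, vw = ms_within, phi_st = va / (va + ms_within))
}

# four-point rule: canonical split string of the pairing minimizing
# d(x,y) + d(z,w); ties -> "star"
four_point_oracle <- function(dm, tol = 1e-12) {
  ids <- rownames(dm)
  pairings <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                   list(c(1, 4), c(2, 3)))
  sums <- vapply(pairings, function(p)
    dm[p[[1]][1], p[[1]][2]] + dm[p[[2]][1], p[[2]][2]], numeric(1))
  best <- which(sums - min(sums) <= tol)
  if (length(best) > 1) return("star")
  p <- pairings[[best]]
  enc <- sort(c(paste(sort(ids[p[[1]]]), collapse = ","),
                paste(sort(ids[p[[2]]]), collapse = ",")))
  paste(enc, collapse = "|")
}

# symmetric random distance matrix over 4 named taxa
rand_dist4 <- function() {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d[upper.tri(d)] <- runif(6, 0.05, 1)
  d + t(d)
}

# genotype matrix whose column-centered form has rank <= (number of row
# patterns - 1); used for the exact low-rank recovery oracles
patterned_geno <- function(patterns, reps) {
  codes <- do.call(rbind, mapply(function(p, r)
    matrix(rep(p, each = r), nrow = r), patterns, reps, SIMPLIFY = FALSE))
  genotype_matrix(codes)
}
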