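#' Simple-matching-coefficient distance matrix
#'
#' For each pair of lines, similarity `S` is the fraction of co-observed
#' loci (both genotypes called) with identical codes, and the distance is
#' `D = 1 - S`. The per-pair count of co-observed loci is recorded.
#'
#' @param g a [genotype_matrix()] with >= 2 lines.
#' @param pair_fallback what to do with a pair sharing no co-observed
#'   locus: `"error"` (default) or `"mean"` (substitute the mean of the
#'   defined distances, with a warning).
#' @return object of class `smc_dist`: list with `ids`, the symmetric
#'   distance matrix `d`, and `valid_counts`.
#' @export
smc_distance <- function(g, pair_fallback = c("error", "mean")) {
  pair_fallback <- match.arg(pair_fallback)
  validate_genotype_matrix(g)
  if (nrow(g) < 2L) stop("need at least 2 lines")
  x <- unclass(g)
  m <- (!is.na(x)) * 1.0
  valid <- tcrossprod(m)
  match_ct <- matrix(0, nrow(g), nrow(g))
  for (code in 1:3) {
    ind <- (x == code & !is.na(x)) * 1.0
    match_ct <- match_ct + tcrossprod(ind)
  }
  d <- 1 - match_ct / valid
  diag(d) <- 0
  off <- row(d) != col(d)
  und <- valid == 0 & off
  if (any(und)) {
    if (pair_fallback == "error")
      stop("line pair(s) with zero co-observed loci; set pair_fallback = ",
           "'mean' to substitute the mean distance")
    warning(sum(und) / 2, " line pair(s) with zero co-observed loci ",
            "assigned the mean defined distance")
    d[und] <- mean(d[off & !und])
  }
  dimnames(d) <- dimnames(valid) <- list(rownames(g), rownames(g))
  structure(list(ids = rownames(g), d = d, valid_counts = valid),
            class = "smc_dist")
}

#' @method print smc_dist
#' @export
print.smc_dist <- function(x, ...) {
  cat(sprintf("smc_dist over %d lines (mean D = %.4f)\n", length(x$ids),
              mean(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' @method as.matrix smc_dist
#' @export
as.matrix.smc_dist <- function(x, ...) x$d

#' @method as.dist smc_dist
#' @export
as.dist.smc_dist <- function(m, ...) stats::as.dist(m$d)

.dist_matrix <- function(d) {
  if (inherits(d, "smc_dist")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d)))
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                        paste0("t", seq_len(nrow(d))))
  if (any(!is.finite(d))) stop("non-finite distance")
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on a distance matrix or an
#' [smc_distance()] object. Negative branch lengths are permitted; only the
#' topology matters downstream.
#'
#' @param d an `smc_dist`, `dist`, or symmetric numeric matrix over >= 3
#'   taxa.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  dm <- .dist_matrix(d)
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  ape::unroot(ape::nj(dm))
}

# canonical "a,b|c,d" encoding of an unordered quartet split
.canonical_quartet <- function(pair1, pair2) {
  p1 <- paste(sort(pair1), collapse = ",")
  p2 <- paste(sort(pair2), collapse = ",")
  paste(sort(c(p1, p2)), collapse = "|")
}

#' Quartet split of four taxa
#'
#' Determines the middle-edge bipartition of the unrooted four-taxon tree.
#' For a distance input the four-point rule is applied: the pairing
#' `{x,y | z,w}` minimizing `d(x,y) + d(z,w)` is the neighbor-joining
#' split; a tie yields the star topology (reported as `"star"`), so that
#' topology-accuracy counting never credits an arbitrary resolution. For a
#' 4-leaf `phylo` the split is read off the internal edge.
#'
#' @param x an `smc_dist` / distance matrix over exactly 4 taxa, or a
#'   4-leaf `phylo`.
#' @param tie_tol absolute tolerance for declaring the four-point sums
#'   tied.
#' @return object of class `quartet_split`: a string `"a,b|c,d"` with both
#'   pairs and the pair order sorted, or `"star"`.
#' @export
quartet_split <- function(x, tie_tol = 1e-12) {
  if (inherits(x, "phylo")) {
    tr <- ape::unroot(x)
    if (length(tr$tip.label) != 4L) stop("quartet_split needs 4 taxa")
    ntip <- 4L
    inner <- tr$edge[tr$edge[, 2L] > ntip, , drop = FALSE]
    if (nrow(inner) == 0L)
      return(structure("star", class = "quartet_split"))
    # tips attached to one of the two internal nodes form a cherry
    node <- inner[1L, 2L]
    tips <- tr$edge[tr$edge[, 1L] == node & tr$edge[, 2L] <= ntip, 2L]
    if (length(tips) != 2L)
      return(structure("star", class = "quartet_split"))
    pair1 <- tr$tip.label[tips]
    pair2 <- setdiff(tr$tip.label, pair1)
    return(structure(.canonical_quartet(pair1, pair2),
                     class = "quartet_split"))
  }
  dm <- .dist_matrix(x)
  if (nrow(dm) != 4L) stop("quartet_split needs 4 taxa")
  ids <- rownames(dm)
  sums <- c(dm[1, 2] + dm[3, 4],   # {1,2 | 3,4}
            dm[1, 3] + dm[2, 4],   # {1,3 | 2,4}
            dm[1, 4] + dm[2, 3])   # {1,4 | 2,3}
  lo <- min(sums)
  best <- which(sums - lo <= tie_tol)
  if (length(best) > 1L) return(structure("star", class = "quartet_split"))
  pairs <- list(c(1, 2), c(1, 3), c(1, 4))[[best]]
  structure(.canonical_quartet(ids[pairs], ids[-pairs]),
            class = "quartet_split")
}

#' @method print quartet_split
#' @export
print.quartet_split <- function(x, ...) {
  cat("quartet split:", unclass(x), "\n")
  invisible(x)
}

#' Unrooted topology equality
#'
#' `TRUE` iff the two trees carry the same unrooted split set over an
#' identical leaf set. Quartet splits compare by canonical bipartition
#' (a star quartet matches only another star); general `phylo` trees
#' compare by Robinson-Foulds distance zero.
#'
#' @param t1,t2 two `quartet_split` objects or two `phylo` trees on the
#'   same leaves.
#' @return logical.
#' @export
same_topology <- function(t1, t2) {
  if (inherits(t1, "quartet_split") && inherits(t2, "quartet_split")) {
    l1 <- if (unclass(t1) == "star") NULL else
      sort(unlist(strsplit(unclass(t1), "[,|]")))
    l2 <- if (unclass(t2) == "star") NULL else
      sort(unlist(strsplit(unclass(t2), "[,|]")))
    if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
      stop("leaf sets differ")
    return(unclass(t1) == unclass(t2))
  }
  if (inherits(t1, "phylo") && inherits(t2, "phylo")) {
    if (!setequal(t1$tip.label, t2$tip.label)) stop("leaf sets differ")
    return(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0)
  }
  stop("same_topology compares two quartet_split or two phylo objects")
}
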