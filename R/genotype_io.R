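#' Construct a genotype matrix
#'
#' The universal data container of the package: a lines x markers integer
#' matrix of diploid biallelic SNP genotype codes, where `1` is the
#' homozygote for allele A, `2` the heterozygote, `3` the other homozygote,
#' and `NA` a missing genotype call.
#'
#' @param codes integer (or coercible) matrix with values in `{1, 2, 3, NA}`.
#' @param line_ids character vector of unique line identifiers (defaults to
#'   `rownames(codes)`, or `L1..Ln`).
#' @param marker_ids character vector of unique marker identifiers (defaults
#'   to `colnames(codes)`, or `M1..Mm`).
#' @return an object of class `genotype_matrix`: an integer matrix with
#'   dimnames set to the line and marker identifiers.
#' @export
genotype_matrix <- function(codes, line_ids = NULL, marker_ids = NULL) {
  if (!is.matrix(codes)) codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(line_ids)) {
    line_ids <- rownames(codes)
    if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(codes)))
  }
  if (is.null(marker_ids)) {
    marker_ids <- colnames(codes)
    if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(codes)))
  }
  dimnames(codes) <- list(as.character(line_ids), as.character(marker_ids))
  g <- structure(codes, class = c("genotype_matrix", "matrix", "array"))
  validate_genotype_matrix(g)
  g
}

#' Validate a genotype matrix
#'
#' Checks the container invariants: every cell in `{1,2,3,NA}`, unique line
#' and marker identifiers, dimensions matching the identifier lengths.
#'
#' @param g a `genotype_matrix`.
#' @return `g`, invisibly; stops with an informative error otherwise.
#' @export
validate_genotype_matrix <- function(g) {
  stopifnot(is.matrix(g))
  bad <- which(!(g %in% c(1L, 2L, 3L)) & !is.na(g))
  if (length(bad) > 0L) {
    i <- arrayInd(bad[1L], dim(g))
    stop(sprintf("invalid genotype code %s at line '%s', marker '%s'",
                 g[bad[1L]], rownames(g)[i[1L]], colnames(g)[i[2L]]))
  }
  if (anyDuplicated(rownames(g))) stop("duplicated line identifiers")
  if (anyDuplicated(colnames(g))) stop("duplicated marker identifiers")
  invisible(g)
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  if (nrow(x) > 0L && ncol(x) > 0L) {
    show <- unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(8L, ncol(x))),
                       drop = FALSE]
    print(show)
    if (nrow(x) > 5L || ncol(x) > 8L) cat("...\n")
  }
  invisible(x)
}

#' @method [ genotype_matrix
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("genotype_matrix", "matrix", "array")
  out
}

# tokens accepted as missing on input; "NA" is written on output
.missing_tokens <- c("NA", "-", "")

#' Read a genotype matrix from TSV
#'
#' Expected layout: a header row `line_id<TAB>marker1<TAB>marker2...`, then
#' one row per line with cells in `{1,2,3}` or a missing token (`NA`, `-`,
#' or empty). Row and column order are preserved.
#'
#' @param path path to a tab-separated genotype file.
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                      colClasses = "character", check.names = FALSE,
                      na.strings = NULL, quote = "", comment.char = ""),
    error = function(e) stop("malformed genotype file '", path, "': ",
                             conditionMessage(e)))
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("malformed genotype file '", path, "': no genotype cells")
  line_ids <- raw[[1L]]
  marker_ids <- colnames(raw)[-1L]
  if (anyDuplicated(line_ids)) stop("duplicated line identifiers in ", path)
  if (anyDuplicated(marker_ids)) stop("duplicated marker identifiers in ", path)
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[cells %in% .missing_tokens] <- NA_character_
  ok <- is.na(cells) | cells %in% c("1", "2", "3")
  if (!all(ok)) {
    i <- arrayInd(which(!ok)[1L], dim(cells))
    stop(sprintf("unparsable genotype cell '%s' at line '%s', marker '%s'",
                 cells[!ok][1L], line_ids[i[1L]], marker_ids[i[2L]]))
  }
  codes <- matrix(as.integer(cells), nrow = nrow(cells))
  genotype_matrix(codes, line_ids = line_ids, marker_ids = marker_ids)
}

#' Write a genotype matrix to TSV
#'
#' Inverse of [read_genotype_matrix()]: `read(write(g))` reproduces `g`
#' cell for cell. Missing genotypes are written as `NA`.
#'
#' @param g a `genotype_matrix`.
#' @param path output path.
#' @export
write_genotype_matrix <- function(g, path) {
  validate_genotype_matrix(g)
  df <- data.frame(line_id = rownames(g), unclass(g), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct a group assignment
#'
#' @param labels vector of group labels, one per line.
#' @param line_ids character vector of line identifiers (defaults to
#'   `names(labels)`).
#' @return object of class `group_assignment`: a factor named by line id.
#' @export
group_assignment <- function(labels, line_ids = names(labels)) {
  if (is.null(line_ids)) stop("line identifiers required")
  line_ids <- as.character(line_ids)
  if (anyDuplicated(line_ids)) stop("duplicated line identifiers in groups")
  if (length(labels) != length(line_ids))
    stop("labels and line_ids differ in length")
  f <- factor(as.character(labels))
  names(f) <- line_ids
  structure(f, class = c("group_assignment", "factor"))
}

#' @method print group_assignment
#' @export
print.group_assignment <- function(x, ...) {
  sz <- group_sizes(x)
  cat(sprintf("group_assignment: %d lines in K = %d groups\n",
              length(x), length(sz)))
  print(sz)
  invisible(x)
}

#' Group sizes of a group assignment
#' @param groups a `group_assignment`.
#' @return named integer vector of group sizes.
#' @export
group_sizes <- function(groups) {
  table(factor(groups))
}

#' Read a line-to-group assignment table
#'
#' Two tab- or whitespace-separated columns, `line_id` and `group`, with or
#' without a header (auto-detected on the `line_id` column name).
#'
#' @param path path to the table.
#' @return a [group_assignment()].
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(tab) != 2L) stop("group table must have two columns: line_id, group")
  if (tolower(tab[1L, 1L]) == "line_id") tab <- tab[-1L, , drop = FALSE]
  if (nrow(tab) == 0L) stop("empty group table: ", path)
  group_assignment(tab[[2L]], line_ids = tab[[1L]])
}

#' Match a group assignment to a genotype matrix
#'
#' Checks every line of `g` has a group and returns the assignment reordered
#' to the matrix rows.
#'
#' @param g a `genotype_matrix`.
#' @param groups a `group_assignment`.
#' @return a `group_assignment` aligned to `rownames(g)`.
#' @export
align_groups <- function(g, groups) {
  miss <- setdiff(rownames(g), names(groups))
  if (length(miss) > 0L)
    stop("lines missing from group table: ", paste(utils::head(miss, 5L),
                                                   collapse = ", "))
  group_assignment(droplevels(factor(groups[rownames(g)])),
                   line_ids = rownames(g))
}

#' Import biallelic SNP genotypes from a VCF file
#'
#' Maps GT fields of biallelic records to genotype codes: `0/0 -> 1`,
#' `0/1` or `1/0 -> 2`, `1/1 -> 3`, `./.` (or any half call) -> missing.
#' Phased separators are accepted. Multiallelic records are skipped and the
#' skip count reported in a message.
#'
#' @param path path to a VCF (v4.x) file.
#' @return a [genotype_matrix()] (markers as columns, samples as lines).
#' @export
vcf_to_matrix <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) stop("no parsable VCF records in ", path)
  alt <- v@fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (sum(multi) > 0L)
    message(sum(multi), " multiallelic record(s) skipped")
  v@gt <- v@gt[!multi, , drop = FALSE]
  v@fix <- v@fix[!multi, , drop = FALSE]
  if (nrow(v@fix) == 0L) stop("no biallelic VCF records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  code[gt %in% "0/0"] <- 1L
  code[gt %in% c("0/1", "1/0")] <- 2L
  code[gt %in% "1/1"] <- 3L
  ids <- v@fix[, "ID"]
  bad <- is.na(ids) | ids == "." | duplicated(ids)
  ids[bad] <- paste0(v@fix[bad, "CHROM"], "_", v@fix[bad, "POS"])
  genotype_matrix(t(code), line_ids = colnames(gt), marker_ids = ids)
}

#' Allele-count view of a genotype matrix
#'
#' The derived numeric convention used by AMOVA and PCA centering:
#' `x = 3 - code`, so `x` counts copies of allele A (2, 1, 0).
#'
#' @param g a `genotype_matrix`.
#' @return numeric matrix of allele-A counts with `NA` where missing.
#' @export
as_allele_counts <- function(g) {
  x <- 3 - unclass(g)
  storage.mode(x) <- "double"
  x
}
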