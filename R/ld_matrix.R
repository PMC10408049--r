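#' Construct a signed LD correlation matrix
#'
#' An `ld_matrix` is a square matrix of signed pairwise correlations (r,
#' not r-squared) over named variants. It is the single source of both r
#' (used by the correlated-variant IVW estimator) and r^2 (used by
#' clumping). On construction the matrix is symmetrized as
#' `(M + t(M))/2`, the diagonal is forced to 1, and, when the smallest
#' eigenvalue falls below `-1e-8`, a positive-semidefinite repair is
#' applied: negative eigenvalues are clipped to `1e-10`, the matrix is
#' reconstructed and its diagonal rescaled back to 1. A repair is
#' recorded in the `psd_repaired` attribute.
#'
#' @param r square numeric matrix with entries in `[-1, 1]`.
#' @param rsids variant identifiers; defaults to `rownames(r)`.
#' @return An `ld_matrix` (matrix subclass with `dimnames = rsids`).
#' @export
ld_matrix <- function(r, rsids = rownames(r)) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("ld_matrix: matrix is not square")
  if (is.null(rsids)) stop("ld_matrix: variant identifiers are required")
  rsids <- as.character(rsids)
  if (length(rsids) != nrow(r)) stop("ld_matrix: rsid/dimension mismatch")
  if (anyDuplicated(rsids)) stop("ld_matrix: duplicate rsids")
  if (any(!is.finite(r))) stop("ld_matrix: non-finite entries")
  if (any(abs(r) > 1 + 1e-6)) stop("ld_matrix: |r| exceeds 1")
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  repaired <- FALSE
  ev <- eigen(r, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    repaired <- TRUE
    vals <- pmax(ev$values, 1e-10)
    r <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(r))
    r <- r / outer(d, d)
    r <- (r + t(r)) / 2
    diag(r) <- 1
  }
  dimnames(r) <- list(rsids, rsids)
  structure(r, psd_repaired = repaired, class = c("ld_matrix", "matrix", "array"))
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("ld_matrix: %d variants%s\n", nrow(x),
              if (isTRUE(attr(x, "psd_repaired"))) " (PSD-repaired)" else ""))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Read an LD matrix from a TSV file
#'
#' Expects a header row of rsids and a first column of rsids; the header
#' and row identifiers must agree as sets and the body must be square.
#' The result goes through [ld_matrix()] (symmetrization, unit diagonal,
#' PSD repair when needed; a message is emitted when a repair triggers).
#'
#' @param path file path.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("read_ld_matrix: cannot read ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           row.names = 1)
  if (nrow(raw) != ncol(raw)) stop("read_ld_matrix: matrix is not square")
  if (!setequal(rownames(raw), colnames(raw))) {
    stop("read_ld_matrix: header and row rsids disagree")
  }
  m <- as.matrix(raw[, rownames(raw), drop = FALSE])
  out <- ld_matrix(m, rsids = rownames(raw))
  if (isTRUE(attr(out, "psd_repaired"))) {
    message("read_ld_matrix: applied positive-semidefinite repair to ", path)
  }
  out
}

#' Write an LD matrix to a TSV file
#'
#' Inverse of [read_ld_matrix()]: header row and first column carry the
#' rsids, cells are signed r.
#'
#' @param ld an `ld_matrix`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(rsid = rownames(ld), unclass(ld), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compute an LD matrix from a dosage table
#'
#' Pairwise signed Pearson correlation of dosage rows (variants x
#' samples), emulating estimation of a reference LD matrix from a
#' genotype panel.
#'
#' @param dosages numeric matrix, rows = variants (rownames = rsids),
#'   columns = samples; at least 2 samples and no constant rows.
#' @return An `ld_matrix`.
#' @export
ld_from_dosages <- function(dosages) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) < 2L) stop("ld_from_dosages: need at least 2 samples")
  v <- apply(dosages, 1L, stats::var)
  if (any(v == 0)) {
    stop("ld_from_dosages: constant dosage row(s): ",
         paste(rownames(dosages)[v == 0], collapse = ", "))
  }
  rsids <- rownames(dosages)
  if (is.null(rsids)) rsids <- paste0("snp", seq_len(nrow(dosages)))
  r <- stats::cor(t(dosages))
  ld_matrix(r, rsids = rsids)
}

#' Subset an LD matrix to a set of variants
#'
#' Extracts the submatrix for `rsids` (in the given order) without
#' re-running PSD repair, so leave-one-out analyses reuse the repaired
#' full matrix deterministically.
#'
#' @param ld an `ld_matrix`.
#' @param rsids variants to keep.
#' @return An `ld_matrix` over `rsids`.
#' @export
ld_subset <- function(ld, rsids) {
  missing <- setdiff(rsids, rownames(ld))
  if (length(missing) > 0L) {
    stop("ld_subset: rsid(s) absent from LD matrix: ",
         paste(missing, collapse = ", "))
  }
  sub <- unclass(ld)[rsids, rsids, drop = FALSE]
  structure(sub, psd_repaired = attr(ld, "psd_repaired"),
            class = c("ld_matrix", "matrix", "array"))
}
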