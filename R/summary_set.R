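#' Construct a summary-statistics set
#'
#' A `summary_set` is a data frame of per-variant association records for
#' one trait in one cohort, carrying trait metadata as attributes. The
#' canonical columns are `rsid`, `chrom`, `pos`, `ea` (effect allele),
#' `oa` (other allele), `eaf` (effect-allele frequency), `beta`, `se`,
#' `pval`, and optionally `n` (sample size), `source` (cohort label) and
#' `region` (gene-region assignment added by [select_region_snps()]).
#'
#' Validation enforces the record invariants: alleles differ and are
#' upper-case, positions are >= 1, `se > 0`, `pval` in (0, 1], `eaf`
#' (when present) strictly inside (0, 1). Rows failing validation are
#' dropped and reported through the `dropped` attribute; an error is
#' raised if no rows survive or if rsids are duplicated.
#'
#' @param records data frame with at least `rsid`, `ea`, `oa`, `beta`, `se`.
#' @param trait trait name.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param units descriptive unit string (e.g. `"SD"` or `"log-odds"`).
#' @param source cohort label recycled into the `source` column when the
#'   column is absent.
#' @return A `summary_set` (data frame subclass).
#' @export
summary_set <- function(records, trait = "trait",
                        trait_type = c("continuous", "binary"),
                        units = "", source = NULL) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  required <- c("rsid", "ea", "oa", "beta", "se")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("summary_set: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("chrom", "pos", "eaf", "pval", "n")) {
    if (is.null(records[[col]])) records[[col]] <- rep(NA, nrow(records))
  }
  if (is.null(records[["source"]])) {
    records$source <- if (is.null(source)) trait else source
  }
  records$rsid  <- as.character(records$rsid)
  records$chrom <- as.character(records$chrom)
  records$ea    <- toupper(as.character(records$ea))
  records$oa    <- toupper(as.character(records$oa))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }

  reasons <- character(nrow(records))
  bad <- function(cond, why) {
    cond <- !is.na(cond) & cond
    reasons[cond & reasons == ""] <<- why
  }
  bad(is.na(records$rsid) | records$rsid == "", "missing rsid")
  bad(records$ea == records$oa, "identical alleles")
  bad(is.na(records$beta), "missing beta")
  bad(is.na(records$se) | records$se <= 0, "nonpositive se")
  bad(records$pos < 1, "nonpositive position")
  bad(records$pval <= 0 | records$pval > 1, "p-value outside (0,1]")
  bad(records$eaf <= 0 | records$eaf >= 1, "eaf outside (0,1)")

  keep <- reasons == ""
  dropped <- data.frame(row = which(!keep),
                        rsid = records$rsid[!keep],
                        reason = reasons[!keep],
                        stringsAsFactors = FALSE)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) stop("summary_set: no rows survived validation")
  if (anyDuplicated(records$rsid)) {
    stop("summary_set: duplicate rsids: ",
         paste(unique(records$rsid[duplicated(records$rsid)]), collapse = ", "))
  }
  rownames(records) <- NULL

  # warn-only internal consistency check of pval against |beta/se|
  has_p <- !is.na(records$pval)
  if (any(has_p)) {
    z <- abs(records$beta[has_p] / records$se[has_p])
    p_implied <- 2 * stats::pnorm(-z)
    lp_rep <- -log10(records$pval[has_p])
    lp_imp <- -log10(pmax(p_implied, 1e-300))
    off <- abs(lp_rep - lp_imp) > 1 & pmin(lp_rep, lp_imp) > 1
    if (any(off)) {
      warning("summary_set: ", sum(off),
              " record(s) have p-values inconsistent with |beta/se|")
    }
  }

  structure(records,
            trait = trait, trait_type = trait_type, units = units,
            dropped = dropped,
            class = c("summary_set", "data.frame"))
}

#' @export
print.summary_set <- function(x, ...) {
  cat(sprintf("summary_set: %d variants, trait '%s' (%s%s)\n",
              nrow(x), attr(x, "trait"), attr(x, "trait_type"),
              if (nzchar(attr(x, "units"))) paste0(", ", attr(x, "units")) else ""))
  dropped <- attr(x, "dropped")
  if (!is.null(dropped) && nrow(dropped) > 0L) {
    cat(sprintf("  (%d input row(s) dropped during validation)\n", nrow(dropped)))
  }
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more\n", nrow(x) - 10L))
  invisible(x)
}

# keep class and metadata through row subsetting
#' @export
`[.summary_set` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("rsid", "beta", "se") %in% names(out))) {
    attr(out, "trait") <- attr(x, "trait")
    attr(out, "trait_type") <- attr(x, "trait_type")
    attr(out, "units") <- attr(x, "units")
    attr(out, "dropped") <- attr(x, "dropped")
    class(out) <- c("summary_set", "data.frame")
  }
  out
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a TSV (or CSV) file with a header row into a validated
#' [summary_set()]. Column names are remapped through `column_map`, whose
#' names are the canonical fields (`rsid`, `chrom`, `pos`, `ea`, `oa`,
#' `eaf`, `beta`, `se`, `pval`, `n`) and whose values are the file's
#' column names. Fields absent from the map default to the canonical
#' header names; unmapped canonical fields that the file lacks are filled
#' with `NA`. Alleles are upper-cased; invalid rows are dropped and
#' logged in the `dropped` attribute.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical fields to
#'   file columns.
#' @param trait,trait_type,units,source trait metadata, see [summary_set()].
#' @param sep field separator; `"\t"` by default, `","` accepted.
#' @return A `summary_set`.
#' @export
read_summary_stats <- function(path, column_map = character(),
                               trait = "trait",
                               trait_type = c("continuous", "binary"),
                               units = "", source = NULL, sep = "\t") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("read_summary_stats: cannot read ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  canonical <- c("rsid", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "pval", "n")
  fields    <- c("rsid", "chrom", "pos", "ea", "oa", "eaf", "beta", "se", "pval", "n")
  map <- stats::setNames(canonical, fields)
  if (length(column_map) > 0L) {
    unknown <- setdiff(names(column_map), fields)
    if (length(unknown) > 0L) {
      stop("read_summary_stats: unknown fields in column_map: ",
           paste(unknown, collapse = ", "))
    }
    map[names(column_map)] <- column_map
  }
  mapped_missing <- names(column_map)[!column_map %in% names(raw)]
  if (length(mapped_missing) > 0L) {
    stop("read_summary_stats: mapped column(s) absent from file: ",
         paste(column_map[mapped_missing], collapse = ", "))
  }
  records <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in fields) {
    records[[f]] <- if (map[[f]] %in% names(raw)) raw[[map[[f]]]] else NA
  }
  summary_set(records, trait = trait, trait_type = trait_type,
              units = units, source = source)
}
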