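#' Define a gene region for cis-instrument selection
#'
#' Coordinates are 1-based inclusive on the GRCh37/hg19 assembly. The
#' flank extends the region by `flank` base pairs on each side; variant
#' positions equal to `start - flank` or `end + flank` are inside.
#'
#' @param name region label (e.g. a gene symbol).
#' @param chrom chromosome label.
#' @param start,end base-pair bounds, `start <= end`.
#' @param flank extension in bp on each side (default 1e5).
#' @return A `gene_region` list.
#' @export
gene_region <- function(name, chrom, start, end, flank = 1e5) {
  stopifnot(start <= end, flank >= 0)
  structure(list(name = as.character(name), chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end),
                 flank = as.numeric(flank)),
            class = "gene_region")
}

#' Default caffeine-metabolism instrument regions
#'
#' The CYP1A2 and AHR gene regions (GRCh37 coordinates from Ensembl),
#' each with a 100 kb flank. Variants in these genes govern the rate of
#' caffeine clearance and are the standard cis instruments for plasma
#' caffeine levels.
#'
#' @param flank flank in bp (default 1e5).
#' @return List of two `gene_region` objects.
#' @export
caffeine_regions <- function(flank = 1e5) {
  list(gene_region("CYP1A2", "15", 75041185, 75048543, flank),
       gene_region("AHR",    "7",  17338246, 17385776, flank))
}

#' Instrument-selection configuration
#'
#' Collects the thresholds of the selection stage: the association
#' p-value cutoff, the clumping r-squared and distance window, and the
#' number of tests used by the FIQT winner's-curse correction. The
#' default p-value threshold, 5e-5, corresponds to a Bonferroni
#' correction at level 0.05 for roughly a thousand variants in the
#' instrument regions (0.05/955 ~ 5.2e-5); see [bonferroni_threshold()].
#'
#' @param p_threshold selection p-value cutoff, in (0, 1) (default 5e-5).
#' @param clump_r2 squared-correlation cutoff for clumping, in (0, 1]
#'   (default 0.3).
#' @param clump_window_kb clumping distance window in kb (default 10000).
#' @param m_total number of tests for FIQT; `NA` (default) means "use
#'   the number of variants in the regions before thresholding".
#' @return A `selection_config` list.
#' @export
selection_config <- function(p_threshold = 5e-5, clump_r2 = 0.3,
                             clump_window_kb = 10000, m_total = NA) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 > 0, clump_r2 <= 1, clump_window_kb > 0)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, m_total = m_total),
            class = "selection_config")
}

#' Bonferroni-derived selection threshold
#'
#' The family-wise threshold `alpha / m` used to motivate the default
#' region-wide selection cutoff: with 955 variants measured across the
#' two caffeine gene regions, `0.05 / 955` is approximately 5e-5.
#'
#' @param m number of tests.
#' @param alpha family-wise level (default 0.05).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  alpha / m
}

region_contains <- function(region, chrom, pos) {
  chrom == region$chrom &
    pos >= region$start - region$flank &
    pos <= region$end + region$flank
}

#' Select cis-region instrument variants
#'
#' Retains variants associated with the exposure at
#' `pval < config$p_threshold` whose position falls inside one of the
#' flanked gene regions (inclusive bounds). Each retained variant is
#' annotated with its region's name in a `region` column; a variant
#' inside several (overlapping) flanked regions is assigned to the first
#' matching region in `regions`. The count of region variants before
#' p-thresholding is stored in the `n_region_variants` attribute — it is
#' the default number of tests for [fiqt_adjust()].
#'
#' @param exposure `summary_set` of variant-exposure associations with
#'   `chrom`, `pos` and `pval` available.
#' @param regions list of [gene_region()] objects.
#' @param config [selection_config()].
#' @return The filtered, region-annotated `summary_set`.
#' @export
select_region_snps <- function(exposure, regions, config = selection_config()) {
  stopifnot(inherits(exposure, "summary_set"))
  if (inherits(regions, "gene_region")) regions <- list(regions)
  assignment <- rep(NA_character_, nrow(exposure))
  for (region in regions) {
    hit <- region_contains(region, exposure$chrom, exposure$pos)
    hit[is.na(hit)] <- FALSE
    assignment[hit & is.na(assignment)] <- region$name
  }
  in_region <- !is.na(assignment)
  pass_p <- !is.na(exposure$pval) & exposure$pval < config$p_threshold
  keep <- in_region & pass_p
  if (!any(keep)) {
    stop("select_region_snps: no variants pass p < ", config$p_threshold,
         " inside the supplied regions (", sum(in_region),
         " region variants examined)")
  }
  out <- exposure[keep, ]
  out$region <- assignment[keep]
  attr(out, "n_region_variants") <- sum(in_region)
  out
}

#' Greedy LD clumping of selected variants
#'
#' Prunes a selected variant set so that no retained pair is both in
#' linkage disequilibrium above `clump_r2` (on r-squared) and within
#' `clump_window_kb` of each other. The algorithm is the field's
#' standard greedy one: repeatedly take the not-yet-removed variant with
#' the smallest p-value (ties broken by rsid lexicographic order, so the
#' result is deterministic) and remove every other remaining variant
#' with `r^2 > clump_r2` against it within the window. Variants on
#' different chromosomes never exclude each other. The retained set is
#' returned in the input order.
#'
#' @param selected `summary_set`, typically from [select_region_snps()].
#' @param ld `ld_matrix` covering all selected rsids.
#' @param config [selection_config()].
#' @return The clumped `summary_set`.
#' @export
clump <- function(selected, ld, config = selection_config()) {
  stopifnot(inherits(selected, "summary_set"))
  missing <- setdiff(selected$rsid, rownames(ld))
  if (length(missing) > 0L) {
    stop("clump: rsid(s) absent from LD matrix: ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(selected)
  r2 <- unclass(ld)[selected$rsid, selected$rsid, drop = FALSE]^2
  window_bp <- config$clump_window_kb * 1000
  # order of consideration: ascending p, rsid as deterministic tie-break
  ord <- order(selected$pval, selected$rsid)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    same_chr <- selected$chrom == selected$chrom[i]
    same_chr[is.na(same_chr)] <- FALSE
    near <- same_chr & abs(selected$pos - selected$pos[i]) <= window_bp
    near[is.na(near)] <- FALSE
    drop <- alive & near & r2[i, ] > config$clump_r2
    alive[drop] <- FALSE
  }
  out <- selected[keep, ]
  attr(out, "n_region_variants") <- attr(selected, "n_region_variants")
  out
}

#' FIQT winner's-curse correction
#'
#' Variants selected for passing a significance threshold have effect
#' sizes that are biased away from zero (winner's curse). The FDR
#' inverse quantile transformation shrinks them: two-sided p-values are
#' Benjamini-Hochberg-adjusted using `m_total` as the number of tests,
#' and each adjusted p is mapped back to a z-score,
#' `z_adj = sign(z) * qnorm(1 - p_adj / 2)`, giving
#' `beta_adj = z_adj * se`. The adjusted beta replaces `beta`; the raw
#' beta is kept in `beta_raw` and `se`/`pval` keep their original
#' values. `|beta_adj| <= |beta|` always. When `p_adj >= 1` the inverse
#' normal argument falls to 0.5 or below and the adjusted beta is set to
#' 0, with a warning.
#'
#' @param selected `summary_set` with `pval` and `se` present on every
#'   record.
#' @param m_total number of tests for the BH adjustment; defaults to the
#'   `n_region_variants` attribute left by [select_region_snps()], and
#'   must be at least the number of records.
#' @return The `summary_set` with shrunken `beta` and added `beta_raw`
#'   and `pval_fiqt` columns.
#' @export
fiqt_adjust <- function(selected, m_total = NULL) {
  stopifnot(inherits(selected, "summary_set"))
  if (any(is.na(selected$pval)) || any(is.na(selected$se))) {
    stop("fiqt_adjust: every record needs pval and se")
  }
  if (is.null(m_total) || is.na(m_total)) {
    m_total <- attr(selected, "n_region_variants")
  }
  if (is.null(m_total)) m_total <- nrow(selected)
  if (m_total < nrow(selected)) {
    stop("fiqt_adjust: m_total (", m_total,
         ") smaller than the number of records (", nrow(selected), ")")
  }
  p_adj <- stats::p.adjust(selected$pval, method = "BH", n = m_total)
  # upper-tail form stays accurate where 1 - p_adj/2 would round to 1
  z_adj <- sign(selected$beta / selected$se) *
    stats::qnorm(p_adj / 2, lower.tail = FALSE)
  dead <- p_adj >= 1
  if (any(dead)) {
    warning("fiqt_adjust: ", sum(dead),
            " record(s) with adjusted p >= 1; adjusted beta set to 0")
    z_adj[dead] <- 0
  }
  out <- selected
  out$beta_raw <- selected$beta
  out$pval_fiqt <- p_adj
  out$beta <- z_adj * selected$se
  attr(out, "n_region_variants") <- attr(selected, "n_region_variants")
  attr(out, "fiqt_m_total") <- m_total
  out
}

#' Instrument-strength diagnostics
#'
#' The mean F statistic of an instrument set, with an LD adjustment:
#' per-variant z-scores `z = beta/se` are decorrelated through the
#' inverse LD matrix, `mean_f = (z' r^{-1} z) / J` for J variants. With
#' independent instruments this is the plain mean of the squared
#' z-scores (`method = "plain"` computes that instead). `1/mean_f`
#' approximates the relative weak-instrument bias of the IVW estimate —
#' e.g. a mean F of 25 suggests roughly 4% bias toward the null.
#'
#' @param selected `summary_set` of the instruments.
#' @param ld `ld_matrix` covering all rsids (ignored for
#'   `method = "plain"`).
#' @param method `"decorrelated"` (default) or `"plain"`.
#' @return A `strength_report` list: `mean_f`, `approx_relative_bias`
#'   (`1/mean_f`), `per_variant_z`, `n_variants`, `method`.
#' @export
instrument_strength <- function(selected, ld = NULL,
                                method = c("decorrelated", "plain")) {
  method <- match.arg(method)
  stopifnot(inherits(selected, "summary_set"))
  z <- selected$beta / selected$se
  names(z) <- selected$rsid
  j <- length(z)
  if (method == "decorrelated") {
    if (is.null(ld)) stop("instrument_strength: ld required for decorrelated F")
    r <- unclass(ld_subset(ld, selected$rsid))
    ri_z <- tryCatch(solve(r, z),
                     error = function(e) stop("instrument_strength: singular LD matrix"))
    mean_f <- as.numeric(crossprod(z, ri_z)) / j
  } else {
    mean_f <- mean(z^2)
  }
  structure(list(mean_f = mean_f,
                 approx_relative_bias = if (mean_f > 0) 1 / mean_f else NA_real_,
                 per_variant_z = z, n_variants = j, method = method),
            class = "strength_report")
}

#' @export
print.strength_report <- function(x, ...) {
  cat(sprintf("Instrument strength (%s): mean F = %.1f over %d variants\n",
              x$method, x$mean_f, x$n_variants))
  cat(sprintf("  approximate relative weak-instrument bias: %.1f%%\n",
              100 * x$approx_relative_bias))
  invisible(x)
}
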