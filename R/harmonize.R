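PALINDROMIC_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the effect alleles of an outcome `summary_set` to those of an
#' exposure `summary_set`, variant by variant. Variants present in only
#' one set are excluded ("missing in other set"). Matching allele pairs
#' in the same orientation are kept unchanged; swapped pairs have the
#' outcome beta sign-flipped and the outcome effect-allele frequency
#' complemented. Palindromic variants (A/T or C/G) cannot be aligned
#' from alleles alone: they are kept only when both effect-allele
#' frequencies are informative, i.e. outside `0.5 +/- eaf_band` and on
#' the same side of 0.5 after alignment; otherwise they are excluded
#' ("palindromic, frequency-ambiguous"), as are palindromic variants
#' missing a frequency. Any other allele pair is excluded
#' ("allele mismatch").
#'
#' @param exposure `summary_set` of variant-exposure associations.
#' @param outcome `summary_set` of variant-outcome associations.
#' @param eaf_band half-width of the frequency band around 0.5 within
#'   which a palindromic variant is declared ambiguous (default 0.08).
#' @return A `harmonized_set`: data frame with one row per retained
#'   variant (exposure columns `beta_exp`, `se_exp`, `pval_exp`, outcome
#'   columns `beta_out`, `se_out`, `pval_out`, `eaf_out`, shared allele
#'   columns `ea`/`oa` in the exposure orientation, and `region` when the
#'   exposure carries assignments), with an `exclusions` attribute
#'   logging every input variant not retained, as `(rsid, reason)`.
#' @export
harmonize <- function(exposure, outcome, eaf_band = 0.08) {
  stopifnot(inherits(exposure, "summary_set"), inherits(outcome, "summary_set"))
  if (nrow(exposure) == 0L || nrow(outcome) == 0L) {
    stop("harmonize: empty summary set")
  }
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0L) stop("harmonize: no shared variants")

  excl <- list()
  note <- function(rsid, reason) {
    excl[[length(excl) + 1L]] <<- data.frame(rsid = rsid, reason = reason,
                                             stringsAsFactors = FALSE)
  }
  only_x <- setdiff(exposure$rsid, outcome$rsid)
  only_y <- setdiff(outcome$rsid, exposure$rsid)
  for (r in c(only_x, only_y)) note(r, "missing in other set")

  ix <- match(shared, exposure$rsid)
  iy <- match(shared, outcome$rsid)
  rows <- vector("list", length(shared))
  for (k in seq_along(shared)) {
    ex <- exposure[ix[k], ]
    ou <- outcome[iy[k], ]
    same    <- ou$ea == ex$ea && ou$oa == ex$oa
    swapped <- ou$ea == ex$oa && ou$oa == ex$ea
    if (!same && !swapped) {
      note(shared[k], "allele mismatch")
      next
    }
    beta_out <- if (swapped) -ou$beta else ou$beta
    eaf_out  <- if (swapped && !is.na(ou$eaf)) 1 - ou$eaf else ou$eaf
    if (is_palindromic(ex$ea, ex$oa)) {
      # palindromic: same/swapped is indistinguishable from a strand flip,
      # so alignment must be supported by the allele frequencies
      ok <- !is.na(ex$eaf) && !is.na(eaf_out) &&
        abs(ex$eaf - 0.5) > eaf_band && abs(eaf_out - 0.5) > eaf_band &&
        sign(ex$eaf - 0.5) == sign(eaf_out - 0.5)
      if (!ok) {
        note(shared[k], "palindromic, frequency-ambiguous")
        next
      }
    }
    rows[[k]] <- data.frame(
      rsid = shared[k], chrom = ex$chrom, pos = ex$pos,
      ea = ex$ea, oa = ex$oa, eaf = ex$eaf,
      region = if (!is.null(ex$region)) ex$region else NA_character_,
      beta_exp = ex$beta, se_exp = ex$se, pval_exp = ex$pval,
      beta_exp_raw = if (!is.null(ex$beta_raw)) ex$beta_raw else ex$beta,
      beta_out = beta_out, se_out = ou$se, pval_out = ou$pval,
      eaf_out = eaf_out, n_out = ou$n, source_out = ou$source,
      stringsAsFactors = FALSE)
  }
  kept <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  exclusions <- if (length(excl) > 0L) {
    do.call(rbind, excl)
  } else {
    data.frame(rsid = character(), reason = character(), stringsAsFactors = FALSE)
  }
  if (is.null(kept)) {
    stop("harmonize: no variants retained (",
         nrow(exclusions), " excluded)")
  }
  rownames(kept) <- NULL
  structure(kept,
            exposure_trait = attr(exposure, "trait"),
            outcome_trait = attr(outcome, "trait"),
            eaf_band = eaf_band,
            exclusions = exclusions,
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("harmonized_set: %d variants (%s -> %s), %d excluded\n",
              nrow(x), attr(x, "exposure_trait"), attr(x, "outcome_trait"),
              nrow(attr(x, "exclusions"))))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' @export
`[.harmonized_set` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("rsid", "beta_exp", "beta_out") %in% names(out))) {
    for (a in c("exposure_trait", "outcome_trait", "eaf_band", "exclusions")) {
      attr(out, a) <- attr(x, a)
    }
    class(out) <- c("harmonized_set", "data.frame")
  }
  out
}
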