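#' Fixed-effect (inverse-variance) meta-analysis of one variant's
#' association across cohorts
#'
#' Combines per-cohort association records for a single variant with
#' weights `w_i = 1/se_i^2`: pooled `beta = sum(w b) / sum(w)`,
#' `se = 1/sqrt(sum(w))`, and a two-sided normal p-value recomputed from
#' the pooled z. All records must describe the same variant with the
#' same aligned effect allele. The pooled record's `source` is `"meta"`
#' and its `n` is the sum of the available cohort sizes.
#'
#' @param per_source data frame of association records (one row per
#'   cohort) with columns `rsid`, `ea`, `oa`, `beta`, `se` and
#'   optionally `n`; at least one row.
#' @return A one-row data frame in the same record layout.
#' @export
fixed_effect_meta <- function(per_source) {
  stopifnot(is.data.frame(per_source), nrow(per_source) >= 1L)
  if (length(unique(per_source$rsid)) != 1L) {
    stop("fixed_effect_meta: records describe different variants")
  }
  if (length(unique(per_source$ea)) != 1L ||
      length(unique(per_source$oa)) != 1L) {
    stop("fixed_effect_meta: effect alleles not aligned across sources for ",
         per_source$rsid[1L])
  }
  w <- 1 / per_source$se^2
  beta <- sum(w * per_source$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  out <- per_source[1L, , drop = FALSE]
  out$beta <- beta
  out$se <- se
  out$pval <- 2 * stats::pnorm(-abs(beta / se))
  out$source <- "meta"
  if (!is.null(per_source$n)) {
    out$n <- if (all(is.na(per_source$n))) NA_real_ else
      sum(per_source$n, na.rm = TRUE)
  }
  if (!is.null(per_source$eaf)) {
    out$eaf <- if (all(is.na(per_source$eaf))) NA_real_ else
      mean(per_source$eaf, na.rm = TRUE)
  }
  rownames(out) <- NULL
  out
}

#' Cochran's Q heterogeneity test
#'
#' Computes Cochran's Q around the fixed-effect pooled mean of a set of
#' estimates, `Q = sum(w_i (b_i - pooled)^2)` with `w_i = 1/se_i^2`,
#' with `df = k - 1` degrees of freedom, the Higgins I-squared statistic
#' `I^2 = max(0, (Q - df)/Q)` (0 when Q = 0), and an upper-tail
#' chi-square p-value.
#'
#' @param beta numeric vector of estimates (length >= 2).
#' @param se their standard errors.
#' @return A `het_result` list: `q`, `df`, `i2`, `p_het`, `k`.
#' @export
cochran_q <- function(beta, se) {
  stopifnot(length(beta) == length(se))
  if (length(beta) < 2L) stop("cochran_q: need at least 2 estimates")
  stopifnot(all(se > 0))
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - pooled)^2)
  df <- length(beta) - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) else 0
  structure(list(q = q, df = df, i2 = i2,
                 p_het = stats::pchisq(q, df, lower.tail = FALSE),
                 k = length(beta)),
            class = "het_result")
}

#' @export
print.het_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df (p = %.3g), I^2 = %.0f%%\n",
              x$q, x$df, x$p_het, 100 * x$i2))
  invisible(x)
}

#' Additive (DerSimonian-Laird) random-effects meta-analysis
#'
#' Pools estimates allowing for between-estimate heterogeneity: the
#' method-of-moments between-study variance is
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with fixed
#' weights `w_i = 1/se_i^2`; random-effects weights are
#' `w*_i = 1/(se_i^2 + tau2)`; the pooled estimate, its standard error
#' `1/sqrt(sum(w*))`, a 95% normal CI and a two-sided p-value follow.
#' When Q <= df, tau2 is exactly 0 and the result equals the
#' fixed-effect pool.
#'
#' @param beta numeric vector of estimates (length >= 2).
#' @param se their standard errors.
#' @param label analysis tag carried into the result.
#' @return An `mr_estimate` (see [correlated_ivw()]) with `tau2` and the
#'   heterogeneity result attached.
#' @export
random_effects_meta <- function(beta, se, label = "random-effects meta") {
  if (length(beta) < 2L) stop("random_effects_meta: need at least 2 estimates")
  het <- cochran_q(beta, se)
  w <- 1 / se^2
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (het$q - het$df) / denom) else 0
  w_star <- 1 / (se^2 + tau2)
  b <- sum(w_star * beta) / sum(w_star)
  s <- 1 / sqrt(sum(w_star))
  est <- mr_estimate(beta = b, se = s, n_variants = length(beta),
                     q = het$q, phi = 1, label = label)
  est$tau2 <- tau2
  est$het <- het
  est
}
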