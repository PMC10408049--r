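#' Construct an MR estimate
#'
#' Container for a causal-slope estimate on the log-odds-per-SD scale:
#' point estimate, standard error, 95% normal confidence interval,
#' two-sided p-value, number of variants, residual heterogeneity Q and
#' the multiplicative overdispersion factor `phi >= 1`.
#'
#' @param beta pooled slope.
#' @param se standard error (> 0).
#' @param n_variants number of instruments used.
#' @param q residual heterogeneity statistic.
#' @param phi overdispersion factor, floored at 1.
#' @param label analysis tag.
#' @return An `mr_estimate` list with `ci_low`, `ci_high` and `pval`
#'   filled in.
#' @export
mr_estimate <- function(beta, se, n_variants, q = NA_real_, phi = 1,
                        label = "") {
  stopifnot(se > 0, phi >= 1)
  z <- stats::qnorm(0.975)
  structure(list(beta = beta, se = se,
                 ci_low = beta - z * se, ci_high = beta + z * se,
                 pval = 2 * stats::pnorm(-abs(beta / se)),
                 n_variants = as.integer(n_variants),
                 q = q, phi = phi, label = label),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate%s: beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  %d variant(s); Q = %s, overdispersion phi = %.3f\n",
              x$n_variants,
              if (is.na(x$q)) "NA" else sprintf("%.3f", x$q), x$phi))
  if (!is.null(x$or)) {
    cat(sprintf("  OR per SD = %.3f [%.3f, %.3f]\n",
                x$or, exp(x$ci_low), exp(x$ci_high)))
  }
  invisible(x)
}

#' Per-variant Wald ratio
#'
#' The single-instrument causal estimate: the ratio of the
#' variant-outcome association to the variant-exposure association,
#' `theta = beta_out / beta_exp`, with the first-order delta-method
#' standard error `se_out / |beta_exp|` (exposure uncertainty ignored,
#' consistent with first-order IVW weights).
#'
#' @param h `harmonized_set` (one ratio per row).
#' @return Data frame with `rsid`, `theta`, `se_theta`, `region`.
#' @export
wald_ratio <- function(h) {
  stopifnot(inherits(h, "harmonized_set") || is.data.frame(h))
  if (any(h$beta_exp == 0)) {
    stop("wald_ratio: zero exposure beta for ",
         paste(h$rsid[h$beta_exp == 0], collapse = ", "))
  }
  data.frame(rsid = h$rsid,
             theta = h$beta_out / h$beta_exp,
             se_theta = h$se_out / abs(h$beta_exp),
             region = if (!is.null(h$region)) h$region else NA_character_,
             stringsAsFactors = FALSE)
}

#' Correlated-variant IVW estimator (multiplicative random effects)
#'
#' Generalized least squares regression of the outcome associations on
#' the exposure associations through the origin, with the residual
#' covariance `Omega[j,k] = se_out[j] * se_out[k] * r[j,k]` built from
#' the signed LD matrix:
#' `beta = (g' Omega^-1 g)^-1 g' Omega^-1 G` for exposure betas `g` and
#' outcome betas `G`. Residual heterogeneity
#' `Q = (G - beta g)' Omega^-1 (G - beta g)` inflates the variance
#' multiplicatively through `phi = max(1, Q/(J-1))` (J >= 2; phi = 1 for
#' a single variant): `se = sqrt(phi / (g' Omega^-1 g))`. The
#' overdispersion can widen but never narrow the confidence interval,
#' and the point estimate is unchanged by it. With J = 1 the estimator
#' reduces exactly to the Wald ratio; with `r = I` it reduces to the
#' standard first-order-weights IVW of the Wald ratios.
#'
#' The signed `r` must be aligned to the harmonized effect alleles: if a
#' variant's alleles are flipped relative to the panel the corresponding
#' row and column of `r` change sign (see [align_ld_signs()]).
#'
#' @param h `harmonized_set` with at least one variant.
#' @param ld `ld_matrix` covering all variants of `h`.
#' @param label analysis tag.
#' @return An `mr_estimate`.
#' @export
correlated_ivw <- function(h, ld, label = "") {
  stopifnot(nrow(h) >= 1L)
  g <- h$beta_exp
  G <- h$beta_out
  s <- h$se_out
  if (any(g == 0)) stop("correlated_ivw: zero exposure beta")
  if (nrow(h) == 1L) {
    # exact single-variant reduction: the Wald ratio
    return(mr_estimate(beta = G / g, se = s / abs(g), n_variants = 1L,
                       q = 0, phi = 1, label = label))
  }
  r <- unclass(ld_subset(ld, h$rsid))
  omega <- outer(s, s) * r
  oi_g <- tryCatch(solve(omega, g),
                   error = function(e) stop("correlated_ivw: singular Omega"))
  oi_G <- solve(omega, G)
  v <- 1 / as.numeric(crossprod(g, oi_g))
  beta <- v * as.numeric(crossprod(g, oi_G))
  resid <- G - beta * g
  q <- as.numeric(crossprod(resid, solve(omega, resid)))
  j <- nrow(h)
  phi <- if (j >= 2L) max(1, q / (j - 1L)) else 1
  mr_estimate(beta = beta, se = sqrt(v * phi), n_variants = j,
              q = q, phi = phi, label = label)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-runs [correlated_ivw()] once per omitted variant, subsetting the
#' (already repaired) LD matrix each time. A variant whose omission
#' moves the pooled slope materially flags an outlier.
#'
#' @param h `harmonized_set` with >= 2 variants.
#' @param ld `ld_matrix` covering `h`.
#' @return List of `mr_estimate`, labeled `"-<rsid>"` by the omitted
#'   variant.
#' @export
leave_one_out <- function(h, ld) {
  if (nrow(h) < 2L) stop("leave_one_out: need at least 2 variants")
  out <- vector("list", nrow(h))
  for (k in seq_len(nrow(h))) {
    out[[k]] <- correlated_ivw(h[-k, ], ld,
                               label = paste0("-", h$rsid[k]))
  }
  names(out) <- h$rsid
  out
}

#' Per-gene-region estimates and between-region heterogeneity
#'
#' Runs [correlated_ivw()] separately on each gene region's variants
#' and tests heterogeneity of the region-level slopes with Cochran's Q.
#' Concordant region estimates support a shared causal pathway through
#' the exposure; discordance suggests region-specific pleiotropy.
#'
#' @param h `harmonized_set` whose `region` column is fully assigned,
#'   with >= 2 distinct regions.
#' @param ld `ld_matrix` covering `h`.
#' @return List with `estimates` (one `mr_estimate` per region, named)
#'   and `het` (a `het_result` across regions).
#' @export
per_gene_estimates <- function(h, ld) {
  if (any(is.na(h$region))) {
    stop("per_gene_estimates: unassigned region for ",
         paste(h$rsid[is.na(h$region)], collapse = ", "))
  }
  regions <- unique(h$region)
  if (length(regions) < 2L) {
    stop("per_gene_estimates: need >= 2 regions (got ",
         length(regions), "); heterogeneity has 0 df")
  }
  ests <- lapply(regions, function(g) {
    correlated_ivw(h[h$region == g, ], ld, label = g)
  })
  names(ests) <- regions
  het <- cochran_q(vapply(ests, `[[`, numeric(1), "beta"),
                   vapply(ests, `[[`, numeric(1), "se"))
  list(estimates = ests, het = het)
}

#' Lead-variant analysis
#'
#' Replicates the MR analysis using only one lead variant per gene
#' region. Leads on different chromosomes are uncorrelated, so the
#' relevant LD submatrix is (close to) the identity and the estimate
#' reduces to an independent-variant IVW; it is less precise than the
#' full correlated-variant analysis but free of within-region LD
#' modeling assumptions.
#'
#' @param h `harmonized_set`.
#' @param ld `ld_matrix` covering `h`.
#' @param leads character vector of lead rsids, all present in `h`.
#' @return An `mr_estimate` labeled `"lead"`.
#' @export
lead_snp_analysis <- function(h, ld, leads) {
  missing <- setdiff(leads, h$rsid)
  if (length(missing) > 0L) {
    stop("lead_snp_analysis: lead(s) absent from harmonized set: ",
         paste(missing, collapse = ", "))
  }
  correlated_ivw(h[match(leads, h$rsid), ], ld, label = "lead")
}

#' Align LD matrix signs to harmonized effect alleles
#'
#' When a variant's harmonized effect allele is the complement of the
#' allele the LD panel counted, the signed correlations involving that
#' variant change sign. Given the set of rsids whose orientation was
#' flipped during harmonization, flips the corresponding rows and
#' columns of `r`.
#'
#' @param ld `ld_matrix`.
#' @param flipped rsids whose effect allele was flipped.
#' @return The sign-aligned `ld_matrix`.
#' @export
align_ld_signs <- function(ld, flipped) {
  if (length(flipped) == 0L) return(ld)
  s <- ifelse(rownames(ld) %in% flipped, -1, 1)
  r <- unclass(ld) * outer(s, s)
  structure(r, psd_repaired = attr(ld, "psd_repaired"),
            class = c("ld_matrix", "matrix", "array"))
}
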