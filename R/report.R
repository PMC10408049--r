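#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate control across the family of primary
#' outcome tests: adjusted values are `min over j >= rank(i) of
#' p(j) * m / j`, capped at 1, hence monotone non-decreasing in the raw
#' p-values. Delegates to [stats::p.adjust()] after validating that all
#' p-values lie in (0, 1].
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("bh_fdr: p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Convert an MR estimate to the odds-ratio scale
#'
#' Exponentiates the slope and its confidence bounds. The odds ratio is
#' the multiplicative change in outcome odds per standard-deviation
#' increase in the exposure.
#'
#' @param est `mr_estimate` on the log-odds scale.
#' @param outcome outcome name for the record.
#' @param p_fdr FDR-adjusted p-value, when the estimate belongs to a
#'   multiple-testing family.
#' @return An `or_record` list: `outcome`, `or`, `ci_low`, `ci_high`,
#'   `pval`, `p_fdr`, `n_variants`.
#' @export
to_odds_ratio <- function(est, outcome = est$label, p_fdr = NA_real_) {
  stopifnot(inherits(est, "mr_estimate"))
  structure(list(outcome = outcome,
                 or = exp(est$beta),
                 ci_low = exp(est$ci_low), ci_high = exp(est$ci_high),
                 pval = est$pval, p_fdr = p_fdr,
                 n_variants = est$n_variants),
            class = "or_record")
}

#' @export
print.or_record <- function(x, ...) {
  cat(sprintf("%s: OR per SD = %.3f [%.3f, %.3f], p = %.3g%s (%d variants)\n",
              x$outcome, x$or, x$ci_low, x$ci_high, x$pval,
              if (!is.na(x$p_fdr)) sprintf(", p_FDR = %.3g", x$p_fdr) else "",
              x$n_variants))
  invisible(x)
}

est_row <- function(outcome, analysis, est, p_fdr = NA_real_) {
  data.frame(outcome = outcome, analysis = analysis,
             beta = est$beta, se = est$se,
             ci_low = est$ci_low, ci_high = est$ci_high,
             pval = est$pval, p_fdr = p_fdr,
             or = exp(est$beta),
             or_ci_low = exp(est$ci_low), or_ci_high = exp(est$ci_high),
             n_variants = est$n_variants,
             q = est$q, phi = est$phi,
             stringsAsFactors = FALSE)
}

# per-variant fixed-effect meta of outcome associations across the
# harmonized per-source sets; variants covered by a single source pass
# through unpooled (sources differ in variant coverage)
meta_outcome_sets <- function(per_source_h) {
  if (length(per_source_h) == 1L) return(per_source_h[[1L]])
  rsids <- unique(unlist(lapply(per_source_h, function(h) h$rsid)))
  template <- per_source_h[[1L]]
  rows <- lapply(rsids, function(rs) {
    recs <- do.call(rbind, lapply(per_source_h, function(h) {
      hit <- h[h$rsid == rs, , drop = FALSE]
      if (nrow(hit) == 0L) NULL else
        data.frame(rsid = hit$rsid, ea = hit$ea, oa = hit$oa,
                   beta = hit$beta_out, se = hit$se_out,
                   eaf = hit$eaf_out, n = hit$n_out,
                   stringsAsFactors = FALSE)
    }))
    pooled <- fixed_effect_meta(recs)
    base <- NULL
    for (h in per_source_h) {
      hit <- h[h$rsid == rs, , drop = FALSE]
      if (nrow(hit) > 0L) { base <- hit; break }
    }
    base$beta_out <- pooled$beta
    base$se_out <- pooled$se
    base$pval_out <- pooled$pval
    base$eaf_out <- pooled$eaf
    base$n_out <- pooled$n
    base$source_out <- "meta"
    base$n_sources <- nrow(recs)
    as.data.frame(base)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (a in c("exposure_trait", "outcome_trait", "eaf_band")) {
    attr(out, a) <- attr(template, a)
  }
  attr(out, "exclusions") <- do.call(rbind, lapply(per_source_h,
                                                   attr, "exclusions"))
  class(out) <- c("harmonized_set", "data.frame")
  out
}

#' Run the full cis-MR pipeline
#'
#' Executes the analysis end to end: region selection at the configured
#' p-value threshold, LD clumping, FIQT winner's-curse correction,
#' instrument-strength diagnostics; then per outcome: harmonization of
#' each cohort's associations to the instrument alleles, per-variant
#' fixed-effect meta-analysis when two cohorts cover a variant, the
#' correlated-variant IVW estimate, and the sensitivity suite
#' (leave-one-out, per-gene-region estimates with between-region
#' heterogeneity, between-source heterogeneity with an additive
#' random-effects pool, lead-variant analysis); finally
#' Benjamini-Hochberg FDR adjustment across the primary outcome
#' p-values. The run is fully deterministic given its configuration.
#'
#' @param exposure `summary_set` of variant-exposure associations
#'   (continuous trait, SD units).
#' @param outcomes named list of outcomes; each element is a list of one
#'   or two `summary_set`s (cohorts) for that outcome.
#' @param ld `ld_matrix` covering the candidate instrument region.
#' @param regions list of [gene_region()]; defaults to
#'   [caffeine_regions()].
#' @param config [selection_config()].
#' @param eaf_band palindromic ambiguity band for [harmonize()].
#' @param leads optional lead rsids for [lead_snp_analysis()]; the lead
#'   analysis runs for an outcome only when every lead survives
#'   harmonization there.
#' @param fiqt apply the winner's-curse correction (default TRUE).
#' @param seed echoed into the bundle for provenance (the pipeline
#'   itself draws no random numbers).
#' @return A `result_bundle`: per outcome the primary `mr_estimate` and
#'   `or_record`, per-source estimates with their heterogeneity and
#'   random-effects pool, per-gene estimates and heterogeneity, the
#'   leave-one-out series and lead estimate; globally the instrument
#'   table, `strength_report`, exclusion log and config echo.
#' @export
run_pipeline <- function(exposure, outcomes, ld,
                         regions = caffeine_regions(),
                         config = selection_config(),
                         eaf_band = 0.08, leads = NULL,
                         fiqt = TRUE, seed = NA) {
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    stop("run_pipeline: outcomes must be a named list")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("run_pipeline [", name, "]: ", conditionMessage(e), call. = FALSE)
    })
  }
  instruments <- stage("select", select_region_snps(exposure, regions, config))
  instruments <- stage("clump", clump(instruments, ld, config))
  if (fiqt) {
    m_total <- if (is.na(config$m_total)) NULL else config$m_total
    instruments <- stage("fiqt", fiqt_adjust(instruments, m_total))
  }
  strength <- stage("strength", instrument_strength(instruments, ld))

  results <- list()
  for (oc in names(outcomes)) {
    sources <- outcomes[[oc]]
    if (inherits(sources, "summary_set")) sources <- list(sources)
    per_source_h <- lapply(sources, function(s) {
      stage(paste0("harmonize:", oc),
            harmonize(instruments, s, eaf_band = eaf_band))
    })
    h <- stage(paste0("meta:", oc), meta_outcome_sets(per_source_h))
    primary <- stage(paste0("ivw:", oc), correlated_ivw(h, ld, label = oc))

    source_ests <- lapply(per_source_h, function(hs) {
      correlated_ivw(hs, ld, label = unique(hs$source_out)[1L])
    })
    source_het <- NULL
    source_re <- NULL
    if (length(source_ests) >= 2L) {
      sb <- vapply(source_ests, `[[`, numeric(1), "beta")
      ss <- vapply(source_ests, `[[`, numeric(1), "se")
      source_het <- cochran_q(sb, ss)
      source_re <- random_effects_meta(sb, ss,
                                       label = paste0(oc, " (source RE meta)"))
    }
    loo <- if (nrow(h) >= 2L) leave_one_out(h, ld) else list()
    per_gene <- if (length(unique(h$region[!is.na(h$region)])) >= 2L &&
                    !any(is.na(h$region))) {
      per_gene_estimates(h, ld)
    } else NULL
    lead <- if (!is.null(leads) && all(leads %in% h$rsid)) {
      lead_snp_analysis(h, ld, leads)
    } else NULL

    results[[oc]] <- list(outcome = oc, harmonized = h,
                          primary = primary,
                          per_source = source_ests,
                          source_het = source_het, source_re = source_re,
                          loo = loo, per_gene = per_gene, lead = lead)
  }

  p_raw <- vapply(results, function(r) r$primary$pval, numeric(1))
  p_fdr <- unname(bh_fdr(p_raw))
  for (k in seq_along(results)) {
    results[[k]]$or <- to_odds_ratio(results[[k]]$primary,
                                     outcome = names(results)[k],
                                     p_fdr = p_fdr[k])
  }

  structure(list(outcomes = results,
                 instruments = as.data.frame(instruments),
                 strength = strength,
                 regions = regions,
                 config = config, eaf_band = eaf_band, leads = leads,
                 fiqt = fiqt, seed = seed),
            class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("cis-MR result bundle: %d outcome(s), %d instrument(s), mean F = %.1f\n",
              length(x$outcomes), nrow(x$instruments), x$strength$mean_f))
  for (r in x$outcomes) print(r$or)
  invisible(x)
}

#' Serialize a result bundle to TSV tables plus run metadata
#'
#' Writes six files into `out_dir`: `estimates.tsv` (one row per outcome
#' and analysis label, with slope, SE, CI, p, FDR-adjusted p, and
#' odds-ratio-scale columns rounded to 3 decimals), `loo.tsv`
#' (leave-one-out series), `heterogeneity.tsv` (between-gene and
#' between-source Q/I-squared), `instruments.tsv`, `exclusions.tsv`
#' (harmonization exclusion log) and `run.json` (config echo, package
#' version, seed; full precision). Output is deterministic: rerunning
#' the same bundle reproduces the files byte for byte.
#'
#' @param bundle `result_bundle` from [run_pipeline()].
#' @param out_dir output directory, created if absent.
#' @return Character vector of the six file paths (the manifest),
#'   invisibly.
#' @export
write_results <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_results: cannot create ", out_dir)
  }
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    path
  }
  round3 <- function(df) {
    for (col in c("or", "or_ci_low", "or_ci_high")) {
      if (!is.null(df[[col]])) df[[col]] <- round(df[[col]], 3)
    }
    df
  }

  est_rows <- list(); loo_rows <- list(); het_rows <- list()
  for (r in bundle$outcomes) {
    est_rows[[length(est_rows) + 1L]] <-
      est_row(r$outcome, "primary", r$primary, p_fdr = r$or$p_fdr)
    for (se_ in r$per_source) {
      est_rows[[length(est_rows) + 1L]] <-
        est_row(r$outcome, paste0("source:", se_$label), se_)
    }
    if (!is.null(r$source_re)) {
      est_rows[[length(est_rows) + 1L]] <-
        est_row(r$outcome, "source-re-meta", r$source_re)
    }
    if (!is.null(r$per_gene)) {
      for (g in names(r$per_gene$estimates)) {
        est_rows[[length(est_rows) + 1L]] <-
          est_row(r$outcome, paste0("gene:", g), r$per_gene$estimates[[g]])
      }
      het_rows[[length(het_rows) + 1L]] <-
        data.frame(outcome = r$outcome, contrast = "between-gene",
                   q = r$per_gene$het$q, df = r$per_gene$het$df,
                   i2 = r$per_gene$het$i2, p_het = r$per_gene$het$p_het,
                   stringsAsFactors = FALSE)
    }
    if (!is.null(r$source_het)) {
      het_rows[[length(het_rows) + 1L]] <-
        data.frame(outcome = r$outcome, contrast = "between-source",
                   q = r$source_het$q, df = r$source_het$df,
                   i2 = r$source_het$i2, p_het = r$source_het$p_het,
                   stringsAsFactors = FALSE)
    }
    if (!is.null(r$lead)) {
      est_rows[[length(est_rows) + 1L]] <-
        est_row(r$outcome, "lead", r$lead)
    }
    for (l in r$loo) {
      loo_rows[[length(loo_rows) + 1L]] <-
        cbind(data.frame(outcome = r$outcome, omitted = sub("^-", "", l$label),
                         stringsAsFactors = FALSE),
              est_row(r$outcome, "loo", l)[, -(1:2)])
    }
  }
  loo_template <- data.frame(outcome = character(), omitted = character(),
                             beta = numeric(), se = numeric(),
                             ci_low = numeric(), ci_high = numeric(),
                             pval = numeric(), p_fdr = numeric(),
                             or = numeric(), or_ci_low = numeric(),
                             or_ci_high = numeric(),
                             n_variants = integer(), q = numeric(),
                             phi = numeric(), stringsAsFactors = FALSE)
  het_template <- data.frame(outcome = character(), contrast = character(),
                             q = numeric(), df = integer(), i2 = numeric(),
                             p_het = numeric(), stringsAsFactors = FALSE)

  exclusions <- do.call(rbind, c(
    list(data.frame(outcome = character(), rsid = character(),
                    reason = character(), stringsAsFactors = FALSE)),
    lapply(bundle$outcomes, function(r) {
      ex <- attr(r$harmonized, "exclusions")
      if (is.null(ex) || nrow(ex) == 0L) return(NULL)
      cbind(data.frame(outcome = r$outcome, stringsAsFactors = FALSE), ex)
    })))

  manifest <- c(
    tsv(round3(do.call(rbind, est_rows)), "estimates.tsv"),
    tsv(if (length(loo_rows) > 0L) round3(do.call(rbind, loo_rows)) else loo_template,
        "loo.tsv"),
    tsv(if (length(het_rows) > 0L) do.call(rbind, het_rows) else het_template,
        "heterogeneity.tsv"),
    tsv(bundle$instruments, "instruments.tsv"),
    tsv(exclusions, "exclusions.tsv"))

  run <- list(
    package = "cismr",
    version = as.character(utils::packageVersion("cismr")),
    seed = bundle$seed,
    eaf_band = bundle$eaf_band,
    fiqt = bundle$fiqt,
    leads = bundle$leads,
    config = unclass(bundle$config),
    regions = lapply(bundle$regions, unclass),
    strength = list(mean_f = bundle$strength$mean_f,
                    approx_relative_bias = bundle$strength$approx_relative_bias,
                    method = bundle$strength$method),
    outcomes = lapply(bundle$outcomes, function(r) {
      list(or = r$or$or, ci_low = r$or$ci_low, ci_high = r$or$ci_high,
           beta = r$primary$beta, se = r$primary$se,
           pval = r$primary$pval, p_fdr = r$or$p_fdr,
           n_variants = r$primary$n_variants)
    }))
  run_path <- file.path(out_dir, "run.json")
  jsonlite::write_json(run, run_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest <- c(manifest, run_path)
  invisible(manifest)
}
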