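NON_PALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                  "G", "A", "C", "A", "G", "T", "C", "T"),
                                ncol = 2, byrow = TRUE)

#' Configuration of the synthetic cis-region generator
#'
#' Describes the generating model for two-sample summary statistics over
#' one or more cis gene regions. Within each region the signed LD
#' follows an AR(1) structure, `r[j,k] = ld_decay^|j-k|`; regions are
#' mutually uncorrelated. A sparse vector of causal per-allele effects
#' (SD units of the exposure) is propagated through LD into the marginal
#' effects the GWAS measures, `gamma = R gamma_causal`. Outcome
#' log-odds associations follow a single causal slope,
#' `Gamma = true_slope * gamma + pleiotropy`, in every cohort.
#'
#' The defaults mirror a plasma-caffeine-style study: two regions
#' (CYP1A2-like on chromosome 15 and AHR-like on chromosome 7, 25
#' variants each, decay 0.9), seven causal signals across the regions
#' strong enough that region-wide selection at p < 5e-5 followed by
#' clumping at r-squared 0.3 retains about seven quasi-independent
#' instruments with a decorrelated mean F statistic of a few tens, an
#' exposure GWAS of ten thousand individuals, and one binary outcome
#' cohort of 300,000 (10% cases) linked by a causal slope of 0.1
#' log-odds per SD.
#'
#' @param regions list of [gene_region()] objects.
#' @param n_snps variants per region (recycled).
#' @param ld_decay AR(1) correlation parameter per region, in [0, 1)
#'   (recycled).
#' @param maf_range range of the uniform minor-allele-frequency draw.
#' @param causal list (one element per region) of named numeric vectors:
#'   names are variant indices within the region, values are causal
#'   per-allele effects in SD units.
#' @param n_exposure exposure GWAS sample size.
#' @param outcomes named list of outcomes; each outcome is a list with
#'   `true_slope` (log-odds per SD), optional `pleiotropy` (per-variant
#'   direct log-odds effects, length = total variants), and `sources`, a
#'   named list of cohorts each holding `n_cases` and `n_controls`.
#' @param pos_start,pos_step base-pair position of the first variant and
#'   spacing per region (recycled).
#' @return A `sim_config` list.
#' @export
sim_config <- function(regions = caffeine_regions(),
                       n_snps = 25,
                       ld_decay = 0.9,
                       maf_range = c(0.1, 0.5),
                       causal = list(
                         c("4" = 0.080, "10" = 0.072, "16" = 0.088, "22" = 0.072),
                         c("5" = 0.072, "13" = 0.088, "21" = 0.080)),
                       n_exposure = 10000,
                       outcomes = list(
                         disorder = list(
                           true_slope = 0.1,
                           sources = list(
                             cohort1 = list(n_cases = 30000,
                                            n_controls = 270000)))),
                       pos_start = c(74945000, 17240000),
                       pos_step = 8000) {
  k <- length(regions)
  n_snps <- rep(n_snps, length.out = k)
  ld_decay <- rep(ld_decay, length.out = k)
  pos_start <- rep(pos_start, length.out = k)
  pos_step <- rep(pos_step, length.out = k)
  stopifnot(all(ld_decay >= 0), all(ld_decay < 1),
            all(maf_range > 0), all(maf_range <= 0.5),
            maf_range[1] <= maf_range[2],
            n_exposure >= 2, length(causal) == k)
  for (oc in outcomes) {
    for (s in oc$sources) {
      stopifnot(s$n_cases >= 1, s$n_controls >= 1,
                s$n_cases + s$n_controls >= 2)
    }
  }
  structure(list(regions = regions, n_snps = n_snps, ld_decay = ld_decay,
                 maf_range = maf_range, causal = causal,
                 n_exposure = n_exposure, outcomes = outcomes,
                 pos_start = pos_start, pos_step = pos_step),
            class = "sim_config")
}

# block-diagonal AR(1) signed LD over all regions
sim_ld <- function(config) {
  blocks <- lapply(seq_along(config$regions), function(g) {
    n <- config$n_snps[g]
    config$ld_decay[g]^abs(outer(seq_len(n), seq_len(n), "-"))
  })
  total <- sum(config$n_snps)
  r <- matrix(0, total, total)
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    r[idx, idx] <- b
    at <- at + nrow(b)
  }
  rsids <- unlist(lapply(seq_along(config$regions), function(g) {
    sprintf("rs%d%03d", g, seq_len(config$n_snps[g]))
  }))
  ld_matrix(r, rsids = rsids)
}

#' Simulate two-sample cis-region summary statistics with known truth
#'
#' Draws one realization of the generating model described by
#' [sim_config()]. Exposure effect estimates are sampled as
#' `gamma_hat ~ MVN(gamma, Dx R Dx)` where `Dx` is diagonal with the
#' standard GWAS standard error `se(gamma_hat_j) =
#' 1/sqrt(2 n_exposure f_j (1 - f_j))`; correlated sampling noise
#' reflects that all associations come from the same cohort. For each
#' binary-outcome cohort, `Gamma_hat ~ MVN(Gamma, Dy R Dy)` with the
#' effective-sample-size approximation `se(Gamma_hat_j) =
#' 1/sqrt(2 n v f_j (1 - f_j))`, `v = phi_case (1 - phi_case)` for case
#' fraction `phi_case` and total size `n`. Two-sided p-values come from
#' the normal z-scores. Allele pairs are drawn from the non-palindromic
#' pairs so harmonization is driven by allele matching, not frequency.
#'
#' One seed drives the run through a deterministic stream-splitting
#' scheme (sub-seeds for structure, exposure noise, and each
#' outcome-cohort's noise are drawn up-front in a fixed order), so
#' adding an outcome to the configuration does not perturb the exposure
#' draws.
#'
#' @param config [sim_config()].
#' @param seed integer seed.
#' @return List with `exposure` (a `summary_set`), `outcomes` (per
#'   outcome, a named list of `summary_set`s, one per cohort), `ld` (the
#'   generating `ld_matrix`) and `truth` (a `sim_truth`: true slopes,
#'   marginal and causal effect vectors, mafs, per-set standard errors,
#'   region assignment, seed).
#' @export
simulate_region <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  n_source_streams <- sum(vapply(config$outcomes,
                                 function(oc) length(oc$sources), integer(1)))
  set.seed(as.integer(seed))
  streams <- sample.int(2147483646L, 2L + n_source_streams)

  ld <- sim_ld(config)
  total <- sum(config$n_snps)
  region_of <- rep(vapply(config$regions, `[[`, character(1), "name"),
                   times = config$n_snps)
  chrom <- rep(vapply(config$regions, `[[`, character(1), "chrom"),
               times = config$n_snps)
  pos <- unlist(lapply(seq_along(config$regions), function(g) {
    config$pos_start[g] + config$pos_step[g] * (seq_len(config$n_snps[g]) - 1L)
  }))

  # structure stream: mafs and allele pairs
  set.seed(streams[1L])
  maf <- stats::runif(total, config$maf_range[1], config$maf_range[2])
  pair <- NON_PALINDROMIC_PAIRS[
    sample.int(nrow(NON_PALINDROMIC_PAIRS), total, replace = TRUE), ,
    drop = FALSE]

  # true marginal exposure effects via LD propagation
  gamma_causal <- numeric(total)
  at <- 0L
  for (g in seq_along(config$regions)) {
    cz <- config$causal[[g]]
    if (length(cz) > 0L) {
      idx <- at + as.integer(names(cz))
      stopifnot(all(idx > at), all(idx <= at + config$n_snps[g]))
      gamma_causal[idx] <- unname(cz)
    }
    at <- at + config$n_snps[g]
  }
  r <- unclass(ld)
  gamma <- as.numeric(r %*% gamma_causal)

  se_x <- 1 / sqrt(2 * config$n_exposure * maf * (1 - maf))
  chol_u <- chol(r)  # r is positive definite by construction

  mvn_draw <- function(mu, se_d, stream_seed) {
    set.seed(stream_seed)
    mu + se_d * as.numeric(crossprod(chol_u, stats::rnorm(total)))
  }

  make_set <- function(beta, se, trait, trait_type, units, source, n) {
    z <- beta / se
    summary_set(data.frame(rsid = rownames(ld), chrom = chrom, pos = pos,
                           ea = pair[, 1L], oa = pair[, 2L], eaf = maf,
                           beta = beta, se = se,
                           pval = 2 * stats::pnorm(-abs(z)),
                           n = n, stringsAsFactors = FALSE),
                trait = trait, trait_type = trait_type, units = units,
                source = source)
  }

  gamma_hat <- mvn_draw(gamma, se_x, streams[2L])
  exposure <- make_set(gamma_hat, se_x, "exposure", "continuous", "SD",
                       "exposure-gwas", config$n_exposure)

  out_sets <- list()
  se_y_all <- list()
  stream_at <- 2L
  for (oc_name in names(config$outcomes)) {
    oc <- config$outcomes[[oc_name]]
    pleio <- if (is.null(oc$pleiotropy)) numeric(total) else oc$pleiotropy
    stopifnot(length(pleio) == total)
    big_gamma <- oc$true_slope * gamma + pleio
    sets <- list()
    for (src_name in names(oc$sources)) {
      src <- oc$sources[[src_name]]
      stream_at <- stream_at + 1L
      n_eff <- src$n_cases + src$n_controls
      cf <- src$n_cases / n_eff
      v <- cf * (1 - cf)
      se_y <- 1 / sqrt(2 * n_eff * v * maf * (1 - maf))
      big_gamma_hat <- mvn_draw(big_gamma, se_y, streams[stream_at])
      sets[[src_name]] <- make_set(big_gamma_hat, se_y, oc_name, "binary",
                                   "log-odds", src_name, n_eff)
      se_y_all[[paste(oc_name, src_name, sep = ".")]] <- se_y
    }
    out_sets[[oc_name]] <- sets
  }

  truth <- structure(list(
    true_slope = vapply(config$outcomes, `[[`, numeric(1), "true_slope"),
    gamma = stats::setNames(gamma, rownames(ld)),
    gamma_causal = stats::setNames(gamma_causal, rownames(ld)),
    maf = maf, se_exposure = se_x, se_outcome = se_y_all,
    region = stats::setNames(region_of, rownames(ld)),
    seed = as.integer(seed)), class = "sim_truth")

  list(exposure = exposure, outcomes = out_sets, ld = ld, truth = truth)
}

#' Calibration and parameter-recovery experiment
#'
#' Repeatedly simulates a dataset from `config` and runs the full
#' selection-to-estimation chain on each replicate: region selection at
#' `sel_config$p_threshold`, LD clumping, FIQT winner's-curse
#' correction, harmonization of every cohort, per-variant fixed-effect
#' meta-analysis across cohorts, and the correlated-variant IVW
#' estimate. Each replicate is estimated twice — with the FIQT-corrected
#' and with the raw exposure betas — so the effect of the winner's-curse
#' correction is measured pairwise on identical data.
#'
#' @param config [sim_config()].
#' @param n_reps number of replicates (>= 100 for stable rates).
#' @param seed master seed; per-replicate seeds are split from it.
#' @param sel_config [selection_config()] for the selection stage.
#' @param eaf_band palindromic band for [harmonize()].
#' @return A `recovery_result`: data frame with one row per outcome and
#'   FIQT setting, reporting the replicate count used, mean estimate,
#'   mean bias, empirical SD of the estimates, mean model-based SE, 95%
#'   CI coverage of the true slope, rejection rate at alpha = 0.05, and
#'   mean instrument count. The `gamma_abs_err` and `gamma_dir_bias`
#'   attributes hold the mean absolute error and the mean directional
#'   (away-from-zero) bias of the selected exposure betas about their
#'   true marginal effects, raw vs FIQT-corrected.
#' @export
recovery_experiment <- function(config, n_reps = 1000, seed = 1,
                                sel_config = selection_config(),
                                eaf_band = 0.08) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2147483646L, n_reps)
  oc_names <- names(config$outcomes)

  rec <- list()
  gamma_err <- list(raw = numeric(0), fiqt = numeric(0),
                    dir_raw = numeric(0), dir_fiqt = numeric(0))
  n_failed <- 0L
  for (i in seq_len(n_reps)) {
    sim <- simulate_region(config, rep_seeds[i])
    adj <- tryCatch({
      sel <- select_region_snps(sim$exposure, config$regions, sel_config)
      sel <- clump(sel, sim$ld, sel_config)
      fiqt_adjust(sel)
    }, error = function(e) NULL)
    if (is.null(adj)) {
      n_failed <- n_failed + 1L
      next
    }
    truth_g <- sim$truth$gamma[adj$rsid]
    gamma_err$raw <- c(gamma_err$raw, mean(abs(adj$beta_raw - truth_g)))
    gamma_err$fiqt <- c(gamma_err$fiqt, mean(abs(adj$beta - truth_g)))
    # directional inflation: winner's curse pushes the estimate away from
    # zero in the direction of the true effect
    s_g <- sign(truth_g)
    gamma_err$dir_raw <- c(gamma_err$dir_raw,
                           mean((adj$beta_raw - truth_g) * s_g))
    gamma_err$dir_fiqt <- c(gamma_err$dir_fiqt,
                            mean((adj$beta - truth_g) * s_g))

    raw <- adj
    raw$beta <- raw$beta_raw
    for (oc in oc_names) {
      slope <- config$outcomes[[oc]]$true_slope
      for (setting in c("fiqt", "raw")) {
        instr <- if (setting == "fiqt") adj else raw
        est <- tryCatch({
          hs <- lapply(sim$outcomes[[oc]],
                       function(s) harmonize(instr, s, eaf_band = eaf_band))
          h <- meta_outcome_sets(hs)
          correlated_ivw(h, sim$ld)
        }, error = function(e) NULL)
        if (is.null(est)) next
        rec[[length(rec) + 1L]] <- data.frame(
          outcome = oc, fiqt = setting == "fiqt", rep = i,
          beta = est$beta, se = est$se,
          covered = est$ci_low <= slope & slope <= est$ci_high,
          rejected = est$pval < 0.05,
          n_variants = est$n_variants,
          true_slope = slope, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rec) == 0L) {
    stop("recovery_experiment: all ", n_reps,
         " replicates failed selection; the configuration is miscalibrated")
  }
  reps <- do.call(rbind, rec)

  summarize <- function(d) {
    data.frame(outcome = d$outcome[1L], fiqt = d$fiqt[1L],
               n_reps_used = nrow(d),
               true_slope = d$true_slope[1L],
               mean_est = mean(d$beta),
               mean_bias = mean(d$beta - d$true_slope),
               empirical_se = stats::sd(d$beta),
               mean_model_se = mean(d$se),
               coverage = mean(d$covered),
               rejection_rate = mean(d$rejected),
               mean_n_variants = mean(d$n_variants),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(reps, list(reps$outcome, reps$fiqt)),
                               summarize))
  rownames(out) <- NULL
  structure(out,
            gamma_abs_err = c(raw = mean(gamma_err$raw),
                              fiqt = mean(gamma_err$fiqt)),
            gamma_dir_bias = c(raw = mean(gamma_err$dir_raw),
                               fiqt = mean(gamma_err$dir_fiqt)),
            gamma_abs_err_reps = gamma_err,
            n_failed = n_failed, seed = as.integer(seed),
            class = c("recovery_result", "data.frame"))
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("Recovery experiment (%d replicate set(s), %d failed selection)\n",
              max(x$n_reps_used), attr(x, "n_failed")))
  print.data.frame(as.data.frame(x), digits = 4)
  ge <- attr(x, "gamma_abs_err")
  gd <- attr(x, "gamma_dir_bias")
  cat(sprintf("Selected exposure betas, mean |error|: raw %.4f, FIQT %.4f\n",
              ge["raw"], ge["fiqt"]))
  cat(sprintf("  directional (winner's curse) bias: raw %+.4f, FIQT %+.4f\n",
              gd["raw"], gd["fiqt"]))
  invisible(x)
}

#' Write a simulated dataset to disk in the package's input formats
#'
#' Emits the exposure and per-cohort outcome summary statistics as TSV
#' files (canonical header), the LD matrix as TSV, and the generating
#' truth as `truth.json`, so a simulated run can exercise the same file
#' interfaces as a real one.
#'
#' @param sim result of [simulate_region()].
#' @param out_dir output directory, created if absent.
#' @return Character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_set <- function(s, name) {
    path <- file.path(out_dir, name)
    df <- as.data.frame(s)[, c("rsid", "chrom", "pos", "ea", "oa", "eaf",
                               "beta", "se", "pval", "n")]
    names(df) <- c("rsid", "chr", "pos", "ea", "oa", "eaf",
                   "beta", "se", "pval", "n")
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- write_set(sim$exposure, "exposure.tsv")
  for (oc in names(sim$outcomes)) {
    for (src in names(sim$outcomes[[oc]])) {
      paths <- c(paths, write_set(sim$outcomes[[oc]][[src]],
                                  sprintf("outcome_%s_%s.tsv", oc, src)))
    }
  }
  ld_path <- file.path(out_dir, "ld.tsv")
  write_ld_matrix(sim$ld, ld_path)
  truth_path <- file.path(out_dir, "truth.json")
  tr <- sim$truth
  jsonlite::write_json(list(true_slope = as.list(tr$true_slope),
                            gamma = as.list(tr$gamma),
                            gamma_causal = as.list(tr$gamma_causal),
                            maf = tr$maf, region = as.list(tr$region),
                            seed = tr$seed),
                       truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, ld_path, truth_path))
}
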