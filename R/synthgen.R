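#' Simulate two-stratum genotype dosages with block LD structure
#'
#' Generates haplotype-like genotypes for two ancestry strata ("EA" and
#' "AA"). Per-variant ancestral frequencies are drawn uniformly from the
#' spec's range and perturbed per stratum with a Balding-Nichols beta draw
#' (F = `fst_divergence`). Within each linkage block the two gametes of
#' every sample are thresholded from a latent exchangeable Gaussian whose
#' correlation is calibrated (via the tetrachoric relation, numerically
#' inverted) so that the mean pairwise genotype r-squared inside the block
#' approaches `within_block_r2`; variants in different blocks are
#' independent. Dosages are therefore exact allele counts in {0, 1, 2}.
#'
#' @param spec A [population_spec()].
#' @param n_per_stratum Integer vector of length 2: samples in the EA-like
#'   and AA-like strata (either may be 0).
#' @param seed Integer seed; identical seeds reproduce identical cohorts.
#' @return A [genotype_matrix()] whose `variants` table carries the
#'   generating per-stratum frequencies (`freq_EA`, `freq_AA`).
#' @export
simulate_genotypes <- function(spec, n_per_stratum, seed) {
  stopifnot(inherits(spec, "population_spec"))
  n_per_stratum <- as.integer(n_per_stratum)
  if (length(n_per_stratum) != 2L || any(n_per_stratum < 0L))
    stop("n_per_stratum must be two non-negative counts (EA, AA)")
  m <- spec$n_variants
  with_seed(seed, {
    # one base frequency per block: tightly linked variants share MAF, and
    # homogeneous thresholds keep the thresholded correlation on target
    base_f <- rep(stats::runif(spec$n_blocks, spec$allele_freq_range[1],
                               spec$allele_freq_range[2]),
                  each = spec$block_size)
    f_strat <- sapply(c("EA", "AA"), function(s) {
      if (spec$fst_divergence > 0) {
        F <- spec$fst_divergence
        f <- stats::rbeta(m, base_f * (1 - F) / F, (1 - base_f) * (1 - F) / F)
        pmin(pmax(f, 1e-3), 1 - 1e-3)
      } else base_f
    })
    variants <- data.frame(
      variant_id = sprintf("v%05d", seq_len(m)),
      chrom = "1",
      pos = (rep(seq_len(spec$n_blocks), each = spec$block_size) - 1L) * 1000000L +
        (rep(seq_len(spec$block_size), spec$n_blocks) - 1L) * 1000L + 1L,
      ref = "A", alt = "G",
      block = rep(seq_len(spec$n_blocks), each = spec$block_size),
      freq_EA = f_strat[, "EA"], freq_AA = f_strat[, "AA"],
      stringsAsFactors = FALSE)

    strata <- rep(c("EA", "AA"), n_per_stratum)
    n_tot <- sum(n_per_stratum)
    dos <- matrix(numeric(0), nrow = n_tot, ncol = m)
    if (n_tot > 0L) {
      r_target <- sqrt(spec$within_block_r2)
      for (s_idx in 1:2) {
        s <- c("EA", "AA")[s_idx]
        ns <- n_per_stratum[s_idx]
        if (ns == 0L) next
        rows <- which(strata == s)
        for (b in seq_len(spec$n_blocks)) {
          cols <- which(variants$block == b)
          fb <- f_strat[cols, s]
          rho <- if (r_target > 0) latent_rho_for_block(r_target, fb) else 0
          thr <- stats::qnorm(fb)
          g <- matrix(0, ns, length(cols))
          for (gamete in 1:2) {
            z0 <- stats::rnorm(ns)
            e <- matrix(stats::rnorm(ns * length(cols)), ns, length(cols))
            z <- sqrt(rho) * z0 + sqrt(1 - rho) * e
            g <- g + (z < matrix(thr, ns, length(cols), byrow = TRUE))
          }
          dos[rows, cols] <- g
        }
      }
    }
    samples <- data.frame(sample_id = sprintf("S%05d", seq_len(n_tot)),
                          stratum = strata, stringsAsFactors = FALSE)
    genotype_matrix(dos, variants, samples)
  })
}

# Bivariate-normal orthant probability P(Z1 < t1, Z2 < t2) at correlation rho
bvn_p11 <- function(t1, t2, rho) {
  stats::integrate(function(z)
    stats::pnorm((t2 - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z),
    -Inf, t1, rel.tol = 1e-8)$value
}

# Latent exchangeable-Gaussian correlation making the mean pairwise
# correlation of the thresholded binaries equal r, for a block with
# (possibly heterogeneous) allele frequencies fb. Tetrachoric relation,
# inverted numerically; the genotype (two-gamete) correlation equals the
# per-gamete correlation.
latent_rho_for_block <- function(r, fb) {
  if (r <= 0) return(0)
  t <- stats::qnorm(fb)
  pairs <- utils::combn(length(fb), 2)
  mean_corr <- function(rho) {
    mean(apply(pairs, 2, function(pr) {
      f1 <- fb[pr[1]]; f2 <- fb[pr[2]]
      (bvn_p11(t[pr[1]], t[pr[2]], rho) - f1 * f2) /
        sqrt(f1 * (1 - f1) * f2 * (1 - f2))
    }))
  }
  upper <- 0.99999
  if (mean_corr(upper) <= r) return(upper)  # unreachable target: saturate
  stats::uniroot(function(rho) mean_corr(rho) - r,
                 lower = 1e-6, upper = upper, tol = 1e-6)$root
}

#' Simulate phenotypes on a genotype matrix
#'
#' Quantitative traits follow the additive model
#' `y = sqrt(h2) * g + covariate terms + sqrt(1 - h2) * e`, where `g` is the
#' causal genetic value standardized within each ancestry stratum and `e`
#' is standard normal. Binary traits use the liability-threshold model: the
#' same construction defines a liability, standardized cohort-wide, and a
#' sample is a case when its liability exceeds `qnorm(1 - prevalence)`.
#' Causal effect sizes are drawn per stratum from a bivariate normal with
#' correlation `ancestry_effect_corr`, so a trait can have partially shared
#' genetic architecture across ancestries.
#'
#' @param geno A [genotype_matrix()].
#' @param traits A [trait_spec()] or list of them.
#' @param covariates `data.frame` aligned with `geno$samples` (same order)
#'   holding any columns named in `covariate_effects`; pass
#'   `geno$samples` when no covariate effects are wanted.
#' @param seed Integer seed.
#' @return The covariate table with one new column per trait, plus a
#'   `"truth"` attribute: per trait, the causal effect table
#'   (`variant_id`, `beta_EA`, `beta_AA`) and the standardized per-sample
#'   genetic values.
#' @export
simulate_phenotypes <- function(geno, traits, covariates, seed) {
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (nrow(covariates) != nrow(geno$dosages))
    stop("covariates must be complete for all samples, in genotype order")
  m <- ncol(geno$dosages)
  strat <- geno$samples$stratum
  truth <- list()
  out <- covariates
  with_seed(seed, {
    for (tr in traits) {
      if (tr$n_causal > m)
        stop("n_causal exceeds the number of variants for trait ", tr$name)
      causal <- sort(sample.int(m, tr$n_causal))
      b_ea <- stats::rnorm(tr$n_causal)
      rho <- tr$ancestry_effect_corr
      b_aa <- rho * b_ea + sqrt(max(0, 1 - rho^2)) * stats::rnorm(tr$n_causal)
      g <- numeric(nrow(out))
      for (s in unique(strat)) {
        rows <- strat == s
        b <- if (s == "AA") b_aa else b_ea
        gv <- geno$dosages[rows, causal, drop = FALSE] %*% b
        sdg <- stats::sd(gv)
        g[rows] <- if (is.na(sdg) || sdg == 0) 0 else (gv - mean(gv)) / sdg
      }
      covterm <- numeric(nrow(out))
      for (nm in names(tr$covariate_effects)) {
        if (!nm %in% names(covariates))
          stop("covariate '", nm, "' named in covariate_effects is absent")
        covterm <- covterm + tr$covariate_effects[[nm]] * as.numeric(covariates[[nm]])
      }
      liab <- sqrt(tr$h2) * g + covterm +
        sqrt(1 - tr$h2) * stats::rnorm(nrow(out))
      if (tr$kind == "binary") {
        z <- (liab - mean(liab)) / stats::sd(liab)
        out[[tr$name]] <- as.integer(z > stats::qnorm(1 - tr$prevalence))
      } else {
        out[[tr$name]] <- liab
      }
      truth[[tr$name]] <- list(
        effects = data.frame(variant_id = geno$variants$variant_id[causal],
                             beta_EA = b_ea, beta_AA = b_aa,
                             stringsAsFactors = FALSE),
        genetic_value = stats::setNames(g, geno$samples$sample_id),
        spec = tr)
    }
  })
  attr(out, "truth") <- truth
  out
}

#' Simulate well-powered reference GWAS summary statistics
#'
#' Emulates published consortium summary statistics for a trait whose causal
#' architecture is known (the `truth` element returned by
#' [simulate_phenotypes()]). For every variant the true marginal
#' (LD-including) effect on the standardized trait scale is computed from
#' the supplied genotype panel; the reported effect is drawn around it with
#' standard error `1 / sqrt(2 f (1 - f) n_reference)` and the p-value is the
#' two-sided Wald probability. Monomorphic variants are emitted with missing
#' statistics.
#'
#' @param geno A [genotype_matrix()] used as the LD/frequency panel for the
#'   reference population.
#' @param trait A [trait_spec()] (for `h2` and the label).
#' @param n_reference Reference GWAS sample size (> 0).
#' @param seed Integer seed.
#' @param truth Optional truth entry from [simulate_phenotypes()]; when
#'   `NULL` a fresh causal architecture is drawn from `trait`.
#' @param stratum Which stratum's genotypes and effects represent the
#'   reference population (default `"EA"`, the usual consortium ancestry).
#' @return A summary-statistics `data.frame` (`variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n`,
#'   `stratum`) with the true marginal effects in attribute
#'   `"true_marginal"`.
#' @export
simulate_reference_sumstats <- function(geno, trait, n_reference, seed,
                                        truth = NULL, stratum = "EA") {
  if (n_reference <= 0) stop("n_reference must be positive")
  rows <- geno$samples$stratum == stratum
  if (!any(rows)) stop("no samples in stratum ", stratum)
  X <- geno$dosages[rows, , drop = FALSE]
  with_seed(child_seed(seed, "refeffects"), {
    if (is.null(truth)) {
      m <- ncol(X)
      causal <- sort(sample.int(m, trait$n_causal))
      eff <- data.frame(variant_id = geno$variants$variant_id[causal],
                        beta_EA = stats::rnorm(trait$n_causal),
                        stringsAsFactors = FALSE)
      eff$beta_AA <- eff$beta_EA
    } else eff <- truth$effects
  })
  bcol <- if (stratum == "AA") "beta_AA" else "beta_EA"
  ci <- match(eff$variant_id, geno$variants$variant_id)
  if (anyNA(ci)) stop("truth refers to variants absent from the panel")
  graw <- X[, ci, drop = FALSE] %*% eff[[bcol]]
  sdg <- stats::sd(graw)
  f <- colMeans(X) / 2
  # marginal per-dosage effect of each variant on the standardized trait
  gc <- graw - mean(graw)
  Xc <- sweep(X, 2, colMeans(X))
  covxg <- as.numeric(crossprod(Xc, gc)) / (nrow(X) - 1)
  varx <- apply(X, 2, stats::var)
  true_marg <- ifelse(varx > 0,
                      sqrt(trait$h2) * covxg / (ifelse(sdg > 0, sdg, 1) * varx), 0)
  se <- ifelse(f > 0 & f < 1, 1 / sqrt(2 * f * (1 - f) * n_reference), NA_real_)
  with_seed(child_seed(seed, "refnoise"), {
    bhat <- true_marg + ifelse(is.na(se), NA_real_, stats::rnorm(length(se)) * se)
  })
  p <- 2 * stats::pnorm(-abs(bhat / se))
  out <- data.frame(variant_id = geno$variants$variant_id,
                    chrom = geno$variants$chrom, pos = geno$variants$pos,
                    effect_allele = geno$variants$alt,
                    other_allele = geno$variants$ref,
                    eaf = f, beta = bhat, se = se, p = p,
                    n = n_reference, stratum = "REF",
                    stringsAsFactors = FALSE)
  attr(out, "true_marginal") <- stats::setNames(true_marg, out$variant_id)
  out
}

#' Simulate eSNP annotations per experimental condition
#'
#' Flags each variant as an eSNP (an expression-associated variant at some
#' nominal FDR in the emulated eQTL study) independently per condition, with
#' probability `base_rate`, raised to `enriched_rate` for variants in
#' `enriched_set`.
#'
#' @param geno A [genotype_matrix()].
#' @param enriched_set Character vector of variant ids to enrich.
#' @param conditions Character vector of condition labels.
#' @param base_rate,enriched_rate Flag probabilities,
#'   `0 <= base_rate <= enriched_rate <= 1`.
#' @param seed Integer seed.
#' @return Long `data.frame` (`variant_id`, `condition`, `esnp`).
#' @export
simulate_eqtl_annotations <- function(geno, enriched_set, conditions,
                                      base_rate, enriched_rate, seed) {
  if (base_rate < 0 || enriched_rate > 1 || base_rate > enriched_rate)
    stop("need 0 <= base_rate <= enriched_rate <= 1")
  ids <- geno$variants$variant_id
  unknown <- setdiff(enriched_set, ids)
  if (length(unknown))
    stop("enriched_set contains unknown variant ids: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  rate <- ifelse(ids %in% enriched_set, enriched_rate, base_rate)
  with_seed(seed, {
    do.call(rbind, lapply(conditions, function(cond) {
      data.frame(variant_id = ids, condition = cond,
                 esnp = stats::runif(length(ids)) < rate,
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Simulate longitudinal clinical records for a cohort
#'
#' Produces the raw-record tables that the phenotype-derivation functions
#' consume: repeated lipid panels scattered around each sample's target
#' values (total cholesterol is built as LDL + HDL + TG/5 so the Friedewald
#' relation holds in expectation; direct LDL is reported on alternate
#' draws), HbA1c draws and medication/diagnosis records consistent with the
#' intended diabetes status under the adjudication rule, and
#' height/weight records.
#'
#' @param cohort `data.frame` with `sample_id` and target columns: `hdl`,
#'   `ldl`, `tg` (mg/dL), logical `t2d`, optional logical `statin`,
#'   optional `height_m` and `weight_kg`.
#' @param seed Integer seed.
#' @param n_draws Lipid draws per sample.
#' @param draw_sd Within-person SD of repeated lipid draws (mg/dL).
#' @return List of `data.frame`s: `lipids`, `labs`, `meds`, `diagnoses`,
#'   `anthro`.
#' @export
simulate_clinical_records <- function(cohort, seed, n_draws = 3, draw_sd = 8) {
  stopifnot(all(c("sample_id", "hdl", "ldl", "tg") %in% names(cohort)))
  n <- nrow(cohort)
  t2d <- if ("t2d" %in% names(cohort)) as.logical(cohort$t2d) else rep(FALSE, n)
  statin <- if ("statin" %in% names(cohort)) as.logical(cohort$statin) else rep(FALSE, n)
  with_seed(seed, {
    lip <- do.call(rbind, lapply(seq_len(n), function(i) {
      hdl <- pmax(5, cohort$hdl[i] + stats::rnorm(n_draws, 0, draw_sd))
      ldl <- pmax(5, cohort$ldl[i] + stats::rnorm(n_draws, 0, draw_sd))
      tg  <- pmax(10, cohort$tg[i] + stats::rnorm(n_draws, 0, draw_sd))
      data.frame(sample_id = cohort$sample_id[i],
                 draw_date = as.Date("2005-01-01") + (seq_len(n_draws) - 1) * 180,
                 total_cholesterol = ldl + hdl + tg / 5,
                 hdl = hdl, triglycerides = tg,
                 ldl_direct = ifelse(seq_len(n_draws) %% 2 == 1, ldl, NA_real_),
                 stringsAsFactors = FALSE)
    }))
    # route each T2D case through one adjudication criterion (or several)
    route <- sample.int(3, n, replace = TRUE)
    labs <- do.call(rbind, lapply(seq_len(n), function(i) {
      a1c <- if (t2d[i] && route[i] == 1)
        c(stats::runif(1, 6.5, 9), stats::runif(2, 5.5, 7.5))
      else pmin(stats::runif(3, 4.8, 6.2), 6.4)
      data.frame(sample_id = cohort$sample_id[i], hba1c = a1c,
                 stringsAsFactors = FALSE)
    }))
    meds <- list()
    dxs <- logical(n)
    for (i in seq_len(n)) {
      if (t2d[i] && route[i] == 2)
        meds[[length(meds) + 1]] <- data.frame(
          sample_id = cohort$sample_id[i], code = "insulin",
          class = "diabetes_specific", date = as.Date("2005-03-01"))
      if (t2d[i] && route[i] == 3) {
        meds[[length(meds) + 1]] <- data.frame(
          sample_id = cohort$sample_id[i], code = "metformin",
          class = "diabetes_related", date = as.Date("2005-03-01"))
        dxs[i] <- TRUE
      }
      if (!t2d[i] && stats::runif(1) < 0.02)  # off-label biguanide, no diagnosis
        meds[[length(meds) + 1]] <- data.frame(
          sample_id = cohort$sample_id[i], code = "metformin",
          class = "diabetes_related", date = as.Date("2005-03-01"))
      if (statin[i])
        meds[[length(meds) + 1]] <- data.frame(
          sample_id = cohort$sample_id[i], code = "atorvastatin",
          class = "lipid_lowering", date = as.Date("2005-01-01"))
    }
    meds <- if (length(meds)) do.call(rbind, meds) else
      data.frame(sample_id = character(0), code = character(0),
                 class = character(0), date = as.Date(character(0)))
    anthro <- data.frame(
      sample_id = cohort$sample_id,
      height_m = if ("height_m" %in% names(cohort)) cohort$height_m
                 else stats::rnorm(n, 1.72, 0.09),
      weight_kg = if ("weight_kg" %in% names(cohort)) cohort$weight_kg
                  else stats::rnorm(n, 80, 14),
      stringsAsFactors = FALSE)
    list(lipids = lip, labs = labs, meds = meds,
         diagnoses = data.frame(sample_id = cohort$sample_id,
                                diabetes_dx = dxs, stringsAsFactors = FALSE),
         anthro = anthro)
  })
}
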