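#' Greedy LD pruning with p-value priority
#'
#' Visits variants by ascending p (ties broken by panel position, then
#' id) and retains a variant unless its r-squared with an
#' already-retained variant reaches the cutoff (`>= r2_cutoff`, or
#' strictly `> r2_cutoff` when `strict = TRUE`, the convention used on the
#' eQTL path). Variants absent from the panel are retained with a warning
#' (no LD evidence against them) and counted.
#'
#' @param variants `data.frame` with `variant_id` and `p`.
#' @param geno Genotype panel ([genotype_matrix()]).
#' @param r2_cutoff LD threshold (default 0.5).
#' @param strict Remove at `r2 > cutoff` instead of `>=`.
#' @return Character vector of retained variant ids, with attribute
#'   `"n_no_panel"`.
#' @export
ld_prune <- function(variants, geno, r2_cutoff = 0.5, strict = FALSE) {
  vi <- match(variants$variant_id, geno$variants$variant_id)
  pos <- geno$variants$pos[vi]
  pos[is.na(pos)] <- Inf
  ord <- order(variants$p, pos, variants$variant_id)
  kept <- character(0)
  n_no_panel <- 0L
  for (i in ord) {
    id <- variants$variant_id[i]
    if (is.na(vi[i])) {
      n_no_panel <- n_no_panel + 1L
      kept <- c(kept, id)
      next
    }
    in_panel <- kept[kept %in% geno$variants$variant_id]
    hit <- FALSE
    if (length(in_panel)) {
      r2 <- panel_r2(geno, id, in_panel)
      r2[is.na(r2)] <- 0
      hit <- if (strict) any(r2 > r2_cutoff) else any(r2 >= r2_cutoff)
    }
    if (!hit) kept <- c(kept, id)
  }
  if (n_no_panel)
    warning(n_no_panel, " variants absent from the LD panel were retained unpruned")
  attr(kept, "n_no_panel") <- n_no_panel
  kept
}

#' Derive thresholding-pruning PRS weights
#'
#' Selects variants with summary p below the threshold, LD-prunes them
#' (removal at r-squared >= `prune_r2`, priority by ascending p) and takes
#' the harmonized betas as weights.
#'
#' @param sumstats Harmonized summary statistics (`variant_id`,
#'   `effect_allele`, `beta`, `p`, optionally `eaf`).
#' @param threshold P-value inclusion cutoff (one of the usual ladder
#'   1e-1 ... 1e-8, or any value).
#' @param panel Genotype panel for pruning.
#' @param prune_r2 Pruning cutoff (default 0.5).
#' @param trait,source Labels stored in the model.
#' @return A [prs_model()]; zero surviving variants yield an empty model
#'   with attribute `"empty"`.
#' @export
derive_prs_weights <- function(sumstats, threshold, panel, prune_r2 = 0.5,
                               trait = "trait", source = "sumstats") {
  sel <- sumstats[!is.na(sumstats$p) & sumstats$p < threshold, , drop = FALSE]
  if (nrow(sel)) {
    keep <- ld_prune(sel[, c("variant_id", "p")], panel, r2_cutoff = prune_r2)
    sel <- sel[sel$variant_id %in% keep, , drop = FALSE]
  }
  w <- data.frame(variant_id = sel$variant_id,
                  effect_allele = sel$effect_allele,
                  beta = sel$beta,
                  source_p = sel$p,
                  eaf = if ("eaf" %in% names(sel)) sel$eaf else NA_real_,
                  stringsAsFactors = FALSE)
  m <- prs_model(trait, source, threshold, w,
                 pruning = list(r2_cutoff = prune_r2, panel = "genotype panel"))
  if (!nrow(w)) attr(m, "empty") <- TRUE
  m
}

#' Score samples with a PRS model
#'
#' `PRS_i = sum_j dosage_ij * beta_j` over the model variants, after
#' aligning each weight's effect allele to the genotype ALT (REF-oriented
#' weights flip the dosage to `2 - d`). Missing dosages are mean-imputed
#' as `2 * eaf` (model eaf when available, else panel frequency). More
#' than 20% unmappable model variants is an error.
#'
#' @param model A [prs_model()].
#' @param geno A [genotype_matrix()].
#' @return Named numeric vector of per-sample scores with attributes
#'   `"n_unmappable"` and `"n_imputed"`.
#' @export
prs_score <- function(model, geno) {
  w <- model$weights
  n <- nrow(geno$dosages)
  out <- stats::setNames(numeric(n), geno$samples$sample_id)
  if (!nrow(w)) {
    attr(out, "n_unmappable") <- 0L
    attr(out, "n_imputed") <- 0L
    return(out)
  }
  j <- match(w$variant_id, geno$variants$variant_id)
  orient <- rep(NA_real_, nrow(w))
  ok <- !is.na(j)
  orient[ok & w$effect_allele == geno$variants$alt[j]] <- 1
  orient[ok & w$effect_allele == geno$variants$ref[j]] <- -1
  unmappable <- is.na(orient)
  if (mean(unmappable) > 0.2)
    stop(sprintf("%d of %d model variants unmappable to the genotypes",
                 sum(unmappable), nrow(w)))
  n_imputed <- 0L
  for (k in which(!unmappable)) {
    d <- geno$dosages[, j[k]]
    if (anyNA(d)) {
      f <- if (!is.na(w$eaf[k])) w$eaf[k] else mean(d, na.rm = TRUE) / 2
      n_imputed <- n_imputed + sum(is.na(d))
      d[is.na(d)] <- 2 * f
    }
    if (orient[k] < 0) d <- 2 - d
    out <- out + d * w$beta[k]
  }
  attr(out, "n_unmappable") <- sum(unmappable)
  attr(out, "n_imputed") <- n_imputed
  out
}

# adjusted R2 penalizing k model degrees of freedom
adj_r2 <- function(r2, n, k) 1 - (1 - r2) * (n - 1) / (n - k - 1)

# incremental R2 of score columns S over covariate matrix C for outcome y
incremental_r2 <- function(y, S, C) {
  qc <- qr(C)
  ry <- qr.resid(qc, y)
  rs <- qr.resid(qc, as.matrix(S))
  fit <- stats::lm.fit(cbind(rs), ry)
  rss_cov <- sum(ry^2)
  rss_full <- sum(fit$residuals^2)
  list(coef = fit$coefficients,
       r2 = if (rss_cov > 0) (rss_cov - rss_full) / rss_cov else 0)
}

#' Combine two ancestry-specific PRS into a multiethnic score
#'
#' Regresses the phenotype on both scores plus covariates; the two score
#' coefficients are the mixing weights alpha1 (EA-derived score) and
#' alpha2 (target-ancestry score). Performance is reported as the
#' incremental R-squared of the two scores over the covariate-only model,
#' adjusted for the two extra degrees of freedom:
#' `adjR2 = 1 - (1 - R2)(n - 1)/(n - k - 1)`, `k = 2`. Near-collinear
#' scores (|r| > 0.999) fall back to the EA-only model with `alpha2 = 0`
#' and are flagged.
#'
#' @param prs_ea,prs_aa Per-sample scores on the same samples.
#' @param phenotype Numeric outcome (0/1 binary outcomes are fitted on the
#'   linear probability scale for weight estimation).
#' @param covariates Optional numeric design `data.frame`/matrix (no
#'   intercept needed) or `NULL`.
#' @return List: `alpha1`, `alpha2`, `r2`, `adj_r2`, `n`, `collinear`.
#' @export
multiethnic_combine <- function(prs_ea, prs_aa, phenotype, covariates = NULL) {
  n <- length(phenotype)
  C <- if (is.null(covariates)) matrix(1, n, 1) else
    cbind(1, as.matrix(covariates))
  collinear <- isTRUE(abs(suppressWarnings(
    stats::cor(prs_ea, prs_aa))) > 0.999)
  if (collinear) {
    fit <- incremental_r2(phenotype, cbind(prs_ea), C)
    return(list(alpha1 = unname(fit$coef[1]), alpha2 = 0,
                r2 = fit$r2, adj_r2 = adj_r2(fit$r2, n, 1), n = n,
                collinear = TRUE))
  }
  fit <- incremental_r2(phenotype, cbind(prs_ea, prs_aa), C)
  list(alpha1 = unname(fit$coef[1]), alpha2 = unname(fit$coef[2]),
       r2 = fit$r2, adj_r2 = adj_r2(fit$r2, n, 2), n = n,
       collinear = FALSE)
}

#' Cross-validated multiethnic PRS in the target ancestry stratum
#'
#' Ten-fold (stratified for binary traits, preserving the case:control
#' ratio in every fold) cross-validation in the target stratum. Per fold:
#' a GWAS on the training 90% of the stratum (adjusted for the supplied
#' covariates plus principal components computed on the target stratum
#' only) yields the target-ancestry weights; the EA score comes from the
#' external reference summary statistics; mixing weights and the adjusted
#' incremental R-squared are estimated on the held-out 10%. The
#' reference-only score's adjusted R-squared on the same folds is
#' reported for comparison.
#'
#' @param geno Full-cohort [genotype_matrix()].
#' @param cohort Cohort table aligned with `geno$samples` containing the
#'   trait and covariate columns.
#' @param trait Name of the trait column.
#' @param ref_sumstats Harmonized reference summary statistics.
#' @param covariates Character vector of cohort covariate columns.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param threshold P-value threshold for both derivations (default 1e-2).
#' @param target_stratum Stratum label to cross-validate in (default
#'   `"AA"`).
#' @param n_pcs Principal components computed within the target stratum
#'   and added to the covariates (0 disables).
#' @param binary Is the trait binary? (fold stratification and logistic
#'   training GWAS).
#' @return Object of class `multiethnic_prs`: per-fold `alpha1`,
#'   `alpha2`, `adj_r2`, `adj_r2_ref_only`; their means; the fold
#'   assignment; and the derivation parameters.
#' @export
crossval_multiethnic <- function(geno, cohort, trait, ref_sumstats,
                                 covariates = character(0), k = 10, seed = 1,
                                 threshold = 1e-2, target_stratum = "AA",
                                 n_pcs = 0, binary = FALSE) {
  rows <- which(cohort$stratum == target_stratum)
  if (!length(rows)) stop("no samples in stratum ", target_stratum)
  gt <- subset_genotypes(geno, samples = rows)
  ct <- cohort[rows, , drop = FALSE]
  y <- ct[[trait]]
  if (n_pcs > 0) {
    pcs <- compute_pcs(gt, n_pcs = n_pcs)
    ct <- cbind(ct, as.data.frame(pcs))
    covariates <- c(covariates, colnames(pcs))
  }
  n <- length(rows)
  folds <- with_seed(child_seed(seed, "folds"), {
    fl <- integer(n)
    if (binary) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fl[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else fl <- sample(rep_len(seq_len(k), n))
    fl
  })
  if (binary)
    for (f in seq_len(k))
      if (sum(y[folds == f] == 1) == 0)
        stop("fold ", f, " has zero cases; reduce k or enlarge the cohort")
  ea_model <- derive_prs_weights(ref_sumstats, threshold, panel = gt,
                                 trait = trait, source = "reference")
  prs_ea_all <- prs_score(ea_model, gt)
  per <- data.frame(fold = seq_len(k), alpha1 = NA_real_, alpha2 = NA_real_,
                    adj_r2 = NA_real_, adj_r2_ref_only = NA_real_)
  Ccols <- covariates
  for (f in seq_len(k)) {
    tr <- which(folds != f); va <- which(folds == f)
    ss_tr <- single_variant_assoc(
      subset_genotypes(gt, samples = tr), y[tr], ct[tr, , drop = FALSE],
      covariates = Ccols, model = if (binary) "logistic" else "linear",
      stratum = target_stratum)
    aa_model <- derive_prs_weights(ss_tr, threshold, panel = gt,
                                   trait = trait, source = "target_gwas")
    prs_aa_va <- prs_score(aa_model, subset_genotypes(gt, samples = va))
    Cva <- covariate_matrix(ct[va, , drop = FALSE], Ccols)
    comb <- multiethnic_combine(prs_ea_all[va], prs_aa_va, y[va],
                                covariates = Cva[, -1, drop = FALSE])
    per$alpha1[f] <- comb$alpha1
    per$alpha2[f] <- comb$alpha2
    per$adj_r2[f] <- comb$adj_r2
    ref_fit <- incremental_r2(y[va], cbind(prs_ea_all[va]), Cva)
    per$adj_r2_ref_only[f] <- adj_r2(ref_fit$r2, length(va), 1)
  }
  structure(list(per_fold = per,
                 mean_adj_r2 = mean(per$adj_r2),
                 mean_adj_r2_ref_only = mean(per$adj_r2_ref_only),
                 folds = folds, trait = trait, threshold = threshold,
                 target_stratum = target_stratum, k = k, seed = seed),
            class = "multiethnic_prs")
}

#' @export
print.multiethnic_prs <- function(x, ...) {
  cat(sprintf(
    "multiethnic_prs (%s, stratum %s, %d folds): mean adjR2 = %.4f (reference-only %.4f)\n",
    x$trait, x$target_stratum, x$k, x$mean_adj_r2, x$mean_adj_r2_ref_only))
  invisible(x)
}

#' PRS-phenotype association matrix across thresholds
#'
#' Scores every model, standardizes each score, and tests its
#' covariate-adjusted association with every phenotype (linear for
#' quantitative, logistic for binary). Returns signed z-statistics with
#' Benjamini-Hochberg significance flags at the requested FDR across all
#' cells.
#'
#' @param models List of [prs_model()]s (rows of the matrix).
#' @param geno A [genotype_matrix()].
#' @param cohort Cohort table aligned with the samples.
#' @param phenotypes Named character vector mapping phenotype column names
#'   to `"quantitative"` or `"binary"`.
#' @param covariates Character vector of covariate columns.
#' @param fdr Flagging level (default 0.10).
#' @return List of matrices `z`, `p`, `flag` (rows = models, cols =
#'   phenotypes).
#' @export
prs_phenotype_matrix <- function(models, geno, cohort, phenotypes,
                                 covariates = character(0), fdr = 0.10) {
  rn <- vapply(models, function(m)
    sprintf("%s@%g", m$trait, m$threshold), "")
  cn <- names(phenotypes)
  z <- p <- matrix(NA_real_, length(models), length(cn),
                   dimnames = list(rn, cn))
  C <- covariate_matrix(cohort, covariates)
  for (i in seq_along(models)) {
    s <- prs_score(models[[i]], geno)
    if (stats::sd(s) == 0) next
    s <- (s - mean(s)) / stats::sd(s)
    for (jn in cn) {
      yv <- cohort[[jn]]
      ok <- !is.na(yv)
      if (!any(ok)) next
      XX <- cbind(C[ok, , drop = FALSE], prs = s[ok])
      if (phenotypes[[jn]] == "binary") {
        fit <- suppressWarnings(
          stats::glm.fit(XX, yv[ok], family = stats::binomial(),
                         control = stats::glm.control(epsilon = 1e-8,
                                                      maxit = 50)))
        if (!fit$converged || fit$rank < ncol(XX)) next
        r <- fit$rank
        covm <- chol2inv(fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE])
        pos <- match(ncol(XX), fit$qr$pivot)
        zz <- fit$coefficients[ncol(XX)] / sqrt(covm[pos, pos])
      } else {
        qc <- qr(C[ok, , drop = FALSE])
        ry <- qr.resid(qc, yv[ok])
        rs <- qr.resid(qc, s[ok])
        sxx <- sum(rs^2)
        b <- sum(rs * ry) / sxx
        dfree <- sum(ok) - ncol(C) - 1
        sig2 <- max(0, (sum(ry^2) - b * sum(rs * ry)) / dfree)
        zz <- b / sqrt(sig2 / sxx)
      }
      z[i, jn] <- zz
      p[i, jn] <- 2 * stats::pnorm(-abs(zz))
    }
  }
  padj <- matrix(bh_fdr(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
  list(z = z, p = p, fdr_adjusted_p = padj, flag = !is.na(padj) & padj < fdr)
}

#' Top-percentile risk stratification
#'
#' For each score and top fraction q: the top group is everyone whose
#' score reaches the empirical (1 - q) quantile (ties included), the OR is
#' the cross-product ratio of the resulting 2x2 disease table, with a Wald
#' 95% CI on the log OR (Haldane-Anscombe 0.5-correction, flagged, when
#' any cell is zero). Benjamini-Hochberg adjustment runs across all
#' (score, fraction) tests.
#'
#' @param scores Numeric vector, or named list of score vectors.
#' @param disease 0/1 vector (>= 1 case and >= 1 control overall).
#' @param top_fractions Fractions defining the top groups.
#' @return `data.frame`: `score`, `top_fraction`, cells (`a` = cases in
#'   top, `b` controls in top, `c` cases in rest, `d` controls in rest),
#'   `prevalence_top`, `prevalence_rest`, `odds_ratio`, `ci_lo`, `ci_hi`,
#'   `p`, `fdr_adjusted_p`, `corrected`, `estimable`.
#' @export
risk_stratification <- function(scores, disease,
                                top_fractions = c(0.05, 0.10, 0.15,
                                                  0.20, 0.25, 0.30)) {
  if (!is.list(scores)) scores <- list(PRS = scores)
  disease <- as.integer(disease)
  if (sum(disease == 1) < 1 || sum(disease == 0) < 1)
    stop("need at least one case and one control")
  rows <- list()
  for (nm in names(scores)) {
    s <- scores[[nm]]
    for (q in top_fractions) {
      cut <- stats::quantile(s, 1 - q, names = FALSE)
      top <- s >= cut
      a <- sum(disease[top] == 1); b <- sum(disease[top] == 0)
      cc <- sum(disease[!top] == 1); d <- sum(disease[!top] == 0)
      corrected <- any(c(a, b, cc, d) == 0)
      est <- !(a + cc == 0)
      aa <- a; bb <- b; cx <- cc; dd <- d
      if (corrected) { aa <- a + 0.5; bb <- b + 0.5; cx <- cc + 0.5; dd <- d + 0.5 }
      or <- (aa * dd) / (bb * cx)
      sel <- sqrt(1 / aa + 1 / bb + 1 / cx + 1 / dd)
      rows[[length(rows) + 1]] <- data.frame(
        score = nm, top_fraction = q, a = a, b = b, c = cc, d = d,
        prevalence_top = if (a + b > 0) a / (a + b) else NA_real_,
        prevalence_rest = if (cc + d > 0) cc / (cc + d) else NA_real_,
        odds_ratio = or,
        ci_lo = exp(log(or) - 1.959964 * sel),
        ci_hi = exp(log(or) + 1.959964 * sel),
        p = 2 * stats::pnorm(-abs(log(or) / sel)),
        corrected = corrected, estimable = est,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr_adjusted_p <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Pooled PRS R-squared from per-stratum marginal associations
#'
#' Inverse-variance (fixed-effects) pooling of standardized marginal PRS
#' coefficients across strata; the pooled R-squared is the squared pooled
#' coefficient.
#'
#' @param assoc `data.frame` with `beta` (standardized marginal
#'   coefficient) and `se` per stratum.
#' @return List: `beta`, `se`, `r2`.
#' @export
meta_prs_r2 <- function(assoc) {
  ok <- !is.na(assoc$beta) & !is.na(assoc$se) & assoc$se > 0
  a <- assoc[ok, , drop = FALSE]
  if (!nrow(a)) stop("no usable strata")
  w <- 1 / a$se^2
  b <- sum(w * a$beta) / sum(w)
  list(beta = b, se = 1 / sqrt(sum(w)), r2 = b^2)
}
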