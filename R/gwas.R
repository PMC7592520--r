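#' Covariate design matrix from a cohort table
#'
#' Expands the named cohort columns into a numeric design matrix with an
#' intercept; character/factor columns (e.g. clinical site) become
#' indicator contrasts.
#'
#' @param cohort Cohort `data.frame`.
#' @param covariates Character vector of column names (may be empty).
#' @return Numeric matrix with an `(Intercept)` column.
#' @export
covariate_matrix <- function(cohort, covariates = character(0)) {
  if (!length(covariates))
    return(matrix(1, nrow(cohort), 1, dimnames = list(NULL, "(Intercept)")))
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) stop("missing covariate columns: ", paste(miss, collapse = ", "))
  df <- cohort[, covariates, drop = FALSE]
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  stats::model.matrix(~ ., data = df)
}

#' Single-variant association on imputed dosages
#'
#' Per-variant Wald test for the dosage term from linear (quantitative
#' trait) or logistic (binary trait) regression adjusted for the supplied
#' covariates. The linear path residualizes trait and dosages on the
#' covariates once (Frisch-Waugh), which is algebraically identical to
#' fitting each full model; the logistic path fits each variant by
#' iteratively reweighted least squares (max 50 iterations, tolerance
#' 1e-8). P-values use the normal reference for the Wald z. Missing
#' dosages are mean-imputed; monomorphic variants are skipped (counted in
#' attribute `"skipped"`); non-converged logistic fits are emitted with
#' missing statistics.
#'
#' @param geno A [genotype_matrix()] for one analysis stratum.
#' @param trait Numeric/binary vector aligned with the samples, or the name
#'   of a `cohort` column.
#' @param cohort Cohort `data.frame` aligned with `geno$samples`.
#' @param covariates Character vector of `cohort` columns to adjust for
#'   (site-like character columns enter as indicators).
#' @param model `"linear"` or `"logistic"`.
#' @param stratum Label stored in the output.
#' @return Summary-statistics `data.frame`: `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n`,
#'   `stratum`.
#' @export
single_variant_assoc <- function(geno, trait, cohort = geno$samples,
                                 covariates = character(0),
                                 model = c("linear", "logistic"),
                                 stratum = unique(geno$samples$stratum)[1]) {
  model <- match.arg(model)
  y <- if (is.character(trait) && length(trait) == 1) cohort[[trait]] else trait
  if (anyNA(y)) stop("trait must be complete for analyzed samples")
  X <- geno$dosages
  n <- nrow(X)
  if (length(y) != n) stop("trait length must match sample count")
  C <- covariate_matrix(cohort, covariates)
  cm <- colMeans(X, na.rm = TRUE)
  if (anyNA(X)) {
    na_idx <- which(is.na(X))
    X[na_idx] <- cm[((na_idx - 1) %/% n) + 1]
  }
  eaf <- cm / 2
  varx <- apply(X, 2, stats::var)
  mono <- varx == 0 | eaf <= 0 | eaf >= 1
  beta <- se <- rep(NA_real_, ncol(X))
  if (model == "linear") {
    qrc <- qr(C)
    ry <- qr.resid(qrc, y)
    rx <- qr.resid(qrc, X)
    sxx <- colSums(rx^2)
    sxy <- colSums(rx * ry)
    syy <- sum(ry^2)
    df <- n - ncol(C) - 1
    ok <- !mono & sxx > 1e-12
    beta[ok] <- sxy[ok] / sxx[ok]
    sig2 <- pmax(0, (syy - beta[ok] * sxy[ok]) / df)
    se[ok] <- sqrt(sig2 / sxx[ok])
  } else {
    if (!all(y %in% c(0, 1))) stop("logistic model requires a 0/1 trait")
    ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 50)
    for (j in which(!mono)) {
      XX <- cbind(C, dosage = X[, j])
      fit <- suppressWarnings(
        stats::glm.fit(XX, y, family = stats::binomial(), control = ctrl))
      if (!fit$converged || fit$rank < ncol(XX) ||
          anyNA(fit$coefficients)) next
      r <- fit$rank
      covm <- chol2inv(fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE])
      pos <- match(ncol(XX), fit$qr$pivot)
      beta[j] <- fit$coefficients[ncol(XX)]
      se[j] <- sqrt(covm[pos, pos])
    }
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  out <- data.frame(variant_id = geno$variants$variant_id,
                    chrom = geno$variants$chrom, pos = geno$variants$pos,
                    effect_allele = geno$variants$alt,
                    other_allele = geno$variants$ref,
                    eaf = eaf, beta = beta, se = se, p = p, n = n,
                    stratum = stratum, stringsAsFactors = FALSE)
  skipped <- sum(mono)
  out <- out[!mono, , drop = FALSE]
  attr(out, "skipped") <- skipped
  attr(out, "n_nonconverged") <- sum(is.na(out$beta))
  out
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Per variant, with fixed-effect weights `w = 1/se^2`: heterogeneity
#' `Q = sum w (beta - beta_FE)^2`, between-stratum variance
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, random-effect
#' weights `w* = 1/(se^2 + tau2)`, pooled `beta = sum w* beta / sum w*`
#' and `se = 1/sqrt(sum w*)`. With a single stratum the input is returned
#' unchanged (`tau2 = 0`); whenever `Q <= k - 1` the result equals the
#' fixed-effects pooling.
#'
#' @param stats `data.frame` with `variant_id`, `beta`, `se` stacked over
#'   strata (one row per stratum per variant), or a list of per-stratum
#'   summary-statistics frames which is row-bound first.
#' @return `data.frame` per variant: `variant_id`, `beta`, `se`, `p`, `Q`,
#'   `tau2`, `k`.
#' @export
random_effects_meta <- function(stats) {
  meta_pool(stats, random = TRUE)
}

#' Fixed-effects (inverse-variance) meta-analysis
#'
#' As [random_effects_meta()] but with `tau2` fixed at zero.
#' @inheritParams random_effects_meta
#' @return `data.frame` per variant: `variant_id`, `beta`, `se`, `p`, `Q`,
#'   `tau2`, `k`.
#' @export
fixed_effects_meta <- function(stats) {
  meta_pool(stats, random = FALSE)
}

meta_pool <- function(stats, random) {
  if (is.data.frame(stats)) stats <- list(stats)
  df <- do.call(rbind, lapply(stats, function(s)
    s[, c("variant_id", "beta", "se"), drop = FALSE]))
  df <- df[!is.na(df$beta) & !is.na(df$se) & df$se > 0, , drop = FALSE]
  if (!nrow(df))
    return(data.frame(variant_id = character(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0), Q = numeric(0),
                      tau2 = numeric(0), k = integer(0)))
  res <- lapply(split(df, df$variant_id), function(g) {
    k <- nrow(g)
    w <- 1 / g$se^2
    b_fe <- sum(w * g$beta) / sum(w)
    Q <- sum(w * (g$beta - b_fe)^2)
    tau2 <- if (random && k > 1)
      max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
    ws <- 1 / (g$se^2 + tau2)
    b <- sum(ws * g$beta) / sum(ws)
    se <- 1 / sqrt(sum(ws))
    data.frame(variant_id = g$variant_id[1], beta = b, se = se,
               p = 2 * stats::pnorm(-abs(b / se)), Q = Q, tau2 = tau2,
               k = k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# complement map for strand flips
.comp <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize effect alleles against a reference source
#'
#' Aligns summary statistics to a reference's allele orientation, matching
#' variants on chromosome and position. Swapped effect/other alleles flip
#' the sign of beta and replace eaf by 1 - eaf; strand flips are resolved
#' by base complement; strand-ambiguous A/T and C/G variants with eaf in
#' (0.4, 0.6) are dropped (outside that band the orientation whose eaf is
#' closer to the reference eaf is used); irreconcilable allele pairs are
#' dropped. Drop and flip counts are reported in attribute `"harmonization"`.
#' The operation is idempotent.
#'
#' @param stats,reference Summary-statistics `data.frame`s with `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`.
#' @return The harmonized subset of `stats`, alleles oriented as in
#'   `reference`.
#' @export
harmonize_alleles <- function(stats, reference) {
  key <- paste(stats$chrom, stats$pos)
  rkey <- paste(reference$chrom, reference$pos)
  idx <- match(key, rkey)
  counts <- c(matched = 0L, flipped = 0L, strand = 0L,
              ambiguous_dropped = 0L, unmatched = 0L, irreconcilable = 0L)
  keep <- logical(nrow(stats))
  out <- stats
  for (i in seq_len(nrow(stats))) {
    j <- idx[i]
    if (is.na(j)) { counts["unmatched"] <- counts["unmatched"] + 1L; next }
    ea <- stats$effect_allele[i]; oa <- stats$other_allele[i]
    rea <- reference$effect_allele[j]; roa <- reference$other_allele[j]
    palindromic <- identical(.comp[[ea]], oa)
    if (palindromic) {
      if (!setequal(c(ea, oa), c(rea, roa))) {
        counts["irreconcilable"] <- counts["irreconcilable"] + 1L
        next
      }
      if (!is.na(stats$eaf[i]) && stats$eaf[i] > 0.4 && stats$eaf[i] < 0.6) {
        counts["ambiguous_dropped"] <- counts["ambiguous_dropped"] + 1L
        next
      }
      # orientation with eaf closest to the reference decides swap vs not
      swap <- if (!is.na(reference$eaf[j]))
        abs((1 - stats$eaf[i]) - reference$eaf[j]) <
          abs(stats$eaf[i] - reference$eaf[j])
      else ea != rea
      if (swap) {
        out$beta[i] <- -out$beta[i]
        out$eaf[i] <- 1 - out$eaf[i]
        out$effect_allele[i] <- rea; out$other_allele[i] <- roa
        counts["flipped"] <- counts["flipped"] + 1L
      } else counts["matched"] <- counts["matched"] + 1L
      keep[i] <- TRUE
      next
    }
    if (ea == rea && oa == roa) {
      counts["matched"] <- counts["matched"] + 1L; keep[i] <- TRUE
    } else if (ea == roa && oa == rea) {
      out$beta[i] <- -out$beta[i]; out$eaf[i] <- 1 - out$eaf[i]
      out$effect_allele[i] <- rea; out$other_allele[i] <- roa
      counts["flipped"] <- counts["flipped"] + 1L; keep[i] <- TRUE
    } else if (identical(.comp[[ea]], rea) && identical(.comp[[oa]], roa)) {
      out$effect_allele[i] <- rea; out$other_allele[i] <- roa
      counts["strand"] <- counts["strand"] + 1L; keep[i] <- TRUE
    } else if (identical(.comp[[ea]], roa) && identical(.comp[[oa]], rea)) {
      out$beta[i] <- -out$beta[i]; out$eaf[i] <- 1 - out$eaf[i]
      out$effect_allele[i] <- rea; out$other_allele[i] <- roa
      counts["flipped"] <- counts["flipped"] + 1L
      counts["strand"] <- counts["strand"] + 1L; keep[i] <- TRUE
    } else {
      counts["irreconcilable"] <- counts["irreconcilable"] + 1L
    }
  }
  res <- out[keep, , drop = FALSE]
  attr(res, "harmonization") <- counts
  res
}

#' Ancestry- (or sex-) stratified GWAS with random-effects pooling
#'
#' Runs [single_variant_assoc()] within each non-empty stratum and pools
#' the per-stratum results per variant with [random_effects_meta()].
#'
#' @inheritParams single_variant_assoc
#' @param strata Name of the `cohort` column defining strata (default
#'   `"stratum"`).
#' @return List with `strata` (named list of per-stratum summary
#'   statistics) and `meta` (per-variant pooled results).
#' @export
stratified_gwas <- function(geno, trait, cohort, covariates = character(0),
                            model = c("linear", "logistic"),
                            strata = "stratum") {
  model <- match.arg(model)
  labels <- unique(cohort[[strata]])
  per <- list()
  for (s in labels) {
    rows <- which(cohort[[strata]] == s)
    if (!length(rows)) { warning("empty stratum ", s, " omitted"); next }
    per[[s]] <- single_variant_assoc(
      subset_genotypes(geno, samples = rows),
      if (is.character(trait) && length(trait) == 1) cohort[[trait]][rows]
      else trait[rows],
      cohort[rows, , drop = FALSE], covariates, model, stratum = s)
  }
  if (!length(per)) stop("no non-empty strata")
  list(strata = per, meta = random_effects_meta(per))
}

#' Genomic inflation factor
#'
#' Lambda = median observed Wald chi-squared over the null median
#' (`qchisq(0.5, 1)`).
#'
#' @param stats Summary-statistics `data.frame` with `beta`, `se`.
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(stats) {
  z2 <- (stats$beta / stats$se)^2
  stats::median(z2, na.rm = TRUE) / stats::qchisq(0.5, 1)
}
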