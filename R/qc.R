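#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on the heterozygote count given the allele
#' counts: the p-value is the sum of probabilities of all heterozygote
#' configurations no more probable than the observed one (the standard
#' two-sided exact HWE test).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total > 0).
#' @return The exact p-value. Monomorphic configurations return 1.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (n_AA < 0 || n_Aa < 0 || n_aa < 0) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("total genotype count must be positive")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa
  if (n_rare == 0 || n_rare == 2 * n) return(1)
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(hom_c) - lfactorial(h) +
      h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }, 0)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_Aa, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

# Hard-call a dosage matrix: nearest integer when within 0.1, else missing.
# HWE and IBS are defined on genotypes, not expected counts.
hard_calls <- function(dosages, band = 0.1) {
  g <- round(dosages)
  g[abs(dosages - g) > band] <- NA
  g
}

#' Variant-level quality control
#'
#' Applies, in fixed order, (1) call rate < `call_rate_min`, (2) minor
#' allele frequency < `maf_min` (on pooled samples), (3) exact HWE p <
#' `hwe_p_min` on hard-called genotypes within each ancestry stratum (a
#' variant fails if it deviates in any stratum it is used in). Boundary
#' values are kept; each removed variant is attributed to the first filter
#' it fails.
#'
#' @param geno A [genotype_matrix()].
#' @param call_rate_min,maf_min,hwe_p_min Thresholds (defaults 0.95, 0.01,
#'   1e-5).
#' @return List: `genotypes` (filtered) and `report` (class `qc_report`).
#' @export
filter_variants <- function(geno, call_rate_min = 0.95, maf_min = 0.01,
                            hwe_p_min = 1e-5) {
  d <- geno$dosages
  m <- ncol(d)
  call_rate <- if (nrow(d)) colMeans(!is.na(d)) else rep(1, m)
  f <- allele_freqs(geno)
  maf <- pmin(f, 1 - f)
  fail <- rep(NA_character_, m)
  fail[call_rate < call_rate_min] <- "call_rate"
  idx <- which(is.na(fail) & maf < maf_min)
  fail[idx] <- "maf"
  g <- hard_calls(d)
  for (j in which(is.na(fail))) {
    for (s in unique(geno$samples$stratum)) {
      gj <- g[geno$samples$stratum == s, j]
      gj <- gj[!is.na(gj)]
      if (!length(gj)) next
      p <- hwe_exact_test(sum(gj == 0), sum(gj == 1), sum(gj == 2))
      if (p < hwe_p_min) { fail[j] <- "hwe"; break }
    }
  }
  keep <- is.na(fail)
  report <- qc_report("variant", n_in = m, n_out = sum(keep),
                      removed = table(factor(fail[!keep],
                                             c("call_rate", "maf", "hwe"))),
                      thresholds = list(call_rate_min = call_rate_min,
                                        maf_min = maf_min,
                                        hwe_p_min = hwe_p_min))
  if (!any(keep))
    stop("all variants removed by QC (",
         paste(sprintf("%s=%d", names(report$removed), report$removed),
               collapse = ", "), ")")
  list(genotypes = subset_genotypes(geno, variants = which(keep)),
       report = report)
}

qc_report <- function(axis, n_in, n_out, removed, thresholds) {
  stopifnot(n_in - sum(removed) == n_out)
  structure(list(axis = axis, n_in = n_in, n_out = n_out,
                 removed = c(removed), thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report (%s): %d in, %d out\n", x$axis, x$n_in, x$n_out))
  for (nm in names(x$removed))
    cat(sprintf("  removed by %s: %d\n", nm, x$removed[[nm]]))
  invisible(x)
}

#' Pairwise relatedness (pi-hat) by method of moments
#'
#' Method-of-moments identity-by-descent estimation from identity-by-state
#' counts on hard-called genotypes, given sample allele frequencies:
#' P(IBD=0/1/2) are solved sequentially from the observed IBS0/1/2 counts
#' and their expectations under each IBD state, clipped to [0, 1], and
#' `pihat = P(IBD=1)/2 + P(IBD=2)`.
#'
#' @param geno A [genotype_matrix()] with >= 2 samples.
#' @param freqs Optional alternate-allele frequencies to condition on;
#'   defaults to the sample frequencies.
#' @return `data.frame` (`id1`, `id2`, `pihat`, `n_variants`) for all
#'   unordered pairs. Fewer than 50 usable variants triggers a warning and
#'   a `low_confidence` attribute.
#' @export
estimate_relatedness <- function(geno, freqs = NULL) {
  g <- hard_calls(geno$dosages)
  n <- nrow(g)
  if (n < 2) stop("need at least 2 samples")
  p <- if (is.null(freqs)) colMeans(g, na.rm = TRUE) / 2 else freqs
  poly <- !is.na(p) & p > 0 & p < 1
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  q <- 1 - p
  low_conf <- ncol(g) < 50
  if (low_conf)
    warning("fewer than 50 usable variants; relatedness estimates are low-confidence")
  # expected IBS-state probabilities given IBD state, with the
  # finite-sample correction: the pair's alleles are treated as draws
  # without replacement from the 2N observed alleles, which removes the
  # bias of plugging in sample frequencies
  nal <- 2 * colSums(!is.na(g))
  deep <- nal >= 4
  g <- g[, deep, drop = FALSE]; p <- p[deep]; q <- q[deep]; nal <- nal[deep]
  x <- nal * p          # observed alternate-allele count
  y <- nal - x
  d0 <- nal * (nal - 1) * (nal - 2) * (nal - 3)
  e0_ibs0 <- 2 * x * (x - 1) * y * (y - 1) / d0
  e0_ibs1 <- 2 * (2 * x * y) *
    ((x - 1) * (x - 2) + (y - 1) * (y - 2)) / d0
  e0_ibs2 <- 1 - e0_ibs0 - e0_ibs1
  d1 <- nal * (nal - 1) * (nal - 2)
  e1_ibs2 <- (x * ((x - 1) * (x - 2) + y * (y - 1)) +
                y * (x * (x - 1) + (y - 1) * (y - 2))) / d1
  e1_ibs1 <- 1 - e1_ibs2
  ids <- geno$samples$sample_id
  pairs <- utils::combn(n, 2)
  res <- apply(pairs, 2, function(pr) {
    g1 <- g[pr[1], ]; g2 <- g[pr[2], ]
    ok <- !is.na(g1) & !is.na(g2)
    ibs <- 2 - abs(g1[ok] - g2[ok])
    n0 <- sum(ibs == 0); n1 <- sum(ibs == 1); n2 <- sum(ibs == 2)
    P0 <- min(1, max(0, n0 / sum(e0_ibs0[ok])))
    P1 <- min(1, max(0, (n1 - P0 * sum(e0_ibs1[ok])) / sum(e1_ibs1[ok])))
    P2 <- min(1, max(0, (n2 - P0 * sum(e0_ibs2[ok]) - P1 * sum(e1_ibs2[ok])) /
                       sum(ok)))
    c(min(1, max(0, P1 / 2 + P2)), sum(ok))
  })
  out <- data.frame(id1 = ids[pairs[1, ]], id2 = ids[pairs[2, ]],
                    pihat = res[1, ], n_variants = as.integer(res[2, ]),
                    stringsAsFactors = FALSE)
  attr(out, "low_confidence") <- low_conf
  out
}

#' Sample-level quality control
#'
#' Applies, in fixed order, (1) sample call rate < `call_rate_min`, (2)
#' genotype-inferred vs reported sex mismatch (heterozygosity on the
#' designated X-analog variants: inferred male when the het rate is below
#' `xhet_male_max`; skipped when `x_variants` is `NULL`), (3) relatedness:
#' for each pair with pi-hat > `pihat_max`, the member with the lower call
#' rate is removed (ties: the lexicographically larger id).
#'
#' @param geno A [genotype_matrix()].
#' @param reported_sex Named character vector ("M"/"F") over sample ids, or
#'   `NULL` to skip the sex check.
#' @param call_rate_min,pihat_max Thresholds (defaults 0.90, 0.9).
#' @param x_variants Variant ids to use for sex inference.
#' @param xhet_male_max Het-rate boundary below which a sample is inferred
#'   male.
#' @return List: `genotypes` (filtered) and `report` (class `qc_report`).
#' @export
filter_samples <- function(geno, reported_sex = NULL, call_rate_min = 0.90,
                           pihat_max = 0.9, x_variants = NULL,
                           xhet_male_max = 0.2) {
  d <- geno$dosages
  n <- nrow(d)
  ids <- geno$samples$sample_id
  call_rate <- if (ncol(d)) rowMeans(!is.na(d)) else rep(1, n)
  fail <- rep(NA_character_, n)
  fail[call_rate < call_rate_min] <- "call_rate"
  if (!is.null(x_variants) && !is.null(reported_sex)) {
    xj <- match(intersect(x_variants, geno$variants$variant_id),
                geno$variants$variant_id)
    if (length(xj)) {
      gx <- hard_calls(d[, xj, drop = FALSE])
      het <- rowMeans(gx == 1, na.rm = TRUE)
      inferred <- ifelse(het < xhet_male_max, "M", "F")
      mism <- inferred != reported_sex[ids]
      fail[is.na(fail) & !is.na(mism) & mism] <- "sex"
    }
  }
  alive <- which(is.na(fail))
  if (length(alive) >= 2 && ncol(d) > 0) {
    rel <- suppressWarnings(
      estimate_relatedness(subset_genotypes(geno, samples = alive)))
    hi <- rel[rel$pihat > pihat_max, , drop = FALSE]
    for (k in seq_len(nrow(hi))) {
      i1 <- hi$id1[k]; i2 <- hi$id2[k]
      if (!is.na(fail[match(i1, ids)]) || !is.na(fail[match(i2, ids)])) next
      cr1 <- call_rate[match(i1, ids)]; cr2 <- call_rate[match(i2, ids)]
      drop_id <- if (cr1 < cr2) i1 else if (cr2 < cr1) i2 else max(i1, i2)
      fail[match(drop_id, ids)] <- "relatedness"
    }
  }
  keep <- is.na(fail)
  report <- qc_report("sample", n_in = n, n_out = sum(keep),
                      removed = table(factor(fail[!keep],
                                             c("call_rate", "sex", "relatedness"))),
                      thresholds = list(call_rate_min = call_rate_min,
                                        pihat_max = pihat_max))
  list(genotypes = subset_genotypes(geno, samples = which(keep)),
       report = report)
}

#' Principal components of the genotype matrix
#'
#' Eigenvectors of the covariance of the standardized dosage matrix
#' (per-variant centered at `2f` and scaled by `sqrt(2 f (1-f))`, missing
#' entries set to the variant mean). Intended to be run within one
#' ancestry stratum, after dropping a designated high-LD region (an
#' MHC/HLA analog) when supplied. Returned coordinates are the unit-norm
#' left singular vectors with a deterministic sign: the
#' largest-magnitude variant loading of each component is positive.
#'
#' @param geno A [genotype_matrix()].
#' @param n_pcs Number of components (must not exceed the matrix rank).
#' @param exclude_region Optional `list(chrom, start, end)`; variants in
#'   the interval are dropped before the decomposition.
#' @return Numeric matrix (samples x `n_pcs`, columns `PC1`...), with the
#'   eigenvalues of the standardized covariance in attribute `"eigenvalues"`.
#' @export
compute_pcs <- function(geno, n_pcs = 10, exclude_region = NULL) {
  d <- geno$dosages
  if (!is.null(exclude_region)) {
    drop <- geno$variants$chrom == exclude_region$chrom &
      geno$variants$pos >= exclude_region$start &
      geno$variants$pos <= exclude_region$end
    d <- d[, !drop, drop = FALSE]
  }
  f <- colMeans(d, na.rm = TRUE) / 2
  poly <- f > 0 & f < 1
  d <- d[, poly, drop = FALSE]
  f <- f[poly]
  x <- sweep(d, 2, 2 * f)
  x[is.na(x)] <- 0
  x <- sweep(x, 2, sqrt(2 * f * (1 - f)), "/")
  rk <- min(nrow(x) - 1L, ncol(x))
  if (n_pcs > rk)
    stop("n_pcs = ", n_pcs, " exceeds the matrix rank (", rk, ")")
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  for (k in seq_len(n_pcs)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) { sv$v[, k] <- -sv$v[, k]; sv$u[, k] <- -sv$u[, k] }
  }
  pcs <- sv$u[, seq_len(n_pcs), drop = FALSE]
  dimnames(pcs) <- list(geno$samples$sample_id, paste0("PC", seq_len(n_pcs)))
  attr(pcs, "eigenvalues") <- sv$d^2 / (nrow(x) - 1)
  pcs
}
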