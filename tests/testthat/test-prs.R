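test_that("LD pruning keeps one of a duplicate pair and all independent variants", {
  g <- random_geno(300, rep(0.4, 6), seed = 1)
  v <- data.frame(variant_id = g$variants$variant_id, p = (1:6) / 100)
  expect_setequal(ld_prune(v, g, 0.5), v$variant_id)

  dup <- make_geno(cbind(g$dosages[, 1], g$dosages[, 1], g$dosages[, 2]))
  v3 <- data.frame(variant_id = c("v001", "v002", "v003"),
                   p = c(0.2, 0.01, 0.5))
  kept <- ld_prune(v3, dup, 0.5)
  expect_setequal(kept, c("v002", "v003"))  # smaller p wins the pair

  expect_warning(
    k2 <- ld_prune(data.frame(variant_id = c("v001", "ghost"), p = c(0.1, 0.2)),
                   dup, 0.5),
    "absent from the LD panel")
  expect_true("ghost" %in% k2)
})

test_that("pruning matches an exhaustive oracle on a 12-variant LD block fixture", {
  set.seed(2)
  base <- matrix(stats::rbinom(400 * 4, 2, 0.45), 400, 4)
  jitter <- function(x, k) ifelse(stats::runif(length(x)) < k,
                                  sample(0:2, length(x), TRUE), x)
  dos <- cbind(base[, 1], jitter(base[, 1], 0.05), jitter(base[, 1], 0.3),
               base[, 2], jitter(base[, 2], 0.1), jitter(base[, 2], 0.4),
               base[, 3], jitter(base[, 3], 0.02), jitter(base[, 3], 0.5),
               base[, 4], jitter(base[, 4], 0.15), jitter(base[, 4], 0.6))
  g <- make_geno(dos)
  v <- data.frame(variant_id = g$variants$variant_id,
                  p = stats::runif(12))
  got <- ld_prune(v, g, r2_cutoff = 0.4)

  ord <- order(v$p, g$variants$pos, v$variant_id)
  kept <- integer(0)
  for (i in ord) {
    r2 <- if (length(kept)) stats::cor(dos[, i], dos[, kept])^2 else 0
    if (!any(r2 >= 0.4)) kept <- c(kept, i)
  }
  expect_setequal(got, g$variants$variant_id[kept])
})

test_that("threshold ladder produces nested, shrinking models", {
  set.seed(3)
  g <- random_geno(500, rep(0.3, 30), seed = 4)
  ss <- data.frame(variant_id = g$variants$variant_id, chrom = "1",
                   pos = g$variants$pos, effect_allele = "G",
                   other_allele = "A", eaf = 0.3,
                   beta = stats::rnorm(30, 0, 0.05),
                   se = 0.02, stringsAsFactors = FALSE)
  ss$p <- 2 * stats::pnorm(-abs(ss$beta / ss$se))
  sizes <- sapply(10^-(1:8), function(th)
    derive_prs_weights(ss, th, panel = g)$n_variants)
  expect_true(all(diff(sizes) <= 0))

  all_in <- derive_prs_weights(ss, 1.01, panel = g)
  expect_equal(all_in$n_variants, 30)  # independent variants survive pruning

  nullss <- ss; nullss$beta <- stats::rnorm(30, 0, 1e-4)
  nullss$p <- 2 * stats::pnorm(-abs(nullss$beta / 0.02))
  empty <- derive_prs_weights(nullss, 1e-8, panel = g)
  expect_equal(empty$n_variants, 0)
  expect_true(isTRUE(attr(empty, "empty")))
})

test_that("scoring is the dosage-weight double loop with allele alignment", {
  g <- make_geno(matrix(0, 3, 2))
  m0 <- prs_model("t", "s", 1, data.frame(variant_id = c("v001", "v002"),
                                          effect_allele = "G",
                                          beta = c(0.5, -0.2)))
  expect_equal(as.numeric(prs_score(m0, g)), c(0, 0, 0))

  g1 <- make_geno(matrix(c(2), 1, 1))
  m1 <- prs_model("t", "s", 1, data.frame(variant_id = "v001",
                                          effect_allele = "G", beta = 0.3))
  expect_equal(as.numeric(prs_score(m1, g1)), 0.6)

  # REF-oriented weight flips the dosage
  m1r <- prs_model("t", "s", 1, data.frame(variant_id = "v001",
                                           effect_allele = "A", beta = 0.3))
  expect_equal(as.numeric(prs_score(m1r, g1)), 0)

  set.seed(5)
  dos <- matrix(stats::rbinom(5 * 8, 2, 0.5), 5, 8)
  g58 <- make_geno(dos)
  w <- stats::rnorm(8)
  m <- prs_model("t", "s", 1, data.frame(
    variant_id = g58$variants$variant_id, effect_allele = "G", beta = w))
  sc <- prs_score(m, g58)
  oracle <- numeric(5)
  for (i in 1:5) for (j in 1:8) oracle[i] <- oracle[i] + dos[i, j] * w[j]
  expect_equal(as.numeric(sc), oracle, tolerance = 1e-12)

  # missing dosages are mean-imputed at 2 * eaf
  dosNA <- dos; dosNA[1, 1] <- NA
  gNA <- make_geno(dosNA)
  mNA <- prs_model("t", "s", 1, data.frame(
    variant_id = g58$variants$variant_id, effect_allele = "G", beta = w,
    eaf = rep(0.25, 8)))
  scNA <- prs_score(mNA, gNA)
  expect_equal(as.numeric(scNA[1]),
               oracle[1] - dos[1, 1] * w[1] + 0.5 * w[1], tolerance = 1e-12)
  expect_equal(attr(scNA, "n_imputed"), 1L)

  bad <- prs_model("t", "s", 1, data.frame(
    variant_id = c("v001", "zz1", "zz2", "zz3"), effect_allele = "G",
    beta = 1))
  expect_error(prs_score(bad, g58), "unmappable")
})

test_that("score is additive in per-variant contributions", {
  set.seed(6)
  dos <- matrix(stats::rbinom(20 * 4, 2, 0.5), 20, 4)
  g <- make_geno(dos)
  w <- c(0.2, -0.4, 0.1, 0.7)
  total <- prs_score(prs_model("t", "s", 1, data.frame(
    variant_id = g$variants$variant_id, effect_allele = "G", beta = w)), g)
  parts <- sapply(1:4, function(j)
    prs_score(prs_model("t", "s", 1, data.frame(
      variant_id = g$variants$variant_id[j], effect_allele = "G",
      beta = w[j])), g))
  expect_equal(as.numeric(total), unname(rowSums(parts)), tolerance = 1e-12)
})

test_that("multiethnic mixing weights: exact fit, pure-noise score, collinearity", {
  set.seed(7)
  pe <- stats::rnorm(500); pa <- stats::rnorm(500)
  exact <- multiethnic_combine(pe, pa, phenotype = pe)
  expect_equal(exact$alpha1, 1, tolerance = 1e-10)
  expect_equal(exact$alpha2, 0, tolerance = 1e-10)
  expect_equal(exact$r2, 1, tolerance = 1e-10)

  y <- 0.8 * pe + stats::rnorm(500, 0, 0.6)
  noise <- multiethnic_combine(pe, stats::rnorm(500), y)
  ea_only <- multiethnic_combine(pe, pe * 0 + stats::rnorm(500, 0, 1e-8), y)
  expect_lt(abs(noise$alpha2), 0.1)

  col <- multiethnic_combine(pe, pe * 1.0000001, y)
  expect_true(col$collinear)
  expect_equal(col$alpha2, 0)

  # two-score in-sample R2 is at least each single-score R2
  pa2 <- 0.5 * pe + stats::rnorm(500)
  y2 <- 0.3 * pe + 0.4 * pa2 + stats::rnorm(500)
  both <- multiethnic_combine(pe, pa2, y2)
  one <- multiethnic_combine(pe, pa2 * 0 + stats::rnorm(500, 0, 1e-9), y2)
  expect_gte(both$r2, one$r2 - 1e-12)
})

test_that("cross-validated folds are stratified, deterministic, and error on empty", {
  spec <- population_spec(n_blocks = 20, block_size = 3,
                          within_block_r2 = 0.2, fst_divergence = 0.1)
  g <- simulate_genotypes(spec, c(100, 400), seed = 8)
  tr <- trait_spec("d", "binary", n_causal = 15, h2 = 0.4, prevalence = 0.3)
  ph <- simulate_phenotypes(g, tr, g$samples, seed = 9)
  ref <- simulate_reference_sumstats(g, tr, 50000, seed = 10,
                                     truth = attr(ph, "truth")$d)
  cv <- crossval_multiethnic(g, ph, "d", ref, k = 5, seed = 3,
                             threshold = 0.05, binary = TRUE)
  y_aa <- ph$d[ph$stratum == "AA"]
  global_cases <- sum(y_aa)
  for (f in 1:5) {
    in_fold <- cv$folds == f
    expect_lte(abs(sum(y_aa[in_fold]) - global_cases / 5), 1)
  }
  cv2 <- crossval_multiethnic(g, ph, "d", ref, k = 5, seed = 3,
                              threshold = 0.05, binary = TRUE)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$per_fold, cv2$per_fold, tolerance = 1e-12)

  rare <- ph; rare$d[rare$stratum == "AA"] <- 0
  rare$d[which(rare$stratum == "AA")[1:3]] <- 1
  expect_error(crossval_multiethnic(g, rare, "d", ref, k = 5, seed = 3,
                                    binary = TRUE), "zero cases")
})

test_that("PRS-phenotype matrix has the grid shape and a dominant diagonal", {
  spec <- population_spec(n_blocks = 30, block_size = 3,
                          within_block_r2 = 0.2, fst_divergence = 0.05)
  g <- simulate_genotypes(spec, c(800, 0), seed = 11)
  trs <- list(trait_spec("ya", "quantitative", n_causal = 15, h2 = 0.5),
              trait_spec("yb", "quantitative", n_causal = 15, h2 = 0.5))
  ph <- simulate_phenotypes(g, trs, g$samples, seed = 12)
  refs <- lapply(c("ya", "yb"), function(nm)
    simulate_reference_sumstats(g, trs[[match(nm, c("ya", "yb"))]], 1e6,
                                seed = 13, truth = attr(ph, "truth")[[nm]]))
  models <- list()
  for (i in 1:2) for (th in c(1e-2, 1e-4))
    models[[length(models) + 1]] <-
      derive_prs_weights(refs[[i]], th, panel = g,
                         trait = c("ya", "yb")[i], source = "ref")
  pm <- prs_phenotype_matrix(models, g, ph,
                             c(ya = "quantitative", yb = "quantitative"))
  expect_equal(dim(pm$z), c(4L, 2L))
  # per-trait models associate more strongly with their own phenotype
  expect_gt(pm$z[1, "ya"], pm$z[3, "ya"])
  expect_gt(pm$z[3, "yb"], pm$z[1, "yb"])
  expect_true(pm$flag[1, "ya"])
})

test_that("risk stratification reproduces the cross-product OR and handles zeros", {
  s <- c(rep(2, 50), rep(0, 950))
  d <- c(rep(1, 10), rep(0, 40), rep(1, 90), rep(0, 860))
  rs <- risk_stratification(s, d, top_fractions = 0.05)
  expect_equal(rs$a, 10); expect_equal(rs$d, 860)
  expect_equal(rs$odds_ratio, (10 * 860) / (40 * 90), tolerance = 1e-12)
  expect_true(rs$ci_lo < rs$odds_ratio & rs$odds_ratio < rs$ci_hi)

  # all cases concentrated in the top group: corrected, finite OR
  d2 <- c(rep(1, 20), rep(0, 980))
  rs2 <- risk_stratification(s, d2, top_fractions = 0.05)
  expect_true(rs2$corrected)
  expect_true(is.finite(rs2$odds_ratio))
  expect_gt(rs2$odds_ratio, 1)

  expect_error(risk_stratification(s, rep(0, 1000)), "at least one case")

  multi <- risk_stratification(list(A = s, B = rev(s)), d,
                               top_fractions = c(0.05, 0.10))
  expect_equal(nrow(multi), 4)
  expect_true(all(multi$fdr_adjusted_p >= multi$p - 1e-15))
})

test_that("pooled marginal R2 follows inverse-variance arithmetic", {
  same <- meta_prs_r2(data.frame(beta = c(0.2, 0.2), se = c(0.1, 0.1)))
  expect_equal(same$beta, 0.2)
  expect_equal(same$r2, 0.04)
  # hand computation: w = (100, 25); pooled b = (0.3*100 + 0.1*25)/125
  two <- meta_prs_r2(data.frame(beta = c(0.3, 0.1), se = c(0.1, 0.2)))
  expect_equal(two$beta, (0.3 * 100 + 0.1 * 25) / 125, tolerance = 1e-12)
  expect_equal(two$r2, two$beta^2)
  zero <- meta_prs_r2(data.frame(beta = c(0, 0), se = c(0.1, 0.2)))
  expect_equal(zero$r2, 0)
  one <- meta_prs_r2(data.frame(beta = 0.5, se = 0.1))
  expect_equal(one$beta, 0.5)
})
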