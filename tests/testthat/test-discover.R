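test_that("BH adjustment matches the worked ladder and is order-stable", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.04, 0.2)),
               c(0.004, 0.02, 0.04 * 4 / 3, 0.2), tolerance = 1e-12)
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(1)
  p <- stats::runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]), tolerance = 1e-15)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("specificity filter applies the three criteria on worked intervals", {
  cohort <- data.frame(variant_id = c("a", "b", "c"),
                       beta = c(0.5, 0.2, 0.5), se = c(0.05, 0.05, 0.05),
                       p = c(1e-23, 0.02, 1e-23), stringsAsFactors = FALSE)
  ref <- data.frame(variant_id = c("a", "b", "c"),
                    beta = c(0, 0.2, 0.5), se = c(0.05, 0.05, 0.05),
                    p = c(1, 0.02, 1e-23), stringsAsFactors = FALSE)
  calls <- specific_variant_filter(cohort, ref)
  # a: CIs [0.371,0.629] vs [-0.129,0.129] disjoint, both p criteria pass
  expect_true(calls$specific[calls$variant_id == "a"])
  expect_equal(calls$ci_cohort_lo[1], 0.5 - 2.5758293 * 0.05, tolerance = 1e-6)
  # b: cohort p 0.02 >= 0.01 fails regardless of intervals
  expect_false(calls$specific[calls$variant_id == "b"])
  expect_match(calls$reasons[calls$variant_id == "b"], "cohort_p")
  # c: identical stats in both sources can never be specific
  expect_false(calls$specific[calls$variant_id == "c"])

  # intervals sharing an endpoint count as overlapping
  z <- stats::qnorm(0.995)
  touch <- specific_variant_filter(
    data.frame(variant_id = "t", beta = 2 * z * 0.1, se = 0.1, p = 1e-9),
    data.frame(variant_id = "t", beta = 0, se = 0.1, p = 0.9))
  expect_false(touch$specific)

  none <- specific_variant_filter(
    data.frame(variant_id = "x", beta = 1, se = 0.1, p = 1e-9),
    data.frame(variant_id = "y", beta = 0, se = 0.1, p = 0.9))
  expect_false(none$specific)
  expect_equal(none$reasons, "absent_from_reference")
})

test_that("specificity filter is mirror-symmetric with symmetric thresholds", {
  set.seed(2)
  a <- data.frame(variant_id = paste0("v", 1:50),
                  beta = stats::rnorm(50, 0, 0.3),
                  se = stats::runif(50, 0.02, 0.1), stringsAsFactors = FALSE)
  a$p <- 2 * stats::pnorm(-abs(a$beta / a$se))
  b <- data.frame(variant_id = paste0("v", 1:50),
                  beta = stats::rnorm(50, 0, 0.3),
                  se = stats::runif(50, 0.02, 0.1), stringsAsFactors = FALSE)
  b$p <- 2 * stats::pnorm(-abs(b$beta / b$se))
  ab <- specific_variant_filter(a, b, p_cohort = 0.01, p_reference = 0.01)
  ba <- specific_variant_filter(b, a, p_cohort = 0.01, p_reference = 0.01)
  # a variant specific in the a-vs-b direction must show disjoint CIs and
  # reversed p-roles; with symmetric p thresholds the CI criterion is shared
  expect_equal(ab$ci_cohort_lo, ba$ci_ref_lo, tolerance = 1e-12)
  disjoint_ab <- ab$ci_cohort_lo > ab$ci_ref_hi | ab$ci_cohort_hi < ab$ci_ref_lo
  disjoint_ba <- ba$ci_cohort_lo > ba$ci_ref_hi | ba$ci_cohort_hi < ba$ci_ref_lo
  expect_equal(disjoint_ab, disjoint_ba)
})

test_that("greedy clumping matches a brute-force oracle and the trivial cases", {
  # mutually independent variants -> as many loci as variants
  g_ind <- random_geno(300, rep(0.5, 6), seed = 3)
  calls <- data.frame(variant_id = g_ind$variants$variant_id,
                      p = stats::runif(6))
  loci <- independent_loci(calls, g_ind, r2_max = 0.5, window_kb = 500)
  expect_equal(length(unique(loci$locus)), 6)

  # a perfect-LD duplicate collapses into one locus led by the smaller p
  dup <- make_geno(cbind(g_ind$dosages[, 1], g_ind$dosages[, 1]))
  calls2 <- data.frame(variant_id = c("v001", "v002"), p = c(0.5, 0.01))
  l2 <- independent_loci(calls2, dup)
  expect_equal(length(unique(l2$locus)), 1)
  expect_true(l2$is_index[l2$variant_id == "v002"])

  # 10-variant LD fixture vs an independently coded greedy oracle
  set.seed(4)
  base <- matrix(stats::rbinom(200 * 3, 2, 0.4), 200, 3)
  noisy <- function(x, k) ifelse(stats::runif(length(x)) < k, sample(0:2,
    length(x), TRUE), x)
  dos <- cbind(base[, 1], noisy(base[, 1], 0.1), noisy(base[, 1], 0.6),
               base[, 2], noisy(base[, 2], 0.15), noisy(base[, 2], 0.7),
               base[, 3], noisy(base[, 3], 0.05), noisy(base[, 3], 0.5),
               stats::rbinom(200, 2, 0.4))
  g10 <- make_geno(dos)
  calls10 <- data.frame(variant_id = g10$variants$variant_id,
                        p = stats::runif(10))
  got <- independent_loci(calls10, g10, r2_max = 0.3, window_kb = 500)

  ord <- order(calls10$p, g10$variants$pos, calls10$variant_id)
  idx <- integer(0); assign_to <- integer(10)
  for (i in ord) {
    placed <- 0L
    for (k in seq_along(idx)) {
      r2 <- stats::cor(dos[, i], dos[, idx[k]])^2
      if (abs(g10$variants$pos[i] - g10$variants$pos[idx[k]]) <= 5e5 &&
          r2 > 0.3) { placed <- k; break }
    }
    if (placed == 0L) { idx <- c(idx, i); placed <- length(idx) }
    assign_to[i] <- placed
  }
  oracle <- assign_to[match(got$variant_id, g10$variants$variant_id)]
  expect_equal(got$locus, oracle)
})

test_that("Fisher over-representation matches the hypergeometric tail", {
  universe <- paste0("g", 1:1000)
  hits <- paste0("g", 1:100)
  lib <- list(setA = paste0("g", c(1:10, 901:910)),   # 10 of 20 in hits
              setB = paste0("g", 500:520),            # disjoint from hits
              setC = character(0))
  res <- gene_set_enrichment(hits, lib, universe)
  a <- 10; m <- 20; k <- 100
  p_oracle <- stats::phyper(a - 1, m, 1000 - m, k, lower.tail = FALSE)
  expect_equal(res$p[res$set == "setA"], p_oracle, tolerance = 1e-12)
  expect_equal(res$odds_ratio[res$set == "setB"], 0)
  expect_equal(res$p[res$set == "setB"], 1)
  expect_equal(res$p[res$set == "setC"], 1)
  expect_true(all(res$fdr_adjusted_p >= res$p - 1e-15))
  expect_error(gene_set_enrichment(hits, lib, character(0)), "empty universe")
  expect_error(gene_set_enrichment("nope", lib, universe), "subset")

  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
})

test_that("eQTL enrichment excludes reference hits, prunes, and tests the 2x2", {
  set.seed(5)
  g <- random_geno(400, rep(0.4, 40), seed = 6)
  ids <- g$variants$variant_id
  all_stats <- data.frame(variant_id = ids, p = stats::runif(40),
                          stringsAsFactors = FALSE)
  all_stats$p[1:10] <- 1e-4   # the "specific" block gets small cohort p
  calls <- data.frame(variant_id = ids, specific = c(rep(TRUE, 10),
                                                     rep(FALSE, 30)))
  reference <- data.frame(variant_id = ids, p = rep(0.5, 40))
  reference$p[11] <- 1e-7     # excluded before testing
  esnp <- data.frame(variant_id = rep(ids, 2),
                     condition = rep(c("basal", "lps"), each = 40),
                     esnp = rep(c(TRUE, FALSE), 40))
  res <- eqtl_enrichment(calls, all_stats, esnp, reference, g)
  expect_equal(nrow(res), 2)
  expect_equal(sum(res$n_spec_esnp + res$n_spec_other +
                     res$n_rest_esnp + res$n_rest_other == 39), 2)

  # hand-computed chi-squared for (30,70 | 100,900)
  chi_hand <- 1100 * (30 * 900 - 70 * 100)^2 / (100 * 1000 * 130 * 970)
  ct <- stats::chisq.test(matrix(c(30, 70, 100, 900), 2, byrow = TRUE),
                          correct = FALSE)
  expect_equal(unname(ct$statistic), chi_hand, tolerance = 1e-12)
  expect_equal(chi_hand, 34.89247, tolerance = 1e-4)
})

test_that("empty 2x2 cells fall back to the exact test, flagged", {
  g <- random_geno(200, rep(0.4, 20), seed = 7)
  ids <- g$variants$variant_id
  all_stats <- data.frame(variant_id = ids, p = seq(0.001, 0.9, length = 20))
  calls <- data.frame(variant_id = ids, specific = c(rep(TRUE, 5),
                                                     rep(FALSE, 15)))
  reference <- data.frame(variant_id = ids, p = 0.5)
  esnp <- data.frame(variant_id = ids, condition = "basal",
                     esnp = c(rep(FALSE, 5), rep(c(TRUE, FALSE), c(5, 10))))
  res <- eqtl_enrichment(calls, all_stats, esnp, reference, g)
  expect_equal(res$method, "fisher_exact")
  expect_true(res$p >= 0 && res$p <= 1)
})

test_that("GMT round trip feeds enrichment", {
  tf <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), tf)
  lib <- read_gmt(tf)
  expect_equal(lib$setA, c("g1", "g2", "g3"))
  res <- gene_set_enrichment(c("g1", "g2"), lib, paste0("g", 1:10))
  expect_lt(res$p[res$set == "setA"], res$p[res$set == "setB"])
})
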