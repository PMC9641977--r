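test_that("overlap percentages and hypergeometric p match printed examples and enumeration", {
  u <- paste0("g", 1:5000)
  a <- paste0("g", 1:1706)
  b <- paste0("g", c(1:1427, 2000:2278))
  os <- overlap_stats(a, b, u)
  expect_equal(os$overlap, 1427L)
  expect_equal(os$pct_of_a, 83.6)   # 1,427 / 1,706

  expect_equal(overlap_stats(paste0("g", 1:146),
                             paste0("g", c(1:72, 200:300)),
                             u)$pct_of_a, 49.3)  # 72 / 146

  # A subset of B -> 100%
  expect_equal(overlap_stats(u[1:10], u[1:50], u)$pct_of_a, 100.0)
  expect_error(overlap_stats(character(), u[1:5], u), "empty")

  # universe 10, |A| = 5, |B| = 4, overlap 4 -> p = 6/252
  u10 <- paste0("x", 1:10)
  os <- overlap_stats(u10[1:5], u10[c(1:4)], u10)
  expect_equal(os$p, 6 / 252, tolerance = 1e-12)

  # exhaustive enumeration oracle over small universes
  set.seed(10)
  for (i in 1:8) {
    N <- sample(8:16, 1); nA <- sample(2:5, 1); nB <- sample(2:6, 1)
    a <- sample(N, nA); b <- sample(N, nB)
    k <- length(intersect(a, b))
    got <- overlap_stats(paste0("x", a), paste0("x", b), paste0("x", 1:N))$p
    expect_equal(got, enum_hyper_p(k, nB, N, nA), tolerance = 1e-10)
  }
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  fl <- c(rep(TRUE, 4), rep(FALSE, 1), rep(TRUE, 1), rep(FALSE, 4))
  dom <- c(rep("center", 5), rep("arm", 5))
  res <- arm_center_fisher(fl, dom)
  expect_equal(res$p, stats::fisher.test(matrix(c(4, 1, 1, 4), 2))$p.value)
  expect_equal(round(res$p, 4), 0.2063)  # table [[4,1],[1,4]], two-sided

  # identical proportions: odds ratio 1, p = 1
  res <- arm_center_fisher(rep(c(TRUE, FALSE), 10), rep(c("arm", "center"),
                                                        each = 10))
  expect_equal(res$p, 1)
  expect_equal(res$odds_ratio, 1, tolerance = 1e-6)
  expect_error(arm_center_fisher(rep(TRUE, 4), rep("arm", 4)), "margin")

  # enumeration oracle: P(table at least as extreme) via dhyper mass ranking
  tab <- matrix(c(5, 2, 1, 6), 2)
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  probs <- stats::dhyper(0:min(m, k), m, n, k)
  p_enum <- sum(probs[probs <= stats::dhyper(tab[1, 1], m, n, k) + 1e-9])
  got <- arm_center_fisher(c(rep(TRUE, 6), rep(FALSE, 8)),
                           rep(c("center", "arm"), c(7, 7))[c(1:5, 8:9, 6:7,
                                                              10:14)])
  expect_equal(stats::fisher.test(tab)$p.value, p_enum, tolerance = 1e-9)
})

test_that("domain assignment uses midpoints deterministically", {
  domains <- data.frame(chrom = "chrI", start = c(1L, 101L, 201L),
                        end = c(100L, 200L, 300L),
                        domain = c("arm", "center", "arm"))
  expect_equal(assign_domain("chrI", c(50, 150, 250, 100, 101), domains),
               c("arm", "center", "arm", "arm", "center"))
  expect_true(is.na(assign_domain("chrII", 50, domains)))
})

test_that("Wilcoxon comparisons match exact enumeration", {
  expr <- rbind(g1 = c(1, 1, 4, 4), g2 = c(2, 2, 5, 5), g3 = c(3, 3, 6, 6))
  colnames(expr) <- c("t20a", "t20b", "t30a", "t30b")
  design <- data.frame(sample = colnames(expr), genotype = "temperate",
                       temperature = c(20, 20, 30, 30), replicate = c(1, 2, 1, 2))
  res <- target_expression_compare(expr, c("g1", "g2", "g3"), design,
                                   "temperate", c(20, 30))
  # per-gene means {1,2,3} vs {4,5,6}: exact two-sided p = 0.1
  expect_equal(res$p.value, 0.1, tolerance = 1e-12)
  expect_equal(res$p.value, enum_wilcox_p(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)

  # identical distributions -> p = 1
  expr2 <- rbind(g1 = c(1, 1, 1, 1), g2 = c(2, 2, 2, 2), g3 = c(3, 3, 3, 3),
                 g4 = c(4, 4, 4, 4))
  colnames(expr2) <- colnames(expr)
  res <- target_expression_compare(expr2, rownames(expr2), design,
                                   "temperate", c(20, 30))
  expect_equal(res$p.value, 1)

  # random small cases against full enumeration
  set.seed(11)
  for (i in 1:5) {
    repeat {  # tie-free draws (ties switch wilcox.test to its approximation)
      x <- round(stats::rnorm(5), 2); y <- round(stats::rnorm(4) + 0.5, 2)
      if (!anyDuplicated(c(x, y))) break
    }
    got <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))$p.value
    expect_equal(got, enum_wilcox_p(x, y), tolerance = 1e-10)
  }
  expect_error(target_expression_compare(expr, "g1", design, "temperate"),
               "fewer than 2")
})

test_that("bin decrease summaries count strict decreases and magnitudes", {
  # X-chromosome worked example: 184 decreased of 217 bins -> 85% (Table-style
  # integer rounding), mean magnitude from the decreased bins only
  n <- 217; ndec <- 184
  prof <- data.frame(
    sample = rep(c("t20", "t30"), each = n),
    chrom = "chrX", win_start = rep(seq(1, by = 100000, length.out = n), 2),
    log2_rpm = c(rep(5, n), c(rep(5 - 1.84, ndec), rep(5, n - ndec))))
  design <- data.frame(sample = c("t20", "t30"), genotype = "temperate",
                       temperature = c(20, 30), replicate = 1)
  bs <- bin_decrease_summary(prof, design, "temperate")
  expect_equal(bs$n_decreased, 184L)
  expect_equal(round(bs$pct_decreased), 85)
  expect_equal(bs$mean_decrease, 1.84, tolerance = 1e-12)
  # percentages recompute exactly from the summary's own counts
  expect_equal(bs$pct_decreased, 100 * bs$n_decreased / bs$n_bins)

  # ties are not decreases
  prof$log2_rpm <- 5
  bs <- bin_decrease_summary(prof, design, "temperate")
  expect_equal(bs$pct_decreased, 0)

  # uniform -1 log2 shift -> 100%, magnitude 1.0
  prof$log2_rpm <- rep(c(5, 4), each = n)
  bs <- bin_decrease_summary(prof, design, "temperate")
  expect_equal(bs$pct_decreased, 100)
  expect_equal(bs$mean_decrease, 1.0)
})

test_that("aggregate chromosome model matches the balanced ANOVA solution", {
  design <- default_design(replicates = 2L)
  chroms <- paste0("chr", c("I", "II", "III", "X"))
  grid <- expand.grid(sample = design$sample, chrom = chroms,
                      stringsAsFactors = FALSE)
  lib <- stats::setNames(rep(1e6, nrow(design)), design$sample)

  # all totals equal -> effect p-values 1 (up to numerical tolerance);
  # the perfect-fit warning from summary.lm is the expected degeneracy
  grid$count <- 1000
  m <- suppressWarnings(chromosome_model(grid, design, lib, x_chrom = "chrX"))
  expect_true(all(m$contrasts$p[m$contrasts$contrast != "interaction_30"] > 0.999 |
                    is.nan(m$contrasts$p[m$contrasts$contrast != "interaction_30"])))

  # X doubled -> X-vs-autosome contrasts significant, estimate = 1 log2
  grid$count <- ifelse(grid$chrom == "chrX", 2000, 1000) +
    rep(stats::rnorm(nrow(design), 0, 1), length(chroms))
  m <- chromosome_model(grid, design, lib, x_chrom = "chrX")
  xc <- m$contrasts[grepl("^chrX_vs_", m$contrasts$contrast), ]
  expect_true(all(xc$p < 1e-10))
  expect_equal(xc$estimate, rep(1, 3), tolerance = 0.02)

  # temperate-only 30C reduction -> interaction significant, tropical not
  set.seed(12)
  mult <- ifelse(grid$sample %in% design$sample[design$genotype == "temperate" &
                                                  design$temperature == 30],
                 1 / 2.3, 1)
  grid$count <- 1000 * mult * exp(stats::rnorm(nrow(grid), 0, 0.02))
  m <- chromosome_model(grid, design, lib, x_chrom = "chrX")
  cc <- m$contrasts
  expect_lt(cc$p[cc$contrast == "interaction_30"], 0.01)
  expect_gt(cc$p[cc$contrast == "tropical_30_vs_20"], 0.05)
  expect_equal(1 / cc$fold_change[cc$contrast == "temperate_30_vs_20"], 2.3,
               tolerance = 0.05)

  # equals the closed-form balanced two-way solution (cell means on log2 RPM)
  d <- merge(grid, design, by = "sample")
  d$y <- log2((d$count + 0.5) / 1e6 * 1e6)
  cell <- function(g, t) mean(d$y[d$genotype == g & d$temperature == t])
  expect_equal(cc$estimate[cc$contrast == "interaction_30"],
               (cell("temperate", 30) - cell("temperate", 20)) -
                 (cell("tropical", 30) - cell("tropical", 20)),
               tolerance = 1e-9)
})

test_that("class-total models recover a configured fold change", {
  design <- default_design(replicates = 3L)
  lib <- stats::setNames(rep(2e6, nrow(design)), design$sample)
  set.seed(13)
  ct <- data.frame(sample = design$sample, feature_class = "protein_coding",
                   count = 50000)
  eff <- design$genotype == "temperate" & design$temperature == 30
  ct$count[eff] <- ct$count[eff] / 2.3
  ct$count <- ct$count * exp(stats::rnorm(nrow(ct), 0, 0.03))
  m <- class_total_model(ct, design, lib)
  cc <- m$protein_coding$contrasts
  expect_equal(1 / cc$fold_change[cc$contrast == "temperate_30_vs_20"], 2.3,
               tolerance = 0.1)
  expect_lt(cc$p[cc$contrast == "interaction_30"], 0.05)
  expect_error(class_total_model(ct[0, ], design, lib))
})

test_that("target sets compile through orthology with availability counts", {
  # identity table leaves sets unchanged
  src <- list(S = paste0("ce", 1:10))
  idt <- data.frame(source = paste0("ce", 1:20), target = paste0("ce", 1:20))
  expect_equal(compile_target_sets(src, idt)$sets$S, src$S)

  # 10 source ids, 7 mapped -> mapped size <= 7, unmapped recorded
  ot <- data.frame(source = paste0("ce", 1:7),
                   target = c(paste0("cb", 1:6), "cb6"))
  cc <- compile_target_sets(src, ot)
  expect_lte(length(cc$sets$S), 7L)
  expect_setequal(cc$unmapped$S, paste0("ce", 8:10))

  # availability columns reproduce printed set-size structure
  sets <- list(`CSR-1` = paste0("g", 1:4839), `EGO-1` = paste0("g", 1:1706),
               `RRF-1` = paste0("g", 1:146))
  coll <- compile_target_sets(sets, NULL)
  avail <- target_set_availability(coll, list(
    srna = paste0("g", 1:3919), mrna = paste0("g", 1:4636)))
  expect_equal(avail$n_total, c(4839L, 1706L, 146L))
  expect_equal(avail$n_srna[avail$set == "CSR-1"], 3919L)
  expect_equal(avail$n_mrna[avail$set == "CSR-1"], 4636L)
})

test_that("correlation suite captures opposing bulk and top-decile trends", {
  # perfectly monotone pairs -> rho = 1
  x <- seq_len(50); y <- x^2
  cs <- correlation_suite(x, y)
  expect_equal(cs$rho_all, 1)

  # antitonic top decile grafted onto a monotone bulk
  set.seed(14)
  x <- sort(stats::runif(500, 0, 10))
  y <- x + stats::rnorm(500, 0, 0.1)
  top <- x >= stats::quantile(x, 0.9)
  y[top] <- 25 - 1.5 * x[top] + stats::rnorm(sum(top), 0, 0.1)
  cs <- correlation_suite(x, y)
  expect_gt(cs$rho_all, 0)
  expect_lt(cs$rho_top, 0)
  expect_lt(cs$z_test$p, 1e-6)
  expect_equal(cs$n_top, 50L)

  # equal correlations, equal n -> z = 0, p = 1
  zt <- fisher_z_test(0.5, 100, 0.5, 100)
  expect_equal(zt$z, 0)
  expect_equal(zt$p, 1)

  # polynomial coefficients equal the closed-form least squares solution
  cs <- correlation_suite(x, y)
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(cs$poly_coef, drop(beta), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(correlation_suite(1:2, 1:2), "at least 3")
})

test_that("DE category overlap reproduces printed percentages", {
  # identical tables -> 100% overlap per category
  ca <- data.frame(feature_id = paste0("g", 1:100),
                   category = rep(c("interaction", "no_effect"), 50))
  ov <- de_category_overlap(ca, ca)
  expect_equal(ov$pct_of_a, c(100, 100))

  # 1,269 of 4,108 interaction genes shared -> 30.9%
  u <- paste0("g", seq_len(9000))
  ca <- data.frame(feature_id = u,
                   category = rep("none", 9000), stringsAsFactors = FALSE)
  cb <- ca
  ca$category[1:4108] <- "interaction"
  cb$category[c(1:1269, 5000:7000)] <- "interaction"
  ov <- de_category_overlap(ca, cb)
  expect_equal(ov$n_both[ov$category == "interaction"], 1269L)
  expect_equal(ov$pct_of_a[ov$category == "interaction"], 30.9)

  # label permutation sits near the null expectation
  set.seed(15)
  cb2 <- ca
  cb2$category <- sample(ca$category)
  ov <- de_category_overlap(ca, cb2)
  expect_equal(ov$pct_of_a[ov$category == "interaction"],
               100 * 4108 / 9000, tolerance = 0.12)
  expect_error(de_category_overlap(ca, data.frame(feature_id = "zz",
                                                  category = "x")),
               "disjoint")
})
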