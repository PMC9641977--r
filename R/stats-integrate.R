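# Aggregate-level models, bin summaries, arm/center contrasts and
# Argonaute/RdRP target-set statistics.

# log2 RPM with 0.5-count pseudocount
log2_rpm <- function(count, lib) log2((count + 0.5) / lib * 1e6)

# t-test of a linear contrast L'beta from an lm fit
lm_contrast <- function(fit, L) {
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  est <- sum(L * b)
  se <- sqrt(drop(t(L) %*% V %*% L))
  if (se < 1e-12) {  # degenerate perfect fit: a zero contrast is a null one
    tval <- if (abs(est) < 1e-9) 0 else sign(est) * Inf
  } else tval <- est / se
  p <- 2 * stats::pt(-abs(tval), df = fit$df.residual)
  c(estimate = est, se = se, t = tval, p = p)
}

#' Linear model of per-chromosome small RNA totals
#'
#' Fits `log2 RPM ~ chromosome + genotype + temperature +
#' genotype:temperature` by ordinary least squares on per-chromosome totals
#' (unplaced scaffolds excluded by the caller) and reports the
#' genotype-specific 30 vs 20 degree effects, the interaction at 30 degrees,
#' and X-vs-autosome chromosome contrasts.
#'
#' @param totals Data frame `sample`, `chrom`, `count`.
#' @param design Sample design (`sample`, `genotype`, `temperature`).
#' @param lib_sizes Named per-sample library sizes.
#' @param x_chrom Name of the X chromosome for the chromosome contrasts
#'   (`NULL` to skip).
#' @return List of class `aggregate_fit`: `fit` (the `lm`), `contrasts`
#'   (data frame with estimate, fold_change, p per reported contrast).
#' @export
chromosome_model <- function(totals, design, lib_sizes, x_chrom = NULL) {
  d <- merge(totals, design, by = "sample")
  d$y <- log2_rpm(d$count, lib_sizes[d$sample])
  d$genotype <- factor(d$genotype, levels = c("tropical", "temperate"))
  d$temperature <- factor(d$temperature, levels = c(20, 14, 30))
  d$chrom <- factor(d$chrom)
  fit <- stats::lm(y ~ chrom + genotype * temperature, data = d)
  if (any(is.na(stats::coef(fit)))) stopf("rank-deficient aggregate model")
  rows <- aggregate_contrasts(fit)
  if (!is.null(x_chrom)) {
    cn <- names(stats::coef(fit))
    lev <- levels(d$chrom)
    for (a in setdiff(lev, x_chrom)) {
      L <- stats::setNames(numeric(length(cn)), cn)
      cx <- paste0("chrom", x_chrom); ca <- paste0("chrom", a)
      if (cx %in% cn) L[cx] <- 1
      if (ca %in% cn) L[ca] <- -1
      rows <- rbind(rows, data.frame(
        contrast = sprintf("%s_vs_%s", x_chrom, a),
        as.list(lm_contrast(fit, L)), stringsAsFactors = FALSE))
    }
  }
  rows$fold_change <- 2^rows$estimate
  structure(list(fit = fit, contrasts = rows), class = "aggregate_fit")
}

# 30-vs-20 contrasts shared by the aggregate models
aggregate_contrasts <- function(fit) {
  cn <- names(stats::coef(fit))
  mk <- function(parts) {
    L <- stats::setNames(numeric(length(cn)), cn)
    L[parts] <- 1
    L
  }
  int30 <- grep("genotypetemperate:temperature30", cn, value = TRUE)
  t30 <- "temperature30"
  rbind(
    data.frame(contrast = "tropical_30_vs_20",
               as.list(lm_contrast(fit, mk(t30))), stringsAsFactors = FALSE),
    data.frame(contrast = "temperate_30_vs_20",
               as.list(lm_contrast(fit, mk(c(t30, int30)))),
               stringsAsFactors = FALSE),
    data.frame(contrast = "interaction_30",
               as.list(lm_contrast(fit, mk(int30))), stringsAsFactors = FALSE))
}

#' Per-feature-class linear models of class totals
#'
#' As [chromosome_model()] but fit separately per feature class, without the
#' chromosome term.
#'
#' @param class_totals Data frame `sample`, `feature_class`, `count`.
#' @param design Sample design.
#' @param lib_sizes Named per-sample library sizes.
#' @return Named list (per class) of `aggregate_fit` objects.
#' @export
class_total_model <- function(class_totals, design, lib_sizes) {
  if (!nrow(class_totals)) stopf("no class totals supplied")
  out <- list()
  for (cl in unique(class_totals$feature_class)) {
    d <- merge(class_totals[class_totals$feature_class == cl, , drop = FALSE],
               design, by = "sample")
    if (!nrow(d)) stopf("no observations for class '%s'", cl)
    d$y <- log2_rpm(d$count, lib_sizes[d$sample])
    d$genotype <- factor(d$genotype, levels = c("tropical", "temperate"))
    d$temperature <- factor(d$temperature, levels = c(20, 14, 30))
    fit <- stats::lm(y ~ genotype * temperature, data = d)
    if (any(is.na(stats::coef(fit)))) stopf("rank-deficient model for '%s'", cl)
    rows <- aggregate_contrasts(fit)
    rows$fold_change <- 2^rows$estimate
    out[[cl]] <- structure(list(fit = fit, contrasts = rows),
                           class = "aggregate_fit")
  }
  out
}

#' Summarise windows with decreased expression at 30 degrees
#'
#' A bin counts as decreased iff its replicate-mean log2 RPM at 30 degrees is
#' strictly below the 20 degree mean (ties are not decreases); the magnitude
#' is the mean (20 minus 30) difference over decreased bins.
#'
#' @param profile Window profile (from [window_profile()]) joined across
#'   samples, or any data frame with `sample`, `chrom`, `win_start`,
#'   `log2_rpm`.
#' @param design Sample design.
#' @param genotype Genotype to summarise.
#' @param temps Length-2 vector: reference and stress temperature.
#' @return Data frame of class `bin_summary`: per chromosome `n_bins`,
#'   `n_decreased`, `pct_decreased`, `mean_decrease`.
#' @export
bin_decrease_summary <- function(profile, design, genotype,
                                 temps = c(20, 30)) {
  s1 <- design$sample[design$genotype == genotype &
                        design$temperature == temps[1]]
  s2 <- design$sample[design$genotype == genotype &
                        design$temperature == temps[2]]
  if (!length(s1) || !length(s2))
    stopf("no samples for genotype '%s' at the requested temperatures", genotype)
  key <- interaction(profile$chrom, profile$win_start, drop = TRUE)
  m1 <- tapply(profile$log2_rpm[profile$sample %in% s1],
               key[profile$sample %in% s1], mean)
  m2 <- tapply(profile$log2_rpm[profile$sample %in% s2],
               key[profile$sample %in% s2], mean)
  stopifnot(identical(names(m1), names(m2)))
  if (!length(m1)) stopf("zero bins in profile")
  chrom <- sub("\\..*$", "", names(m1))
  dec <- m2 < m1
  out <- do.call(rbind, lapply(sort(unique(chrom)), function(ch) {
    i <- chrom == ch
    data.frame(chrom = ch, n_bins = sum(i), n_decreased = sum(dec[i]),
               pct_decreased = 100 * sum(dec[i]) / sum(i),
               mean_decrease = if (any(dec[i]))
                 mean(m1[i][dec[i]] - m2[i][dec[i]]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("bin_summary", class(out))
  out
}

#' Fisher's exact test of a flag across arm/center domains
#'
#' @param flag Logical vector per bin (or gene), e.g. "decreased in one
#'   genotype but not the other".
#' @param domain Character vector (`"arm"` / `"center"`) per bin.
#' @return List with `table` (2 x 2), `odds_ratio`, `p` (two-sided).
#' @export
arm_center_fisher <- function(flag, domain) {
  tab <- table(factor(domain, levels = c("center", "arm")),
               factor(flag, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("empty margin in arm/center contingency table")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Assign bins (by midpoint) or genes (by start) to arm/center domains
#'
#' @param chrom,pos Vectors of chromosome names and positions (midpoints for
#'   bins, starts for genes).
#' @param domains Domain table (`chrom`, `start`, `end`, `domain`).
#' @return Character vector of domain labels (`NA` outside any domain).
#' @export
assign_domain <- function(chrom, pos, domains) {
  out <- rep(NA_character_, length(chrom))
  for (i in seq_len(nrow(domains))) {
    sel <- chrom == domains$chrom[i] & pos >= domains$start[i] &
      pos <= domains$end[i]
    out[sel] <- domains$domain[i]
  }
  out
}

#' Compile Argonaute/RdRP target-gene sets via an ortholog map
#'
#' Native sets pass through unchanged; ortholog-mapped sets are the image of
#' the source ids under the map (many-to-many rows permitted; duplicates
#' collapse).  Unmapped ids are recorded, not fatal.
#'
#' @param native_sets Named list of character vectors of gene ids.
#' @param ortholog_table Data frame with columns `source`, `target`
#'   (`NULL` for identity).
#' @param native Names of sets that are already in target-id space.
#' @return List of class `target_set_collection`: `sets` (named list),
#'   `provenance`, `unmapped` (named list of dropped source ids).
#' @export
compile_target_sets <- function(native_sets, ortholog_table = NULL,
                                native = character()) {
  sets <- list(); unmapped <- list()
  for (nm in names(native_sets)) {
    ids <- unique(native_sets[[nm]])
    if (nm %in% native || is.null(ortholog_table)) {
      sets[[nm]] <- ids
      unmapped[[nm]] <- character()
    } else {
      hit <- ortholog_table$source %in% ids
      sets[[nm]] <- unique(ortholog_table$target[hit])
      unmapped[[nm]] <- setdiff(ids, ortholog_table$source)
    }
  }
  structure(list(sets = sets,
                 provenance = ifelse(names(native_sets) %in% native |
                                       is.null(ortholog_table),
                                     "native", "ortholog_mapped"),
                 unmapped = unmapped), class = "target_set_collection")
}

#' Set sizes and data availability per target set
#'
#' @param collection A `target_set_collection`.
#' @param universes Named list of gene-id universes (e.g. genes with 22G
#'   data, genes with mRNA data).
#' @return Data frame: one row per set with total size and per-universe
#'   availability counts.
#' @export
target_set_availability <- function(collection, universes) {
  out <- data.frame(set = names(collection$sets),
                    n_total = lengths(collection$sets),
                    stringsAsFactors = FALSE)
  for (u in names(universes))
    out[[paste0("n_", u)]] <- vapply(collection$sets, function(s)
      length(intersect(s, universes[[u]])), integer(1))
  rownames(out) <- NULL
  out
}

#' Overlap between two gene sets with a hypergeometric p-value
#'
#' @param a,b Character vectors (subsets of `universe`).
#' @param universe Character vector, or its size.
#' @return List: `overlap`, `pct_of_a` (one decimal), `p` (upper-tail
#'   hypergeometric `P(X >= overlap)`).
#' @examples
#' # 1,427 of 1,706 -> 83.6%
#' overlap_stats(paste0("g", 1:1706),
#'               paste0("g", 1:1427), paste0("g", 1:5000))$pct_of_a
#' @export
overlap_stats <- function(a, b, universe) {
  if (!length(a)) stopf("overlap percentage undefined: set A is empty")
  n_u <- if (is.numeric(universe) && length(universe) == 1L) universe
  else length(unique(universe))
  k <- length(intersect(a, b))
  list(overlap = k,
       pct_of_a = round(100 * k / length(unique(a)), 1),
       p = stats::phyper(k - 1, length(unique(b)),
                         n_u - length(unique(b)), length(unique(a)),
                         lower.tail = FALSE))
}

#' Wilcoxon rank-sum comparison of target-set expression across temperatures
#'
#' Compares per-gene mean expression (over replicates) between two
#' temperatures within one genotype, for the genes of a target set.  Exact p
#' for small groups (min n <= 25, no ties), normal approximation with
#' continuity correction otherwise.
#'
#' @param expr Gene x sample expression matrix (e.g. voom log2 RPM).
#' @param set Gene ids to test (>= 2 with data required).
#' @param design Sample design.
#' @param genotype Genotype to test within.
#' @param temps Length-2 temperature pair.
#' @return `htest`-like list with `p.value`, `statistic`, `n`.
#' @export
target_expression_compare <- function(expr, set, design, genotype,
                                      temps = c(20, 30)) {
  genes <- intersect(rownames(expr), set)
  if (length(genes) < 2L) stopf("fewer than 2 target genes with data")
  s1 <- design$sample[design$genotype == genotype &
                        design$temperature == temps[1]]
  s2 <- design$sample[design$genotype == genotype &
                        design$temperature == temps[2]]
  x <- rowMeans(expr[genes, s1, drop = FALSE])
  y <- rowMeans(expr[genes, s2, drop = FALSE])
  exact <- min(length(x), length(y)) <= 25 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(p.value = wt$p.value, statistic = unname(wt$statistic),
       n = length(genes))
}

#' Fisher z-test for the difference of two correlations
#'
#' @param r1,r2 Correlation coefficients.
#' @param n1,n2 Sample sizes.
#' @return List with `z` and two-sided `p`.
#' @export
fisher_z_test <- function(r1, n1, r2, n2) {
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Correlation bundle: small RNA vs mRNA expression
#'
#' Spearman rank correlation over all genes and over the top decile of small
#' RNA expression, a Fisher z-test comparing the two, and a descriptive
#' second-order polynomial least-squares fit of mRNA on small RNA expression.
#' Ties receive average ranks; p-values use the exact distribution for small
#' n and the normal approximation for n > 1290.
#'
#' @param srna,mrna Matched numeric vectors (condition means per gene).
#' @param top_fraction Fraction defining the top-expression subset (0.1).
#' @return List with `rho_all`, `p_all`, `n_all`, `rho_top`, `p_top`,
#'   `n_top`, `z_test` (all vs top), `poly_coef` (intercept, linear,
#'   quadratic).
#' @export
correlation_suite <- function(srna, mrna, top_fraction = 0.1) {
  if (length(srna) != length(mrna)) stopf("srna and mrna lengths differ")
  if (length(srna) < 3L) stopf("need at least 3 genes")
  exact_flag <- function(n) if (n <= 1290) NULL else FALSE
  ct <- suppressWarnings(stats::cor.test(srna, mrna, method = "spearman",
                                         exact = exact_flag(length(srna))))
  top <- srna >= stats::quantile(srna, 1 - top_fraction)
  ct_top <- suppressWarnings(stats::cor.test(srna[top], mrna[top],
                                             method = "spearman",
                                             exact = exact_flag(sum(top))))
  pf <- stats::lm(mrna ~ srna + I(srna^2))
  list(rho_all = unname(ct$estimate), p_all = ct$p.value, n_all = length(srna),
       rho_top = unname(ct_top$estimate), p_top = ct_top$p.value,
       n_top = sum(top),
       z_test = fisher_z_test(unname(ct$estimate), length(srna),
                              unname(ct_top$estimate), sum(top)),
       poly_coef = unname(stats::coef(pf)))
}

#' Overlap of differential-expression categories between two data types
#'
#' For each category, counts genes assigned that category in both tables
#' (within the shared universe), the percentage of the first table's category
#' genes shared, and an upper-tail hypergeometric p against the shared
#' universe.
#'
#' @param cat_a,cat_b Data frames with `feature_id` and `category` (e.g. 22G
#'   and mRNA classifications).
#' @return Data frame per category: `n_a`, `n_b`, `n_both`, `pct_of_a`, `p`.
#' @examples
#' # 1,269 of 4,108 -> 30.9%
#' @export
de_category_overlap <- function(cat_a, cat_b) {
  universe <- intersect(cat_a$feature_id, cat_b$feature_id)
  if (!length(universe)) stopf("disjoint feature universes")
  a <- cat_a[cat_a$feature_id %in% universe, ]
  b <- cat_b[cat_b$feature_id %in% universe, ]
  cats <- sort(unique(c(a$category, b$category)))
  out <- do.call(rbind, lapply(cats, function(cl) {
    ga <- a$feature_id[a$category == cl]
    gb <- b$feature_id[b$category == cl]
    k <- length(intersect(ga, gb))
    data.frame(category = cl, n_a = length(ga), n_b = length(gb), n_both = k,
               pct_of_a = if (length(ga)) round(100 * k / length(ga), 1)
               else NA_real_,
               p = if (length(ga))
                 stats::phyper(k - 1, length(gb),
                               length(universe) - length(gb), length(ga),
                               lower.tail = FALSE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
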