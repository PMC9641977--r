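# Per-feature genotype + temperature + genotype:temperature models on voom
# log2-RPM values with precision weights and empirical-Bayes moderation, and
# the five-group significance classification.

#' Build the genotype x temperature design matrix
#'
#' Temperature is an unordered factor with 20 degrees as the reference level,
#' so the interaction at 30 vs 20 degrees is a single coefficient.
#'
#' @param design Data frame with `sample`, `genotype`, `temperature`.
#' @return Model matrix with intercept, genotype indicator, two temperature
#'   indicators and two interaction indicators; rows named by sample.
#' @export
design_matrix <- function(design) {
  g <- factor(design$genotype, levels = c("tropical", "temperate"))
  t <- factor(design$temperature, levels = c(20, 14, 30))
  mm <- stats::model.matrix(~ g * t)
  colnames(mm) <- sub("^g", "genotype_", colnames(mm))
  colnames(mm) <- sub("t14", "temp_14", colnames(mm))
  colnames(mm) <- sub("t30", "temp_30", colnames(mm))
  colnames(mm) <- sub(":", "_x_", colnames(mm), fixed = TRUE)
  rownames(mm) <- design$sample
  if (qr(mm)$rank < ncol(mm))
    stopf("design matrix is not of full column rank")
  mm
}

#' Filter features on minimum RPM support
#'
#' @param counts Feature x sample count matrix.
#' @param lib_sizes Per-sample library sizes (same order as columns).
#' @param min_rpm Minimum reads-per-million.
#' @param min_reps Minimum number of samples (across all conditions) that
#'   must reach `min_rpm`.
#' @return Character vector of retained feature ids (rownames).
#' @export
expression_filter <- function(counts, lib_sizes, min_rpm = 1, min_reps = 3) {
  rpm <- sweep(counts, 2, lib_sizes, "/") * 1e6
  rownames(counts)[rowSums(rpm >= min_rpm) >= min_reps]
}

#' voom transform: log2 RPM with precision weights
#'
#' Computes `log2((count + 0.5) / (libsize + 1) * 1e6)`, fits the
#' mean-variance trend by local regression of per-feature sqrt residual
#' standard deviations on average log-counts, and derives per-observation
#' inverse-variance weights (the published voom recipe, via limma).  No
#' between-sample scale factors are applied beyond library size unless
#' `tmm = TRUE`.
#'
#' @param counts Feature x sample count matrix.
#' @param design Model matrix (see [design_matrix()]).
#' @param lib_sizes Per-sample library sizes.
#' @param tmm Apply trimmed-mean-of-M-values scale factors (off by default).
#' @return A `limma::EList` with components `E` (log2 RPM) and `weights`.
#' @export
voom_transform <- function(counts, design, lib_sizes, tmm = FALSE) {
  if (ncol(counts) < ncol(design))
    stopf("fewer samples (%d) than model columns (%d)", ncol(counts),
          ncol(design))
  lib <- lib_sizes
  if (tmm) lib <- lib * edgeR::calcNormFactors(counts, lib.size = lib_sizes)
  limma::voom(counts, design = design, lib.size = lib, span = 0.5)
}

#' Fit per-feature models and assign the five-group classification
#'
#' Weighted least squares per feature, residual variances shrunk toward a
#' common prior (moderated t with augmented degrees of freedom), and
#' Benjamini-Hochberg adjustment across features per coefficient.  Families:
#' genotype (1 coefficient), temperature (both temperature contrasts) and
#' interaction (both interaction contrasts); a family is significant when any
#' member coefficient has adjusted p below `fdr`.  Categories:
#' `interaction` (significant interaction), `additive` (genotype and
#' temperature, no interaction), `genotype_only`, `temperature_only`,
#' `no_effect` — a partition of the tested features.
#'
#' @param y Numeric matrix of log2 expression (or a `voom` `EList`).
#' @param design Model matrix.
#' @param weights Optional observation weights (taken from the `EList` when
#'   `y` is one; use `NULL` with `moderate = FALSE` for ordinary least
#'   squares + classical t).
#' @param fdr Adjusted-p threshold (0.05).
#' @param moderate Apply empirical-Bayes variance moderation.
#' @return List of class `fit_result`: `table` (per-feature coefficients,
#'   t, p, adjusted p, category), `coefficients`, `design`, `fdr`.
#' @export
fit_models <- function(y, design, weights = NULL, fdr = 0.05,
                       moderate = TRUE) {
  if (methods::is(y, "EList")) {
    if (is.null(weights)) weights <- y$weights
    y <- y$E
  }
  if (ncol(y) <= ncol(design)) stopf("zero residual degrees of freedom")
  # weighted LS inference is invariant to a global weight scale; normalising
  # to mean 1 keeps sigma on the log2 data scale so the floor below works
  if (!is.null(weights)) weights <- weights / mean(weights)
  fit <- limma::lmFit(y, design, weights = weights)
  # Degenerate near-zero-variance features (zero-noise data) would make the
  # moderated t 0/0.  Residual sds below 1e-4 on the log2 scale are smaller
  # than the quantisation introduced by count rounding and the 0.5
  # pseudocount, so they are floored there.
  fit$sigma[fit$sigma < 1e-4] <- 1e-4
  if (moderate) {
    eb <- limma::eBayes(fit)
    tt <- eb$t; pp <- eb$p.value
  } else {
    tt <- fit$coefficients / (fit$stdev.unscaled * fit$sigma)
    pp <- 2 * stats::pt(-abs(tt), df = fit$df.residual)
  }
  coefs <- colnames(design)
  fam <- list(genotype = grep("^genotype_[^x]*$", coefs, value = TRUE),
              temperature = grep("^temp_", coefs, value = TRUE),
              interaction = grep("_x_", coefs, value = TRUE))
  adj <- apply(pp, 2, stats::p.adjust, method = "BH")
  if (is.null(dim(adj))) adj <- matrix(adj, nrow = 1, dimnames = dimnames(pp))
  fam_sig <- vapply(fam, function(cols)
    if (length(cols)) apply(adj[, cols, drop = FALSE] < fdr, 1, any)
    else rep(FALSE, nrow(y)), logical(nrow(y)))
  if (is.null(dim(fam_sig)))
    fam_sig <- matrix(fam_sig, nrow = 1, dimnames = list(rownames(y), names(fam)))
  category <- ifelse(fam_sig[, "interaction"], "interaction",
              ifelse(fam_sig[, "genotype"] & fam_sig[, "temperature"], "additive",
              ifelse(fam_sig[, "genotype"], "genotype_only",
              ifelse(fam_sig[, "temperature"], "temperature_only", "no_effect"))))
  tab <- data.frame(feature_id = rownames(y), fit$coefficients,
                    check.names = FALSE)
  colnames(tab)[-1] <- paste0("coef.", coefs)
  for (cn in coefs) {
    tab[[paste0("t.", cn)]] <- tt[, cn]
    tab[[paste0("p.", cn)]] <- pp[, cn]
    tab[[paste0("adj.p.", cn)]] <- adj[, cn]
  }
  tab$category <- unname(category)
  rownames(tab) <- NULL
  structure(list(table = tab, coefficients = fit$coefficients,
                 design = design, fdr = fdr), class = "fit_result")
}

#' 2-D multidimensional scaling of samples
#'
#' Pairwise distances are root-mean-square log-fold-changes over the top 500
#' most divergent features per pair (leading-logFC convention); classical
#' metric scaling to two dimensions.  Axis signs are fixed by making each
#' axis's largest-magnitude loading positive.
#'
#' @param y Log-expression matrix (features x samples), >= 3 samples.
#' @param top Number of top features per pair.
#' @return Matrix samples x 2 of coordinates.
#' @export
mds_coordinates <- function(y, top = 500) {
  if (ncol(y) < 3L) stopf("need at least 3 samples for MDS")
  mds <- limma::plotMDS(y, top = top, plot = FALSE,
                        gene.selection = "pairwise")
  xy <- cbind(mds$x, mds$y)
  rownames(xy) <- colnames(y)
  colnames(xy) <- c("dim1", "dim2")
  for (k in 1:2) if (xy[which.max(abs(xy[, k])), k] < 0) xy[, k] <- -xy[, k]
  xy
}

#' Row-scale an expression matrix (heatmap utility)
#'
#' Centers and scales each row to unit variance, as used for row-normalised
#' heatmap display.
#'
#' @param y Numeric matrix.
#' @return Matrix of the same shape.
#' @export
row_scale <- function(y) {
  t(scale(t(y)))
}
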