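#' Ratio matrix of group means versus control
#'
#' Builds the proteins x (tissue, contrast) matrix of log2 ratios of group
#' means versus the control group, per tissue, restricted to proteins
#' quantified in every tissue and complete across all columns
#' (complete-case).  The number of proteins shared across tissues (before
#' the complete-case restriction) is reported as an attribute.
#'
#' @param tables Named list (by tissue) of protein-level quantification
#'   tables.
#' @param ann Sample annotation covering all tissues.
#' @param contrasts Case group labels (default `c("TM", "TS", "TSm")`).
#' @param control Control group label (default `"SH"`).
#' @return Numeric matrix (rows = proteins, columns named
#'   `<tissue>.<case>_<control>`) with attribute `n_shared`.
#' @export
build_ratio_matrix <- function(tables, ann, contrasts = c("TM", "TS", "TSm"),
                               control = "SH") {
  stopifnot(is.list(tables), length(tables) >= 1L, !is.null(names(tables)))
  ids <- Reduce(intersect, lapply(tables, `[[`, "protein_group_id"))
  if (length(ids) == 0L) stop("no proteins shared across tissues")
  cols <- list()
  for (t in names(tables)) {
    m <- intensity_matrix(tables[[t]])[ids, , drop = FALSE]
    ctrl <- rowMeans(m[, intersect(group_samples(ann, control, t),
                                   colnames(m)), drop = FALSE], na.rm = TRUE)
    for (g in contrasts) {
      case <- rowMeans(m[, intersect(group_samples(ann, g, t),
                                     colnames(m)), drop = FALSE],
                       na.rm = TRUE)
      cols[[paste0(t, ".", g, "_", control)]] <- log2(case / ctrl)
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- ids
  out <- out[rowSums(!is.finite(out)) == 0L, , drop = FALSE]
  attr(out, "n_shared") <- length(ids)
  out
}

#' PCA of ratio vectors
#'
#' Principal component analysis treating each (tissue, contrast) ratio
#' vector - a column of the ratio matrix - as an observation and proteins
#' as variables, on centered data.  This is the view in which tissues and
#' treatment groups separate.
#'
#' @param m Ratio matrix from [build_ratio_matrix()].
#' @return List with `scores` (observations x components),
#'   `explained` (variance fractions, summing to 1) and the `prcomp` fit.
#' @export
pca_of_ratios <- function(m) {
  if (ncol(m) < 2L) stop("PCA needs >= 2 columns")
  obs <- t(m)
  if (all(apply(obs, 2L, var) < 1e-24)) stop("constant ratio matrix")
  fit <- prcomp(obs, center = TRUE, scale. = FALSE)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, explained = explained, fit = fit)
}

#' Pairwise squared Pearson correlations between ratio vectors
#'
#' R-squared per column pair over pairwise-complete cases; the signed
#' correlations are kept as an attribute.  Zero-variance columns are
#' flagged and their off-diagonal entries reported as `NA`.
#'
#' @param m Ratio matrix from [build_ratio_matrix()].
#' @return Symmetric matrix of squared correlations (diagonal 1) with
#'   attributes `signed_r` and `zero_variance`.
#' @export
pairwise_r2 <- function(m) {
  if (ncol(m) < 2L) stop("needs >= 2 columns")
  zero_var <- apply(m, 2L, function(x) var(x, na.rm = TRUE)) < 1e-24
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  r2 <- r^2
  diag(r2) <- 1
  diag(r) <- 1
  attr(r2, "signed_r") <- r
  attr(r2, "zero_variance") <- colnames(m)[zero_var]
  r2
}

#' Overlap report for two AP sets
#'
#' Because the field uses several incompatible "overlap rate" definitions,
#' the report gives intersection and union counts, the Jaccard index, the
#' overlap coefficient (intersection over the smaller set) and the count of
#' shared proteins altered in the same direction, side by side.
#'
#' @param a,b `ap_set` objects (see [call_aps()]).
#' @return Data frame with one row: `label_a`, `label_b`, `n_a`, `n_b`,
#'   `intersection`, `union`, `jaccard`, `overlap_coefficient`,
#'   `same_direction`.
#' @export
ap_overlap <- function(a, b) {
  stopifnot(inherits(a, "ap_set"), inherits(b, "ap_set"))
  ia <- ap_ids(a)
  ib <- ap_ids(b)
  common <- intersect(ia, ib)
  uni <- union(ia, ib)
  jac <- if (length(uni) == 0L) 0 else length(common) / length(uni)
  ovc <- if (min(length(ia), length(ib)) == 0L) 0 else
    length(common) / min(length(ia), length(ib))
  dir_a <- a$members$direction[match(common, a$members$protein_group_id)]
  dir_b <- b$members$direction[match(common, b$members$protein_group_id)]
  data.frame(label_a = a$contrast, label_b = b$contrast,
             n_a = length(ia), n_b = length(ib),
             intersection = length(common), union = length(uni),
             jaccard = jac, overlap_coefficient = ovc,
             same_direction = sum(dir_a == dir_b),
             stringsAsFactors = FALSE)
}

#' Volcano-plot export of a comparison
#'
#' Emits the plot-ready table (log2 fold change, -log10 p, AP flag) whose
#' flags exactly reproduce [call_aps()] membership at the same cutoffs,
#' optionally writing a TSV and a PNG volcano figure.
#'
#' @param comparisons Comparison data frame from [compare_groups()].
#' @param fc_cutoff Fold-change cutoff (> 1).
#' @param alpha p-value cutoff.
#' @param tsv,fig Optional output file paths.
#' @return The export data frame, invisibly if `tsv` is written.
#' @export
volcano_export <- function(comparisons, fc_cutoff, alpha = 0.05,
                           tsv = NULL, fig = NULL) {
  if (nrow(comparisons) == 0L) stop("empty comparison list")
  aps <- call_aps(comparisons, fc_cutoff, alpha)
  out <- data.frame(
    protein_group_id = comparisons$protein_group_id,
    contrast = comparisons$contrast,
    log2fc = comparisons$log2fc,
    neg_log10_p = -log10(pmax(comparisons$p_value, 1e-300)),
    is_ap = comparisons$protein_group_id %in% ap_ids(aps),
    stringsAsFactors = FALSE)
  if (!is.null(tsv)) write_quant_table(out, tsv)
  if (!is.null(fig)) {
    png(fig, width = 900, height = 750)
    ok <- is.finite(out$log2fc) & is.finite(out$neg_log10_p)
    plot(out$log2fc[ok], out$neg_log10_p[ok],
         col = ifelse(out$is_ap[ok], "firebrick", "grey60"), pch = 16,
         cex = 0.6, xlab = "log2 fold change", ylab = "-log10 p",
         main = paste("Volcano:", out$contrast[1]))
    abline(v = c(-log2(fc_cutoff), log2(fc_cutoff)), lty = 2)
    abline(h = -log10(alpha), lty = 2)
    dev.off()
  }
  if (is.null(tsv) && is.null(fig)) out else invisible(out)
}
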