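#' Run the full altered-protein discovery pipeline on one dataset
#'
#' Chains, per tissue: normalization, outlier-peptide removal, ion-current
#' aggregation, case-versus-control comparisons, the experimental null,
#' the FADR grid, fold-change cutoff selection (unless `fc_cutoff` is
#' fixed), AP calling, fold-of-significance classification of the AP union,
#' and the TSm/TM-vs-TSm/TS validation.  Across tissues it adds the ratio
#' matrix, its PCA, pairwise R-squared and the AP-union overlap.
#'
#' @param peptides Peptide-level quantification table.
#' @param ann Sample annotation.
#' @param contrasts Case groups compared against `control`.
#' @param control Control group label.
#' @param fc_thresholds FADR grid thresholds.
#' @param alpha p-value cutoff.
#' @param fc_cutoff Fixed fold-change cutoff; `NULL` (default) selects one
#'   from the FADR grid via [select_cutoff()].
#' @param n_splits Experimental-null splits.
#' @param seed Seed for the experimental-null partitions.
#' @param min_corr,min_peptides_for_test Outlier-removal parameters.
#' @param classify_method Passed to [classify_aps()].
#' @param tau Margin for the category rule.
#' @return List with one entry per tissue (`norm_factors`, `outlier_report`,
#'   `proteins`, `dropped`, `comparisons`, `nulls`, `grid`, `cutoff`,
#'   `aps`, `ap_union`, `z`, `classes`, `validation`) plus `cross_tissue`
#'   (`ratio_matrix`, `pca`, `r2`, `ap_overlap`) when several tissues are
#'   present.
#' @export
run_ap_pipeline <- function(peptides, ann,
                            contrasts = c("TM", "TS", "TSm"),
                            control = "SH",
                            fc_thresholds = c(1.2, 1.3, 1.4, 1.5, 2),
                            alpha = 0.05, fc_cutoff = NULL,
                            n_splits = 20, seed = 1L,
                            min_corr = 0.5, min_peptides_for_test = 4,
                            classify_method = "cluster", tau = 0.5) {
  check_annotation(ann)
  tissues <- unique(ann$tissue)
  res <- list()
  for (t in tissues) {
    a <- ann[ann$tissue == t, , drop = FALSE]
    cols <- c(intersect(names(peptides), .meta_cols), a$sample_id)
    pep <- peptides[, intersect(cols, names(peptides)), drop = FALSE]
    norm <- normalize_intensities(pep)
    filt <- remove_outlier_peptides(norm$peptides, min_corr = min_corr,
                                    min_peptides_for_test =
                                      min_peptides_for_test)
    agg <- aggregate_to_protein(filt$peptides,
                                removal_report = filt$report)
    prot <- agg$proteins

    cmp <- lapply(contrasts, function(g) {
      compare_groups(prot, a, case = g, control = control, tissue = t)
    })
    names(cmp) <- contrasts
    nulls <- experimental_null(prot, a, control = control, tissue = t,
                               n_splits = n_splits, seed = seed)
    grid <- do.call(rbind, lapply(cmp, fadr_grid, nulls = nulls,
                                  fc_thresholds = fc_thresholds,
                                  alpha = alpha))
    class(grid) <- c("fadr_grid", "data.frame")
    cut <- select_cutoff(grid)
    fc <- if (is.null(fc_cutoff)) cut$fc_cutoff else fc_cutoff
    aps <- lapply(cmp, call_aps, fc_cutoff = fc, alpha = alpha)
    union_ids <- do.call(ap_union, unname(aps))

    # classification needs a testable value in every contrast
    all_cmp <- do.call(rbind, cmp)
    testable_all <- Reduce(intersect, lapply(cmp, function(x) {
      x$protein_group_id[x$testable & !is.na(x$p_value)]
    }))
    zids <- intersect(union_ids, testable_all)
    if (length(zids) >= 3L) {
      z <- fold_of_significance(all_cmp, proteins = zids,
                                contrasts = paste0(contrasts, "/", control))
      classes <- classify_aps(z, method = classify_method, tau = tau)
      validation <- validate_classification(classes, prot, a, tissue = t)
    } else {
      z <- NULL; classes <- NULL; validation <- NULL
    }
    res[[t]] <- list(norm_factors = norm$factors,
                     outlier_report = filt$report,
                     proteins = prot, dropped = agg$dropped,
                     comparisons = cmp, nulls = nulls, grid = grid,
                     cutoff = cut, fc_cutoff = fc, aps = aps,
                     ap_union = union_ids, z = z, classes = classes,
                     validation = validation)
  }
  if (length(tissues) > 1L) {
    tables <- lapply(res, `[[`, "proteins")
    rm_ <- build_ratio_matrix(tables, ann, contrasts = contrasts,
                              control = control)
    cross <- list(ratio_matrix = rm_, pca = pca_of_ratios(rm_),
                  r2 = pairwise_r2(rm_))
    # overlap of the per-tissue AP unions (pseudo ap_sets over the union)
    mk_union_set <- function(r, label) {
      mem <- do.call(rbind, lapply(r$aps, function(s) s$members))
      mem <- mem[!duplicated(mem$protein_group_id), , drop = FALSE]
      structure(list(contrast = label, fc_cutoff = r$fc_cutoff,
                     alpha = alpha, members = mem), class = "ap_set")
    }
    u <- lapply(tissues, function(t) mk_union_set(res[[t]], t))
    if (length(u) == 2L) cross$ap_overlap <- ap_overlap(u[[1]], u[[2]])
    res$cross_tissue <- cross
  }
  res
}
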