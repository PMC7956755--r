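#' Dataset-wide median normalization of a peptide table
#'
#' Computes one multiplicative factor per sample so that every sample's
#' median log2 intensity - taken over peptides present in all samples -
#' equals the grand center (the mean of the per-sample medians, so the
#' factors have geometric mean exactly 1).  If no peptide is complete
#' across samples, per-sample medians over present values are used instead.
#' Missing cells are preserved.
#'
#' Because the grand center is estimated from the data, rescaling one
#' sample by `c` moves the normalized table by the single global factor
#' `c^(1/n)`; all between-sample ratios - and hence every downstream fold
#' change and test statistic - are exactly invariant.
#'
#' @param peptides Peptide-level quantification data frame.
#' @return List with `peptides` (normalized table) and `factors` (data frame
#'   `sample_id`, `factor`; attribute `reference` names the statistic used).
#' @export
#' @examples
#' tab <- data.frame(peptide_id = "p1", protein_group_id = "P1",
#'                   s1 = 100, s2 = 400)
#' normalize_intensities(tab)$factors
normalize_intensities <- function(peptides) {
  m <- intensity_matrix(peptides)
  if (ncol(m) < 2L) stop("normalization needs >= 2 samples")
  present <- colSums(!is.na(m))
  if (any(present == 0L)) {
    stop("sample(s) with no present intensities: ",
         paste(colnames(m)[present == 0L], collapse = ", "))
  }
  complete <- rowSums(is.na(m)) == 0L
  ref <- "median_log2_complete_peptides"
  if (any(complete)) {
    med <- apply(log2(m[complete, , drop = FALSE]), 2L, median)
  } else {
    med <- apply(log2(m), 2L, median, na.rm = TRUE)
    ref <- "median_log2_present_peptides"
  }
  target <- mean(med)
  f <- 2^(target - med)
  out <- set_intensities(peptides, sweep(m, 2L, f, `*`))
  factors <- data.frame(sample_id = colnames(m), factor = unname(f),
                        stringsAsFactors = FALSE)
  attr(factors, "reference") <- ref
  list(peptides = out, factors = factors)
}

#' Remove outlier peptides by leave-one-out profile correlation
#'
#' For each protein with at least `min_peptides_for_test` peptides, every
#' peptide's log2 profile across samples is correlated (Pearson,
#' pairwise-complete) with the per-sample median profile of the protein's
#' *other* peptides, computed on row-centered log2 values so that
#' peptide-specific ionization offsets cancel even when peptides have
#' missing cells.  Peptides with correlation below `min_corr` are
#' removed, except that a protein is never reduced below 2 peptides (the
#' highest-correlation peptides are kept).  Proteins with fewer than
#' `min_peptides_for_test` peptides pass through untouched.  Peptides whose
#' correlation is undefined (constant profile, too few shared samples) are
#' kept.
#'
#' @param peptides Normalized peptide table.
#' @param min_corr Correlation threshold below which a peptide is discordant.
#' @param min_peptides_for_test Minimum peptide count for a protein to be
#'   screened at all.
#' @return List with `peptides` (filtered table) and `report` (one row per
#'   screened peptide: `peptide_id`, `protein_group_id`, `correlation`,
#'   `removed`).
#' @export
remove_outlier_peptides <- function(peptides, min_corr = 0.5,
                                    min_peptides_for_test = 4) {
  m <- intensity_matrix(peptides)
  l <- log2(m)
  # center rows so the reference profile is invariant to which peptides
  # (with their very different ionization efficiencies) are present
  lc <- l - apply(l, 1L, median, na.rm = TRUE)
  idx <- split(seq_len(nrow(peptides)), peptides$protein_group_id)
  rep_rows <- list()
  drop_rows <- integer()
  for (pid in names(idx)) {
    rows <- idx[[pid]]
    if (length(rows) < min_peptides_for_test) next
    r <- vapply(seq_along(rows), function(i) {
      prof <- apply(lc[rows[-i], , drop = FALSE], 2L, median, na.rm = TRUE)
      suppressWarnings(cor(l[rows[i], ], prof,
                           use = "pairwise.complete.obs"))
    }, numeric(1))
    removed <- !is.na(r) & r < min_corr
    if (sum(!removed) < 2L) {
      keep <- head(order(r, decreasing = TRUE, na.last = TRUE), 2L)
      removed <- rep(TRUE, length(rows))
      removed[keep] <- FALSE
    }
    rep_rows[[pid]] <- data.frame(
      peptide_id = peptides$peptide_id[rows], protein_group_id = pid,
      correlation = r, removed = removed, stringsAsFactors = FALSE)
    drop_rows <- c(drop_rows, rows[removed])
  }
  report <- if (length(rep_rows)) {
    out <- do.call(rbind, rep_rows)
    rownames(out) <- NULL
    out
  } else {
    data.frame(peptide_id = character(), protein_group_id = character(),
               correlation = numeric(), removed = logical())
  }
  kept <- peptides[setdiff(seq_len(nrow(peptides)), drop_rows), , drop = FALSE]
  rownames(kept) <- NULL
  list(peptides = kept, report = report)
}

#' Aggregate peptide ion currents to protein-group level
#'
#' Per protein and sample, the aggregated intensity is the sum of the
#' protein's present peptide intensities; a cell is missing only when all
#' peptides are missing in that sample.  Proteins quantified by fewer than
#' 2 peptide rows are dropped and reported, enforcing the two-unique-peptide
#' rule.
#'
#' @param peptides (Filtered) peptide table.
#' @param removal_report Optional report from [remove_outlier_peptides()],
#'   used to fill `n_peptides_removed`.
#' @return List with `proteins` (data frame `protein_group_id`,
#'   `n_peptides_used`, `n_peptides_removed`, one column per sample) and
#'   `dropped` (single-peptide proteins with their peptide counts).
#' @export
aggregate_to_protein <- function(peptides, removal_report = NULL) {
  if (nrow(peptides) == 0L) stop("empty peptide table")
  m <- intensity_matrix(peptides)
  f <- peptides$protein_group_id
  npep <- table(f)
  sums <- rowsum(replace(m, is.na(m), 0), f)
  cnt <- rowsum((!is.na(m)) * 1L, f)
  sums[cnt == 0L] <- NA_real_
  ids <- rownames(sums)
  used <- as.integer(npep[ids])
  removed <- integer(length(ids))
  if (!is.null(removal_report) && nrow(removal_report)) {
    rm_tab <- table(removal_report$protein_group_id[removal_report$removed])
    hit <- ids %in% names(rm_tab)
    removed[hit] <- as.integer(rm_tab[ids[hit]])
  }
  keep <- used >= 2L
  prot <- data.frame(protein_group_id = ids[keep],
                     n_peptides_used = used[keep],
                     n_peptides_removed = removed[keep],
                     stringsAsFactors = FALSE)
  prot <- cbind(prot, as.data.frame(sums[keep, , drop = FALSE]))
  rownames(prot) <- NULL
  dropped <- data.frame(protein_group_id = ids[!keep],
                        n_peptides = used[!keep], stringsAsFactors = FALSE)
  list(proteins = prot, dropped = dropped)
}

#' Intra-group coefficient-of-variation summary at the protein level
#'
#' Per protein and replicate group, CV = sd/mean of present intensities
#' (sample sd, n-1 denominator; at least two present values required).
#' Biological groups are the (tissue, group) cells of the design; technical
#' groups are replicate pairs sharing a `pair_id`.  Returns the median CV
#' per group, split by replicate kind.
#'
#' @param proteins Protein-level quantification table.
#' @param ann Sample annotation.
#' @return Data frame `tissue`, `group`, `replicate_kind`, `n_proteins`,
#'   `median_cv`, with attribute `per_protein` (long per-protein CVs).
#' @export
cv_summary <- function(proteins, ann) {
  check_annotation(ann)
  m <- intensity_matrix(proteins)
  ann <- ann[ann$sample_id %in% colnames(m), , drop = FALSE]
  units <- list()
  for (t in unique(ann$tissue)) {
    sub <- ann[ann$tissue == t, , drop = FALSE]
    bio <- sub[sub$replicate_kind == "biological", , drop = FALSE]
    for (g in unique(bio$group)) {
      units[[paste(t, g, "biological")]] <- list(
        tissue = t, group = g, kind = "biological",
        samples = bio$sample_id[bio$group == g])
    }
    tech <- sub[sub$replicate_kind == "technical", , drop = FALSE]
    if (nrow(tech)) {
      for (p in unique(tech$pair_id)) {
        units[[paste(t, p, "technical")]] <- list(
          tissue = t, group = p, kind = "technical",
          samples = tech$sample_id[tech$pair_id == p])
      }
    }
  }
  rows <- list()
  per_protein <- list()
  for (u in units) {
    if (length(u$samples) < 2L) next
    cvs <- row_cv(m[, u$samples, drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      tissue = u$tissue, group = u$group, replicate_kind = u$kind,
      n_proteins = sum(!is.na(cvs)),
      median_cv = median(cvs, na.rm = TRUE), stringsAsFactors = FALSE)
    per_protein[[length(per_protein) + 1L]] <- data.frame(
      protein_group_id = rownames(m), tissue = u$tissue, group = u$group,
      replicate_kind = u$kind, cv = cvs, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no replicate group with >= 2 samples")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_protein") <- do.call(rbind, per_protein)
  out
}
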