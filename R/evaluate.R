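#' Recall of planted effects among called APs
#'
#' For each non-null planted protein, checks whether it was called an AP in
#' each contrast its pattern affects (sustained: TS and TSm; ma_induced:
#' TM and TSm; ma_unique: TSm).  Recall is the fraction of
#' (protein, affected contrast) pairs recovered; proteins absent from the
#' quantified tables (e.g. dropped by the two-peptide rule) count as
#' missed.
#'
#' @param aps Named list of `ap_set` objects by case group
#'   (`TM`, `TS`, `TSm`).
#' @param truth Truth table from [simulate_dataset()].
#' @return List with `recall` (overall), `by_pattern` (data frame) and `n`
#'   (number of evaluated pairs).
#' @export
ap_recall <- function(aps, truth) {
  affected <- list(sustained = c("TS", "TSm"),
                   ma_induced = c("TM", "TSm"),
                   ma_unique = "TSm")
  rows <- list()
  for (pat in names(affected)) {
    ids <- truth$protein_group_id[truth$pattern == pat]
    if (length(ids) == 0L) next
    for (g in affected[[pat]]) {
      called <- ids %in% ap_ids(aps[[g]])
      rows[[paste(pat, g)]] <- data.frame(
        pattern = pat, contrast = g, n = length(ids),
        n_called = sum(called), recall = mean(called),
        stringsAsFactors = FALSE)
    }
  }
  by_pattern <- do.call(rbind, rows)
  rownames(by_pattern) <- NULL
  list(recall = sum(by_pattern$n_called) / sum(by_pattern$n),
       by_pattern = by_pattern, n = sum(by_pattern$n))
}

#' Category recovery against planted truth
#'
#' Fraction of classified, truly non-null proteins whose assigned category
#' matches their planted pattern.
#'
#' @param classes Classification data frame from [classify_aps()].
#' @param truth Truth table from [simulate_dataset()].
#' @return List with `recovery` (overall, among classified non-null
#'   proteins), `recovery_of_planted` (denominator = all planted non-null
#'   proteins, unclassified counted as missed) and `by_pattern`.
#' @export
category_recovery <- function(classes, truth) {
  tr <- truth[truth$pattern != "null", , drop = FALSE]
  hit <- match(tr$protein_group_id, classes$protein_group_id)
  assigned <- classes$category[hit]
  ok <- !is.na(assigned) & assigned == tr$pattern
  by_pattern <- do.call(rbind, lapply(split(seq_len(nrow(tr)), tr$pattern),
                                      function(idx) {
    data.frame(pattern = tr$pattern[idx[1]], n_planted = length(idx),
               n_classified = sum(!is.na(assigned[idx])),
               n_correct = sum(ok[idx]),
               stringsAsFactors = FALSE)
  }))
  rownames(by_pattern) <- NULL
  list(recovery = sum(ok) / sum(!is.na(assigned)),
       recovery_of_planted = mean(ok),
       by_pattern = by_pattern)
}
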