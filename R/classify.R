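#' Fold-of-significance z-score matrix for altered proteins
#'
#' Per protein and contrast, the raw fold-of-significance score is
#' `log2FC * (-log10 p)` - the fold change weighted by the evidence against
#' the null - with p floored at `p_floor` before the log.  Rows are then
#' standardized (mean 0, sd 1 across the contrasts; sample sd, n-1
#' denominator) unless `standardize = FALSE`; rows with zero spread are
#' flagged and left at 0.  A pure-significance construction,
#' `sign(log2FC) * (-log10 p)`, is available via `score = "signed_logp"`;
#' it discards the fold-change magnitude, which makes it saturate on
#' vanishing but formally significant shifts (e.g. residual normalization
#' offsets under near-zero within-group variance), so the weighted form is
#' the default.
#'
#' @param comparisons Stacked comparison data frame covering all of
#'   `contrasts` (e.g. rbound results of [compare_groups()]).
#' @param proteins Optional character vector restricting the rows (e.g. the
#'   AP union of a tissue); default: all proteins present.
#' @param contrasts Contrast labels, in column order; default
#'   `c("TM/SH", "TS/SH", "TSm/SH")`.
#' @param standardize Row-standardize the raw scores (default TRUE).
#' @param p_floor Lower bound applied to p-values before `-log10`.
#' @param score Score construction, `"fc_weighted"` (default) or
#'   `"signed_logp"`.
#' @return Numeric matrix (rows = proteins, columns = contrasts) with
#'   attributes `raw` (unstandardized scores), `zero_spread` (logical per
#'   row) and `standardized`.
#' @export
fold_of_significance <- function(comparisons, proteins = NULL,
                                 contrasts = c("TM/SH", "TS/SH", "TSm/SH"),
                                 standardize = TRUE, p_floor = 1e-15,
                                 score = c("fc_weighted", "signed_logp")) {
  score <- match.arg(score)
  cmp <- comparisons[comparisons$contrast %in% contrasts, , drop = FALSE]
  cmp <- cmp[cmp$testable & !is.na(cmp$p_value), , drop = FALSE]
  if (is.null(proteins)) {
    proteins <- sort(unique(cmp$protein_group_id))
  }
  raw <- matrix(NA_real_, length(proteins), length(contrasts),
                dimnames = list(proteins, contrasts))
  for (ct in contrasts) {
    sub <- cmp[cmp$contrast == ct, , drop = FALSE]
    idx <- match(proteins, sub$protein_group_id)
    lp <- -log10(pmax(sub$p_value[idx], p_floor))
    raw[, ct] <- if (score == "signed_logp") {
      sign(sub$log2fc[idx]) * lp
    } else {
      sub$log2fc[idx] * lp
    }
  }
  bad <- rowSums(is.na(raw)) > 0L
  if (any(bad)) {
    stop("protein(s) lacking a testable value in every contrast: ",
         paste(head(proteins[bad], 10L), collapse = ", "),
         if (sum(bad) > 10L) sprintf(" (and %d more)", sum(bad) - 10L))
  }
  zero_spread <- apply(raw, 1L, sd) < 1e-12
  if (standardize) {
    mu <- rowMeans(raw)
    s <- apply(raw, 1L, sd)
    z <- (raw - mu) / s
    z[zero_spread, ] <- 0
  } else {
    z <- raw
  }
  attr(z, "raw") <- raw
  attr(z, "zero_spread") <- zero_spread
  attr(z, "standardized") <- standardize
  z
}

# distance-based category rule for one z row (columns TM, TS, TSm)
rule_category <- function(z, tau, tau_prime) {
  d_tm <- abs(z[3L] - z[1L])
  d_ts <- abs(z[3L] - z[2L])
  if (d_tm < d_ts - tau) {
    cat <- "ma_induced"; amb <- FALSE
  } else if (d_ts < d_tm - tau) {
    cat <- "sustained"; amb <- FALSE
  } else if (min(d_tm, d_ts) >= tau_prime) {
    cat <- "ma_unique"; amb <- FALSE
  } else {
    cat <- if (d_tm < d_ts) "ma_induced" else "sustained"
    amb <- TRUE
  }
  list(category = cat, d_tm = unname(d_tm), d_ts = unname(d_ts),
       ambiguous = amb)
}

#' Classify altered proteins into sustained / MA-induced / MA-unique
#'
#' Categories describe how the treated severe-injury group (TSm) relates to
#' the untreated groups in fold-of-significance space: `sustained` when TSm
#' tracks TS (the alteration persists under treatment), `ma_induced` when
#' TSm tracks TM (treatment normalizes the severe-injury change towards the
#' mild pattern), `ma_unique` when TSm resembles neither.
#'
#' With `method = "rule"` each protein is assigned directly from its z row
#' via the distances `d_TM = |z_TSm - z_TM|` and `d_TS = |z_TSm - z_TS|`
#' with margin `tau`: `ma_induced` if `d_TM < d_TS - tau`, `sustained` if
#' `d_TS < d_TM - tau`, `ma_unique` if both distances are at least
#' `tau_prime`; remaining ambiguous rows go to the nearer neighbor's
#' category with an `ambiguous` flag.
#'
#' With `method = "cluster"` (default) the rows are clustered by
#' agglomerative hierarchical clustering (Ward linkage, Euclidean distance)
#' and the tree is cut at the smallest `k <= k_max` for which every cluster
#' is label-pure (all members' rule labels match their cluster centroid's
#' rule label); each protein then inherits its cluster centroid's category.
#'
#' @param z Z-score matrix from [fold_of_significance()].
#' @param method `"cluster"` or `"rule"`.
#' @param k_max Largest tree cut considered (default 8).
#' @param tau Margin in z units for the labeling rule (default 0.5).
#' @param tau_prime Minimum distance for `ma_unique` (default `tau`).
#' @param seed Unused by the deterministic methods; kept for interface
#'   stability.
#' @return Data frame `protein_group_id`, `category`, `cluster` (NA for the
#'   rule method), `d_tm`, `d_ts`, `ambiguous`.
#' @export
classify_aps <- function(z, method = c("cluster", "rule"), k_max = 8,
                         tau = 0.5, tau_prime = tau, seed = 1L) {
  method <- match.arg(method)
  if (nrow(z) < 3L) stop("classification needs >= 3 APs, got ", nrow(z))
  rules <- lapply(seq_len(nrow(z)), function(i) {
    rule_category(z[i, ], tau, tau_prime)
  })
  out <- data.frame(
    protein_group_id = rownames(z),
    category = vapply(rules, `[[`, character(1), "category"),
    cluster = NA_integer_,
    d_tm = vapply(rules, `[[`, numeric(1), "d_tm"),
    d_ts = vapply(rules, `[[`, numeric(1), "d_ts"),
    ambiguous = vapply(rules, `[[`, logical(1), "ambiguous"),
    stringsAsFactors = FALSE)
  if (method == "rule") return(out)

  hc <- hclust(dist(z), method = "ward.D2")
  best <- NULL
  for (k in seq_len(min(k_max, nrow(z)))) {
    cl <- cutree(hc, k = k)
    cent_lab <- vapply(split(seq_len(nrow(z)), cl), function(idx) {
      cent <- colMeans(z[idx, , drop = FALSE])
      rule_category(cent, tau, tau_prime)$category
    }, character(1))
    assigned <- cent_lab[as.character(cl)]
    pure <- all(assigned == out$category)
    best <- list(cluster = cl, category = unname(assigned))
    if (pure) break
  }
  out$cluster <- unname(best$cluster)
  out$category <- best$category
  out
}

#' Validate AP categories with the TSm/TM versus TSm/TS ratio pattern
#'
#' Retrospective check of the classification: sustained APs (TSm tracks TS)
#' should show larger |log2(TSm/TM)| than |log2(TSm/TS)|, MA-induced APs
#' (TSm tracks TM) the reverse; MA-unique APs carry no dominance
#' requirement.  Ratios are computed from arithmetic group means of present
#' intensities.  Categories with no members are skipped with a note; the
#' dominance test is reported not-applicable when both mean magnitudes are
#' negligible (below 0.1 log2 units, an all-null situation).
#'
#' @param classes Classification data frame from [classify_aps()].
#' @param proteins Protein-level quantification table.
#' @param ann Sample annotation.
#' @param tissue Optional tissue restriction.
#' @return List with `summary` (per category: member count, mean
#'   |log2(TSm/TM)|, mean |log2(TSm/TS)|, `dominant` dimension, `applicable`,
#'   `pass`) and `scatter` (per AP: x = log2(TSm/TM), y = log2(TSm/TS),
#'   category) for plotting.
#' @export
validate_classification <- function(classes, proteins, ann, tissue = NULL) {
  if (nrow(classes) == 0L) stop("empty classification")
  m <- intensity_matrix(proteins)
  gm <- function(g) {
    sel <- intersect(group_samples(ann, g, tissue), colnames(m))
    rowMeans(m[, sel, drop = FALSE], na.rm = TRUE)
  }
  mtm <- gm("TM"); mts <- gm("TS"); mtsm <- gm("TSm")
  ids <- intersect(classes$protein_group_id, rownames(m))
  x <- log2(mtsm[ids] / mtm[ids])
  y <- log2(mtsm[ids] / mts[ids])
  scatter <- data.frame(protein_group_id = ids, x = unname(x), y = unname(y),
                        category = classes$category[
                          match(ids, classes$protein_group_id)],
                        stringsAsFactors = FALSE)
  cats <- c("sustained", "ma_induced", "ma_unique")
  rows <- lapply(cats, function(cc) {
    sub <- scatter[scatter$category == cc, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(data.frame(category = cc, n = 0L,
                        mean_abs_log2_tsm_tm = NA_real_,
                        mean_abs_log2_tsm_ts = NA_real_,
                        dominant = "none (no members)",
                        applicable = FALSE, pass = NA))
    }
    m1 <- mean(abs(sub$x), na.rm = TRUE)  # TSm/TM magnitude
    m2 <- mean(abs(sub$y), na.rm = TRUE)  # TSm/TS magnitude
    applicable <- max(m1, m2) >= 0.1
    dominant <- if (!applicable) "none (ratios ~ 0)" else
      if (m1 > m2) "TSm/TM" else "TSm/TS"
    pass <- if (!applicable) NA else switch(
      cc,
      sustained = m1 > m2,
      ma_induced = m2 > m1,
      ma_unique = TRUE)
    data.frame(category = cc, n = nrow(sub), mean_abs_log2_tsm_tm = m1,
               mean_abs_log2_tsm_ts = m2, dominant = dominant,
               applicable = applicable, pass = pass)
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, scatter = scatter)
}
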