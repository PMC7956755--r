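#' Case-versus-control comparison of protein intensities
#'
#' Per protein: fold change = arithmetic mean of case intensities divided by
#' arithmetic mean of control intensities (present values only), and a
#' two-sided equal-variance Student t-test on log2 intensities.  Proteins
#' with fewer than `min_present` present values in either group are marked
#' untestable (`testable = FALSE`, p-value `NA`) rather than dropped.
#' Zero-variance cases are flagged `degenerate` and get p = 1 when the
#' group means coincide, p = 0 otherwise.
#'
#' @param proteins Protein-level quantification table.
#' @param ann Sample annotation.
#' @param case,control Group labels (e.g. `"TM"`, `"SH"`).
#' @param tissue Optional tissue restriction.
#' @param min_present Minimum present values per group for a valid test.
#' @return Data frame `protein_group_id`, `contrast`, `fc`, `log2fc`,
#'   `p_value`, `n_case`, `n_control`, `testable`, `degenerate`.
#' @export
compare_groups <- function(proteins, ann, case, control, tissue = NULL,
                           min_present = 3) {
  check_annotation(ann)
  cs <- group_samples(ann, case, tissue)
  ct <- group_samples(ann, control, tissue)
  m <- intensity_matrix(proteins)
  cs <- intersect(cs, colnames(m))
  ct <- intersect(ct, colnames(m))
  if (length(cs) == 0L || length(ct) == 0L) {
    stop("no overlap between annotation samples and table columns for ",
         if (length(cs) == 0L) case else control)
  }
  if (length(cs) < 2L || length(ct) < 2L) {
    stop("both groups need >= 2 samples")
  }
  res <- row_t_test(m[, cs, drop = FALSE], m[, ct, drop = FALSE],
                    min_present = min_present)
  cbind(data.frame(protein_group_id = rownames(m),
                   contrast = paste0(case, "/", control),
                   stringsAsFactors = FALSE),
        res)
}

# vectorized equal-variance two-sample Student t on log2 values, FC on the
# linear scale; the workhorse behind compare_groups and experimental_null
row_t_test <- function(mc, mk, min_present = 3) {
  n1 <- rowSums(!is.na(mc))
  n2 <- rowSums(!is.na(mk))
  mean1 <- rowMeans(mc, na.rm = TRUE)
  mean2 <- rowMeans(mk, na.rm = TRUE)
  fc <- mean1 / mean2
  l1 <- log2(mc)
  l2 <- log2(mk)
  mu1 <- rowMeans(l1, na.rm = TRUE)
  mu2 <- rowMeans(l2, na.rm = TRUE)
  ss1 <- rowSums((l1 - mu1)^2, na.rm = TRUE)
  ss2 <- rowSums((l2 - mu2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2L
  vp <- (ss1 + ss2) / pmax(df, 1L)
  se <- sqrt(vp * (1 / n1 + 1 / n2))
  tstat <- (mu1 - mu2) / se
  p <- rep(NA_real_, length(tstat))
  ok <- df >= 1L & is.finite(tstat)
  p[ok] <- 2 * pt(-abs(tstat[ok]), df[ok])
  degenerate <- vp < 1e-12
  p[degenerate] <- ifelse(abs(mu1 - mu2)[degenerate] < 1e-9, 1, 0)
  testable <- n1 >= min_present & n2 >= min_present
  p[!testable] <- NA_real_
  fc[n1 == 0L | n2 == 0L] <- NA_real_
  data.frame(fc = fc, log2fc = log2(fc), p_value = p,
             n_case = n1, n_control = n2,
             testable = testable, degenerate = degenerate & testable)
}

#' Experimental-null comparisons from splits of the control group
#'
#' Builds the null distribution of the dataset by repeatedly splitting the
#' biological control group into two balanced halves (sizes floor(n/2) and
#' ceiling(n/2)) and running [compare_groups()]-style tests between the
#' halves.  Distinct partitions are sampled without replacement when the
#' partition space allows; the same seed always yields the same splits.
#'
#' @param proteins Protein-level quantification table.
#' @param ann Sample annotation.
#' @param control Control group label (default `"SH"`).
#' @param tissue Optional tissue restriction.
#' @param n_splits Number of control-control splits (default 20).
#' @param seed Integer seed for partition sampling.
#' @param min_present Passed to the per-split test.
#' @return List of comparison data frames (one per split, contrasts labeled
#'   `EN01`, `EN02`, ...), with attribute `splits` holding the half-A sample
#'   ids of each partition.
#' @export
experimental_null <- function(proteins, ann, control = "SH", tissue = NULL,
                              n_splits = 20, seed = 1L, min_present = 3) {
  check_annotation(ann)
  s <- group_samples(ann, control, tissue)
  m <- intensity_matrix(proteins)
  s <- intersect(s, colnames(m))
  if (length(s) < 4L) {
    stop("control group needs >= 4 samples for an experimental null, got ",
         length(s))
  }
  halves <- sample_partitions(s, n_splits, seed)
  out <- lapply(seq_along(halves), function(i) {
    a <- halves[[i]]
    b <- setdiff(s, a)
    res <- row_t_test(m[, a, drop = FALSE], m[, b, drop = FALSE],
                      min_present = min_present)
    cbind(data.frame(protein_group_id = rownames(m),
                     contrast = sprintf("EN%02d", i),
                     stringsAsFactors = FALSE),
          res)
  })
  attr(out, "splits") <- halves
  out
}

# seeded balanced partitions of `s`, distinct while the space allows
sample_partitions <- function(s, n_splits, seed) {
  set.seed(seed)
  n <- length(s)
  h <- n %/% 2L
  space <- choose(n, h) / (if (n %% 2L == 0L) 2 else 1)
  if (choose(n, h) <= 1e5) {
    cmb <- combn(s, h, simplify = FALSE)
    if (n %% 2L == 0L) {
      cmb <- Filter(function(x) s[1] %in% x, cmb)  # drop mirror duplicates
    }
    if (n_splits <= length(cmb)) {
      cmb[sample.int(length(cmb), n_splits)]
    } else {
      c(cmb[sample.int(length(cmb))],
        cmb[sample.int(length(cmb), n_splits - length(cmb), replace = TRUE)])
    }
  } else {
    seen <- character()
    halves <- list()
    while (length(halves) < n_splits) {
      a <- sort(sample(s, h))
      key <- paste(a, collapse = "|")
      if (key %in% seen && length(seen) < space) next
      seen <- c(seen, key)
      halves[[length(halves) + 1L]] <- a
    }
    halves
  }
}

#' FADR grid over fold-change thresholds
#'
#' For one case-control comparison and a set of experimental-null
#' comparisons, counts altered proteins (p < `alpha` and FC beyond the
#' threshold in either direction) at each fold-change threshold and forms
#' the false altered-protein discovery rate FADR = mean null AP count /
#' case AP count.  Untestable proteins are excluded from both counts.
#' A 0/0 cell gives FADR 0; a positive null count over a zero case count
#' gives `Inf`.
#'
#' @param case Comparison data frame from [compare_groups()].
#' @param nulls List of null comparison data frames from
#'   [experimental_null()].
#' @param fc_thresholds Fold-change thresholds (> 1); default
#'   `c(1.2, 1.3, 1.4, 1.5, 2)`.
#' @param alpha Significance level (default 0.05).
#' @return Data frame of class `fadr_grid`: `fc_threshold`, `contrast`,
#'   `n_case_aps`, `n_null_aps`, `fadr`, `alpha`.
#' @export
fadr_grid <- function(case, nulls, fc_thresholds = c(1.2, 1.3, 1.4, 1.5, 2),
                      alpha = 0.05) {
  if (is.null(case) || nrow(case) == 0L) stop("empty case comparison list")
  if (any(fc_thresholds <= 1)) stop("fc_thresholds must all be > 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  count_aps <- function(cmp, t) {
    sum(cmp$testable & !is.na(cmp$p_value) & cmp$p_value < alpha &
          (cmp$fc >= t | cmp$fc <= 1 / t), na.rm = TRUE)
  }
  rows <- lapply(fc_thresholds, function(t) {
    nc <- count_aps(case, t)
    nn <- mean(vapply(nulls, count_aps, numeric(1), t = t))
    fadr <- if (nc > 0L) nn / nc else if (nn == 0) 0 else Inf
    data.frame(fc_threshold = t, contrast = case$contrast[1],
               n_case_aps = nc, n_null_aps = nn, fadr = fadr, alpha = alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fadr_grid", "data.frame")
  out
}

#' Select the fold-change cutoff from a FADR grid
#'
#' Returns the smallest threshold whose FADR (worst case over the contrasts
#' in the grid) is at or below `fadr_tolerance`.  A larger qualifying
#' threshold is adopted only when its additional FADR reduction exceeds the
#' fraction of APs it gives up, and it retains at least `min_retention` of
#' the AP count - so trading most of the discoveries for a marginal FADR
#' gain is refused.  If no threshold qualifies, the largest threshold is
#' returned with a warning flag.
#'
#' @param grid A `fadr_grid` (rows for several contrasts may be rbound).
#' @param fadr_tolerance Maximum acceptable FADR (default 0.05).
#' @param min_retention Minimum acceptable AP-count fraction relative to the
#'   smallest qualifying threshold (default 0.5).
#' @return List of class `cutoff_selection`: `fc_cutoff`, `qualified`,
#'   `warning`, `rationale` (per-threshold summary) and the input `grid`.
#' @export
select_cutoff <- function(grid, fadr_tolerance = 0.05, min_retention = 0.5) {
  if (is.null(grid) || nrow(grid) == 0L) stop("empty FADR grid")
  ts <- sort(unique(grid$fc_threshold))
  summ <- do.call(rbind, lapply(ts, function(t) {
    g <- grid[grid$fc_threshold == t, , drop = FALSE]
    data.frame(fc_threshold = t, worst_fadr = max(g$fadr),
               total_case_aps = sum(g$n_case_aps))
  }))
  summ$qualifies <- is.finite(summ$worst_fadr) &
    summ$worst_fadr <= fadr_tolerance
  if (!any(summ$qualifies)) {
    return(structure(list(fc_cutoff = max(ts), qualified = FALSE,
                          warning = TRUE, rationale = summ, grid = grid),
                     class = "cutoff_selection"))
  }
  qual <- summ[summ$qualifies, , drop = FALSE]
  sel <- qual[1L, ]
  base_aps <- sel$total_case_aps
  if (nrow(qual) > 1L) {
    for (i in 2:nrow(qual)) {
      retention <- if (base_aps > 0) qual$total_case_aps[i] / base_aps else 1
      gain <- sel$worst_fadr - qual$worst_fadr[i]
      if (retention >= min_retention && gain > (1 - retention)) {
        sel <- qual[i, ]
      }
    }
  }
  structure(list(fc_cutoff = sel$fc_threshold, qualified = TRUE,
                 warning = FALSE, rationale = summ, grid = grid),
            class = "cutoff_selection")
}

#' @export
print.cutoff_selection <- function(x, ...) {
  cat("selected FC cutoff:", x$fc_cutoff,
      if (x$warning) "(no threshold met the FADR tolerance)" else "", "\n")
  print(x$rationale, row.names = FALSE)
  invisible(x)
}

#' Call altered proteins at a fold-change / p-value cutoff
#'
#' Members satisfy p < `alpha` and FC >= `fc_cutoff` (direction `up`) or
#' FC <= 1/`fc_cutoff` (direction `down`); untestable proteins never
#' qualify.
#'
#' @param comparisons Comparison data frame from [compare_groups()].
#' @param fc_cutoff Fold-change cutoff (> 1), e.g. 1.4.
#' @param alpha p-value cutoff (default 0.05).
#' @return Object of class `ap_set`: list with `contrast`, `fc_cutoff`,
#'   `alpha` and `members` (data frame `protein_group_id`, `direction`,
#'   `fc`, `log2fc`, `p_value`).
#' @export
call_aps <- function(comparisons, fc_cutoff, alpha = 0.05) {
  if (fc_cutoff <= 1) stop("fc_cutoff must be > 1")
  cmp <- comparisons
  if (nrow(cmp) == 0L) {
    members <- data.frame(protein_group_id = character(),
                          direction = character(), fc = numeric(),
                          log2fc = numeric(), p_value = numeric())
  } else {
    hit <- cmp$testable & !is.na(cmp$p_value) & cmp$p_value < alpha &
      (cmp$fc >= fc_cutoff | cmp$fc <= 1 / fc_cutoff)
    hit[is.na(hit)] <- FALSE
    members <- data.frame(
      protein_group_id = cmp$protein_group_id[hit],
      direction = ifelse(cmp$fc[hit] >= fc_cutoff, "up", "down"),
      fc = cmp$fc[hit], log2fc = cmp$log2fc[hit],
      p_value = cmp$p_value[hit], stringsAsFactors = FALSE)
  }
  structure(list(contrast = if (nrow(cmp)) cmp$contrast[1] else NA_character_,
                 fc_cutoff = fc_cutoff, alpha = alpha, members = members),
            class = "ap_set")
}

#' @export
print.ap_set <- function(x, ...) {
  cat(sprintf("ap_set %s: %d APs (FC >= %g or <= %.3g, p < %g)\n",
              x$contrast, nrow(x$members), x$fc_cutoff, 1 / x$fc_cutoff,
              x$alpha))
  invisible(x)
}

#' Member protein ids of an AP set
#' @param x An `ap_set`.
#' @return Character vector of protein group ids.
#' @export
ap_ids <- function(x) {
  stopifnot(inherits(x, "ap_set"))
  x$members$protein_group_id
}

#' Union of AP sets across contrasts
#'
#' Protein ids altered in at least one of the given sets (e.g. the union
#' over the TM, TS and TSm contrasts within a tissue).
#'
#' @param ... `ap_set` objects.
#' @return Sorted character vector of protein group ids.
#' @export
ap_union <- function(...) {
  sets <- list(...)
  sort(unique(unlist(lapply(sets, ap_ids))))
}
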