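#' Simulate a peptide-level quantification dataset with ground truth
#'
#' Generates a peptide x sample intensity table, its sample annotation and a
#' per-protein truth table under the generative model:
#'
#' * protein baseline log2 abundance ~ Normal(`baseline_log2_mean`,
#'   `baseline_log2_sd`), spanning ~6 orders of magnitude;
#' * per-sample protein log2 abundance = baseline + planted group effect +
#'   biological noise (per-protein sd chosen so the lognormal CV matches the
#'   protein's drawn biological CV);
#' * peptide intensity = protein abundance x fixed per-peptide ionization
#'   factor x per-sample loading factor x technical noise (CV `tech_cv`);
#' * a fraction `outlier_peptide_rate` of peptides get independent
#'   per-cell corrupting multipliers (discordant quantification);
#' * cells are set missing at a peptide-level rate calibrated so that
#'   post-aggregation protein-level missingness is about `missing_rate`.
#'
#' The generator is fully deterministic for a fixed `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_dataset` with elements `peptides` (data frame
#'   `peptide_id`, `protein_group_id`, one column per sample; `NA` = missing),
#'   `annotation` (`sample_id`, `group`, `tissue`, `replicate_kind`,
#'   `pair_id`), `truth` (`protein_group_id`, `pattern`, `effect_TM`,
#'   `effect_TS`, `effect_TSm`) and `config`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_proteins = 50, n_tissues = 1))
#' dim(sim$peptides)
#' table(sim$truth$pattern)
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be a sim_config object")
  }
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_proteins
  protein_ids <- sprintf("P%05d", seq_len(n))

  truth <- make_truth(config, protein_ids)
  eff <- as.matrix(truth[, c("effect_TM", "effect_TS", "effect_TSm")])
  colnames(eff) <- c("TM", "TS", "TSm")

  # per-protein biological sd on the log2 scale from a heterogeneous CV
  cv <- config$bio_cv * exp(rnorm(n, 0, config$bio_cv_sdlog))
  cv <- pmin(pmax(cv, config$bio_cv * config$bio_cv_range[1]),
             config$bio_cv * config$bio_cv_range[2])
  sd_bio <- cv_to_sdlog2(cv)
  sd_tech <- cv_to_sdlog2(config$tech_cv)
  sd_load <- cv_to_sdlog2(config$loading_cv)

  baseline <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)

  # peptide layout (shared across tissues)
  k <- rtriangle_int(n, config$peptides_per_protein)
  prot_of_pep <- rep(seq_len(n), k)
  pep_within <- sequence(k)
  peptide_ids <- sprintf("%s_pep%02d", protein_ids[prot_of_pep], pep_within)
  npep <- length(peptide_ids)
  ion <- 2^rnorm(npep, 0, config$ionization_sdlog2)
  outlier_pep <- runif(npep) < config$outlier_peptide_rate

  tissues <- tissue_names(config$n_tissues)
  ann <- make_annotation(config, tissues)

  mats <- vector("list", length(tissues))
  for (ti in seq_along(tissues)) {
    a <- ann[ann$tissue == tissues[ti], , drop = FALSE]
    ns <- nrow(a)
    # biological draw per (protein, animal); technical pairs share an animal
    animal <- ifelse(is.na(a$pair_id), a$sample_id,
                     paste0(tissues[ti], "_", a$pair_id))
    uniq <- unique(animal)
    bio <- matrix(rnorm(n * length(uniq)), n, length(uniq)) * sd_bio
    colnames(bio) <- uniq
    g <- as.character(a$group)
    shift <- matrix(0, n, ns)
    for (grp in c("TM", "TS", "TSm")) {
      sel <- which(g == grp)
      if (length(sel)) shift[, sel] <- eff[, grp]
    }
    prot_log2 <- baseline + shift + bio[, animal, drop = FALSE]

    load <- 2^rnorm(ns, 0, sd_load)
    tech <- matrix(rnorm(npep * ns, 0, sd_tech), npep, ns)
    m <- 2^(prot_log2[prot_of_pep, , drop = FALSE] + tech)
    m <- sweep(m, 1L, ion, `*`)
    m <- sweep(m, 2L, load, `*`)
    if (any(outlier_pep)) {
      no <- sum(outlier_pep)
      m[outlier_pep, ] <- m[outlier_pep, , drop = FALSE] *
        2^matrix(rnorm(no * ns, 0, 2), no, ns)
    }
    m <- apply_missingness(m, k, prot_of_pep, config)
    colnames(m) <- a$sample_id
    mats[[ti]] <- m
  }
  intens <- do.call(cbind, mats)

  peptides <- data.frame(peptide_id = peptide_ids,
                         protein_group_id = protein_ids[prot_of_pep],
                         stringsAsFactors = FALSE)
  peptides <- cbind(peptides, as.data.frame(intens))
  # peptides never detected in any sample are not part of a real table
  detected <- rowSums(!is.na(intens)) > 0L
  peptides <- peptides[detected, , drop = FALSE]
  rownames(peptides) <- NULL

  structure(list(peptides = peptides, annotation = ann, truth = truth,
                 config = config),
            class = "sim_dataset")
}

# CV of a lognormal variable -> sd on the log2 scale
cv_to_sdlog2 <- function(cv) sqrt(log1p(cv^2)) / log(2)

# triangular integer distribution on {min..max} peaking at mode
rtriangle_int <- function(n, ppp) {
  lo <- as.integer(ppp[["min"]])
  mo <- as.integer(ppp[["mode"]])
  hi <- as.integer(ppp[["max"]])
  support <- lo:hi
  w <- ifelse(support <= mo, support - lo + 1L, hi - support + 1L)
  sample(support, n, replace = TRUE, prob = w)
}

make_truth <- function(config, protein_ids) {
  n <- config$n_proteins
  n_s <- round(config$frac_sustained * n)
  n_mi <- round(config$frac_ma_induced * n)
  n_mu <- round(config$frac_ma_unique * n)
  n_null <- n - n_s - n_mi - n_mu  # remainder goes to null
  if (n_null < 0) stop("pattern quotas exceed n_proteins")
  pattern <- sample(rep(c("sustained", "ma_induced", "ma_unique", "null"),
                        c(n_s, n_mi, n_mu, n_null)))
  delta <- sample(c(-1, 1), n, replace = TRUE) * config$effect_log2fc
  eff <- matrix(0, n, 3, dimnames = list(NULL, c("TM", "TS", "TSm")))
  s <- pattern == "sustained"
  eff[s, "TS"] <- eff[s, "TSm"] <- delta[s]
  mi <- pattern == "ma_induced"
  eff[mi, "TM"] <- eff[mi, "TSm"] <- delta[mi]
  mu <- pattern == "ma_unique"
  eff[mu, "TSm"] <- delta[mu]
  data.frame(protein_group_id = protein_ids, pattern = pattern,
             effect_TM = eff[, "TM"], effect_TS = eff[, "TS"],
             effect_TSm = eff[, "TSm"], stringsAsFactors = FALSE)
}

make_annotation <- function(config, tissues) {
  gs <- config$group_sizes[c("SH", "TM", "TS", "TSm")]
  out <- list()
  for (t in tissues) {
    sid <- unlist(lapply(names(gs), function(g) {
      sprintf("%s_%s_%02d", t, g, seq_len(gs[[g]]))
    }))
    grp <- rep(names(gs), unlist(gs))
    ann <- data.frame(sample_id = sid, group = grp, tissue = t,
                      replicate_kind = "biological", pair_id = NA_character_,
                      stringsAsFactors = FALSE)
    if (config$n_tech_pairs > 0L) {
      for (j in seq_len(config$n_tech_pairs)) {
        pid <- sprintf("techpair%02d", j)
        tech <- data.frame(
          sample_id = sprintf("%s_SH_%s_%s", t, pid, c("a", "b")),
          group = "SH", tissue = t, replicate_kind = "technical",
          pair_id = pid, stringsAsFactors = FALSE)
        ann <- rbind(ann, tech)
      }
    }
    out[[t]] <- ann
  }
  ann <- do.call(rbind, out)
  rownames(ann) <- NULL
  ann
}

# set peptide cells missing so that expected post-aggregation protein-level
# missingness (all peptides of a protein absent in a sample) hits the target
apply_missingness <- function(m, k, prot_of_pep, config) {
  target <- config$missing_rate
  if (target <= 0) return(m)
  keep <- k >= 2L  # proteins surviving the two-peptide rule
  if (!any(keep)) keep <- rep(TRUE, length(k))
  if (config$missing_mode == "mcar") {
    # uniform cell rate r solving mean(r^k) = target
    r <- uniroot(function(r) mean(r^k[keep]) - target,
                 c(1e-12, 1 - 1e-12))$root
    p <- matrix(r, nrow(m), ncol(m))
  } else {
    # dropout probability logistic in the peptide's typical log2 intensity
    # (low-abundance peptides vanish first, as in real ion-current data),
    # constant within a row so observed profiles stay uncensored; scaled by
    # c to hit the protein-level target mean over proteins of prod_j(p_j)
    lrow <- apply(log2(m), 1L, median)
    w <- stats::plogis(-(lrow - stats::quantile(lrow, 0.05)) / 0.7)
    miss_rate <- function(logc) {
      p <- pmin(exp(logc) * w, 1)
      lp <- rowsum(log(pmax(p, 1e-300)), prot_of_pep)
      mean(exp(lp[keep])) - target
    }
    logc <- uniroot(miss_rate, c(-30, 30), tol = 1e-6)$root
    p <- matrix(pmin(exp(logc) * w, 1), nrow(m), ncol(m))
  }
  m[runif(length(m)) < p] <- NA_real_
  m
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", nrow(x$peptides), "peptides /",
      length(unique(x$peptides$protein_group_id)), "proteins x",
      nrow(x$annotation), "samples in",
      length(unique(x$annotation$tissue)), "tissue(s)\n")
  print(table(x$truth$pattern))
  invisible(x)
}

#' Check a simulated dataset against its configured targets
#'
#' Rolls the peptide table up to protein level (normalization + aggregation,
#' no outlier filtering) and reports the realized biological and technical
#' intra-group CVs, protein-level missingness, and - when `truth` is
#' supplied - the realized mean |log2 fold change| per planted pattern in
#' its affected contrasts, each next to its configured target.
#'
#' @param peptides Peptide table from [simulate_dataset()].
#' @param ann Matching sample annotation.
#' @param config The [sim_config()] used.
#' @param truth Optional truth table; enables the per-pattern effect check.
#' @return Data frame with columns `metric`, `value`, `target`, plus an
#'   attribute `cv_by_group` holding the per-group CV summary.
#' @export
calibration_report <- function(peptides, ann, config, truth = NULL) {
  if (nrow(peptides) == 0L) stop("empty peptide table")
  check_annotation(ann)
  norm <- normalize_intensities(peptides)
  agg <- aggregate_to_protein(norm$peptides)
  prot <- agg$proteins
  cvs <- cv_summary(prot, ann)
  bio <- cvs[cvs$replicate_kind == "biological", , drop = FALSE]
  tech <- cvs[cvs$replicate_kind == "technical", , drop = FALSE]
  m <- intensity_matrix(prot)
  miss <- mean(is.na(m))

  rows <- list(
    data.frame(metric = "median_biological_cv",
               value = stats::median(bio$median_cv), target = config$bio_cv),
    data.frame(metric = "median_technical_cv",
               value = if (nrow(tech)) stats::median(tech$median_cv)
                       else NA_real_,
               target = config$tech_cv),
    data.frame(metric = "protein_missingness", value = miss,
               target = config$missing_rate)
  )

  if (!is.null(truth)) {
    affected <- list(sustained = c("TS", "TSm"),
                     ma_induced = c("TM", "TSm"),
                     ma_unique = "TSm")
    tissue1 <- ann$tissue[1]
    means <- lapply(c("SH", "TM", "TS", "TSm"), function(g) {
      sel <- group_samples(ann, g, tissue = tissue1)
      rowMeans(m[, sel, drop = FALSE], na.rm = TRUE)
    })
    names(means) <- c("SH", "TM", "TS", "TSm")
    for (pat in names(affected)) {
      ids <- truth$protein_group_id[truth$pattern == pat]
      ids <- intersect(ids, rownames(m))
      if (length(ids) == 0L) next
      lfc <- unlist(lapply(affected[[pat]], function(g) {
        abs(log2(means[[g]][ids] / means[["SH"]][ids]))
      }))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = paste0("mean_abs_log2fc_", pat),
        value = mean(lfc, na.rm = TRUE), target = config$effect_log2fc)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cv_by_group") <- cvs
  out
}
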