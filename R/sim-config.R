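#' Configuration for the synthetic peptide-level data generator
#'
#' Builds and validates the parameter set for [simulate_dataset()].  The
#' defaults emulate the study design the pipeline targets: a 4-group rat
#' cohort (sham `SH` n=10, mild injury `TM` n=11, severe injury `TS` n=9,
#' severe injury + methamphetamine `TSm` n=9; 39 animals per tissue) profiled
#' in two brain tissues, with ~6500 protein groups spanning roughly six
#' orders of magnitude of ion intensity, a median intra-group biological CV
#' of 16.7%, technical CV of 5%, and protein-level missingness below 0.5%.
#'
#' Effect patterns are planted per protein as log2 shifts versus `SH`:
#' * `null` - no change in any group;
#' * `sustained` - `TS` and `TSm` share the effect, `TM` unchanged
#'   (alteration tracks severe injury regardless of treatment);
#' * `ma_induced` - `TM` and `TSm` share the effect, `TS` unchanged
#'   (the treated severe brain resembles mild injury);
#' * `ma_unique` - only `TSm` carries the effect (treatment-specific change).
#'
#' Pattern counts are assigned by exact quota (`round(frac * n_proteins)`,
#' remainder to `null`) so truth composition is reproducible.
#'
#' @param n_proteins Number of protein groups.
#' @param peptides_per_protein Named vector `c(min=, mode=, max=)` of the
#'   triangular integer distribution of peptides per protein.  The floor of
#'   1 leaves single-peptide proteins for the downstream >=2-peptide filter
#'   to remove.
#' @param group_sizes Named vector of biological replicates per group; names
#'   must be exactly `SH`, `TM`, `TS`, `TSm`.
#' @param n_tissues Number of tissues (1 or 2 named `cortex`,
#'   `hippocampus`; more get generic names).
#' @param frac_null,frac_sustained,frac_ma_induced,frac_ma_unique Pattern
#'   proportions; must sum to 1.
#' @param effect_log2fc Planted absolute log2 fold change (sign drawn per
#'   protein).
#' @param bio_cv Target median intra-group biological CV (proportion).
#' @param bio_cv_sdlog Spread (lognormal sdlog) of per-protein biological
#'   CVs around `bio_cv`; label-free tissue data show strongly right-skewed
#'   protein-wise CVs, which this reproduces.
#' @param bio_cv_range Length-2 multiplier range truncating per-protein CVs
#'   relative to `bio_cv`.
#' @param tech_cv Technical (per-measurement) CV at the peptide level.
#' @param loading_cv CV of per-sample loading factors (removed later by
#'   normalization).
#' @param missing_rate Target protein-level missingness after aggregation.
#' @param missing_mode `"intensity"` (default; dropout probability logistic
#'   in log2 intensity, so low-abundance cells vanish first as in real
#'   ion-current data) or `"mcar"` (uniform cell rate).  Both are calibrated
#'   so post-aggregation protein-level missingness matches `missing_rate`;
#'   the uniform mode needs a high peptide-cell rate to reach the protein
#'   target, which distorts sum-of-present intensities when a dominant
#'   peptide drops out.
#' @param outlier_peptide_rate Fraction of peptides whose cells receive an
#'   independent corrupting multiplier (quantification outliers).
#' @param baseline_log2_mean,baseline_log2_sd Protein baseline log2
#'   abundance distribution; the default sd of 3 spans ~6 orders of
#'   magnitude across the proteome.
#' @param ionization_sdlog2 Spread (log2 sd) of fixed per-peptide ionization
#'   efficiency factors.
#' @param n_tech_pairs Number of injected technical-replicate pairs per
#'   tissue (same animal re-measured with technical noise only); 0 keeps
#'   the annotation at exactly the biological design.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_dataset()], [calibration_report()]
#' @export
#' @examples
#' cfg <- sim_config(n_proteins = 200, n_tissues = 1, seed = 7)
#' cfg$group_sizes
sim_config <- function(n_proteins = 6500,
                       peptides_per_protein = c(min = 1, mode = 3, max = 8),
                       group_sizes = c(SH = 10, TM = 11, TS = 9, TSm = 9),
                       n_tissues = 2,
                       frac_null = 0.70,
                       frac_sustained = 0.10,
                       frac_ma_induced = 0.10,
                       frac_ma_unique = 0.10,
                       effect_log2fc = 1,
                       bio_cv = 0.167,
                       bio_cv_sdlog = 0.6,
                       bio_cv_range = c(1 / 3, 6),
                       tech_cv = 0.05,
                       loading_cv = 0.10,
                       missing_rate = 0.005,
                       missing_mode = c("intensity", "mcar"),
                       outlier_peptide_rate = 0.02,
                       baseline_log2_mean = 23,
                       baseline_log2_sd = 3,
                       ionization_sdlog2 = 1.5,
                       n_tech_pairs = 0,
                       seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = peptides_per_protein,
    group_sizes = group_sizes,
    n_tissues = as.integer(n_tissues),
    frac_null = frac_null,
    frac_sustained = frac_sustained,
    frac_ma_induced = frac_ma_induced,
    frac_ma_unique = frac_ma_unique,
    effect_log2fc = effect_log2fc,
    bio_cv = bio_cv,
    bio_cv_sdlog = bio_cv_sdlog,
    bio_cv_range = bio_cv_range,
    tech_cv = tech_cv,
    loading_cv = loading_cv,
    missing_rate = missing_rate,
    missing_mode = missing_mode,
    outlier_peptide_rate = outlier_peptide_rate,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    ionization_sdlog2 = ionization_sdlog2,
    n_tech_pairs = as.integer(n_tech_pairs),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid sim_config field '", field, "': ", why, call. = FALSE)
  }
  chk_count <- function(field, x, min = 1L) {
    if (length(x) != 1L || is.na(x) || x < min) {
      bad(field, paste0("must be a single count >= ", min))
    }
  }
  chk_prop <- function(field, x) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      bad(field, "must be a proportion in [0, 1]")
    }
  }
  chk_count("n_proteins", cfg$n_proteins)
  chk_count("n_tissues", cfg$n_tissues)
  chk_count("n_tech_pairs", cfg$n_tech_pairs, min = 0L)
  ppp <- cfg$peptides_per_protein
  if (!all(c("min", "mode", "max") %in% names(ppp))) {
    bad("peptides_per_protein", "needs named elements min, mode, max")
  }
  if (ppp[["min"]] < 1 || ppp[["mode"]] < ppp[["min"]] ||
      ppp[["max"]] < ppp[["mode"]]) {
    bad("peptides_per_protein", "requires 1 <= min <= mode <= max")
  }
  gs <- cfg$group_sizes
  if (!identical(sort(names(gs)), sort(c("SH", "TM", "TS", "TSm")))) {
    bad("group_sizes", "names must be exactly SH, TM, TS, TSm")
  }
  if (any(gs < 1)) bad("group_sizes", "all group sizes must be >= 1")
  for (f in c("frac_null", "frac_sustained", "frac_ma_induced",
              "frac_ma_unique")) {
    chk_prop(f, cfg[[f]])
  }
  fr <- cfg$frac_null + cfg$frac_sustained + cfg$frac_ma_induced +
    cfg$frac_ma_unique
  if (abs(fr - 1) > 1e-9) {
    bad("frac_null", sprintf("pattern fractions sum to %.12f, not 1", fr))
  }
  if (length(cfg$effect_log2fc) != 1L || cfg$effect_log2fc < 0) {
    bad("effect_log2fc", "must be a single nonnegative real")
  }
  for (f in c("bio_cv", "tech_cv", "loading_cv", "missing_rate",
              "outlier_peptide_rate")) {
    chk_prop(f, cfg[[f]])
  }
  if (cfg$bio_cv_sdlog < 0) bad("bio_cv_sdlog", "must be >= 0")
  if (length(cfg$bio_cv_range) != 2L || any(cfg$bio_cv_range <= 0) ||
      diff(cfg$bio_cv_range) < 0) {
    bad("bio_cv_range", "must be two positive multipliers, increasing")
  }
  if (cfg$baseline_log2_sd < 0) bad("baseline_log2_sd", "must be >= 0")
  if (cfg$ionization_sdlog2 < 0) bad("ionization_sdlog2", "must be >= 0")
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_proteins, "proteins,",
      x$n_tissues, "tissue(s),",
      sum(x$group_sizes), "samples/tissue",
      sprintf("(SH=%d TM=%d TS=%d TSm=%d)\n", x$group_sizes[["SH"]],
              x$group_sizes[["TM"]], x$group_sizes[["TS"]],
              x$group_sizes[["TSm"]]))
  cat(sprintf("  patterns: null %.2f / sustained %.2f / ma_induced %.2f / ma_unique %.2f, |log2FC| = %g\n",
              x$frac_null, x$frac_sustained, x$frac_ma_induced,
              x$frac_ma_unique, x$effect_log2fc))
  cat(sprintf("  noise: bio CV %.3f (sdlog %.2f), tech CV %.3f, missing %.4f, outlier peptides %.3f, seed %d\n",
              x$bio_cv, x$bio_cv_sdlog, x$tech_cv, x$missing_rate,
              x$outlier_peptide_rate, x$seed))
  invisible(x)
}

tissue_names <- function(n) {
  base <- c("cortex", "hippocampus")
  if (n <= 2L) base[seq_len(n)] else c(base, paste0("tissue", 3:n))[seq_len(n)]
}
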