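test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(bio_cv = 2), "bio_cv")
  expect_error(sim_config(missing_rate = -0.1), "missing_rate")
  expect_error(sim_config(frac_null = 0.5), "frac")
  expect_error(sim_config(group_sizes = c(SH = 10, TM = 11, TS = 9)),
               "group_sizes")
  expect_error(sim_config(group_sizes = c(SH = 0, TM = 11, TS = 9, TSm = 9)),
               "group_sizes")
  expect_error(sim_config(peptides_per_protein = c(min = 3, mode = 2,
                                                   max = 8)),
               "peptides_per_protein")
  expect_error(sim_config(n_proteins = 0), "n_proteins")
})

test_that("the default design yields 39 samples per tissue across two tissues", {
  sim <- simulate_dataset(tiny_config(n_tissues = 2))
  ann <- sim$annotation
  expect_setequal(unique(ann$tissue), c("cortex", "hippocampus"))
  expect_equal(unname(table(ann$tissue)["cortex"]), 39, ignore_attr = TRUE)
  expect_equal(unname(table(ann$tissue)["hippocampus"]), 39,
               ignore_attr = TRUE)
  counts <- table(ann$group[ann$tissue == "cortex"])
  expect_equal(as.integer(counts[c("SH", "TM", "TS", "TSm")]),
               c(10, 11, 9, 9))
  expect_false(anyDuplicated(ann$sample_id) > 0)
  m <- intensity_matrix(sim$peptides)
  expect_true(all(m[!is.na(m)] > 0))
  expect_true(all(table(sim$peptides$protein_group_id) >= 1))
})

test_that("truth table respects quotas and pattern structure", {
  cfg <- tiny_config(n_proteins = 100, frac_null = 0.72,
                     frac_sustained = 0.11, frac_ma_induced = 0.09,
                     frac_ma_unique = 0.08)
  tr <- simulate_dataset(cfg)$truth
  expect_equal(sum(tr$pattern == "sustained"), round(0.11 * 100))
  expect_equal(sum(tr$pattern == "ma_induced"), round(0.09 * 100))
  expect_equal(sum(tr$pattern == "ma_unique"), round(0.08 * 100))
  nul <- tr[tr$pattern == "null", ]
  expect_true(all(nul$effect_TM == 0 & nul$effect_TS == 0 &
                    nul$effect_TSm == 0))
  sus <- tr[tr$pattern == "sustained", ]
  expect_true(all(sus$effect_TS == sus$effect_TSm & sus$effect_TS != 0 &
                    sus$effect_TM == 0))
  mi <- tr[tr$pattern == "ma_induced", ]
  expect_true(all(mi$effect_TM == mi$effect_TSm & mi$effect_TM != 0 &
                    mi$effect_TS == 0))
  mu <- tr[tr$pattern == "ma_unique", ]
  expect_true(all(mu$effect_TSm != 0 & mu$effect_TM == 0 &
                    mu$effect_TS == 0))
  eff <- unlist(tr[, c("effect_TM", "effect_TS", "effect_TSm")])
  expect_true(all(abs(eff) %in% c(0, cfg$effect_log2fc)))
})

test_that("zero-noise all-null data varies only by per-sample loading", {
  cfg <- tiny_config(n_proteins = 30, bio_cv = 0, tech_cv = 0,
                     frac_null = 1, frac_sustained = 0, frac_ma_induced = 0,
                     frac_ma_unique = 0, outlier_peptide_rate = 0,
                     missing_rate = 0)
  sim <- simulate_dataset(cfg)
  m <- intensity_matrix(sim$peptides)
  rel <- sweep(m, 1L, m[, 1L], `/`)  # loading profile, identical per row
  expect_true(all(abs(sweep(rel, 2L, rel[1L, ], `-`)) < 1e-9))
  expect_true(all(sim$truth[, c("effect_TM", "effect_TS",
                                "effect_TSm")] == 0))
})

test_that("planted sustained effects average to the configured fold change", {
  cfg <- tiny_config(n_proteins = 600, effect_log2fc = 1, seed = 202)
  sim <- simulate_dataset(cfg)
  m <- intensity_matrix(sim$peptides)
  ann <- sim$annotation
  ts <- rowMeans(m[, group_samples(ann, "TS", "cortex")], na.rm = TRUE)
  sh <- rowMeans(m[, group_samples(ann, "SH", "cortex")], na.rm = TRUE)
  prot_lfc <- tapply(log2(ts / sh), sim$peptides$protein_group_id,
                     median, na.rm = TRUE)
  sus <- sim$truth$protein_group_id[sim$truth$pattern == "sustained"]
  # oracle: direct averaging of the generated values
  expect_gt(mean(abs(prot_lfc[sus]), na.rm = TRUE), 0.9)
  expect_lt(mean(abs(prot_lfc[sus]), na.rm = TRUE), 1.1)
})

test_that("identical seeds give byte-identical serialized outputs", {
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_quant_table(simulate_dataset(tiny_config(seed = 7))$peptides, f1)
  write_quant_table(simulate_dataset(tiny_config(seed = 7))$peptides, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  f3 <- tempfile(fileext = ".tsv")
  write_quant_table(simulate_dataset(tiny_config(seed = 8))$peptides, f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
  unlink(c(f1, f2, f3))
})

test_that("realized intra-group CV rises strictly with configured bio_cv", {
  med_cv <- vapply(c(0.08, 0.167, 0.33), function(cv) {
    sim <- simulate_dataset(tiny_config(n_proteins = 250, bio_cv = cv,
                                        seed = 77))
    agg <- aggregate_to_protein(normalize_intensities(sim$peptides)$peptides)
    cvs <- cv_summary(agg$proteins, sim$annotation)
    median(cvs$median_cv[cvs$replicate_kind == "biological"])
  }, numeric(1))
  expect_true(all(diff(med_cv) > 0))
})

test_that("group labels are exchangeable when no effects are planted", {
  cfg <- tiny_config(n_proteins = 500, frac_null = 1, frac_sustained = 0,
                     frac_ma_induced = 0, frac_ma_unique = 0, seed = 5)
  sim <- simulate_dataset(cfg)
  agg <- aggregate_to_protein(normalize_intensities(sim$peptides)$peptides)
  cmp <- compare_groups(agg$proteins, sim$annotation, "TM", "SH")
  p <- cmp$p_value[cmp$testable & !cmp$degenerate]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  # permuting group labels leaves the p-value distribution uniform too
  ann2 <- sim$annotation
  set.seed(1)
  ann2$group <- sample(ann2$group)
  cmp2 <- compare_groups(agg$proteins, ann2, "TM", "SH")
  p2 <- cmp2$p_value[cmp2$testable & !cmp2$degenerate]
  expect_gt(stats::ks.test(p2, "punif")$p.value, 0.01)
})

test_that("calibration report tracks the configured noise targets", {
  cfg0 <- tiny_config(n_proteins = 40, bio_cv = 0, tech_cv = 0,
                      outlier_peptide_rate = 0, missing_rate = 0)
  sim0 <- simulate_dataset(cfg0)
  rep0 <- calibration_report(sim0$peptides, sim0$annotation, cfg0)
  expect_equal(rep0$value[rep0$metric == "median_biological_cv"], 0,
               tolerance = 1e-6)

  cfg <- tiny_config(n_proteins = 400, n_tech_pairs = 2, seed = 31)
  sim <- simulate_dataset(cfg)
  rep <- calibration_report(sim$peptides, sim$annotation, cfg,
                            truth = sim$truth)
  bio <- rep$value[rep$metric == "median_biological_cv"]
  expect_gt(bio, 0.167 * 0.8)
  expect_lt(bio, 0.167 * 1.2)
  miss <- rep$value[rep$metric == "protein_missingness"]
  expect_gt(miss, 0)
  expect_lt(miss, 0.01)
  tech <- rep$value[rep$metric == "median_technical_cv"]
  expect_gt(tech, 0)
  expect_lt(tech, bio)  # technical replication is tighter than biological
  eff <- rep$value[rep$metric == "mean_abs_log2fc_sustained"]
  expect_equal(eff, 1, tolerance = 0.15)
  expect_error(calibration_report(sim$peptides[0, ], sim$annotation, cfg),
               "empty")
})
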