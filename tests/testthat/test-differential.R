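protein_table <- function(m) {
  tab <- data.frame(protein_group_id = rownames(m),
                    n_peptides_used = 2L, n_peptides_removed = 0L,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  cbind(tab, as.data.frame(m))
}

test_that("group comparison matches the closed-form Student t-test", {
  m <- rbind(P1 = c(190, 200, 210, 95, 100, 105),
             P2 = c(80, 90, 100, 80, 90, 100))
  colnames(m) <- paste0("s", 1:6)
  ann <- ann_for(colnames(m), rep(c("TM", "SH"), each = 3))
  cmp <- compare_groups(protein_table(m), ann, "TM", "SH")

  expect_equal(cmp$fc[1], 2, tolerance = 1e-12)        # 200 / 100 exactly
  expect_equal(cmp$log2fc, log2(cmp$fc), tolerance = 1e-9)
  # textbook pooled-variance t on log2 values, 4 df
  x <- log2(c(190, 200, 210)); y <- log2(c(95, 100, 105))
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  expect_equal(cmp$p_value[1], 2 * pt(-abs(tt), 4), tolerance = 1e-12)
  # identical groups: FC 1, t statistic 0, p 1
  expect_equal(cmp$fc[2], 1)
  expect_equal(cmp$p_value[2], 1)
  expect_error(compare_groups(protein_table(m), ann, "TX", "SH"), "TX")
})

test_that("p-values agree with stats::t.test to 1e-10 over random data", {
  set.seed(99)
  for (i in 1:100) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- 2^rnorm(n1, 10, 1); y <- 2^rnorm(n2, 10.3, 0.8)
    m <- matrix(c(x, y), nrow = 1,
                dimnames = list("P1", paste0("s", seq_len(n1 + n2))))
    ann <- ann_for(colnames(m), rep(c("TM", "SH"), c(n1, n2)))
    cmp <- compare_groups(protein_table(m), ann, "TM", "SH")
    ref <- t.test(log2(x), log2(y), var.equal = TRUE)$p.value
    expect_equal(cmp$p_value, ref, tolerance = 1e-10)
  }
})

test_that("sparse proteins are reported untestable, not dropped", {
  m <- rbind(P1 = c(10, 11, 12, 9, 10, 11),
             P2 = c(10, NA, NA, 9, 10, 11))
  colnames(m) <- paste0("s", 1:6)
  ann <- ann_for(colnames(m), rep(c("TM", "SH"), each = 3))
  cmp <- compare_groups(protein_table(m), ann, "TM", "SH")
  expect_equal(nrow(cmp), 2)
  expect_false(cmp$testable[2])
  expect_true(is.na(cmp$p_value[2]))
})

test_that("experimental null splits the control into balanced halves", {
  sim <- simulate_dataset(tiny_config(n_proteins = 50, seed = 21))
  agg <- aggregate_to_protein(normalize_intensities(sim$peptides)$peptides)
  nulls <- experimental_null(agg$proteins, sim$annotation, n_splits = 10,
                             seed = 3)
  expect_length(nulls, 10)
  splits <- attr(nulls, "splits")
  expect_true(all(lengths(splits) == 5))  # 10 SH animals -> 5 vs 5
  keys <- vapply(splits, function(s) paste(sort(s), collapse = "|"), "")
  expect_false(anyDuplicated(keys) > 0)   # partitions sampled w/o repeats
  # determinism under the same seed
  nulls2 <- experimental_null(agg$proteins, sim$annotation, n_splits = 10,
                              seed = 3)
  expect_identical(nulls[[4]]$p_value, nulls2[[4]]$p_value)
  expect_error(experimental_null(agg$proteins,
                                 sim$annotation[sim$annotation$group != "SH" |
                                   sim$annotation$sample_id %in%
                                     sim$annotation$sample_id[1:3], ],
                                 n_splits = 5),
               ">= 4")
})

test_that("identical control samples give an exactly flat null", {
  m <- matrix(rep(c(100, 220, 3000), 8), nrow = 3,
              dimnames = list(paste0("P", 1:3), paste0("s", 1:8)))
  ann <- ann_for(colnames(m), rep("SH", 8))
  nulls <- experimental_null(protein_table(m), ann, n_splits = 4, seed = 1)
  for (nl in nulls) {
    expect_equal(nl$fc, rep(1, 3))
    expect_equal(nl$p_value, rep(1, 3))
    expect_true(all(nl$degenerate))
  }
})

test_that("FADR grid arithmetic follows its definition", {
  # case counts {100, 60, 40} and mean null counts {10, 3, 1}
  # at thresholds {1.2, 1.4, 2.0} give FADR {0.10, 0.05, 0.025}
  fc_for <- function(n_top, n_mid, n_low, total = 150) {
    # n_low proteins beyond 2.0, then up to n_mid beyond 1.4, n_top beyond 1.2
    fc <- rep(1, total)
    fc[seq_len(n_top)] <- 1.25
    fc[seq_len(n_mid)] <- 1.45
    fc[seq_len(n_low)] <- 2.5
    fc
  }
  case <- cmp_table(fc_for(100, 60, 40), p = rep(0.01, 150))
  nulls <- lapply(c(0, 20), function(extra) {
    cmp_table(fc_for(10 + extra, 3, 1), p = rep(0.01, 150), contrast = "EN")
  })
  grid <- fadr_grid(case, nulls, fc_thresholds = c(1.2, 1.4, 2.0))
  expect_equal(grid$n_case_aps, c(100, 60, 40))
  expect_equal(grid$n_null_aps, c(20, 3, 1))  # mean of {10,30},{3,3},{1,1}
  expect_equal(grid$fadr, c(0.20, 0.05, 0.025))
  expect_true(all(diff(grid$n_case_aps) <= 0))

  # zero null APs everywhere: FADR 0; zero case APs with null hits: Inf
  quiet <- list(cmp_table(rep(1, 150), rep(0.9, 150), contrast = "EN"))
  expect_equal(fadr_grid(case, quiet)$fadr, rep(0, 5))
  none <- cmp_table(rep(1, 150), rep(0.9, 150))
  expect_true(all(is.infinite(
    fadr_grid(none, nulls, fc_thresholds = c(1.2))$fadr)))
  expect_equal(fadr_grid(none, quiet, fc_thresholds = c(1.2))$fadr, 0)
  expect_error(fadr_grid(case[0, ], nulls), "empty")
  expect_error(fadr_grid(case, nulls, fc_thresholds = c(0.9, 1.4)), "> 1")
})

test_that("cutoff selection balances FADR against AP retention", {
  mk_grid <- function(fadr, n_case, ts = c(1.2, 1.3, 1.4, 1.5, 2)) {
    g <- data.frame(fc_threshold = ts, contrast = "TM/SH",
                    n_case_aps = n_case, n_null_aps = fadr * n_case,
                    fadr = fadr, alpha = 0.05)
    class(g) <- c("fadr_grid", "data.frame")
    g
  }
  # FADR first dips under 5% at 1.4, like the study's own grid
  sel <- select_cutoff(mk_grid(c(0.113, 0.07, 0.040, 0.037, 0.010),
                               c(300, 250, 200, 190, 70)))
  expect_equal(sel$fc_cutoff, 1.4)
  expect_true(sel$qualified)
  # 2.0 lowers FADR slightly but drops 65% of APs: refuse to move
  sel2 <- select_cutoff(mk_grid(c(0.20, 0.10, 0.045, 0.044, 0.030),
                                c(300, 250, 200, 195, 70)))
  expect_equal(sel2$fc_cutoff, 1.4)
  # all-zero FADR: keep the smallest threshold
  sel3 <- select_cutoff(mk_grid(rep(0, 5), c(300, 250, 200, 190, 70)))
  expect_equal(sel3$fc_cutoff, 1.2)
  # nothing qualifies: largest threshold plus a warning flag
  sel4 <- select_cutoff(mk_grid(rep(0.2, 5), c(300, 250, 200, 190, 70)))
  expect_equal(sel4$fc_cutoff, 2)
  expect_true(sel4$warning)
  expect_false(sel4$qualified)
})

test_that("AP calling enumerates the joint FC and p filter", {
  cmp <- cmp_table(c(1.5, 1.3, 1.5, 0.6, 0.75),
                   c(0.01, 0.01, 0.2, 0.01, 0.01))
  aps <- call_aps(cmp, fc_cutoff = 1.4, alpha = 0.05)
  expect_setequal(ap_ids(aps), c("P001", "P004"))
  expect_equal(aps$members$direction[aps$members$protein_group_id == "P001"],
               "up")
  expect_equal(aps$members$direction[aps$members$protein_group_id == "P004"],
               "down")
  expect_equal(nrow(call_aps(cmp[0, ], 1.4)$members), 0)
  expect_error(call_aps(cmp, fc_cutoff = 1), "> 1")
  # boundary: FC exactly at the cutoff qualifies, 1/cutoff too
  edge <- cmp_table(c(1.4, 1 / 1.4), c(0.049, 0.049))
  expect_setequal(ap_ids(call_aps(edge, 1.4)), c("P001", "P002"))
  # union across contrasts
  b <- call_aps(cmp_table(c(2, 1, 1, 1, 1), rep(0.01, 5),
                          contrast = "TS/SH"), 1.4)
  expect_setequal(ap_union(aps, b), c("P001", "P004"))
})

test_that("AP counts shrink monotonically in both cutoffs", {
  sim <- simulate_dataset(tiny_config(n_proteins = 300, seed = 55))
  agg <- aggregate_to_protein(normalize_intensities(sim$peptides)$peptides)
  cmp <- compare_groups(agg$proteins, sim$annotation, "TSm", "SH")
  n_fc <- vapply(c(1.1, 1.2, 1.4, 1.7, 2, 3),
                 function(t) nrow(call_aps(cmp, t)$members), numeric(1))
  expect_true(all(diff(n_fc) <= 0))
  n_a <- vapply(c(0.1, 0.05, 0.01, 0.001),
                function(a) nrow(call_aps(cmp, 1.4, a)$members), numeric(1))
  expect_true(all(diff(n_a) <= 0))
})

test_that("a pure p-filter on null data calls at the nominal alpha rate", {
  cfg <- tiny_config(n_proteins = 800, frac_null = 1, frac_sustained = 0,
                     frac_ma_induced = 0, frac_ma_unique = 0, seed = 71)
  sim <- simulate_dataset(cfg)
  agg <- aggregate_to_protein(normalize_intensities(sim$peptides)$peptides)
  cmp <- compare_groups(agg$proteins, sim$annotation, "TM", "SH")
  called <- nrow(call_aps(cmp, fc_cutoff = 1 + 1e-9, alpha = 0.05)$members)
  n <- sum(cmp$testable)
  expect_lt(abs(called / n - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 0.005)
})
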