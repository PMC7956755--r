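# small seeded configurations and hand-built tables used across tests

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_proteins = 80, n_tissues = 1, seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# peptide table from an intensity matrix; protein gives the group of each row
pep_table <- function(m, protein, peptide = NULL) {
  if (is.null(peptide)) {
    peptide <- paste0(protein, "_pep", stats::ave(seq_along(protein),
                                                  protein, FUN = seq_along))
  }
  out <- data.frame(peptide_id = peptide, protein_group_id = protein,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(m))
}

# minimal annotation for a vector of sample ids
ann_for <- function(samples, groups, tissue = "cortex") {
  data.frame(sample_id = samples, group = groups, tissue = tissue,
             replicate_kind = "biological", pair_id = NA_character_,
             stringsAsFactors = FALSE)
}

# comparison rows with prescribed fold changes and p-values
cmp_table <- function(fc, p, contrast = "TM/SH",
                      ids = sprintf("P%03d", seq_along(fc))) {
  data.frame(protein_group_id = ids, contrast = contrast, fc = fc,
             log2fc = log2(fc), p_value = p, n_case = 5L, n_control = 5L,
             testable = TRUE, degenerate = FALSE, stringsAsFactors = FALSE)
}
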