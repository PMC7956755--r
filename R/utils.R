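#' Extract the sample intensity matrix from a quantification table
#'
#' Peptide and protein tables carry identifier/metadata columns ahead of one
#' numeric column per sample.  This helper returns the numeric part as a
#' matrix (rows in table order), leaving `NA` for missing cells.
#'
#' @param x A peptide- or protein-level quantification data frame.
#' @param samples Optional character vector restricting (and ordering) the
#'   sample columns.
#' @return Numeric matrix with one column per sample.
#' @export
intensity_matrix <- function(x, samples = NULL) {
  stopifnot(is.data.frame(x))
  meta <- intersect(names(x), .meta_cols)
  cols <- setdiff(names(x), meta)
  if (!is.null(samples)) {
    missing <- setdiff(samples, cols)
    if (length(missing) > 0L) {
      stop("samples not present in table: ", paste(missing, collapse = ", "))
    }
    cols <- samples
  }
  m <- as.matrix(x[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- if ("protein_group_id" %in% meta && !"peptide_id" %in% meta) {
    x$protein_group_id
  } else if ("peptide_id" %in% meta) {
    x$peptide_id
  } else {
    rownames(x)
  }
  m
}

.meta_cols <- c("peptide_id", "protein_group_id",
                "n_peptides_used", "n_peptides_removed")

# sample columns of a quantification table
sample_cols <- function(x) setdiff(names(x), .meta_cols)

# replace the sample columns of `x` with matrix `m` (same dimensions/order)
set_intensities <- function(x, m) {
  cols <- sample_cols(x)
  stopifnot(ncol(m) == length(cols), nrow(m) == nrow(x))
  x[, cols] <- m
  x
}

# validate a sample annotation data frame
check_annotation <- function(ann) {
  stopifnot(is.data.frame(ann))
  req <- c("sample_id", "group", "tissue", "replicate_kind")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0L) {
    stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(ann$sample_id)) stop("annotation sample_id not unique")
  invisible(ann)
}

# samples of one biological group (technical replicates excluded)
group_samples <- function(ann, group, tissue = NULL) {
  check_annotation(ann)
  if (!group %in% ann$group) stop("unknown group label: ", group)
  keep <- ann$group == group & ann$replicate_kind == "biological"
  if (!is.null(tissue)) keep <- keep & ann$tissue == tissue
  ann$sample_id[keep]
}

# row-wise coefficient of variation over present values (>= 2 required)
row_cv <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  s <- sqrt(ss / pmax(n - 1L, 1L))
  out <- s / mu
  out[n < 2L] <- NA_real_
  out
}
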