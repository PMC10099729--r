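#' Tau tissue-specificity index
#'
#' `tau = sum(1 - x_i / max(x)) / (n - 1)`: 0 for uniform expression across
#' tissues, 1 for expression confined to a single tissue. Scale-invariant.
#'
#' @param x non-negative per-tissue expression vector (e.g. TPM).
#' @return tau in `[0, 1]`; `NA` for an all-zero vector.
#' @export
tau <- function(x) {
  if (length(x) < 2L) stop("tau needs at least two tissues")
  if (any(x < 0)) stop("negative expression values")
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1L)
}

#' Binary feature grouping of genes
#'
#' Splits genes into Low/High groups at the field's printed cutpoints:
#' expression TPM 50 (High: `>= 50`), tau 0.3 (High: `>= 0.3`), dN/dS 0.0993
#' (High/fast-evolving: `> 0.0993`), PPI degree at the median (High:
#' `> median`). Housekeeping and age annotations are consumed as boolean /
#' categorical columns directly.
#'
#' @param values numeric feature values per gene (`NA` allowed).
#' @param feature one of `"expression"`, `"tau"`, `"dnds"`, `"ppi_degree"`.
#' @param cutpoint override for the default threshold.
#' @return character vector `"Low"`/`"High"` with `NA` for missing values.
#' @export
group_genes <- function(values, feature = c("expression", "tau", "dnds",
                                            "ppi_degree"),
                        cutpoint = NULL) {
  feature <- match.arg(feature)
  if (is.null(cutpoint))
    cutpoint <- switch(feature, expression = 50, tau = 0.3, dnds = 0.0993,
                       ppi_degree = stats::median(values, na.rm = TRUE))
  lab <- switch(feature,
    expression = ifelse(values >= cutpoint, "High", "Low"),
    tau = ifelse(values >= cutpoint, "High", "Low"),
    dnds = ifelse(values > cutpoint, "High", "Low"),
    ppi_degree = ifelse(values > cutpoint, "High", "Low"))
  lab[is.na(values)] <- NA_character_
  lab
}

#' Compare splicing entropy between two gene groups
#'
#' Two-sided Wilcoxon rank-sum test (mid-ranks for ties) with group medians,
#' matching the bean-plot summaries of event-level entropy comparisons.
#'
#' @param entropy_a,entropy_b event entropy values for the two groups.
#' @param exact logical passed to [stats::wilcox.test()]; default lets the
#'   test choose.
#' @return list: `statistic` (rank-sum W), `p_value` (two-sided; `NA` when a
#'   group has fewer than 2 values), `median_a`, `median_b`, `n_a`, `n_b`.
#' @export
compare_entropy_groups <- function(entropy_a, entropy_b, exact = NULL) {
  entropy_a <- entropy_a[!is.na(entropy_a)]
  entropy_b <- entropy_b[!is.na(entropy_b)]
  if (length(entropy_a) == 0L || length(entropy_b) == 0L)
    stop("both groups must be non-empty")
  out <- list(statistic = NA_real_, p_value = NA_real_,
              median_a = stats::median(entropy_a),
              median_b = stats::median(entropy_b),
              n_a = length(entropy_a), n_b = length(entropy_b))
  wt <- suppressWarnings(stats::wilcox.test(entropy_a, entropy_b,
                                            alternative = "two.sided",
                                            exact = exact))
  out$statistic <- unname(wt$statistic)
  if (length(entropy_a) >= 2L && length(entropy_b) >= 2L)
    out$p_value <- wt$p.value
  out
}

#' Read a gene annotation table
#'
#' Expects TSV columns `gene_id`, `housekeeping` (logical), `age_class`
#' (`young`/`old`), `dnds`, `ppi_degree`, and one `tpm_<tissue>` column per
#' tissue.
#'
#' @param path TSV file.
#' @return data.frame with an added `tau` column computed from the
#'   `tpm_` columns.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(ann)) stop("gene_id column required in ", path)
  tpm_cols <- grep("^tpm_", names(ann), value = TRUE)
  if (length(tpm_cols) >= 2L)
    ann$tau <- apply(as.matrix(ann[, tpm_cols]), 1L, tau)
  ann
}
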