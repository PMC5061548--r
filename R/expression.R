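#' FPKM to TPM transform
#'
#' `TPM_i = FPKM_i / sum(FPKM) * 1e6`; the output always sums to one
#' million.
#'
#' @param fpkm A non-negative numeric vector, or a data frame with an
#'   `fpkm` column (a `tpm` column is appended).
#' @return A numeric vector, or the input data frame with `tpm`.
#' @examples
#' fpkm_to_tpm(c(1, 3))
#' @export
fpkm_to_tpm <- function(fpkm) {
  if (is.data.frame(fpkm)) {
    return(mutate(as_tibble(fpkm), tpm = fpkm_to_tpm(.data$fpkm)))
  }
  if (any(fpkm < 0)) abort("FPKM values must be >= 0")
  s <- sum(fpkm)
  if (s == 0) abort("all-zero FPKM vector: TPM undefined")
  fpkm / s * 1e6
}

#' Call expressed genes at a TPM threshold
#'
#' The threshold comparison is inclusive: a gene at exactly the threshold
#' is expressed.
#'
#' @param tpm A named non-negative numeric vector, or a data frame with
#'   `gene` and `tpm` columns.
#' @param threshold TPM cutoff (default 2).
#' @return Character vector of expressed gene ids.
#' @export
call_expressed <- function(tpm, threshold = 2) {
  if (is.data.frame(tpm)) tpm <- setNames(tpm$tpm, tpm$gene)
  if (any(tpm < 0)) abort("TPM values must be >= 0")
  names(tpm)[tpm >= threshold]
}

#' Unique-read counts per gene
#'
#' Counts reads with a single best reference (`status == "unique"`);
#' ambiguous and unassigned reads are excluded.
#'
#' @param assignment A [assign_reads()] result.
#' @param genes Genes to report (default: all in the assignment's depth
#'   profile), zero-filled.
#' @return A tibble: `gene`, `unique_reads`.
#' @export
unique_read_counts <- function(assignment, genes = NULL) {
  stopifnot(inherits(assignment, "read_assignment"))
  genes <- genes %||% names(assignment$depth)
  uni <- filter(assignment$assignments, .data$status == "unique")
  hit <- vapply(uni$genes, function(g) g[[1]], character(1))
  tb <- table(factor(hit, levels = genes))
  tibble(gene = genes, unique_reads = as.integer(tb))
}
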