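#' Simulate an FPKM expression table for a sampled repertoire
#'
#' Emulates the observed expression pattern of a retrogene family: the
#' parent gene is always robustly expressed, a small designated set of
#' retrogene copies is expressed (one high, a few low-but-real), the rest
#' are silent apart from sub-threshold leakage, and a lognormal background
#' transcriptome supplies a realistic denominator for the TPM transform.
#'
#' @param history A [simulate_gene_family()] result.
#' @param config A [sim_config()]; `expressed_high`, `expressed_low`,
#'   `n_background` control the pattern. Set both expressed counts to 0 for
#'   an all-silent family.
#' @param species Which species' repertoire to profile.
#' @return An `expression_table` tibble: `gene`, `class`
#'   (`parent`/`retrogene`/`background`), `fpkm`, `designated_expressed`.
#' @export
simulate_expression <- function(history, config = history$config,
                                species = "African_elephant") {
  if (!species %in% history$species_tree$nodes$label) {
    abort(sprintf("'%s' is not in the species tree", species))
  }
  copies <- filter(history$copy_map, .data$species == !!species)$tip
  n_hi <- min(config$expressed_high, length(copies))
  n_lo <- min(config$expressed_low, max(0L, length(copies) - n_hi))
  with_seed(derive_seed(config$seed, paste0("expression/", species)), {
    expressed <- sample(copies, n_hi + n_lo)
    hi <- head(expressed, n_hi)
    lo <- tail(expressed, n_lo)
    fpkm <- dplyr::case_when(
      copies %in% hi ~ rlnorm(length(copies), log(10), 0.2),
      copies %in% lo ~ rlnorm(length(copies), log(0.5), 0.3),
      TRUE ~ 0)
    out <- bind_rows(
      tibble(gene = sprintf("%s|TP53", species), class = "parent",
             fpkm = rlnorm(1, log(30), 0.2), designated_expressed = TRUE),
      tibble(gene = copies, class = "retrogene", fpkm = fpkm,
             designated_expressed = copies %in% expressed),
      tibble(gene = sprintf("BG%04d", seq_len(config$n_background)),
             class = "background",
             fpkm = rlnorm(config$n_background, log(20), 1),
             designated_expressed = NA))
    class(out) <- c("expression_table", class(out))
    out
  })
}

#' Body-size-through-time series
#'
#' Either wraps a user table of `(time, value)` rows or loads the packaged
#' `"proboscidea_fixture"`, a synthetic series emulating the published
#' proboscidean trend (kilogram-scale ancestors before ~40 MY BP rising to
#' elephant-scale masses toward the present).
#'
#' @param table A data frame with columns `time` (MY BP) and `value`
#'   (body mass, kg), or the string `"proboscidea_fixture"`.
#' @return A tibble `time`, `value` ordered from oldest to youngest.
#' @examples
#' body_size_series("proboscidea_fixture")
#' @export
body_size_series <- function(table = "proboscidea_fixture") {
  if (is.character(table) && length(table) == 1L) {
    if (table != "proboscidea_fixture") abort(sprintf("unknown preset '%s'", table))
    path <- system.file("extdata", "body_size_proboscidea_synthetic.tsv",
                        package = "retroexpand", mustWork = TRUE)
    table <- readr::read_tsv(path, show_col_types = FALSE)
  }
  table <- as_tibble(table)
  if (!all(c("time", "value") %in% names(table))) {
    abort("body size table needs `time` and `value` columns")
  }
  if (nrow(table) == 0L) abort("body size table is empty")
  if (anyDuplicated(table$time)) abort("duplicate time points in body size table")
  arrange(table, dplyr::desc(.data$time))
}
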