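#' Reciprocal-best-hit orthology between two gene sets
#'
#' Aligns every gene in `genes_a` against every gene in `genes_b` with the
#' package's local aligner and reports a pair `(a, b)` when `b` is `a`'s
#' best hit and `a` is `b`'s best hit. Score ties are broken by identity,
#' then lexical gene id. Unpaired genes are listed with an `NA` partner.
#'
#' @param genes_a,genes_b Data frames with `gene` and `sequence` columns, or
#'   named character vectors.
#' @param match,mismatch,gap_open,gap_extend Aligner parameters.
#' @return A tibble with columns `gene_a`, `gene_b`, `score`, `identity`,
#'   `paired`; unpaired genes of either side appear with the other column
#'   `NA`.
#' @export
reciprocal_best_hit <- function(genes_a, genes_b, match = 1, mismatch = 2,
                                gap_open = 5, gap_extend = 2) {
  a <- as_gene_vector(genes_a)
  b <- as_gene_vector(genes_b)
  if (!length(a) || !length(b)) abort("need at least one gene per side")
  hits <- purrr::map(seq_along(a), function(i) {
    align_batch(a[[i]], b, match, mismatch, gap_open, gap_extend) |>
      mutate(gene_a = names(a)[i])
  }) |> bind_rows() |>
    rename(gene_b = "ref") |>
    select("gene_a", "gene_b", "score", "identity")

  best_of <- function(h, by) {
    h |>
      group_by(.data[[by]]) |>
      arrange(dplyr::desc(.data$score), dplyr::desc(.data$identity),
              .data$gene_a, .data$gene_b, .by_group = TRUE) |>
      slice(1L) |>
      ungroup()
  }
  best_a <- best_of(hits, "gene_a")  # best b for each a
  best_b <- best_of(hits, "gene_b")  # best a for each b
  pairs <- dplyr::inner_join(
    select(best_a, "gene_a", "gene_b", "score", "identity"),
    select(best_b, "gene_a", "gene_b"),
    by = c("gene_a", "gene_b")) |>
    mutate(paired = TRUE)
  bind_rows(
    pairs,
    tibble(gene_a = setdiff(names(a), pairs$gene_a), gene_b = NA_character_,
           score = NA_real_, identity = NA_real_, paired = FALSE),
    tibble(gene_a = NA_character_, gene_b = setdiff(names(b), pairs$gene_b),
           score = NA_real_, identity = NA_real_, paired = FALSE)) |>
    arrange(dplyr::desc(.data$paired), .data$gene_a, .data$gene_b)
}

as_gene_vector <- function(x) {
  if (is.data.frame(x)) setNames(x$sequence, x$gene) else x
}

#' Coding potential and longest open reading frame
#'
#' Scans the three forward frames of the given (stranded) sequence for the
#' longest ATG-initiated open reading frame; a gene is called coding when
#' that ORF reaches `min_aa` amino acids (stop codon excluded).
#'
#' @param sequence Nucleotide string.
#' @param min_aa Minimum ORF length in amino acids to call a gene coding
#'   (default 25).
#' @return A tibble with `coding` (logical) and `orf_length` (aa; `NA` when
#'   not coding).
#' @examples
#' assess_coding_potential("ATGAAATAA")  # 2 aa, below the default cutoff
#' @export
assess_coding_potential <- function(sequence, min_aa = 25) {
  sequence <- check_dna(sequence, "sequence")
  if (nchar(sequence) == 0L) abort("sequence has length 0")
  v <- strsplit(sequence, "")[[1]]
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (frame in 0:2) {
    n_codon <- (length(v) - frame) %/% 3L
    if (n_codon < 2L) next
    codons <- vapply(seq_len(n_codon), function(k) {
      paste(v[(frame + 3L * (k - 1L) + 1L):(frame + 3L * k)], collapse = "")
    }, character(1))
    open_at <- NA_integer_
    for (k in seq_len(n_codon)) {
      if (is.na(open_at) && codons[k] == "ATG") open_at <- k
      if (!is.na(open_at) && codons[k] %in% stops) {
        best <- max(best, k - open_at)
        open_at <- NA_integer_
      }
    }
    # an ORF running off the end without a stop is not closed; keep the
    # conservative reading and require a stop codon
  }
  coding <- best >= min_aa
  tibble(coding = coding, orf_length = if (coding) best else NA_integer_)
}

#' Summarize a gene-record table
#'
#' @param records A data frame of gene records with columns `gene`,
#'   `is_retrogene` (logical) and `coding` (logical), such as
#'   [load_table1_fixture()].
#' @return A one-row tibble: `total`, `retrogenes`, `coding_retrogenes`.
#' @export
summarize_repertoire <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) {
    return(tibble(total = 0L, retrogenes = 0L, coding_retrogenes = 0L))
  }
  if (anyDuplicated(records$gene)) abort("duplicate gene ids in records")
  tibble(total = nrow(records),
         retrogenes = sum(records$is_retrogene),
         coding_retrogenes = sum(records$is_retrogene & records$coding))
}

#' Find diagnostic indels in a multiple sequence alignment
#'
#' Reports maximal alignment-column blocks that are gapped in every ingroup
#' row and ungapped in every outgroup row, with block length inside
#' `[min_len, max_len]` -- the signature of a deletion fixed on the ingroup
#' stem (for retrogene families, the diagnostic deletion shared by all
#' retrogene copies and absent from the parent gene).
#'
#' @param msa A data frame with `gene`, `sequence` columns (aligned,
#'   equal-length, gaps as `-`), or a named character vector.
#' @param ingroup_ids,outgroup_ids Gene ids splitting the rows; must not
#'   overlap.
#' @param min_len,max_len Length bounds in columns (defaults 15 and 30).
#' @param ingroup_coverage Minimum fraction of ingroup rows that must carry
#'   the gap (default 1: universal).
#' @return A tibble with one row per indel: `col_start`, `col_end` (1-based
#'   inclusive alignment columns), `length`, `ingroup_coverage`,
#'   `outgroup_absent`.
#' @export
find_diagnostic_indels <- function(msa, ingroup_ids, outgroup_ids,
                                   min_len = 15, max_len = 30,
                                   ingroup_coverage = 1) {
  x <- as_gene_vector(msa)
  if (length(unique(nchar(x))) != 1L) abort("ragged MSA: rows differ in length")
  if (length(intersect(ingroup_ids, outgroup_ids))) {
    abort("ingroup and outgroup overlap")
  }
  missing <- setdiff(c(ingroup_ids, outgroup_ids), names(x))
  if (length(missing)) abort(sprintf("rows not in MSA: %s",
                                     paste(missing, collapse = ", ")))
  m <- do.call(rbind, strsplit(unname(x[c(ingroup_ids, outgroup_ids)]), ""))
  n_in <- length(ingroup_ids)
  gap_in <- colMeans(m[seq_len(n_in), , drop = FALSE] == "-")
  gap_out <- colSums(m[-seq_len(n_in), , drop = FALSE] == "-")
  candidate <- gap_in >= ingroup_coverage & gap_out == 0
  r <- rle(candidate)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len & r$lengths <= max_len
  tibble(col_start = starts[keep], col_end = ends[keep],
         length = r$lengths[keep],
         ingroup_coverage = vapply(which(keep), function(k) {
           min(gap_in[starts[k]:ends[k]])
         }, numeric(1)),
         outgroup_absent = TRUE)
}

#' Predict a PCR amplicon from a primer pair
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer on the template (exact matching by default; up to
#' `max_mismatch` substitutions allowed) and returns the implied amplicon
#' length(s), end of reverse site minus start of forward site.
#'
#' @param template Nucleotide string.
#' @param forward,reverse Primer sequences, 5'->3'.
#' @param max_mismatch Allowed substitutions per primer site (default 0).
#' @return A tibble with `fwd_start`, `rev_end` (1-based), `length`, and
#'   `ambiguous` (TRUE on all rows when several site pairs are possible);
#'   zero rows when either site is absent or only in invalid orientation.
#' @examples
#' # forward site at 1, reverse site at the end: amplicon spans the template
#' predict_amplicon("ACGTACGTAAATTTCCCGGG", "ACGTAC", "CCCGGG")
#' @export
predict_amplicon <- function(template, forward, reverse, max_mismatch = 0) {
  template <- check_dna(template, "template")
  forward <- check_dna(forward, "forward primer", allow_n = FALSE)
  reverse <- check_dna(reverse, "reverse primer", allow_n = FALSE)
  if (!nchar(forward) || !nchar(reverse)) abort("primers must be non-empty")
  fwd_sites <- find_sites(template, forward, max_mismatch)
  rev_sites <- find_sites(template, revcomp(reverse), max_mismatch)
  if (!length(fwd_sites) || !length(rev_sites)) {
    return(tibble(fwd_start = integer(), rev_end = integer(),
                  length = integer(), ambiguous = logical()))
  }
  combos <- tidyr::expand_grid(fwd_start = fwd_sites, rev_start = rev_sites) |>
    mutate(rev_end = .data$rev_start + nchar(reverse) - 1L,
           length = .data$rev_end - .data$fwd_start + 1L) |>
    filter(.data$rev_start > .data$fwd_start + nchar(forward) - 1L) |>
    select("fwd_start", "rev_end", "length")
  if (nrow(combos) > 1L) {
    warn("multiple candidate amplicons; reporting all")
  }
  mutate(combos, ambiguous = nrow(combos) > 1L)
}

find_sites <- function(template, probe, max_mismatch) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(probe),
                                   Biostrings::DNAString(template),
                                   max.mismatch = max_mismatch)
  Biostrings::start(hits)
}

#' Classify the duplication mechanism of each locus
#'
#' A duplicate is called a segmental duplication when its flanks align to
#' its parent locus' flanks at or above `identity_threshold` percent
#' identity *and* the two loci carry the same transposable-element
#' fingerprint labels; otherwise it is called an independent
#' retrotransposition. Loci without flanks are skipped with a warning; the
#' family's founding copy (no parent locus) is not classified.
#'
#' @param loci An [assemble_loci()] result (rows with `role ==
#'   "retrogene"` are classified).
#' @param identity_threshold Percent flank identity cutoff (default 80).
#' @return A tibble: `gene`, `parent_gene`, `flank_identity`,
#'   `fingerprint_match`, `mechanism`.
#' @export
classify_expansion_mechanism <- function(loci, identity_threshold = 80) {
  loci <- as_tibble(loci)
  cand <- filter(loci, .data$role == "retrogene", !is.na(.data$parent_gene))
  rows <- purrr::map(seq_len(nrow(cand)), function(k) {
    parent <- filter(loci, .data$gene == cand$parent_gene[k])
    if (nrow(parent) == 0L || !nzchar(cand$flank_left[k]) ||
        !nzchar(parent$flank_left[1])) {
      warn(sprintf("locus %s skipped: missing flanks", cand$gene[k]))
      return(NULL)
    }
    idl <- local_align(cand$flank_left[k], parent$flank_left[1])$identity
    idr <- local_align(cand$flank_right[k], parent$flank_right[1])$identity
    flank_id <- mean(c(idl, idr), na.rm = TRUE)
    fp <- setequal(cand$te_labels[[k]], parent$te_labels[[1]])
    tibble(gene = cand$gene[k], parent_gene = cand$parent_gene[k],
           flank_identity = flank_id, fingerprint_match = fp,
           mechanism = if (!is.na(flank_id) && flank_id >= identity_threshold && fp)
             "segmental_duplication" else "independent_retrotransposition")
  })
  bind_rows(rows)
}
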