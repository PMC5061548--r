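#' Optimal local alignment with affine gap costs
#'
#' A Smith-Waterman/Gotoh aligner (the package's stand-in for whole-genome
#' aligners at desk scale). A gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. Ties between equally scoring
#' alignments are broken deterministically: prefer the smaller start on
#' `seq_a`, then on `seq_b`, then the smaller ends. Percent identity is
#' matches over aligned columns including internal gaps; `N` never matches.
#'
#' @param seq_a,seq_b Nucleotide strings (ACGTN).
#' @param match Match reward (default 1).
#' @param mismatch,gap_open,gap_extend Penalty magnitudes (defaults 2, 5, 2
#'   -- BLAT-like stringency).
#' @return A `local_alignment` list: `score`, `a_start`, `a_end`,
#'   `b_start`, `b_end` (1-based inclusive; `NA` for the empty alignment),
#'   `identity` (percent), `matches`, `columns`, `a_aligned`, `b_aligned`.
#' @examples
#' local_align("ACGTACGT", "ACGTTCGT")$identity
#' @export
local_align <- function(seq_a, seq_b, match = 1, mismatch = 2, gap_open = 5,
                        gap_extend = 2) {
  seq_a <- check_dna(seq_a, "seq_a")
  seq_b <- check_dna(seq_b, "seq_b")
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) abort("sequences must be non-empty")
  res <- .sw_align_cpp(seq_a, seq_b, match, mismatch, gap_open, gap_extend, TRUE)
  structure(res, class = "local_alignment",
            params = c(match = match, mismatch = mismatch,
                       gap_open = gap_open, gap_extend = gap_extend))
}

#' @export
print.local_alignment <- function(x, ...) {
  if (is.na(x$a_start)) {
    cat("<local_alignment> empty (score 0)\n")
  } else {
    cat(sprintf("<local_alignment> score %g, identity %.1f%% over %d columns\n",
                x$score, x$identity, x$columns))
    cat(" a:", x$a_aligned, sprintf("[%d-%d]\n", x$a_start, x$a_end))
    cat(" b:", x$b_aligned, sprintf("[%d-%d]\n", x$b_start, x$b_end))
  }
  invisible(x)
}

#' @export
tidy.local_alignment <- function(x, ...) {
  tibble(score = x$score, identity = x$identity, columns = x$columns,
         matches = x$matches, a_start = x$a_start, a_end = x$a_end,
         b_start = x$b_start, b_end = x$b_end)
}

# one query against many references (summary only, no aligned strings)
align_batch <- function(query, refs, match = 1, mismatch = 2, gap_open = 5,
                        gap_extend = 2) {
  df <- .sw_align_batch_cpp(query, refs, match, mismatch, gap_open, gap_extend)
  as_tibble(df) |> mutate(ref = names(refs) %||% as.character(seq_along(refs)),
                          .before = 1L)
}
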