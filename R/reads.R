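#' Simulate shotgun reads from a synthetic genome
#'
#' Read start positions are uniform over each contig, the number of reads
#' per contig is Poisson with mean `coverage * contig_length / read_length`,
#' and each base is miscalled with probability `config$error_rate`. The
#' ancient profile draws read lengths uniformly from
#' `config$ancient$read_len_range` and uses `config$ancient$coverage`.
#' Provenance (source contig and 0-based half-open origin interval) is kept
#' for truth-aware tests.
#'
#' @param genome An [assemble_loci()] result (or any tibble with `species`,
#'   `contig`, `sequence`).
#' @param config A [sim_config()].
#' @param species Restrict to one species' contigs (default: all).
#' @param ancient Use the ancient-DNA profile.
#' @param label Extra label mixed into the derived seed so independent read
#'   sets can be drawn from one master seed.
#' @return A `read_set` tibble: `read_id`, `sequence`, `quality`, `contig`,
#'   `start`, `end`, `mate` (0 for single-end).
#' @export
simulate_reads <- function(genome, config, species = NULL, ancient = FALSE,
                           label = if (ancient) "reads/ancient" else "reads/modern") {
  contigs <- as_tibble(genome)
  if (!is.null(species)) contigs <- filter(contigs, .data$species %in% !!species)
  if (!nrow(contigs)) abort("no contigs to simulate reads from")
  cov <- if (ancient) config$ancient$coverage else config$coverage
  if (cov < 0) abort("coverage must be >= 0")
  lmin <- if (ancient) config$ancient$read_len_range[1] else config$read_len
  lmax <- if (ancient) config$ancient$read_len_range[2] else config$read_len
  clen <- nchar(contigs$sequence)
  if (lmax > min(clen)) {
    abort(sprintf("read length %d exceeds shortest contig (%d nt)", lmax, min(clen)))
  }

  with_seed(derive_seed(config$seed, label), {
    out <- list()
    mean_len <- (lmin + lmax) / 2
    for (k in seq_len(nrow(contigs))) {
      n <- rpois(1L, cov * clen[k] / mean_len)
      if (n == 0L) next
      len <- if (lmin == lmax) rep(lmin, n) else sample(lmin:lmax, n, replace = TRUE)
      start <- vapply(len, function(l) sample.int(clen[k] - l + 1L, 1L) - 1L,
                      integer(1))
      sq <- substring(contigs$sequence[k], start + 1L, start + len)
      if (config$error_rate > 0) sq <- vapply(sq, add_read_errors,
                                              character(1),
                                              rate = config$error_rate,
                                              USE.NAMES = FALSE)
      out[[length(out) + 1L]] <- tibble(
        read_id = sprintf("%s:%d", contigs$contig[k], seq_len(n)),
        sequence = sq, quality = strrep("I", len),
        contig = contigs$contig[k], start = start, end = start + len,
        mate = 0L)
    }
    reads <- if (length(out)) bind_rows(out) else {
      tibble(read_id = character(), sequence = character(),
             quality = character(), contig = character(),
             start = integer(), end = integer(), mate = integer())
    }
    if (isTRUE(config$paired) && !ancient && nrow(reads)) {
      mates <- mutate(reads,
                      read_id = paste0(.data$read_id, "/2"),
                      sequence = vapply(.data$sequence, revcomp, character(1),
                                        USE.NAMES = FALSE),
                      mate = 2L)
      reads <- bind_rows(mutate(reads, read_id = paste0(.data$read_id, "/1"),
                                mate = 1L), mates)
    }
    class(reads) <- c("read_set", class(reads))
    reads
  })
}

add_read_errors <- function(s, rate) {
  v <- seq_to_int(s)
  hit <- which(runif(length(v)) < rate)
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(1:4, b), 1L), integer(1))
  }
  int_to_seq(v)
}

#' Write / read FASTQ
#'
#' Quality strings are the simulator's placeholder `"I"` run.
#'
#' @param reads A `read_set` (or tibble with `read_id`, `sequence`).
#' @param path File path.
#' @return `write_fastq()` returns `path` invisibly; `read_fastq()` returns
#'   a tibble with `read_id`, `sequence`, `quality`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qual <- reads$quality %||% strrep("I", nchar(reads$sequence))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(read_id = names(x), sequence = unname(as.character(x)),
         quality = unname(as.character(S4Vectors::mcols(x)$qualities)))
}
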