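family_with_loci <- function(seed, ...) {
  tr <- build_species_tree("paenungulata")
  h <- simulate_gene_family(tr, quick_config(seed = seed, ...))
  seqs <- evolve_sequences(h)
  list(history = h, seqs = seqs, genome = assemble_loci(h, seqs))
}

ungapped_identity <- function(a, b) {
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

test_that("zero flank drift gives identical flanks between relatives", {
  f <- family_with_loci(seed = 1, flank_drift = 0)
  loci <- dplyr::filter(f$genome, role == "retrogene", !is.na(parent_gene))
  expect_gt(nrow(loci), 0)
  for (k in seq_len(nrow(loci))) {
    parent <- dplyr::filter(f$genome, gene == loci$parent_gene[k])
    expect_equal(loci$flank_left[k], parent$flank_left[1])
    expect_equal(loci$flank_right[k], parent$flank_right[1])
  }
})

test_that("flank drift 0.1 yields about 90% sister-flank identity", {
  idents <- c()
  seed <- 0
  while (length(idents) < 50 && seed < 60) {
    seed <- seed + 1
    f <- family_with_loci(seed = seed, flank_drift = 0.1, flank_len = 300)
    loci <- dplyr::filter(f$genome, role == "retrogene", !is.na(parent_gene))
    for (k in seq_len(nrow(loci))) {
      parent <- dplyr::filter(f$genome, gene == loci$parent_gene[k])
      # only immediate sisters: exactly one drift application apart
      gt <- f$history$gene_tree$phylo
      pk <- retroexpand:::phylo_parents(gt)
      i <- match(loci$gene[k], gt$tip.label)
      j <- match(loci$parent_gene[k], gt$tip.label)
      same_species <- sub("\\|.*$", "", loci$gene[k]) ==
        sub("\\|.*$", "", loci$parent_gene[k])
      # true sisters within a species arise from one duplication (one drift)
      if (!is.na(i) && !is.na(j) && pk[i] == pk[j] && same_species) {
        idents <- c(idents, ungapped_identity(loci$flank_left[k],
                                              parent$flank_left[1]))
      }
    }
  }
  expect_gte(length(idents), 50)
  expect_lt(abs(mean(idents) - 0.9), 0.02)
})

test_that("independent retrocopies have background-level flank identity", {
  f <- family_with_loci(seed = 2, mechanism = "independent_retro")
  loci <- dplyr::filter(f$genome, role == "retrogene", !is.na(parent_gene))
  idents <- vapply(seq_len(nrow(loci)), function(k) {
    parent <- dplyr::filter(f$genome, gene == loci$parent_gene[k])
    ungapped_identity(loci$flank_left[k], parent$flank_left[1])
  }, numeric(1))
  expect_lt(mean(idents), 0.35)  # ~25% for uniform base composition
  expect_gt(mean(idents), 0.15)
})

test_that("the mechanism classifier separates segmental from independent", {
  seg <- family_with_loci(seed = 3, flank_drift = 0.05)
  calls <- classify_expansion_mechanism(seg$genome)
  expect_gt(nrow(calls), 0)
  expect_true(all(calls$mechanism == "segmental_duplication"))

  ind <- family_with_loci(seed = 3, mechanism = "independent_retro")
  calls2 <- classify_expansion_mechanism(ind$genome)
  expect_gt(nrow(calls2), 0)
  expect_true(all(calls2$mechanism == "independent_retrotransposition"))
})

test_that("read counts follow coverage and provenance is exact without errors", {
  f <- family_with_loci(seed = 4, error_rate = 0)
  genome <- f$genome

  cfg0 <- quick_config(seed = 4, coverage = 0)
  expect_equal(nrow(simulate_reads(genome, cfg0)), 0)

  cfg <- quick_config(seed = 4, coverage = 10, read_len = 80, error_rate = 0)
  total_len <- sum(nchar(genome$sequence))
  counts <- vapply(1:20, function(s) {
    nrow(simulate_reads(genome, quick_config(seed = s, coverage = 10,
                                             read_len = 80, error_rate = 0)))
  }, numeric(1))
  expected <- 10 * total_len / 80
  expect_lt(abs(mean(counts) - expected), 4 * sqrt(expected / 20))

  reads <- simulate_reads(genome, cfg)
  for (k in sample(nrow(reads), min(50, nrow(reads)))) {
    src <- genome$sequence[genome$contig == reads$contig[k]]
    expect_equal(reads$sequence[k],
                 substr(src, reads$start[k] + 1, reads$end[k]))
  }
})

test_that("the ancient profile draws short reads at low coverage", {
  f <- family_with_loci(seed = 5)
  cfg <- quick_config(seed = 5)
  anc <- simulate_reads(f$genome, cfg, ancient = TRUE)
  mod <- simulate_reads(f$genome, cfg)
  lens <- nchar(anc$sequence)
  expect_true(all(lens >= 40 & lens <= 100))
  expect_gt(length(unique(lens)), 1)
  expect_lt(nrow(anc), nrow(mod) / 4)  # 0.5x vs 5x
})

test_that("FASTQ output round-trips and paired mode emits mates", {
  f <- family_with_loci(seed = 6)
  reads <- simulate_reads(f$genome, quick_config(seed = 6, coverage = 1))
  tmp <- withr::local_tempfile(fileext = ".fq")
  write_fastq(reads, tmp)
  back <- read_fastq(tmp)
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$sequence, reads$sequence)
  expect_true(all(grepl("^I+$", back$quality)))

  paired <- simulate_reads(f$genome, quick_config(seed = 6, coverage = 1,
                                                  paired = TRUE))
  expect_setequal(unique(paired$mate), c(1L, 2L))
  one <- dplyr::filter(paired, mate == 1)[1, ]
  two <- dplyr::filter(paired, mate == 2,
                       read_id == sub("/1", "/2", one$read_id))
  expect_equal(two$sequence,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(one$sequence))))
})

test_that("reads longer than the shortest contig are rejected", {
  f <- family_with_loci(seed = 7)
  cfg <- quick_config(seed = 7, read_len = 10000)
  expect_error(simulate_reads(f$genome, cfg), "shortest contig")
})
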