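test_that("reciprocal best hits pair orthologs and report the unpaired", {
  a <- c(gA = "ATGGCATTAGCCTTAGACGAT")
  b <- c(gB = "ATGGCATTGGCCTTAGACGAT")
  one <- reciprocal_best_hit(a, b)
  expect_equal(nrow(dplyr::filter(one, paired)), 1)
  expect_equal(dplyr::filter(one, paired)$gene_b, "gB")

  # a 1:1 family of five with low drift pairs 5/5
  set.seed(21)
  fam <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""), "")
  drift <- vapply(fam, function(s) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(200, 6)
    v[idx] <- chartr("ACGT", "CATG", v[idx])
    paste(v, collapse = "")
  }, "", USE.NAMES = FALSE)
  ga <- setNames(fam, paste0("a", 1:5))
  gb <- setNames(drift, paste0("b", 1:5))
  rb <- reciprocal_best_hit(ga, gb)
  paired <- dplyr::filter(rb, paired)
  expect_equal(nrow(paired), 5)
  expect_equal(sub("b", "a", paired$gene_b), paired$gene_a)

  # an extra duplicate on one side stays unpaired
  ga2 <- c(ga, a6 = fam[1])
  rb2 <- reciprocal_best_hit(ga2, gb)
  expect_equal(sum(rb2$paired), 5)
  unpaired <- dplyr::filter(rb2, !paired, !is.na(gene_a))
  expect_equal(nrow(unpaired), 1)
  expect_true(unpaired$gene_a %in% c("a1", "a6"))
})

test_that("reciprocal best hits are symmetric under side swap", {
  set.seed(22)
  ga <- setNames(vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""), ""),
    paste0("x", 1:4))
  gb <- setNames(vapply(unname(ga), function(s) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(150, 5)
    v[idx] <- chartr("ACGT", "CATG", v[idx])
    paste(v, collapse = "")
  }, "", USE.NAMES = FALSE), paste0("y", 1:4))
  ab <- dplyr::filter(reciprocal_best_hit(ga, gb), paired)
  ba <- dplyr::filter(reciprocal_best_hit(gb, ga), paired)
  expect_setequal(paste(ab$gene_a, ab$gene_b),
                  paste(ba$gene_b, ba$gene_a))
  expect_error(reciprocal_best_hit(character(), gb), "at least one")
})

test_that("coding potential requires an ATG-initiated ORF of 25 aa", {
  r <- assess_coding_potential("ATGTAA")
  expect_false(r$coding)
  expect_true(is.na(r$orf_length))

  # ATG + 209 sense codons + stop: a 210-aa reading frame
  set.seed(30)
  codons <- replicate(209, {
    repeat {
      c0 <- paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")
      if (!c0 %in% c("TAA", "TAG", "TGA")) return(c0)
    }
  })
  orf <- paste0("ATG", paste(codons, collapse = ""), "TGA")
  expect_equal(nchar(orf), 633)
  r2 <- assess_coding_potential(orf)
  expect_true(r2$coding)
  expect_equal(r2$orf_length, 210L)

  r3 <- assess_coding_potential("CCCCCCTTTTTTCCC")  # no ATG anywhere
  expect_false(r3$coding)
  expect_error(assess_coding_potential(""), "length 0")
})

test_that("ORF length is additive under in-frame extension", {
  set.seed(31)
  mk <- function(n) {
    codons <- replicate(n, {
      repeat {
        c0 <- paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")
        if (!c0 %in% c("TAA", "TAG", "TGA")) return(c0)
      }
    })
    paste(codons, collapse = "")
  }
  body <- mk(40)
  for (k in c(1, 5, 12)) {
    base <- paste0("ATG", body, "TAA")
    ext <- paste0("ATG", body, mk(k), "TAA")
    expect_equal(assess_coding_potential(ext)$orf_length,
                 assess_coding_potential(base)$orf_length + k)
  }
})

test_that("repertoire summaries count flags and reject duplicate ids", {
  expect_equal(summarize_repertoire(tibble::tibble()),
               tibble::tibble(total = 0L, retrogenes = 0L,
                              coding_retrogenes = 0L))
  rec <- tibble::tibble(gene = c("g1", "g2", "g3"),
                        is_retrogene = c(FALSE, TRUE, TRUE),
                        coding = c(TRUE, TRUE, FALSE))
  expect_equal(summarize_repertoire(rec),
               tibble::tibble(total = 3L, retrogenes = 2L,
                              coding_retrogenes = 1L))
  expect_error(summarize_repertoire(rec[c(1, 1, 2), ]), "duplicate")
})

test_that("diagnostic indels are found only in the configured length band", {
  gap <- function(n) strrep("-", n)
  base <- strrep("ACGT", 20)  # 80 columns
  mk_msa <- function(gap_len, at = 30) {
    ing <- paste0(substr(base, 1, at), gap(gap_len),
                  substr(base, at + gap_len + 1, 80))
    c(in1 = ing, in2 = ing, out1 = base, out2 = base)
  }
  msa21 <- mk_msa(21)
  found <- find_diagnostic_indels(msa21, c("in1", "in2"), c("out1", "out2"))
  expect_equal(nrow(found), 1)
  expect_equal(found$length, 21)
  expect_equal(found$col_start, 31)
  expect_equal(found$ingroup_coverage, 1)

  # identical rows: nothing to report
  same <- c(in1 = base, out1 = base)
  expect_equal(nrow(find_diagnostic_indels(same, "in1", "out1")), 0)
  # 10-column gap is below the 15-column floor
  expect_equal(nrow(find_diagnostic_indels(mk_msa(10), c("in1", "in2"),
                                           c("out1", "out2"))), 0)
  expect_error(find_diagnostic_indels(c(a = "AC-", b = "ACGT"), "a", "b"),
               "ragged")
  expect_error(find_diagnostic_indels(msa21, c("in1", "out1"), c("out1")),
               "overlap")
})

test_that("indel discovery is invariant to row order and padding columns", {
  gap <- function(n) strrep("-", n)
  base <- strrep("GATTACA", 12)  # 84 columns
  ing <- paste0(substr(base, 1, 40), gap(18), substr(base, 59, 84))
  msa <- c(i1 = ing, i2 = ing, o1 = base)
  f1 <- find_diagnostic_indels(msa, c("i1", "i2"), "o1")
  f2 <- find_diagnostic_indels(msa[c(3, 1, 2)], c("i2", "i1"), "o1")
  expect_equal(f1, f2)
  # an all-gap column outside the block shifts coordinates but not content
  pad <- setNames(paste0("-", msa), names(msa))
  f3 <- find_diagnostic_indels(pad, c("i1", "i2"), "o1")
  expect_equal(f3$length, f1$length)
  expect_equal(f3$col_start, f1$col_start + 1)
})

test_that("amplicon prediction mirrors the diagnostic-deletion arithmetic", {
  set.seed(33)
  fwd <- "GGGGAAACTCCTTCCTGAGA"
  rev <- "CCAGACAGAAACGATAGGTG"
  mid <- paste(sample(c("A", "C", "G", "T"), 251 - 40, TRUE), collapse = "")
  site_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rev)))
  template <- paste0(
    paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""),
    fwd, mid, site_rev,
    paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = ""))
  expect_equal(nchar(template), 300)
  amp <- predict_amplicon(template, fwd, rev)
  expect_equal(amp$length, 251)

  # a 31-nt deletion strictly between the primer sites: 251 -> 220
  del_at <- 25 + 20 + 50
  template_del <- paste0(substr(template, 1, del_at),
                         substr(template, del_at + 32, 300))
  amp2 <- predict_amplicon(template_del, fwd, rev)
  expect_equal(amp2$length, 220)

  # absent primer site
  expect_equal(nrow(predict_amplicon(strrep("ACGT", 30), fwd, rev)), 0)
  # minimal template: amplicon is the sum of the primer lengths
  minimal <- paste0(fwd, site_rev)
  expect_equal(predict_amplicon(minimal, fwd, rev)$length, 40)
})

test_that("amplicons shrink by exactly the deleted length", {
  set.seed(34)
  fwd <- "ACGTACGTCC"
  rev <- "TTGGCCAACC"
  core <- paste(sample(c("A", "G"), 120, TRUE), collapse = "")
  template <- paste0(fwd, core, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(rev))))
  base_len <- predict_amplicon(template, fwd, rev)$length
  for (d in c(5, 17, 31)) {
    cut <- paste0(substr(template, 1, 30),
                  substr(template, 31 + d, nchar(template)))
    expect_equal(predict_amplicon(cut, fwd, rev)$length, base_len - d)
  }
})
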