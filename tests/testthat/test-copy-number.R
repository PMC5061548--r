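# two 120-nt paralogs identical except one diagnostic site at position 60
make_paralog_pair <- function() {
  set.seed(123)
  base <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  p2 <- base
  substr(p2, 60, 60) <- if (substr(base, 60, 60) == "A") "C" else "A"
  tibble::tibble(gene = c("p1", "p2"), sequence = c(base, p2))
}

test_that("reads are unique, ambiguous or unassigned as constructed", {
  refs <- make_paralog_pair()
  reads <- tibble::tibble(
    read_id = c("span_diag", "shared", "diverged"),
    sequence = c(substr(refs$sequence[1], 31, 90),   # covers the site
                 substr(refs$sequence[1], 61, 120),  # identical region
                 {
                   s <- substr(refs$sequence[1], 31, 90)
                   v <- strsplit(s, "")[[1]]
                   idx <- seq(2, 58, by = 7)  # 9/60 sites flipped: 85% identity
                   v[idx] <- chartr("ACGT", "CATG", v[idx])
                   paste(v, collapse = "")
                 }))
  asn <- assign_reads(reads, refs, min_identity = 90, min_aligned_len = 20)
  a <- asn$assignments
  expect_equal(a$status[a$read_id == "span_diag"], "unique")
  expect_equal(a$genes[a$read_id == "span_diag"][[1]], "p1")
  expect_equal(a$status[a$read_id == "shared"], "ambiguous")
  expect_setequal(a$genes[a$read_id == "shared"][[1]], c("p1", "p2"))
  expect_equal(a$status[a$read_id == "diverged"], "unassigned")

  expect_error(assign_reads(reads, refs, min_identity = 0), "\\(0, 100\\]")
  expect_error(assign_reads(reads, refs, min_identity = 120), "\\(0, 100\\]")
})

test_that("fractional ambiguous depth conserves total assigned depth", {
  refs <- make_paralog_pair()
  set.seed(5)
  starts <- sample(1:61, 40, TRUE)
  reads <- tibble::tibble(read_id = sprintf("r%d", 1:40),
                          sequence = substr(rep(refs$sequence[1], 40),
                                            starts, starts + 59))
  asn <- assign_reads(reads, refs, min_identity = 90)
  assigned <- dplyr::filter(asn$assignments, status != "unassigned")
  total_depth <- sum(vapply(asn$depth, sum, numeric(1)))
  expect_equal(total_depth, 60 * nrow(assigned))
})

test_that("breadth-based recovery thresholds behave as specified", {
  depth <- structure(list(
    covered = c(rep(2, 70), rep(0, 30)),     # 70% breadth
    sparse = c(rep(1, 40), rep(0, 60)),      # 40% breadth
    fractional = rep(0.5, 100)),             # never reaches depth 1
    class = "depth_profile")
  rec <- recovered_orthologs(depth, breadth_min = 0.5, depth_min = 1)
  expect_equal(rec$recovered, c(TRUE, FALSE, FALSE))
  rec2 <- recovered_orthologs(depth, breadth_min = 0.3, depth_min = 1)
  expect_equal(rec2$recovered, c(TRUE, TRUE, FALSE))
  expect_error(recovered_orthologs(depth, breadth_min = 0), "\\(0, 1\\]")
})

test_that("the depth ratio is ~1 for a single-copy family and errors without controls", {
  set.seed(31)
  depth <- structure(list(
    fam = rpois(500, 8) + 0.0,
    c1 = rpois(500, 8) + 0.0, c2 = rpois(500, 8) + 0.0),
    class = "depth_profile")
  est <- depth_copy_number(depth, "fam", c("c1", "c2"), n_boot = 500, seed = 1)
  expect_lt(abs(est$estimate - 1), 0.2)
  expect_lte(est$ci_low, 1)
  expect_gte(est$ci_high, 1)

  zero <- structure(list(fam = rep(1, 100), c1 = rep(0, 100)),
                    class = "depth_profile")
  expect_error(depth_copy_number(zero, "fam", "c1"), "zero control depth")
  expect_error(depth_copy_number(depth, "fam", character()), "control")
})

test_that("the bootstrap CI is deterministic given its seed", {
  set.seed(17)
  depth <- structure(list(fam = rpois(400, 5) + 0.0, c1 = rpois(400, 5) + 0.0),
                     class = "depth_profile")
  e1 <- depth_copy_number(depth, "fam", "c1", n_boot = 300, seed = 7)
  e2 <- depth_copy_number(depth, "fam", "c1", n_boot = 300, seed = 7)
  e3 <- depth_copy_number(depth, "fam", "c1", n_boot = 300, seed = 8)
  expect_identical(e1, e2)
  expect_false(identical(e1$ci_low, e3$ci_low))
})

test_that("a single-copy family yields the {1, ~1, 1} estimate triple", {
  set.seed(42)
  gseq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  ctls <- tibble::tibble(
    gene = paste0("ctl", 1:3),
    sequence = vapply(1:3, function(i)
      paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""), ""))
  genome <- dplyr::bind_rows(
    tibble::tibble(species = "X", contig = "g", gene = "fam1", role = "parent",
                   sequence = gseq),
    dplyr::mutate(ctls, species = "X", contig = gene, role = "control"))
  cfg <- quick_config(seed = 11, coverage = 8, error_rate = 0)
  reads <- simulate_reads(genome, cfg)
  rt <- dated_gene_tree(ape::read.tree(text = "(X|fam1:1,dummy|z:1);"),
                        origin_time = 2)
  est <- estimate_copy_number(
    reads, tibble::tibble(gene = "fam1", sequence = gseq), ctls,
    reference_tree = rt, split_time = 5, n_boot = 300, seed = 2)
  expect_equal(est$minimum, 1)
  expect_equal(est$maximum, 1)
  expect_lt(abs(est$average - 1), 0.25)
  expect_lte(est$ci[1], est$average)
  expect_gte(est$ci[2], est$average)
  td <- tidy(est)
  expect_equal(td$minimum, 1)
  expect_true(td$ci_low <= td$average & td$average <= td$ci_high)
})
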