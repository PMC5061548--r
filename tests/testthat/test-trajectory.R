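test_that("a single-copy family has a flat unit trajectory", {
  tr <- build_species_tree(spec = data.frame(
    label = c("R", "C", "S", "A", "B"),
    parent = c(NA, "R", "R", "S", "S"), age = c(30, 0, 10, 0, 0)))
  cfg <- sim_config(t_retro = 25, retro_lineage = "S", dup_clade = NULL,
                    dup_rate = data.frame(older = 40, younger = 0, rate = 0),
                    loss_rate = 0, seed = 1)
  h <- simulate_gene_family(tr, cfg)
  # one copy in A, one in B; restrict to A
  expect_false(is.null(h$gene_tree))
  ctt <- copies_through_time(h$gene_tree, "A", grid = seq(25, 0, by = -1))
  expect_true(all(ctt$copies == 1))
})

test_that("hand-placed duplications step the curve 1,2,3,4", {
  gt <- dated_gene_tree(
    ape::read.tree(text = "(((A|1:20,A|2:20):10,A|3:30):10,A|4:40);"),
    origin_time = 64)
  ctt <- copies_through_time(gt, "A", grid = c(50, 45, 40, 35, 30, 25, 20, 10, 0))
  expect_equal(ctt$copies, c(1, 1, 2, 2, 3, 3, 4, 4, 4))
})

test_that("N(0) matches the simulated extant copy count and losses shape truth", {
  tr <- build_species_tree("paenungulata")
  for (seed in c(3, 8, 21)) {
    h <- simulate_gene_family(tr, sim_config(seed = seed, loss_rate = 0.02))
    for (s in c("African_elephant", "mammoth")) {
      n_true <- h$true_copies$copies[h$true_copies$species == s]
      if (n_true == 0) next
      tip_age <- species_age(h$species_tree, s)
      ctt <- copies_through_time(h$gene_tree, s, grid = tip_age)
      expect_equal(ctt$copies, n_true, info = sprintf("seed %d %s", seed, s))
    }
  }
})

test_that("the curve is invariant to ladderization and leaf order", {
  gt_txt <- "(((A|1:20,A|2:20):10,A|3:30):10,A|4:40);"
  gt_txt2 <- "(A|4:40,(A|3:30,(A|2:20,A|1:20):10):10);"  # rotated
  g1 <- dated_gene_tree(ape::read.tree(text = gt_txt), origin_time = 64)
  g2 <- dated_gene_tree(ape::read.tree(text = gt_txt2), origin_time = 64)
  grid <- seq(60, 0, by = -2.5)
  expect_equal(copies_through_time(g1, "A", grid)$copies,
               copies_through_time(g2, "A", grid)$copies)
})

test_that("grids beyond the family origin are clamped with a warning", {
  gt <- dated_gene_tree(ape::read.tree(text = "(A|1:10,A|2:10);"),
                        origin_time = 15)
  expect_warning(ctt <- copies_through_time(gt, "A", grid = c(20, 12, 5)),
                 "clamp")
  expect_equal(ctt$time, c(12, 5))
  expect_error(copies_through_time(gt, "Z"), "no sampled copies")
})

test_that("identical series correlate perfectly; constant series error", {
  a <- tibble::tibble(time = seq(40, 0, by = -1), value = seq(1, 41))
  r <- correlate_series(a, a, interp_b = "step", n_perm = 200, seed = 1)
  expect_equal(r$estimate, 1)
  const <- tibble::tibble(time = seq(40, 0, by = -1), value = rep(2, 41))
  expect_error(correlate_series(a, const, n_perm = 50), "constant")
  short <- tibble::tibble(time = c(5, 4), value = c(1, 2))
  expect_error(correlate_series(short, short, grid = c(5, 4)), "3 common grid")
})

test_that("circular-shift p-values are calibrated on independent noise", {
  set.seed(2024)
  pvals <- vapply(1:200, function(i) {
    a <- tibble::tibble(time = seq(30, 0, by = -1), value = rnorm(31))
    b <- tibble::tibble(time = seq(30, 0, by = -1), value = rnorm(31))
    correlate_series(a, b, interp_a = "linear", interp_b = "linear",
                     n_perm = 199, seed = i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the body-size fixture rises monotonically toward the present", {
  bs <- body_size_series("proboscidea_fixture")
  expect_true(all(diff(bs$value) > 0))  # ordered old -> young
  expect_true(all(diff(bs$time) < 0))
  expect_error(body_size_series(tibble::tibble(time = numeric(),
                                               value = numeric())), "empty")
  expect_error(body_size_series(tibble::tibble(time = c(1, 1),
                                               value = c(2, 3))), "duplicate")
  one <- body_size_series(tibble::tibble(time = 5, value = 100))
  expect_equal(nrow(one), 1)
})
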