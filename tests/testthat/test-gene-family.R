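two_taxon_tree <- function(split = 70) {
  build_species_tree(spec = data.frame(
    label = c("R", "A", "B"), parent = c(NA, "R", "R"),
    age = c(split, 0, 0)))
}

test_that("with no duplication or loss every descendant gets one copy", {
  tr <- build_species_tree("paenungulata")
  cfg <- sim_config(dup_rate = data.frame(older = 40, younger = 0, rate = 0),
                    loss_rate = 0, seed = 3)
  h <- simulate_gene_family(tr, cfg)
  desc <- c("hyrax", "manatee", "mastodon", "African_elephant",
            "Asian_elephant", "mammoth")
  got <- setNames(h$true_copies$copies, h$true_copies$species)
  expect_equal(unname(got[desc]), rep(1L, 6))
  expect_equal(unname(got["outgroup"]), 0L)
  expect_equal(sum(h$events$type == "retrotransposition"), 1L)
  expect_equal(sum(h$events$type == "duplication"), 0L)
})

test_that("the quiescent interval contains no duplication events", {
  tr <- build_species_tree("paenungulata")
  for (seed in 1:10) {
    h <- simulate_gene_family(tr, sim_config(seed = seed))
    dups <- dplyr::filter(h$events, type == "duplication")
    expect_true(all(dups$time <= 40), info = paste("seed", seed))
    expect_true(all(dups$time < h$config$t_retro))
  }
})

test_that("pure-birth mean copy number matches the analytic expectation", {
  # one lineage, rate r on (40, 0]: E[N] = exp(r * 40)
  tr <- two_taxon_tree(70)
  r <- log(19) / 40
  n_rep <- 2000
  copies <- vapply(seq_len(n_rep), function(s) {
    h <- simulate_gene_family(tr, sim_config(
      t_retro = 64, retro_lineage = "A", dup_clade = NULL,
      dup_rate = data.frame(older = 40, younger = 0, rate = r),
      loss_rate = 0, seed = s))
    h$true_copies$copies[h$true_copies$species == "A"]
  }, integer(1))
  expected <- exp(r * 40)
  se <- sd(copies) / sqrt(n_rep)
  expect_lt(abs(mean(copies) - expected), 3 * se + 1e-9)
  # the sibling species holds no copies: the event sits on A's own branch
  expect_true(all(vapply(1:20, function(s) {
    h <- simulate_gene_family(tr, sim_config(
      t_retro = 64, retro_lineage = "A", dup_clade = NULL,
      dup_rate = data.frame(older = 40, younger = 0, rate = 0),
      loss_rate = 0, seed = s))
    h$true_copies$copies[h$true_copies$species == "B"] == 0L
  }, logical(1))))
})

test_that("copies, duplications and losses balance along each species path", {
  tr <- build_species_tree("paenungulata")
  for (seed in 1:15) {
    h <- simulate_gene_family(tr, sim_config(loss_rate = 0.02, seed = seed))
    for (s in c("African_elephant", "Asian_elephant", "mastodon")) {
      path <- retroexpand:::species_path(h, s)
      ev <- dplyr::filter(h$events, lineage %in% path)
      # events on shared branches count once per species path
      n_dup <- sum(ev$type == "duplication")
      n_loss <- sum(ev$type == "loss")
      copies <- h$true_copies$copies[h$true_copies$species == s]
      expect_equal(copies, 1L + n_dup - n_loss,
                   info = sprintf("seed %d species %s", seed, s))
    }
  }
})

test_that("identical config and seed reproduce the history byte-for-byte", {
  tr <- build_species_tree("paenungulata")
  h1 <- simulate_gene_family(tr, sim_config(seed = 42, loss_rate = 0.01))
  h2 <- simulate_gene_family(tr, sim_config(seed = 42, loss_rate = 0.01))
  expect_identical(h1$events, h2$events)
  expect_identical(ape::write.tree(h1$gene_tree$phylo),
                   ape::write.tree(h2$gene_tree$phylo))
  h3 <- simulate_gene_family(tr, sim_config(seed = 43, loss_rate = 0.01))
  expect_false(identical(h1$events, h3$events))
})

test_that("truth-side copies-through-time steps at event ages and hits N(0)", {
  tr <- build_species_tree("paenungulata")
  for (seed in c(2, 5, 9)) {
    h <- simulate_gene_family(tr, sim_config(loss_rate = 0.03, seed = seed))
    s <- "African_elephant"
    truth <- true_copies_through_time(h, s, grid = 0)
    expect_equal(truth$copies,
                 h$true_copies$copies[h$true_copies$species == s])
    # +1 at each duplication age, -1 at each loss age on the focal path
    path <- retroexpand:::species_path(h, s)
    ev <- dplyr::filter(h$events, lineage %in% path,
                        type %in% c("duplication", "loss"))
    for (k in seq_len(nrow(ev))) {
      t <- ev$time[k]
      before <- true_copies_through_time(h, s, t + 1e-9)$copies
      after <- true_copies_through_time(h, s, t)$copies
      step <- if (ev$type[k] == "duplication") 1L else -1L
      others <- sum(ev$time == t) - 1L  # coincident events (measure zero)
      if (others == 0L) {
        expect_equal(after - before, step,
                     info = sprintf("seed %d %s at %.3f", seed, ev$type[k], t))
      }
    }
  }
})

test_that("simulation preconditions are enforced", {
  tr <- build_species_tree("paenungulata")
  expect_error(sim_config(dup_rate = data.frame(older = 40, younger = 0,
                                                rate = -1)), ">= 0")
  expect_error(simulate_gene_family(tr, sim_config(t_retro = 90)), "stem")
  expect_error(simulate_gene_family(tr, sim_config(retro_lineage = "yeti")),
               "not in species tree")
  expect_error(sim_config(deletion_len = 40), "\\[15, 30\\]")
  expect_error(sim_config(deletion_len = 10), "\\[15, 30\\]")
})
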