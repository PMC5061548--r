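#' Simulate a retrogene family history along a dated species tree
#'
#' One retrotransposition event seeds a gene lineage on a species-tree
#' branch; the lineage then follows the species tree, splitting at
#' speciations, duplicating as a Poisson process with the piecewise-constant
#' rate `config$dup_rate` (optionally restricted to a clade) and dying at
#' rate `config$loss_rate`. The full event list is retained as ground truth;
#' the dated gene tree of the surviving (sampled) copies is returned with a
#' `"species|copy"` leaf map.
#'
#' @param species_tree A [build_species_tree()] object.
#' @param config A [sim_config()].
#' @return An object of class `gene_family_history` with elements `events`
#'   (tibble: type, time, lineage, gene_node), `nodes` (full truth table,
#'   including lost lineages), `gene_tree` (a `dated_gene_tree`, or `NULL`
#'   when fewer than two copies survive), `true_copies` (tibble: species,
#'   copies) and the inputs.
#' @examples
#' tr <- build_species_tree("paenungulata")
#' h <- simulate_gene_family(tr, sim_config(seed = 7))
#' h$true_copies
#' @export
simulate_gene_family <- function(species_tree, config) {
  stopifnot(inherits(species_tree, "species_tree"), inherits(config, "sim_config"))
  sp <- species_tree$nodes
  ri <- match(config$retro_lineage, sp$label)
  if (is.na(ri)) abort(sprintf("retro lineage '%s' not in species tree",
                               config$retro_lineage))
  if (is.na(sp$parent[ri])) abort("retro lineage cannot be the species-tree root")
  top_age <- sp$age[match(sp$parent[ri], sp$label)]
  if (config$t_retro >= top_age || config$t_retro <= sp$age[ri]) {
    abort(sprintf("t_retro must lie on the %s stem branch (%.2f, %.2f)",
                  config$retro_lineage, sp$age[ri], top_age))
  }

  sp_children <- split(sp$label, factor(sp$parent, levels = sp$label))
  sp_age <- setNames(sp$age, sp$label)
  sp_is_tip <- setNames(sp$is_tip, sp$label)
  in_clade <- setNames(
    species_in_clade(species_tree, sp$label, config$dup_clade), sp$label)

  env <- new.env(parent = emptyenv())
  env$id <- integer(); env$parent <- integer(); env$age <- numeric()
  env$type <- character(); env$species <- character()
  env$ev_type <- character(); env$ev_time <- numeric()
  env$ev_lineage <- character(); env$ev_node <- integer()

  new_node <- function(parent, age, type, species) {
    k <- length(env$id) + 1L
    env$id[k] <- k; env$parent[k] <- parent; env$age[k] <- age
    env$type[k] <- type; env$species[k] <- species
    k
  }
  new_event <- function(type, time, lineage, node) {
    k <- length(env$ev_type) + 1L
    env$ev_type[k] <- type; env$ev_time[k] <- time
    env$ev_lineage[k] <- lineage; env$ev_node[k] <- node
  }

  mu <- config$loss_rate
  sim_lineage <- function(parent_id, t_from, sp_label) {
    bottom <- sp_age[[sp_label]]
    lam_on <- in_clade[[sp_label]]
    breaks <- rate_breaks(config, t_from, bottom)
    for (k in seq_len(length(breaks) - 1L)) {
      seg_from <- breaks[k]; seg_to <- breaks[k + 1L]
      lam <- if (lam_on) dup_rate_at(config, (seg_from + seg_to) / 2) else 0
      tot <- lam + mu
      t <- seg_from
      while (tot > 0) {
        t_event <- t - rexp(1L, tot)
        if (t_event <= seg_to) break
        if (runif(1L) < lam / tot) {
          node <- new_node(parent_id, t_event, "dup", sp_label)
          new_event("duplication", t_event, sp_label, node)
          sim_lineage(node, t_event, sp_label)
          sim_lineage(node, t_event, sp_label)
          return(invisible(NULL))
        } else {
          node <- new_node(parent_id, t_event, "loss", sp_label)
          new_event("loss", t_event, sp_label, node)
          return(invisible(NULL))
        }
      }
    }
    # reached the bottom of the species branch
    if (sp_is_tip[[sp_label]]) {
      new_node(parent_id, bottom, "tip", sp_label)
    } else {
      node <- new_node(parent_id, bottom, "spec", sp_label)
      for (child in sp_children[[sp_label]]) {
        sim_lineage(node, bottom, child)
      }
    }
    invisible(NULL)
  }

  with_seed(derive_seed(config$seed, "gene_family"), {
    root <- new_node(NA_integer_, config$t_retro, "retro", config$retro_lineage)
    new_event("retrotransposition", config$t_retro, config$retro_lineage, root)
    sim_lineage(root, config$t_retro, config$retro_lineage)
  })

  nodes <- tibble(id = env$id, parent = env$parent, age = env$age,
                  type = env$type, species = env$species)
  events <- tibble(type = env$ev_type, time = env$ev_time,
                   lineage = env$ev_lineage, gene_node = env$ev_node) |>
    arrange(dplyr::desc(.data$time))

  # survivors: nodes with at least one sampled tip below (ids are in preorder)
  surv <- nodes$type == "tip"
  for (k in rev(seq_len(nrow(nodes)))) {
    if (surv[k] && !is.na(nodes$parent[k])) surv[nodes$parent[k]] <- TRUE
  }
  nodes$surviving <- surv

  kids <- split(nodes$id[surv & !is.na(nodes$parent)],
                factor(nodes$parent[surv & !is.na(nodes$parent)],
                       levels = nodes$id))
  collapse <- function(id) {
    repeat {
      ch <- kids[[id]]
      if (length(ch) != 1L) return(id)
      id <- ch
    }
  }

  sp_counter <- new.env(parent = emptyenv())
  copy_label <- function(species) {
    k <- (get0(species, envir = sp_counter, ifnotfound = 0L)) + 1L
    assign(species, k, envir = sp_counter)
    sprintf("%s|RTG%d", species, k)
  }

  tip_ids <- nodes$id[nodes$type == "tip"]
  gene_tree <- NULL
  copy_map <- tibble(tip = character(), species = character(),
                     gene_node = integer())
  if (length(tip_ids) >= 2L) {
    out <- list()
    walk <- function(id, parent_out) {
      id <- collapse(id)
      if (nodes$type[id] == "tip") {
        lab <- copy_label(nodes$species[id])
        copy_map <<- bind_rows(copy_map,
          tibble(tip = lab, species = nodes$species[id], gene_node = id))
        out[[length(out) + 1L]] <<- tibble(
          id = id, parent = parent_out, age = nodes$age[id], label = lab,
          is_tip = TRUE)
      } else {
        out[[length(out) + 1L]] <<- tibble(
          id = id, parent = parent_out, age = nodes$age[id],
          label = sprintf("n%d", id), is_tip = FALSE)
        for (ch in kids[[id]]) walk(ch, id)
      }
      id
    }
    root_eff <- walk(collapse(1L), NA_integer_)
    ptab <- bind_rows(out)
    built <- phylo_from_nodes(ptab)
    built$phylo$root.edge <- config$t_retro - nodes$age[root_eff]
    gene_tree <- dated_gene_tree(
      built$phylo,
      leaf_map = select(copy_map, "tip", "species"),
      tip_ages = built$ages[seq_len(sum(ptab$is_tip))],
      origin_time = config$t_retro)
    gene_tree$ages <- built$ages
  } else if (length(tip_ids) == 1L) {
    copy_map <- tibble(tip = copy_label(nodes$species[tip_ids]),
                       species = nodes$species[tip_ids], gene_node = tip_ids)
  }

  true_copies <- tibble(species = sp$label[sp$is_tip]) |>
    left_join(count(copy_map, .data$species, name = "copies"),
              by = "species") |>
    mutate(copies = dplyr::coalesce(.data$copies, 0L))

  structure(list(events = events, nodes = nodes, gene_tree = gene_tree,
                 copy_map = copy_map, true_copies = true_copies,
                 species_tree = species_tree, config = config),
            class = "gene_family_history")
}

#' @export
print.gene_family_history <- function(x, ...) {
  cat(sprintf("<gene_family_history> %d events; sampled copies: %s\n",
              nrow(x$events),
              paste(sprintf("%s=%d", x$true_copies$species,
                            x$true_copies$copies), collapse = " ")))
  invisible(x)
}

# species-tree branch labels on the path from the retro lineage down to tip s
species_path <- function(history, s) {
  sp <- history$species_tree$nodes
  path <- character()
  lab <- s
  repeat {
    path <- c(path, lab)
    if (lab == history$config$retro_lineage) break
    lab <- sp$parent[match(lab, sp$label)]
    if (is.na(lab)) abort(sprintf("'%s' does not descend from the retro lineage", s))
  }
  path
}

#' True copies-through-time of a simulated history
#'
#' Ground-truth lineage count toward one species, including lineages that
#' are later lost: the count steps up by one at each duplication on the
#' focal species path and down by one at each loss (right-continuous toward
#' the present).
#'
#' @param history A [simulate_gene_family()] result.
#' @param species A species-tree tip label.
#' @param grid Numeric vector of ages (MY BP).
#' @return A tibble with columns `time`, `copies`.
#' @export
true_copies_through_time <- function(history, species, grid) {
  path <- species_path(history, species)
  nd <- history$nodes
  on_path <- nd$species %in% path & !is.na(nd$parent)
  a_par <- nd$age[nd$parent[on_path]]
  a_chl <- nd$age[on_path]
  is_tip <- nd$type[on_path] == "tip"
  copies <- vapply(grid, function(t) {
    sum(a_par >= t & (t > a_chl | (is_tip & t >= a_chl)))
  }, numeric(1))
  copies[grid > history$config$t_retro] <- 0
  tibble(time = grid, copies = copies)
}
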