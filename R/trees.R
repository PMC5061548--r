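# Shared helpers for rooted, dated (node-age) trees built on ape::phylo.
# Ages are in million years before present (MY BP); present = 0. Branch
# lengths are parent age minus child age, so extinct tips simply end early.

# Build an ape phylo (plus per-index age vector) from a parent-pointer node
# table with columns: id, parent (NA for root), age, label, is_tip (logical).
# Internal nodes are numbered in preorder so the result is cladewise.
phylo_from_nodes <- function(nodes) {
  stopifnot(all(c("id", "parent", "age", "label", "is_tip") %in% names(nodes)))
  root <- nodes$id[is.na(nodes$parent)]
  if (length(root) != 1L) abort("tree must have exactly one root")
  kids <- split(nodes$id, factor(nodes$parent, levels = nodes$id))
  tips <- nodes$id[nodes$is_tip]
  n_tip <- length(tips)
  if (n_tip == 1L) abort("a phylo needs at least two tips")
  bad <- !nodes$is_tip & lengths(kids)[as.character(nodes$id)] != 2L
  if (any(bad)) abort("internal nodes must be binary")

  tip_index <- setNames(seq_len(n_tip), tips)
  idx <- integer(nrow(nodes))
  names(idx) <- as.character(nodes$id)
  next_internal <- n_tip + 1L
  edge <- matrix(0L, nrow(nodes) - 1L, 2L)
  elen <- numeric(nrow(nodes) - 1L)
  e <- 0L
  age_by_id <- setNames(nodes$age, as.character(nodes$id))
  is_tip_by_id <- setNames(nodes$is_tip, as.character(nodes$id))

  assign_idx <- function(id) {
    key <- as.character(id)
    if (is_tip_by_id[[key]]) tip_index[[key]] else {
      v <- next_internal
      next_internal <<- next_internal + 1L
      v
    }
  }
  # iterative preorder
  stack <- list(root)
  idx[as.character(root)] <- assign_idx(root)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (child in kids[[as.character(node)]]) {
      idx[as.character(child)] <- assign_idx(child)
      e <- e + 1L
      edge[e, ] <- c(idx[[as.character(node)]], idx[[as.character(child)]])
      elen[e] <- age_by_id[[as.character(node)]] - age_by_id[[as.character(child)]]
      if (elen[e] < 0) abort("child node older than its parent")
      if (!is_tip_by_id[[as.character(child)]]) {
        stack[[length(stack) + 1L]] <- child
      }
    }
  }

  labels <- setNames(nodes$label, as.character(nodes$id))
  tip_lab <- character(n_tip)
  node_lab <- character(next_internal - n_tip - 1L)
  ages <- numeric(next_internal - 1L)
  for (key in names(idx)) {
    i <- idx[[key]]
    ages[i] <- age_by_id[[key]]
    if (i <= n_tip) tip_lab[i] <- labels[[key]] else node_lab[i - n_tip] <- labels[[key]]
  }
  phy <- structure(list(edge = edge, edge.length = elen, Nnode = next_internal - n_tip - 1L,
                        tip.label = tip_lab, node.label = node_lab),
                   class = "phylo", order = "cladewise")
  list(phylo = phy, ages = ages)
}

# children lists indexed by phylo node number
phylo_children <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  kids <- vector("list", n)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]
    kids[[p]] <- c(kids[[p]], phy$edge[e, 2L])
  }
  kids
}

phylo_parents <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  par <- rep(NA_integer_, n)
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  par
}

phylo_root <- function(phy) {
  setdiff(unique(phy$edge[, 1L]), phy$edge[, 2L])[1L]
}

# node ages from branch lengths, anchoring the deepest tip at `min_tip_age`
phylo_node_ages <- function(phy, tip_ages = NULL) {
  depth <- ape::node.depth.edgelength(phy)
  n_tip <- length(phy$tip.label)
  root_age <- if (is.null(tip_ages)) {
    max(depth[seq_len(n_tip)])
  } else {
    ta <- rep_len(tip_ages, n_tip)
    max(depth[seq_len(n_tip)] + ta)
  }
  root_age - depth
}

# postorder node sequence (children before parents)
phylo_postorder <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  unique(c(po$edge[, 2L], po$edge[, 1L]))
}

#' Construct a dated gene tree
#'
#' Wraps a rooted binary `ape::phylo` with node ages (MY before present) and
#' a leaf-to-species map, the form consumed by [reconcile_lca()] and
#' [copies_through_time()]. When `leaf_map` is omitted, tip labels of the
#' form `"species|copy"` are parsed.
#'
#' @param phylo A rooted binary `ape::phylo` with branch lengths in MY.
#' @param leaf_map Optional tibble with columns `tip`, `species`.
#' @param tip_ages Tip ages in MY BP (scalar or per tip, default 0).
#' @param origin_time Optional age at which the family originated (the
#'   retrotransposition time); defaults to the root age plus any root edge.
#' @return An object of class `dated_gene_tree`.
#' @export
dated_gene_tree <- function(phylo, leaf_map = NULL, tip_ages = 0,
                            origin_time = NULL) {
  if (!inherits(phylo, "phylo")) abort("`phylo` must be an ape phylo")
  ages <- phylo_node_ages(phylo, tip_ages)
  if (is.null(leaf_map)) {
    sp <- sub("\\|.*$", "", phylo$tip.label)
    leaf_map <- tibble(tip = phylo$tip.label, species = sp)
  }
  root_age <- ages[phylo_root(phylo)]
  origin <- origin_time %||% (root_age + (phylo$root.edge %||% 0))
  structure(list(phylo = phylo, ages = ages, leaf_map = leaf_map,
                 root_age = root_age, origin_time = origin),
            class = "dated_gene_tree")
}

#' @export
print.dated_gene_tree <- function(x, ...) {
  cat(sprintf("<dated_gene_tree> %d copies in %d species; root %.2f MY, origin %.2f MY\n",
              length(x$phylo$tip.label), length(unique(x$leaf_map$species)),
              x$root_age, x$origin_time))
  invisible(x)
}

#' @export
as_tibble.dated_gene_tree <- function(x, ...) {
  phy <- x$phylo
  n_tip <- length(phy$tip.label)
  par <- phylo_parents(phy)
  tibble(
    node = seq_along(x$ages),
    label = c(phy$tip.label, phy$node.label %||% rep("", phy$Nnode)),
    parent = par,
    age = x$ages,
    is_tip = seq_along(x$ages) <= n_tip
  )
}

#' Write / read a dated gene tree as newick
#'
#' Branch lengths carry MY; the leaf map is encoded in the
#' `"species|copy"` tip-label convention.
#'
#' @param tree A `dated_gene_tree`.
#' @param path File path.
#' @return `write_gene_tree()` returns `path` invisibly; `read_gene_tree()`
#'   returns a `dated_gene_tree`.
#' @export
write_gene_tree <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' @rdname write_gene_tree
#' @param tip_ages Tip ages in MY BP used to anchor node ages when reading.
#' @export
read_gene_tree <- function(path, tip_ages = 0) {
  dated_gene_tree(ape::read.tree(path), tip_ages = tip_ages)
}
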