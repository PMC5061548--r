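#' Reconcile a gene tree with a species tree by LCA mapping
#'
#' The most-parsimonious duplication-loss reconciliation of a rooted binary
#' gene tree against a rooted binary species tree: each gene leaf maps to
#' its species, each internal gene node to the LCA of its children's
#' mappings; a node is a duplication exactly when its mapping equals one of
#' its children's mappings. Losses are read off the mapping gaps along each
#' gene-tree edge and attributed to the species branch that lost the
#' lineage.
#'
#' @param gene_tree A `dated_gene_tree` or `ape::phylo` (rooted, binary).
#' @param species_tree A [build_species_tree()] object or `ape::phylo`.
#' @param leaf_map Tibble `tip`, `species`; defaults to the gene tree's own
#'   map (or `"species|copy"` tip labels).
#' @return A `reconciliation` object: `mapping` (tibble: `gene_node`,
#'   `label`, `species`, `is_duplication`), `losses` (tibble:
#'   `species_branch`, `n`), `n_duplications`, `n_losses`.
#' @examples
#' gt <- ape::read.tree(text = "((A|1:5,B|1:5):5,(A|2:5,B|2:5):5);")
#' st <- build_species_tree(spec = data.frame(
#'   label = c("R", "A", "B"), parent = c(NA, "R", "R"), age = c(5, 0, 0)))
#' reconcile_lca(dated_gene_tree(gt), st)$n_duplications
#' @export
reconcile_lca <- function(gene_tree, species_tree, leaf_map = NULL) {
  gphy <- if (inherits(gene_tree, "dated_gene_tree")) gene_tree$phylo else gene_tree
  sphy <- if (inherits(species_tree, "species_tree")) species_tree$phylo
          else species_tree
  binary_rooted <- function(p) {
    length(p$tip.label) >= 2L && max(tabulate(p$edge[, 1L])) <= 2L &&
      p$Nnode == length(p$tip.label) - 1L
  }
  if (!binary_rooted(gphy) || !binary_rooted(sphy)) {
    abort("both trees must be rooted and binary (resolve upstream)")
  }
  if (is.null(leaf_map)) {
    leaf_map <- if (inherits(gene_tree, "dated_gene_tree")) gene_tree$leaf_map
                else tibble(tip = gphy$tip.label,
                            species = sub("\\|.*$", "", gphy$tip.label))
  }
  sp_labels <- c(sphy$tip.label, sphy$node.label %||%
                   sprintf("node%d", seq_len(sphy$Nnode)))
  if (is.null(sphy$node.label) || !all(nzchar(sphy$node.label))) {
    blank <- which(!nzchar(sp_labels))
    sp_labels[blank] <- sprintf("node%d", blank)
  }
  spar <- phylo_parents(sphy)
  sdepth <- integer(length(sp_labels))
  ord <- phylo_postorder(sphy)
  for (v in rev(ord)) {
    sdepth[v] <- if (is.na(spar[v])) 0L else sdepth[spar[v]] + 1L
  }
  s_lca <- function(u, v) {
    while (u != v) {
      if (sdepth[u] < sdepth[v]) v <- spar[v] else u <- spar[u]
    }
    u
  }

  n_tip <- length(gphy$tip.label)
  mapped <- leaf_map$species[match(gphy$tip.label, leaf_map$tip)]
  if (anyNA(mapped)) {
    abort(sprintf("unmapped gene leaves: %s",
                  paste(gphy$tip.label[is.na(mapped)], collapse = ", ")))
  }
  sp_idx <- match(mapped, sphy$tip.label)
  if (anyNA(sp_idx)) {
    abort(sprintf("leaf map points to unknown species: %s",
                  paste(unique(mapped[is.na(sp_idx)]), collapse = ", ")))
  }

  gkids <- phylo_children(gphy)
  M <- integer(n_tip + gphy$Nnode)
  M[seq_len(n_tip)] <- sp_idx
  is_dup <- logical(length(M))
  for (v in phylo_postorder(gphy)) {
    if (v > n_tip) {
      ch <- gkids[[v]]
      M[v] <- s_lca(M[ch[1]], M[ch[2]])
      is_dup[v] <- M[v] == M[ch[1]] || M[v] == M[ch[2]]
    }
  }

  # losses: walk each gene edge's species path; every bypassed sibling
  # branch (plus the entry branch under a duplication) lost the lineage
  loss_branches <- character()
  skids <- phylo_children(sphy)
  for (e in seq_len(nrow(gphy$edge))) {
    u <- gphy$edge[e, 1L]; v <- gphy$edge[e, 2L]
    path <- integer()
    s <- M[v]
    while (s != M[u]) {
      path <- c(path, s)
      s <- spar[s]
      if (is.na(s)) abort("leaf map inconsistent with species tree")
    }
    # path is M[v] .. child-of-M[u]; siblings of all but the entry step are
    # lost; under a duplication the entry step's sibling is lost too
    drop_top <- if (is_dup[u]) 0L else 1L
    steps <- rev(path)  # from just under M[u] down to M[v]
    if (length(steps) > drop_top) {
      for (k in seq.int(drop_top + 1L, length(steps))) {
        parent_sp <- if (k == 1L) M[u] else steps[k - 1L]
        sib <- setdiff(skids[[parent_sp]], steps[k])
        loss_branches <- c(loss_branches, sp_labels[sib])
      }
    }
  }

  losses <- if (length(loss_branches)) {
    count(tibble(species_branch = loss_branches), .data$species_branch, name = "n")
  } else {
    tibble(species_branch = character(), n = integer())
  }
  gene_labels <- c(gphy$tip.label,
                   gphy$node.label %||% sprintf("g%d", seq_len(gphy$Nnode)))
  structure(list(
    mapping = tibble(gene_node = seq_along(M), label = gene_labels,
                     species = sp_labels[M], is_duplication = is_dup),
    losses = losses,
    n_duplications = sum(is_dup),
    n_losses = sum(losses$n)),
    class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation> %d duplications, %d losses\n",
              x$n_duplications, x$n_losses))
  invisible(x)
}
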