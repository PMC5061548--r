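#' Build a dated species tree
#'
#' Either from a node table (`spec`) giving labels, parent pointers and node
#' ages in MY before present, or from the packaged `"paenungulata"` preset:
#' African and Asian elephants, woolly/Columbian-style mammoth, American
#' mastodon, rock hyrax, West Indian manatee and an afrotherian outgroup,
#' with the Paenungulata crown at 64.2 MY, the mastodon-elephant split at
#' 25 MY and the African-(Asian elephant/mammoth) split at 8 MY.
#'
#' @param preset Name of a packaged tree; currently `"paenungulata"`.
#' @param spec A data frame with columns `label`, `parent` (label, `NA` for
#'   the root) and `age` (MY BP). Tips are rows never used as a parent; tips
#'   with age 0 are flagged extant.
#' @return An object of class `species_tree`: a dated, rooted, binary tree.
#' @examples
#' tr <- build_species_tree("paenungulata")
#' species_age(tr, "Paenungulata")
#' @export
build_species_tree <- function(preset = NULL, spec = NULL) {
  if (is.null(preset) == is.null(spec)) {
    abort("supply exactly one of `preset` or `spec`")
  }
  if (!is.null(preset)) {
    if (!identical(preset, "paenungulata")) {
      abort(sprintf("unknown preset '%s'", preset))
    }
    spec <- paenungulata_spec()
  }
  spec <- as_tibble(spec)
  stopifnot(all(c("label", "parent", "age") %in% names(spec)))
  if (anyDuplicated(spec$label)) abort("duplicate node labels in species tree spec")
  if (sum(is.na(spec$parent)) != 1L) abort("species tree must have exactly one root")
  if (any(spec$age < 0)) abort("node ages must be >= 0 MY BP")
  page <- spec$age[match(spec$parent, spec$label)]
  bad <- !is.na(page) & page <= spec$age
  if (any(bad)) {
    abort(sprintf("child node(s) as old as or older than their parent: %s",
                  paste(spec$label[bad], collapse = ", ")))
  }
  nodes <- spec |>
    mutate(id = .data$label,
           is_tip = !(.data$label %in% stats::na.omit(spec$parent)))
  built <- phylo_from_nodes(nodes)
  extant <- setNames(nodes$age[nodes$is_tip] == 0, nodes$label[nodes$is_tip])
  extant <- extant[built$phylo$tip.label]
  structure(list(phylo = built$phylo, ages = built$ages,
                 nodes = select(nodes, "label", "parent", "age", "is_tip"),
                 extant = extant),
            class = "species_tree")
}

paenungulata_spec <- function() {
  tibble::tribble(
    ~label,             ~parent,            ~age,
    "Root",             NA,                 80,
    "outgroup",         "Root",             0,
    "Paenungulata",     "Root",             64.2,
    "hyrax",            "Paenungulata",     0,
    "Tethytheria",      "Paenungulata",     60,
    "manatee",          "Tethytheria",      0,
    "Proboscidea",      "Tethytheria",      25,
    "mastodon",         "Proboscidea",      0.09,
    "Elephantidae",     "Proboscidea",      8,
    "African_elephant", "Elephantidae",     0,
    "Elephantina",      "Elephantidae",     6.7,
    "Asian_elephant",   "Elephantina",      0,
    "mammoth",          "Elephantina",      0.011
  )
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("<species_tree> %d tips (%d extant), root age %.2f MY\n",
              length(x$phylo$tip.label), sum(x$extant),
              max(x$ages)))
  invisible(x)
}

#' @export
as_tibble.species_tree <- function(x, ...) x$nodes

#' Age of a named node of a species tree
#'
#' @param tree A `species_tree`.
#' @param label A tip or internal node label.
#' @return Age in MY before present.
#' @export
species_age <- function(tree, label) {
  i <- match(label, tree$nodes$label)
  if (anyNA(i)) abort(sprintf("no node labelled %s", label[is.na(i)][1]))
  tree$nodes$age[i]
}

# phylo index of a labelled node
species_node_index <- function(tree, label) {
  phy <- tree$phylo
  i <- match(label, c(phy$tip.label, phy$node.label))
  if (is.na(i)) abort(sprintf("no node labelled '%s'", label))
  i
}

# labels of all tips descending from (and including, if a tip) `label`
species_clade_tips <- function(tree, label) {
  phy <- tree$phylo
  i <- species_node_index(tree, label)
  if (i <= length(phy$tip.label)) return(phy$tip.label[i])
  kids <- phylo_children(phy)
  out <- character()
  stack <- i
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v <= length(phy$tip.label)) out <- c(out, phy$tip.label[v])
    else stack <- c(stack, kids[[v]])
  }
  out
}

# is species-tree node `label` inside the clade rooted at `clade` (including
# the clade root itself)?
species_in_clade <- function(tree, label, clade) {
  if (is.null(clade)) return(rep(TRUE, length(label)))
  i <- species_node_index(tree, clade)
  par <- phylo_parents(tree$phylo)
  vapply(label, function(lab) {
    v <- species_node_index(tree, lab)
    while (!is.na(v)) {
      if (v == i) return(TRUE)
      v <- par[v]
    }
    FALSE
  }, logical(1))
}
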