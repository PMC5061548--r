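#' Assemble genomic loci for every sampled gene copy
#'
#' Each copy is embedded in a contig `flank | gene | flank`. Under the
#' `"segmental"` mechanism a duplicate inherits its parent locus' flanks
#' (each segmental duplication replaces a fraction `config$flank_drift` of
#' flank sites with a different base in the newly created copy) and carries
#' the same transposable-element fingerprint labels; under
#' `"independent_retro"` every copy is dropped into unrelated random flanks
#' with its own fingerprint. Five single-copy control regions, equal in
#' length to the average family gene, are emitted per species for read-depth
#' normalization.
#'
#' @param history A [simulate_gene_family()] result.
#' @param sequences An [evolve_sequences()] result.
#' @param config A [sim_config()]; defaults to the history's.
#' @return A `synthetic_genome` tibble with one row per contig: `species`,
#'   `contig`, `gene` (NA for control regions), `role` (`parent`,
#'   `retrogene`, `control`), `sequence`, `gene_start`, `gene_end` (0-based
#'   half-open), `flank_left`, `flank_right`, `te_labels` (list column),
#'   `parent_gene` (the copy this one was segmentally duplicated from).
#' @export
assemble_loci <- function(history, sequences, config = history$config) {
  stopifnot(inherits(history, "gene_family_history"))
  fl <- config$flank_len
  with_seed(derive_seed(config$seed, "loci"), {
    rows <- list()
    add_contig <- function(species, contig, gene, role, gene_seq, left, right,
                           te, parent_gene) {
      rows[[length(rows) + 1L]] <<- tibble(
        species = species, contig = contig, gene = gene, role = role,
        sequence = paste0(int_to_seq(left), gene_seq, int_to_seq(right)),
        gene_start = length(left), gene_end = length(left) + nchar(gene_seq),
        flank_left = int_to_seq(left), flank_right = int_to_seq(right),
        te_labels = list(te), parent_gene = parent_gene)
    }

    # ancestral retro-locus flanks, shared by the whole segmental family
    f0_left <- seq_to_int(random_dna(fl))
    f0_right <- seq_to_int(random_dna(fl))

    seqs <- as_tibble(sequences)
    # parent-gene loci: own flanks and own TE context per species
    for (k in which(seqs$role == "parent")) {
      add_contig(seqs$species[k], sprintf("contig_%s", seqs$gene[k]),
                 seqs$gene[k], "parent", seqs$sequence[k],
                 seq_to_int(random_dna(fl)), seq_to_int(random_dna(fl)),
                 c("MIR", "L2"), NA_character_)
    }

    retro <- filter(seqs, .data$role == "retrogene")
    if (nrow(retro)) {
      if (config$mechanism == "independent_retro") {
        for (k in seq_len(nrow(retro))) {
          add_contig(retro$species[k], sprintf("contig_%s", retro$gene[k]),
                     retro$gene[k], "retrogene", retro$sequence[k],
                     seq_to_int(random_dna(fl)), seq_to_int(random_dna(fl)),
                     sprintf("TE_%02d", sample.int(1000L, 2L)),
                     retro_parent_of(history, retro$gene[k]))
        }
      } else if (!is.null(history$gene_tree)) {
        gt <- history$gene_tree
        phy <- gt$phylo
        kids <- phylo_children(phy)
        n_tip <- length(phy$tip.label)
        walk <- function(node, left, right) {
          if (node <= n_tip) {
            lab <- phy$tip.label[node]
            k <- match(lab, retro$gene)
            add_contig(retro$species[k], sprintf("contig_%s", lab), lab,
                       "retrogene", retro$sequence[k], left, right,
                       config$te_fingerprint, retro_parent_of(history, lab))
          } else {
            ch <- kids[[node]]
            is_dup <- gene_node_type(history, phy, node) == "dup"
            walk(ch[1L], left, right)
            if (is_dup) {
              walk(ch[2L], drift_seq(left, config$flank_drift),
                   drift_seq(right, config$flank_drift))
            } else {
              walk(ch[2L], left, right)
            }
          }
        }
        walk(phylo_root(phy), f0_left, f0_right)
      } else {
        k <- 1L
        add_contig(retro$species[k], sprintf("contig_%s", retro$gene[k]),
                   retro$gene[k], "retrogene", retro$sequence[k],
                   f0_left, f0_right, config$te_fingerprint, NA_character_)
      }
    }

    # five orthologous single-copy control regions, equal in length to the
    # average family gene, evolved neutrally along the species tree so that
    # focal reads map onto the reference species' copies
    fam_len <- round(mean(nchar(seqs$sequence)))
    sp <- history$species_tree$nodes
    sp_children <- split(sp$label, factor(sp$parent, levels = sp$label))
    sp_age <- setNames(sp$age, sp$label)
    root_lab <- sp$label[is.na(sp$parent)]
    rate <- config$subst_rate
    for (j in 1:5) {
      ctl0 <- seq_to_int(random_dna(fam_len))
      walk_ctl <- function(label, seq_in, age_from) {
        s_out <- mutate_seq(seq_in, rate * (age_from - sp_age[[label]]),
                            config$kappa)
        if (sp$is_tip[match(label, sp$label)]) {
          if (label %in% unique(seqs$species)) {
            nm <- sprintf("%s|control%d", label, j)
            rows[[length(rows) + 1L]] <<- tibble(
              species = label, contig = nm, gene = nm, role = "control",
              sequence = int_to_seq(s_out), gene_start = 0L,
              gene_end = length(s_out), flank_left = "", flank_right = "",
              te_labels = list(character()), parent_gene = NA_character_)
          }
        } else {
          for (ch in sp_children[[label]]) walk_ctl(ch, s_out, sp_age[[label]])
        }
      }
      for (ch in sp_children[[root_lab]]) walk_ctl(ch, ctl0, sp_age[[root_lab]])
    }

    out <- bind_rows(rows)
    class(out) <- c("synthetic_genome", class(out))
    out
  })
}

# node type ("dup" or "spec") of a gene-tree internal node, recovered from
# the truth table via its age and descendant species
gene_node_type <- function(history, phy, node) {
  lab <- phy$node.label[node - length(phy$tip.label)]
  id <- as.integer(sub("^n", "", lab))
  history$nodes$type[id]
}

# the sampled copy a duplicate arose from: the closest tip (by node path)
# outside its own terminal branch; NA for the family's founding copy
retro_parent_of <- function(history, gene) {
  if (is.null(history$gene_tree)) return(NA_character_)
  phy <- history$gene_tree$phylo
  i <- match(gene, phy$tip.label)
  par <- phylo_parents(phy)
  if (is.na(par[i])) return(NA_character_)
  kids <- phylo_children(phy)
  sib <- setdiff(kids[[par[i]]], i)
  # first tip of the sibling subtree
  v <- sib
  while (v > length(phy$tip.label)) v <- kids[[v]][1L]
  phy$tip.label[v]
}
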