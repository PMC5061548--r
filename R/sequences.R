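# Sequence evolution under a 2-parameter (transition/transversion) model.
# Sequences are integer vectors over c(A, C, G, T) internally.

DNA_BASES <- c("A", "C", "G", "T")
# transitions: A<->G (1<->3), C<->T (2<->4)
TRANSITION_OF <- c(3L, 4L, 1L, 2L)
TRANSVERSIONS_OF <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))

seq_to_int <- function(x) match(strsplit(toupper(x), "")[[1]], DNA_BASES)
int_to_seq <- function(v) paste(DNA_BASES[v], collapse = "")

# apply an expected number of substitutions/site along one branch
mutate_seq <- function(v, expected, kappa) {
  if (expected <= 0) return(v)
  n_events <- rpois(length(v), expected)
  p_ts <- kappa / (kappa + 2)
  for (pass in seq_len(max(n_events, 0))) {
    hit <- which(n_events >= pass)
    if (!length(hit)) break
    is_ts <- runif(length(hit)) < p_ts
    v[hit[is_ts]] <- TRANSITION_OF[v[hit[is_ts]]]
    tv <- hit[!is_ts]
    if (length(tv)) {
      pick <- runif(length(tv)) < 0.5
      v[tv] <- vapply(seq_along(tv), function(k) {
        TRANSVERSIONS_OF[[v[tv[k]]]][if (pick[k]) 1L else 2L]
      }, integer(1))
    }
  }
  v
}

# replace each site independently with a *different* base w.p. `p`
drift_seq <- function(v, p) {
  hit <- which(runif(length(v)) < p)
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(1:4, b), 1L), integer(1))
  }
  v
}

# a random valid CDS: ATG + (len/3 - 2) sense codons + TAA
random_orf <- function(len) {
  len <- 3L * (len %/% 3L)
  n_codon <- len %/% 3L - 2L
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(matrix(sample(DNA_BASES, 3L * n_codon, replace = TRUE), 3L),
                  2L, paste, collapse = "")
  bad <- codons %in% stops
  while (any(bad)) {
    codons[bad] <- apply(matrix(sample(DNA_BASES, 3L * sum(bad), replace = TRUE), 3L),
                         2L, paste, collapse = "")
    bad <- codons %in% stops
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

# purifying selection on the parent gene: restore the start codon and
# recode internal in-frame stops
repair_orf <- function(v) {
  v[1:3] <- c(1L, 4L, 3L)  # ATG
  n_codon <- length(v) %/% 3L
  for (k in seq_len(n_codon - 1L)[-1L]) {
    i <- 3L * (k - 1L) + 1L
    codon <- int_to_seq(v[i:(i + 2L)])
    if (codon %in% c("TAA", "TAG", "TGA")) v[i + 2L] <- 2L  # -> TAC/TGC
  }
  v
}

#' Evolve parent-gene and retrogene sequences over a simulated history
#'
#' The parent gene evolves along the species tree under a 2-parameter
#' substitution model with purifying repair of its reading frame. At the
#' retrotransposition point the nascent retrogene receives the single
#' diagnostic deletion (`config$deletion_len` nt, shared by every retrogene
#' descendant) and then evolves neutrally along the gene tree; a configured
#' fraction of sampled copies additionally receive an ORF-disrupting
#' premature stop codon.
#'
#' @param history A [simulate_gene_family()] result.
#' @param root_sequence Optional ancestral CDS (character); defaults to a
#'   seeded random ORF of `config$root_seq_len` nt.
#' @param config A [sim_config()]; defaults to the history's.
#' @return A `family_sequences` tibble with columns `gene`, `species`,
#'   `role` (`"parent"`/`"retrogene"`), `sequence`, `orf_disrupted`.
#'   Attributes: `deletion` (0-based half-open interval in parent
#'   coordinates), `root_sequence`.
#' @export
evolve_sequences <- function(history, root_sequence = NULL,
                             config = history$config) {
  stopifnot(inherits(history, "gene_family_history"))
  if (!is.null(root_sequence)) {
    root_sequence <- check_dna(root_sequence, "root_sequence", allow_n = FALSE)
    if (nchar(root_sequence) == 0L) abort("root_sequence is empty")
    if (nchar(root_sequence) <= config$deletion_len + 100) {
      abort("root_sequence must be longer than deletion length + 100 nt")
    }
  }
  rate <- config$subst_rate
  kappa <- config$kappa

  with_seed(derive_seed(config$seed, "sequences"), {
    if (is.null(root_sequence)) root_sequence <- random_orf(config$root_seq_len)
    r0 <- seq_to_int(root_sequence)
    L <- length(r0)

    # deletion interval: frame-preserving when deletion_len %% 3 == 0,
    # placed mid-gene (0-based half-open, parent coordinates)
    del_start <- 3L * ((L %/% 2L) %/% 3L)
    del <- c(del_start, del_start + config$deletion_len)

    sp <- history$species_tree$nodes
    sp_children <- split(sp$label, factor(sp$parent, levels = sp$label))
    sp_age <- setNames(sp$age, sp$label)
    root_lab <- sp$label[is.na(sp$parent)]
    root_age <- sp_age[[root_lab]]

    # --- parent gene down the species tree (with ORF repair) -------------
    parent_seq <- new.env(parent = emptyenv())
    retro_parent <- sp$parent[match(config$retro_lineage, sp$label)]
    p_retro <- NULL
    walk_sp <- function(label, seq_in, age_from) {
      b <- age_from - sp_age[[label]]
      if (label == config$retro_lineage) {
        # stop at the retro point to snapshot the donor transcript
        b1 <- age_from - config$t_retro
        s_mid <- repair_orf(mutate_seq(seq_in, rate * b1, kappa))
        p_retro <<- s_mid
        s_out <- repair_orf(mutate_seq(s_mid, rate * (config$t_retro - sp_age[[label]]),
                                       kappa))
      } else {
        s_out <- repair_orf(mutate_seq(seq_in, rate * b, kappa))
      }
      if (sp$is_tip[match(label, sp$label)]) {
        assign(label, s_out, envir = parent_seq)
      } else {
        for (ch in sp_children[[label]]) walk_sp(ch, s_out, sp_age[[label]])
      }
    }
    for (ch in sp_children[[root_lab]]) walk_sp(ch, r0, root_age)
    if (is.null(p_retro)) abort("retro lineage not reached in species tree")

    # --- retrogene copies down the gene tree ----------------------------
    retro_root <- p_retro[-((del[1] + 1L):del[2])]
    rows <- list()
    if (!is.null(history$gene_tree)) {
      gt <- history$gene_tree
      phy <- gt$phylo
      kids <- phylo_children(phy)
      rt <- phylo_root(phy)
      n_tip <- length(phy$tip.label)
      stem <- config$t_retro - gt$ages[rt]
      walk_gt <- function(node, seq_in, age_from) {
        s <- mutate_seq(seq_in, rate * (age_from - gt$ages[node]), kappa)
        if (node <= n_tip) {
          rows[[length(rows) + 1L]] <<- tibble(
            gene = phy$tip.label[node],
            species = gt$leaf_map$species[match(phy$tip.label[node], gt$leaf_map$tip)],
            role = "retrogene", sequence = int_to_seq(s))
        } else {
          for (ch in kids[[node]]) walk_gt(ch, s, gt$ages[node])
        }
      }
      walk_gt(rt, retro_root, config$t_retro)
    } else if (nrow(history$copy_map) == 1L) {
      # single surviving copy: evolve along the species path
      tipp <- history$copy_map
      path <- rev(species_path(history, tipp$species))
      s <- retro_root
      t_prev <- config$t_retro
      for (lab in path) {
        s <- mutate_seq(s, rate * (t_prev - sp_age[[lab]]), kappa)
        t_prev <- sp_age[[lab]]
      }
      rows[[1L]] <- tibble(gene = tipp$tip, species = tipp$species,
                           role = "retrogene", sequence = int_to_seq(s))
    }
    retro <- bind_rows(rows)

    # ORF-disrupting premature stops in a configured fraction of copies
    if (nrow(retro)) {
      disrupt <- runif(nrow(retro)) < config$orf_disrupt_prob
      retro$orf_disrupted <- disrupt
      for (k in which(disrupt)) {
        v <- seq_to_int(retro$sequence[k])
        n_codon <- length(v) %/% 3L
        at <- sample(5:max(6L, n_codon %/% 2L), 1L)
        v[(3L * (at - 1L) + 1L):(3L * (at - 1L) + 3L)] <- c(4L, 1L, 1L)  # TAA
        retro$sequence[k] <- int_to_seq(v)
      }
    } else {
      retro$orf_disrupted <- logical()
    }

    parents <- tibble(
      gene = sprintf("%s|TP53", ls(parent_seq)),
      species = ls(parent_seq),
      role = "parent",
      sequence = vapply(ls(parent_seq),
                        function(s) int_to_seq(get(s, envir = parent_seq)),
                        character(1)),
      orf_disrupted = FALSE)

    out <- bind_rows(parents, retro) |> arrange(.data$species, .data$role, .data$gene)
    attr(out, "deletion") <- del
    attr(out, "root_sequence") <- root_sequence
    class(out) <- c("family_sequences", class(out))
    out
  })
}

#' Write sequences to FASTA
#'
#' @param sequences A data frame with `gene` and `sequence` columns (for
#'   example a [evolve_sequences()] result), or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.data.frame(sequences)) {
    x <- setNames(sequences$sequence, sequences$gene)
  } else {
    x <- sequences
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), filepath = path)
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' @param path FASTA path.
#' @return Tibble with columns `gene`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(gene = names(x), sequence = as.character(x))
}
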