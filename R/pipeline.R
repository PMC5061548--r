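#' Packaged African elephant TP53/TP53RTG repertoire table
#'
#' A transcription of the published summary table for the African elephant
#' repertoire: the parent gene plus 19 retrogenes with their loxAfr3
#' scaffolds, coding-potential calls and ORF sizes (aa).
#'
#' @return A tibble with 20 rows: `gene`, `scaffold`, `is_retrogene`,
#'   `coding`, `orf_length`.
#' @examples
#' summarize_repertoire(load_table1_fixture())
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "tp53_repertoire_loxodonta.tsv",
                      package = "retroexpand", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), scaffold = readr::col_character(),
    is_retrogene = readr::col_logical(), coding = readr::col_logical(),
    orf_length = readr::col_integer()))
}

#' Run the full simulate-infer-evaluate pipeline
#'
#' Simulates a retrogene family on the species tree, assembles loci and
#' read sets, and runs every inference stage: repertoire characterization
#' of the reference species, duplication-mechanism classification,
#' three-way copy-number estimation for a modern and an ancient focal
#' genome, the copies-through-time / body-size correlation, and expression
#' calls. Everything derives from `config$seed`, so a report regenerates
#' identically.
#'
#' @param config A [sim_config()].
#' @param species_tree A [build_species_tree()] object.
#' @param reference_species Species whose repertoire is the mapping
#'   reference (default African elephant).
#' @param modern_species,ancient_species Focal genomes for the modern and
#'   ancient copy-number estimates.
#' @param body_size A body-size series (default: packaged fixture).
#' @param out_dir Optional directory; when given, intermediate files
#'   (FASTA/FASTQ/newick/TSV) and `report.json` are written there.
#' @param n_boot,n_perm Bootstrap and permutation sizes.
#' @return A `run_report` list; see the vignette for a walk-through.
#' @export
run_end_to_end <- function(config = sim_config(),
                           species_tree = build_species_tree("paenungulata"),
                           reference_species = "African_elephant",
                           modern_species = "Asian_elephant",
                           ancient_species = "mastodon",
                           body_size = body_size_series("proboscidea_fixture"),
                           out_dir = NULL, n_boot = 1000, n_perm = 2000) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  history <- stage("simulate", simulate_gene_family(species_tree, config))
  seqs <- stage("sequences", evolve_sequences(history))
  genome <- stage("loci", assemble_loci(history, seqs))

  # --- repertoire of the reference species ------------------------------
  ref_rows <- filter(as_tibble(seqs), .data$species == reference_species)
  records <- stage("repertoire", {
    cp <- purrr::map(ref_rows$sequence, assess_coding_potential) |> bind_rows()
    tibble(gene = ref_rows$gene, is_retrogene = ref_rows$role == "retrogene",
           coding = cp$coding, orf_length = cp$orf_length)
  })
  repertoire_summary <- summarize_repertoire(records)

  mechanism <- stage("mechanism", classify_expansion_mechanism(genome))

  # --- copy number ------------------------------------------------------
  ref_genes <- filter(as_tibble(genome), .data$species == reference_species,
                      .data$role %in% c("parent", "retrogene")) |>
    mutate(sequence = substr(.data$sequence, .data$gene_start + 1L, .data$gene_end)) |>
    select("gene", "sequence")
  controls <- filter(as_tibble(genome), .data$species == reference_species,
                     .data$role == "control") |>
    select("gene", "sequence")
  ref_tree <- prune_to_species(history, reference_species)

  cn_for <- function(species, ancient) {
    reads <- simulate_reads(genome, config, species = species,
                            ancient = ancient,
                            label = paste0("reads/", species))
    split_node <- species_split(species_tree, species, reference_species)
    estimate_copy_number(
      reads, ref_genes, controls, ref_tree,
      split_time = split_node, ancient_mode = ancient,
      n_boot = n_boot, seed = derive_seed(config$seed, paste0("boot/", species)))
  }
  cn_modern <- stage("copy_number/modern", cn_for(modern_species, FALSE))
  cn_ancient <- stage("copy_number/ancient", cn_for(ancient_species, TRUE))

  # --- trajectory -------------------------------------------------------
  trajectory <- stage("trajectory", {
    ctt <- copies_through_time(history$gene_tree, reference_species)
    corr <- correlate_series(ctt, body_size, n_perm = n_perm,
                             seed = derive_seed(config$seed, "perm"))
    list(copies = ctt, correlation = corr)
  })

  # --- expression -------------------------------------------------------
  expression <- stage("expression", {
    tab <- simulate_expression(history, config, species = reference_species)
    tab <- fpkm_to_tpm(tab)
    list(table = tab, expressed = call_expressed(tab))
  })

  true_cn <- setNames(history$true_copies$copies, history$true_copies$species)
  report <- structure(list(
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "dup_rate")],
    dup_rate = as.data.frame(config$dup_rate),
    true_copies = history$true_copies,
    repertoire = list(records = records, summary = repertoire_summary),
    mechanism = list(
      calls = mechanism,
      n_segmental = sum(mechanism$mechanism == "segmental_duplication"),
      n_independent = sum(mechanism$mechanism == "independent_retrotransposition")),
    copy_number = list(
      modern = list(species = modern_species,
                    true = unname(true_cn[modern_species]) + 1L,
                    estimate = tidy(cn_modern)),
      ancient = list(species = ancient_species,
                     true = unname(true_cn[ancient_species]) + 1L,
                     estimate = tidy(cn_ancient))),
    trajectory = list(correlation = tidy(trajectory$correlation),
                      copies = trajectory$copies),
    expression = list(expressed = expression$expressed,
                      n_expressed_retrogenes = sum(
                        expression$expressed %in%
                          filter(expression$table, .data$class == "retrogene")$gene)),
    objects = list(history = history, sequences = seqs, genome = genome,
                   cn_modern = cn_modern, cn_ancient = cn_ancient,
                   correlation = trajectory$correlation,
                   expression = expression$table)),
    class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

# dated gene tree restricted to one species' copies
prune_to_species <- function(history, species) {
  gt <- history$gene_tree
  if (is.null(gt)) abort("history has no sampled gene tree")
  keep <- filter(gt$leaf_map, .data$species == !!species)$tip
  if (length(keep) < 2L) abort(sprintf("'%s' has fewer than 2 copies", species))
  phy <- ape::keep.tip(gt$phylo, keep)
  tip_ages <- gt$ages[match(phy$tip.label, c(gt$phylo$tip.label))]
  dated_gene_tree(phy, leaf_map = filter(gt$leaf_map, .data$tip %in% keep),
                  tip_ages = gt$ages[match(phy$tip.label, gt$phylo$tip.label)],
                  origin_time = gt$origin_time)
}

# divergence age of two species (their LCA's age)
species_split <- function(species_tree, a, b) {
  par <- phylo_parents(species_tree$phylo)
  anc <- function(lab) {
    v <- species_node_index(species_tree, lab)
    out <- v
    while (!is.na(par[v])) {
      v <- par[v]
      out <- c(out, v)
    }
    out
  }
  lca <- intersect(anc(a), anc(b))[1]
  species_tree$ages[lca]
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  seed %d; repertoire %d/%d/%d (total/retro/coding-retro)\n",
              x$seed, x$repertoire$summary$total,
              x$repertoire$summary$retrogenes,
              x$repertoire$summary$coding_retrogenes))
  cat(sprintf("  modern %s: true %d, min %d, avg %.1f [%.1f, %.1f], max %d\n",
              x$copy_number$modern$species, x$copy_number$modern$true,
              x$copy_number$modern$estimate$minimum,
              x$copy_number$modern$estimate$average,
              x$copy_number$modern$estimate$ci_low,
              x$copy_number$modern$estimate$ci_high,
              x$copy_number$modern$estimate$maximum))
  cat(sprintf("  ancient %s: true %d, min %d, max %d\n",
              x$copy_number$ancient$species, x$copy_number$ancient$true,
              x$copy_number$ancient$estimate$minimum,
              x$copy_number$ancient$estimate$maximum))
  cat(sprintf("  trajectory r = %.3f (p = %.3g); %d expressed retrogenes\n",
              x$trajectory$correlation$estimate, x$trajectory$correlation$p_value,
              x$expression$n_expressed_retrogenes))
  invisible(x)
}

# serialize a run report and its standard-format intermediates
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- report$objects
  write_fasta(as_tibble(obj$sequences), file.path(out_dir, "family.fasta"))
  readr::write_tsv(select(as_tibble(obj$genome), -"te_labels"),
                   file.path(out_dir, "loci.tsv"))
  if (!is.null(obj$history$gene_tree)) {
    write_gene_tree(obj$history$gene_tree, file.path(out_dir, "gene_tree.nwk"))
  }
  ape::write.tree(report$objects$history$species_tree$phylo,
                  file.path(out_dir, "species_tree.nwk"))
  readr::write_tsv(obj$history$events, file.path(out_dir, "events.tsv"))
  readr::write_tsv(obj$expression, file.path(out_dir, "expression.tsv"))
  json <- report[setdiff(names(report), "objects")]
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}
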