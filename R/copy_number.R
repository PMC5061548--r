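#' Assign shotgun reads to reference genes by local alignment
#'
#' Every read is aligned against every reference with the package's
#' Smith-Waterman aligner (exhaustive all-reference scoring, the desk-scale
#' analogue of a very sensitive read mapper). The best-scoring reference
#' wins; score ties make the read `ambiguous` and its depth contribution is
#' split 1/k across the k tied genes, so summed depth stays unbiased for
#' near-identical paralogs. Reads whose best alignment falls below
#' `min_identity` percent or `min_aligned_len` columns are `unassigned`.
#'
#' @param reads Tibble with `read_id`, `sequence` (e.g. [simulate_reads()]).
#' @param reference Tibble with `gene`, `sequence`.
#' @param min_identity Minimum percent identity (default 90, the ancient-DNA
#'   mapping stringency); must lie in (0, 100].
#' @param min_aligned_len Minimum aligned columns (default 30).
#' @param match,mismatch,gap_open,gap_extend Aligner parameters.
#' @return A `read_assignment` list: `assignments` (tibble: `read_id`,
#'   `genes` list-column of best gene(s), `identity`, `score`, `status`)
#'   and `depth` (named list of per-position depth vectors, one per
#'   reference gene).
#' @export
assign_reads <- function(reads, reference, min_identity = 90,
                         min_aligned_len = 30, match = 1, mismatch = 2,
                         gap_open = 5, gap_extend = 2) {
  reads <- as_tibble(reads)
  reference <- as_tibble(reference)
  if (!nrow(reads) || !nrow(reference)) abort("reads and reference must be non-empty")
  if (min_identity <= 0 || min_identity > 100) {
    abort("`min_identity` must lie in (0, 100]")
  }
  refs <- setNames(reference$sequence, reference$gene)
  depth <- lapply(refs, function(s) numeric(nchar(s)))

  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    # fast score-only pass over all references, full alignment (identity,
    # subject span) only for the tied best
    scores <- .sw_score_cpp(reads$sequence[i], unname(refs), match,
                            mismatch, gap_open, gap_extend)
    best <- max(scores)
    tied <- which(scores == best)
    hits <- .sw_align_batch_cpp(reads$sequence[i], unname(refs)[tied], match,
                                mismatch, gap_open, gap_extend)
    hits$score <- scores[tied]
    ok <- best > 0 &&
      all(!is.na(hits$identity)) &&
      max(hits$identity) >= min_identity &&
      max(hits$columns) >= min_aligned_len
    if (!ok) {
      rows[[i]] <- tibble(read_id = reads$read_id[i], genes = list(character()),
                          identity = NA_real_, score = best,
                          status = "unassigned")
      next
    }
    status <- if (length(tied) == 1L) "unique" else "ambiguous"
    w <- 1 / length(tied)
    for (h in seq_along(tied)) {
      t <- tied[h]
      span <- hits$b_start[h]:hits$b_end[h]
      depth[[t]][span] <- depth[[t]][span] + w
    }
    rows[[i]] <- tibble(read_id = reads$read_id[i],
                        genes = list(names(refs)[tied]),
                        identity = max(hits$identity), score = best,
                        status = status)
  }
  structure(list(assignments = bind_rows(rows),
                 depth = structure(depth, class = "depth_profile")),
            class = "read_assignment")
}

#' @export
print.read_assignment <- function(x, ...) {
  s <- table(factor(x$assignments$status,
                    levels = c("unique", "ambiguous", "unassigned")))
  cat(sprintf("<read_assignment> %d reads: %d unique, %d ambiguous, %d unassigned over %d genes\n",
              nrow(x$assignments), s[["unique"]], s[["ambiguous"]],
              s[["unassigned"]], length(x$depth)))
  invisible(x)
}

#' Breadth-based ortholog recovery and the minimum copy number
#'
#' A reference gene is recovered when the fraction of its positions at
#' depth >= `depth_min` reaches `breadth_min`. The count of recovered genes
#' is the 1:1-orthology (minimum) copy-number estimate.
#'
#' @param assignment A [assign_reads()] result, or a bare `depth_profile`.
#' @param genes Restrict to these reference genes (default: all in the
#'   profile).
#' @param breadth_min Fraction of covered positions required (default 0.5).
#' @param depth_min Depth threshold per position (default 1).
#' @return A tibble: `gene`, `breadth`, `mean_depth`, `recovered`.
#' @export
recovered_orthologs <- function(assignment, genes = NULL, breadth_min = 0.5,
                                depth_min = 1) {
  if (breadth_min <= 0 || breadth_min > 1) abort("`breadth_min` must be in (0, 1]")
  if (depth_min < 1) abort("`depth_min` must be >= 1")
  depth <- if (inherits(assignment, "read_assignment")) assignment$depth
           else assignment
  genes <- genes %||% names(depth)
  tibble(gene = genes,
         breadth = vapply(genes, function(g) mean(depth[[g]] >= depth_min),
                          numeric(1), USE.NAMES = FALSE),
         mean_depth = vapply(genes, function(g) mean(depth[[g]]), numeric(1),
                             USE.NAMES = FALSE),
         recovered = .data$breadth >= breadth_min)
}

#' Normalized read-depth copy number with a bootstrap confidence interval
#'
#' The point estimate is the summed mean depth across family genes divided
#' by the mean depth of the single-copy control regions -- the ratio
#' estimator of total family copy number. The confidence interval is a
#' seeded percentile bootstrap over fixed-size windows resampled within the
#' family set and within the control set.
#'
#' @param assignment A [assign_reads()] result or `depth_profile`.
#' @param family_genes,control_genes Character vectors naming profile
#'   entries.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param window Window size in nt (default 100).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return A tibble: `estimate`, `ci_low`, `ci_high`, `n_boot`.
#' @export
depth_copy_number <- function(assignment, family_genes, control_genes,
                              n_boot = 1000, window = 100, conf = 0.95,
                              seed = 1) {
  depth <- if (inherits(assignment, "read_assignment")) assignment$depth
           else assignment
  missing <- setdiff(c(family_genes, control_genes), names(depth))
  if (length(missing)) abort(sprintf("genes not in depth profile: %s",
                                     paste(missing, collapse = ", ")))
  if (!length(control_genes)) abort("need at least one control region")
  ctrl <- unlist(depth[control_genes], use.names = FALSE)
  if (!length(ctrl) || sum(ctrl) == 0) {
    abort("zero control depth: normalized ratio is uncomputable")
  }
  fam_means <- vapply(family_genes, function(g) mean(depth[[g]]), numeric(1))
  est <- sum(fam_means) / mean(ctrl)

  chunk <- function(v) {
    if (!length(v)) return(list())
    idx <- ceiling(seq_along(v) / window)
    lapply(split(v, idx), function(w) c(sum(w), length(w)))
  }
  fam_w <- do.call(rbind, unlist(lapply(depth[family_genes], chunk),
                                 recursive = FALSE))
  ctl_w <- do.call(rbind, unlist(lapply(depth[control_genes], chunk),
                                 recursive = FALSE))
  n_fam <- length(family_genes)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      fi <- sample.int(nrow(fam_w), replace = TRUE)
      ci <- sample.int(nrow(ctl_w), replace = TRUE)
      fam_mean <- sum(fam_w[fi, 1]) / sum(fam_w[fi, 2])
      ctl_mean <- sum(ctl_w[ci, 1]) / sum(ctl_w[ci, 2])
      if (ctl_mean == 0) NA_real_ else n_fam * fam_mean / ctl_mean
    }, numeric(1))
  })
  qs <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE,
                 names = FALSE)
  tibble(estimate = est, ci_low = qs[1], ci_high = qs[2], n_boot = n_boot)
}

#' Unsampled-gene rule for reconciliation-based (maximum) copy number
#'
#' A reference-genome paralog that is absent from a focal genome's reads is
#' counted as *unsampled* (present in the genome but missed by sequencing)
#' when its divergence (duplication) age predates the focal-reference
#' species split; paralogs younger than the split are reference-lineage
#' duplicates instead, and are not imputed. For low-coverage ancient
#' genomes (`ancient_mode`) the same rule applies at that species' deeper
#' split, where it discounts most reference paralogs as
#' reference-lineage-specific.
#'
#' @param divergence_ages Named numeric vector (or tibble with `gene`,
#'   `divergence_age`) of missing paralogs' duplication ages, MY BP.
#' @param split_time Focal-reference species divergence, MY BP (> 0).
#' @param ancient_mode Flag recorded on the output (the rule is identical;
#'   the caller supplies the appropriate split).
#' @return A tibble: `gene`, `divergence_age`, `unsampled`.
#' @examples
#' infer_unsampled(c(a = 12, b = 30, c = 5, d = 3, e = 2), split_time = 8)
#' @export
infer_unsampled <- function(divergence_ages, split_time, ancient_mode = FALSE) {
  if (is.data.frame(divergence_ages)) {
    ages <- setNames(divergence_ages$divergence_age, divergence_ages$gene)
  } else {
    ages <- divergence_ages
    if (is.null(names(ages))) names(ages) <- sprintf("missing%d", seq_along(ages))
  }
  if (anyNA(ages)) abort("divergence ages contain NA (gene tree lacks ages?)")
  if (!is.numeric(split_time) || split_time <= 0) abort("`split_time` must be > 0")
  tibble(gene = names(ages), divergence_age = unname(ages),
         unsampled = unname(ages) > split_time,
         ancient_mode = ancient_mode)
}

# divergence age of each reference-tree tip: the age of its parent node
paralog_divergence_ages <- function(gene_tree) {
  phy <- gene_tree$phylo
  par <- phylo_parents(phy)
  n_tip <- length(phy$tip.label)
  setNames(gene_tree$ages[par[seq_len(n_tip)]], phy$tip.label)
}

#' Three-way copy-number estimate for a focal genome
#'
#' Composes the package's three estimators: the 1:1-orthology minimum
#' (breadth-based recovery of reference genes), the normalized read-depth
#' average with a bootstrap CI, and the reconciliation-based maximum
#' (recovered genes plus unsampled genes imputed by the age-versus-split
#' rule of [infer_unsampled()]).
#'
#' @param reads A read tibble for the focal genome.
#' @param reference Family reference genes: tibble `gene`, `sequence` (the
#'   reference species' parent gene + retrogenes).
#' @param controls Single-copy control regions: tibble `gene`, `sequence`.
#' @param reference_tree `dated_gene_tree` of the reference species' copies
#'   (tip labels matching `reference$gene`), used for divergence ages.
#' @param split_time Focal-reference species divergence (MY BP).
#' @param ancient_mode Ancient-genome flag passed to [infer_unsampled()].
#' @param min_identity,breadth_min,depth_min,n_boot,window Estimator
#'   parameters (see the component functions).
#' @param seed Bootstrap seed.
#' @return A `copy_number_estimate` object; see [tidy.copy_number_estimate()].
#' @export
estimate_copy_number <- function(reads, reference, controls, reference_tree,
                                 split_time, ancient_mode = FALSE,
                                 min_identity = 90, breadth_min = 0.5,
                                 depth_min = 1, n_boot = 1000, window = 100,
                                 seed = 1) {
  asn <- assign_reads(reads, bind_rows(as_tibble(reference)[c("gene", "sequence")],
                                       as_tibble(controls)[c("gene", "sequence")]),
                      min_identity = min_identity)
  fam <- as_tibble(reference)$gene
  ctl <- as_tibble(controls)$gene
  rec <- recovered_orthologs(asn, genes = fam, breadth_min = breadth_min,
                             depth_min = depth_min)
  minimum <- sum(rec$recovered)
  avg <- depth_copy_number(asn, fam, ctl, n_boot = n_boot, window = window,
                           seed = seed)
  div_ages <- paralog_divergence_ages(reference_tree)
  missing <- setdiff(intersect(fam, names(div_ages)),
                     rec$gene[rec$recovered])
  uns <- infer_unsampled(div_ages[missing], split_time, ancient_mode)
  maximum <- minimum + sum(uns$unsampled)
  structure(list(minimum = minimum, average = avg$estimate,
                 ci = c(avg$ci_low, avg$ci_high), maximum = maximum,
                 recovered = rec, unsampled = uns, assignment = asn,
                 split_time = split_time, ancient_mode = ancient_mode),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("<copy_number_estimate> minimum %d, average %.2f [%.2f, %.2f], maximum %d%s\n",
              x$minimum, x$average, x$ci[1], x$ci[2], x$maximum,
              if (x$ancient_mode) " (ancient mode)" else ""))
  invisible(x)
}
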