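#' Copies-through-time toward a focal species
#'
#' The lineage-through-time curve of a dated gene tree restricted to one
#' species: N(t) is the number of gene-tree lineages at age t that are
#' ancestral to the focal species' sampled copies. The curve is stepwise
#' and right-continuous toward the present, stepping +1 at each duplication
#' on the focal path; it starts at 1 at the family origin
#' (retrotransposition).
#'
#' @param gene_tree A `dated_gene_tree` (sampled copies, with leaf map).
#' @param focal_species Species label with at least one sampled copy.
#' @param grid Ages (MY BP) at which to evaluate; default 1-MY bins from
#'   the family origin to the present. Points older than the origin are
#'   clamped off with a warning.
#' @return A tibble: `time` (descending), `copies`.
#' @export
copies_through_time <- function(gene_tree, focal_species, grid = NULL) {
  stopifnot(inherits(gene_tree, "dated_gene_tree"))
  focal_tips <- filter(gene_tree$leaf_map, .data$species == focal_species)$tip
  if (!length(focal_tips)) {
    abort(sprintf("species '%s' has no sampled copies", focal_species))
  }
  origin <- gene_tree$origin_time
  if (is.null(grid)) {
    grid <- sort(unique(c(seq(floor(origin), 0, by = -1), 0)), decreasing = TRUE)
  }
  if (any(grid > origin)) {
    warn(sprintf("grid extends beyond the family origin (%.2f MY); clamping",
                 origin))
    grid <- grid[grid <= origin]
  }

  phy <- gene_tree$phylo
  n_tip <- length(phy$tip.label)
  anc <- rep(FALSE, n_tip + phy$Nnode)
  anc[match(focal_tips, phy$tip.label)] <- TRUE
  for (v in phylo_postorder(phy)) {
    if (v > n_tip) {
      for (ch in phylo_children(phy)[[v]]) if (anc[ch]) anc[v] <- TRUE
    }
  }
  par <- phylo_parents(phy)
  rt <- phylo_root(phy)
  edges <- tibble(
    child = which(anc & seq_along(anc) != rt),
    parent = par[which(anc & seq_along(anc) != rt)]) |>
    mutate(a_par = gene_tree$ages[.data$parent],
           a_chl = gene_tree$ages[.data$child],
           tip = .data$child <= n_tip)
  root_age <- gene_tree$ages[rt]
  copies <- vapply(grid, function(t) {
    n <- sum(edges$a_par >= t & (t > edges$a_chl | (edges$tip & t >= edges$a_chl)))
    # the stem lineage between the origin and the first surviving split
    if (t <= origin && t > root_age) n <- n + 1L
    n
  }, numeric(1))
  tibble(time = grid, copies = copies)
}

#' Correlate two through-time series
#'
#' Resamples both series onto a common time grid (step interpolation for
#' counts, linear for continuous measures), computes the correlation
#' coefficient and a circular-shift permutation p-value, which respects the
#' autocorrelation of through-time series in a way i.i.d. shuffling would
#' not.
#'
#' @param a,b Data frames with `time` and a value column (`copies` or
#'   `value`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param interp_a,interp_b `"step"` (right-continuous toward the present;
#'   default for `a`, meant for copy-number counts) or `"linear"` (default
#'   for `b`, meant for body mass).
#' @param grid Common grid; default 1-MY steps over the overlapping range.
#' @param n_perm Circular-shift permutations (default 10000).
#' @param seed Permutation seed.
#' @return A `trend_correlation` object; `tidy()` gives a one-row tibble.
#' @export
correlate_series <- function(a, b, method = c("pearson", "spearman"),
                             interp_a = "step", interp_b = "linear",
                             grid = NULL, n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  va <- series_values(a)
  vb <- series_values(b)
  if (is.null(grid)) {
    lo <- max(min(va$time), min(vb$time))
    hi <- min(max(va$time), max(vb$time))
    if (hi <= lo) abort("series do not overlap in time")
    grid <- seq(hi, lo, by = -1)
  }
  ya <- interp_series(va, grid, interp_a)
  yb <- interp_series(vb, grid, interp_b)
  if (length(grid) < 3L) abort("need at least 3 common grid points")
  if (stats::sd(ya) == 0 || stats::sd(yb) == 0) {
    abort("constant series: correlation undefined")
  }
  r <- cor(ya, yb, method = method)
  n <- length(grid)
  perm <- with_seed(seed, {
    shifts <- sample.int(n - 1L, n_perm, replace = TRUE)
    vapply(shifts, function(s) {
      yp <- yb[((seq_len(n) - 1L + s) %% n) + 1L]
      if (stats::sd(yp) == 0) NA_real_ else cor(ya, yp, method = method)
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(r), na.rm = TRUE)) / (1 + sum(!is.na(perm)))
  structure(list(estimate = r, method = method, n = n, p_value = p,
                 grid = grid, series = tibble(time = grid, a = ya, b = yb),
                 n_perm = n_perm),
            class = "trend_correlation")
}

series_values <- function(x) {
  x <- as_tibble(x)
  vcol <- intersect(c("value", "copies", "mass"), names(x))[1]
  if (is.na(vcol) || !"time" %in% names(x)) {
    abort("series need `time` and a `value`/`copies` column")
  }
  arrange(tibble(time = x$time, value = x[[vcol]]), dplyr::desc(.data$time))
}

interp_series <- function(s, grid, how) {
  # internally interpolate on forward time (-age) so "step" carries the
  # most recent past value toward the present
  approx(x = -s$time, y = s$value, xout = -grid,
         method = if (how == "step") "constant" else "linear",
         rule = 2)$y
}

#' @export
print.trend_correlation <- function(x, ...) {
  cat(sprintf("<trend_correlation> %s r = %.3f over %d points; circular-shift p = %.4g\n",
              x$method, x$estimate, x$n, x$p_value))
  invisible(x)
}
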