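#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator. Defaults encode
#' the study conditions the package emulates: one retrotransposition on the
#' Paenungulata stem ~64.5 MY BP, a ~25 MY quiescent interval, then
#' birth-death expansion restricted to the Proboscidean clade at a pure-birth
#' rate chosen so the expected extant elephant repertoire is ~19 retrogenes
#' (`log(19)/40` per lineage per MY on the last 40 MY).
#'
#' @param t_retro Retrotransposition time, MY before present.
#' @param retro_lineage Species-tree node label; the event happens on the
#'   branch ending at this node.
#' @param dup_rate Piecewise-constant duplication rate: a data frame with
#'   columns `older`, `younger`, `rate` (events/lineage/MY on `(older,
#'   younger]`); intervals must not overlap, rate is 0 elsewhere.
#' @param dup_clade Clade label to which duplications are restricted
#'   (including its stem branch); `NULL` for no restriction.
#' @param loss_rate Loss rate, events/lineage/MY.
#' @param subst_rate Substitution rate, substitutions/site/MY.
#' @param kappa Transition/transversion rate ratio of the 2-parameter
#'   substitution model.
#' @param deletion_len Length (nt) of the diagnostic deletion shared by all
#'   retrogenes; must lie in `[15, 30]`.
#' @param orf_disrupt_prob Probability that a retrogene copy acquires an
#'   ORF-disrupting nonsense/frameshift mutation.
#' @param root_seq_len Length (nt) of the ancestral parent-gene CDS.
#' @param flank_len Length (nt) of each locus flank.
#' @param flank_drift Substitutions/site applied to the flank at each
#'   segmental duplication.
#' @param te_fingerprint Character vector of transposable-element labels
#'   stamped on every segmentally duplicated locus.
#' @param mechanism `"segmental"` (duplications copy gene + flanks) or
#'   `"independent_retro"` (each copy reinserts with unrelated flanks).
#' @param coverage Modern sequencing depth (fold coverage).
#' @param read_len Modern read length (nt).
#' @param paired Paired-end flag (reads are emitted as /1 and /2 mates).
#' @param error_rate Per-base sequencing error probability.
#' @param ancient List with `read_len_range` (nt) and `coverage` for the
#'   ancient-DNA profile; the damage model is reserved and off.
#' @param expressed_high,expressed_low Numbers of retrogene copies given
#'   high and low (but above-threshold) expression by the generator.
#' @param n_background Number of background transcriptome genes emitted so
#'   the TPM transform has a realistic denominator.
#' @param seed Master seed; every stochastic stage derives a labelled
#'   sub-seed from it.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 42)
#' cfg$deletion_len
#' @export
sim_config <- function(t_retro = 64.5,
                       retro_lineage = "Paenungulata",
                       dup_rate = tibble(older = 40, younger = 0,
                                         rate = log(19) / 40),
                       dup_clade = "Proboscidea",
                       loss_rate = 0,
                       subst_rate = 0.0015,
                       kappa = 2,
                       deletion_len = 21,
                       orf_disrupt_prob = 5 / 19,
                       root_seq_len = 1182,
                       flank_len = 500,
                       flank_drift = 0.05,
                       te_fingerprint = c("RTE1_LA", "L1MB5"),
                       mechanism = c("segmental", "independent_retro"),
                       coverage = 10,
                       read_len = 100,
                       paired = FALSE,
                       error_rate = 0.001,
                       ancient = list(read_len_range = c(40, 100),
                                      coverage = 0.5),
                       expressed_high = 1,
                       expressed_low = 2,
                       n_background = 500,
                       seed = 1) {
  mechanism <- match.arg(mechanism)
  dup_rate <- as_tibble(dup_rate)
  stopifnot(all(c("older", "younger", "rate") %in% names(dup_rate)))
  if (any(dup_rate$rate < 0)) abort("duplication rates must be >= 0")
  if (any(dup_rate$older <= dup_rate$younger)) {
    abort("`dup_rate` intervals need older > younger")
  }
  if (loss_rate < 0) abort("`loss_rate` must be >= 0")
  if (subst_rate < 0) abort("`subst_rate` must be >= 0")
  if (deletion_len < 15 || deletion_len > 30) {
    abort("`deletion_len` must lie in [15, 30] nt")
  }
  if (orf_disrupt_prob < 0 || orf_disrupt_prob > 1) {
    abort("`orf_disrupt_prob` must be a probability")
  }
  if (root_seq_len <= deletion_len + 100) {
    abort("`root_seq_len` must exceed `deletion_len` + 100")
  }
  if (coverage < 0 || ancient$coverage < 0) abort("coverage must be >= 0")
  if (error_rate < 0 || error_rate > 1) abort("`error_rate` must be a probability")
  structure(
    list(t_retro = t_retro, retro_lineage = retro_lineage,
         dup_rate = dup_rate, dup_clade = dup_clade, loss_rate = loss_rate,
         subst_rate = subst_rate, kappa = kappa, deletion_len = deletion_len,
         orf_disrupt_prob = orf_disrupt_prob, root_seq_len = root_seq_len,
         flank_len = flank_len, flank_drift = flank_drift,
         te_fingerprint = te_fingerprint, mechanism = mechanism,
         coverage = coverage, read_len = read_len, paired = paired,
         error_rate = error_rate, ancient = ancient,
         expressed_high = expressed_high, expressed_low = expressed_low,
         n_background = n_background, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> retro %.1f MY on %s stem; dup rate %s; loss %.3f;\n",
    "  deletion %d nt; mechanism %s; coverage %gx (%d nt reads); seed %d\n"),
    x$t_retro, x$retro_lineage,
    paste(sprintf("%.4f on (%g,%g]", x$dup_rate$rate, x$dup_rate$older,
                  x$dup_rate$younger), collapse = ", "),
    x$loss_rate, x$deletion_len, x$mechanism, x$coverage, x$read_len, x$seed))
  invisible(x)
}

# total duplication rate at age t (MY BP)
dup_rate_at <- function(config, t) {
  r <- 0
  for (k in seq_len(nrow(config$dup_rate))) {
    if (t <= config$dup_rate$older[k] && t > config$dup_rate$younger[k]) {
      r <- r + config$dup_rate$rate[k]
    }
  }
  r
}

# breakpoints of the piecewise rate within the age interval (from, to], from > to
rate_breaks <- function(config, from, to) {
  b <- sort(unique(c(config$dup_rate$older, config$dup_rate$younger)), decreasing = TRUE)
  b <- b[b < from & b > to]
  c(from, b, to)
}
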