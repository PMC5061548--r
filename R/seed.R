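#' Derive a labelled sub-seed from a master seed
#'
#' All stochastic components draw their own seed deterministically from one
#' master seed plus a short text label, so that adding or reordering
#' simulation stages never perturbs the random stream of another stage.
#'
#' @param master Integer master seed.
#' @param label Character scalar naming the consumer (e.g. `"reads/modern"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1L, "reads")
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(master)) %% 2147483647 * 7919 + h) %% 2147483647)
}

# run `expr` under a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# validate a DNA string (ACGTN only, upper-cased)
check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("%s must be a single character string", what))
  }
  x <- toupper(x)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, x)) {
    abort(sprintf("%s contains characters outside %s", what,
                  if (allow_n) "ACGTN" else "ACGT"))
  }
  x
}

random_dna <- function(n, freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
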