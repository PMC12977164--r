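#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' library functions that need reproducible draws do not clobber the
#' session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a stage-local seed from a global one, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% .Machine$integer.max)
}

#' Percentage of annotated genes, printed-precision rounding
#'
#' Annotation-completeness summary: `100 * annotated / total`, rounded to
#' `digits` decimals (one decimal by default, matching genome-report
#' convention, e.g. 95668 of 98699 genes -> 96.9).
#'
#' @param annotated number of functionally annotated genes.
#' @param total total predicted genes (> 0).
#' @param digits decimals to round to.
#' @return numeric percentage.
#' @export
#' @examples
#' annotation_rate(95668, 98699)
annotation_rate <- function(annotated, total, digits = 1) {
  stopifnot(length(annotated) == 1L, length(total) == 1L)
  if (total <= 0) stop("total must be positive")
  if (annotated < 0 || annotated > total) stop("annotated must be in [0, total]")
  round(100 * annotated / total, digits)
}

#' Protein length encoded by an ORF
#'
#' Amino acids encoded by an open reading frame whose length includes the
#' stop codon: `orf_bp / 3 - 1` (a 1305-bp ORF encodes 434 aa).
#'
#' @param orf_bp ORF length in bp, a positive multiple of 3 (>= 6: at least
#'   one codon plus the stop).
#' @return integer number of amino acids.
#' @export
orf_protein_length <- function(orf_bp) {
  stopifnot(length(orf_bp) == 1L, orf_bp > 0)
  if (orf_bp %% 3 != 0) stop("ORF length must be a multiple of 3")
  if (orf_bp < 6) stop("ORF must contain at least one codon plus the stop")
  as.integer(orf_bp / 3 - 1)
}

# stop() with a consistent prefix for user-input validation failures
fail_validation <- function(...) {
  stop(paste0(...), call. = FALSE)
}
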