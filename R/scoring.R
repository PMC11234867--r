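#' @include AllClasses.R
NULL

#' Default protein scoring scheme
#'
#' BLOSUM62 with affine gap penalties 11 (open) / 1 (extend) and the standard
#' gapped Karlin-Altschul constants lambda = 0.267, K = 0.041 for that
#' parameter combination. The matrix is restricted to the 20 canonical amino
#' acids plus \code{X}, and \code{X} is made score-neutral (0 against
#' everything, including itself) so ambiguous residues neither reward nor
#' penalize an alignment.
#'
#' @param gapOpen,gapExtend affine gap penalties (positive integers); a gap of
#'   length g costs \code{gapOpen + g * gapExtend}.
#' @param lambda,K Karlin-Altschul parameters for the chosen matrix/penalties.
#' @return a [ScoringScheme-class] object.
#' @examples
#' sch <- defaultScheme()
#' eValue(40L, 100L, 100L, sch)
#' @export
defaultScheme <- function(gapOpen = 11L, gapExtend = 1L,
                          lambda = 0.267, K = 0.041) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  keep <- c(.AA20, "X")
  m <- env$BLOSUM62[keep, keep]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  new("ScoringScheme", matrix = m, gapOpen = as.integer(gapOpen),
      gapExtend = as.integer(gapExtend), lambda = lambda, K = K,
      name = "BLOSUM62")
}

#' Karlin-Altschul E-value and bit score
#'
#' Converts a raw local-alignment score into the expected number of chance
#' alignments scoring at least as high in a search space of m x n residues:
#' \eqn{E = K m n e^{-\lambda S}}. The bit score is
#' \eqn{(\lambda S - \ln K) / \ln 2}.
#'
#' @param rawScore integer raw alignment score (>= 0).
#' @param m query length in residues.
#' @param n database size in residues (sum over all subjects).
#' @param scheme a [ScoringScheme-class].
#' @return for `eValue`, the E-value; for `bitScore`, the bit score.
#' @examples
#' sch <- defaultScheme()
#' eValue(0L, 10L, 10L, sch)  # K * m * n
#' @export
eValue <- function(rawScore, m, n, scheme = defaultScheme()) {
  stopifnot(m >= 1, n >= 1)
  scheme@K * as.numeric(m) * as.numeric(n) * exp(-scheme@lambda * rawScore)
}

#' @rdname eValue
#' @export
bitScore <- function(rawScore, scheme = defaultScheme()) {
  (scheme@lambda * rawScore - log(scheme@K)) / log(2)
}
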