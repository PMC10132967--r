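#' Amplicon complexity score
#'
#' Structural complexity of an amplicon is quantified as the diversity of
#' its cycle decomposition: with walk weights \eqn{w_i} and fractions
#' \eqn{f_i = w_i / \sum_j w_j} over the positive-weight decomposition
#' elements, the score is the Shannon entropy
#' \deqn{H = -\sum_i f_i \log_2 f_i}
#' in bits. A single-walk decomposition scores 0; k equally weighted walks
#' score log2(k). The score is permutation- and scale-invariant and is
#' comparable only within analyses using this definition.
#'
#' @param decomp A [decomposition()] with at least one positive-weight walk.
#' @return Entropy in bits (>= 0).
#' @export
complexity_score <- function(decomp) {
  w <- decomp$cycles$weight
  w <- w[w > 0]
  if (length(w) == 0) stop("decomposition has no positive-weight walks")
  f <- w / sum(w)
  -sum(f * log2(f))
}
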