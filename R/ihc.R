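#' Compute an IHC H-score from an intensity distribution
#'
#' The score is the intensity-weighted percentage of cells,
#' sum over i in 0..3 of i * percent_at_i, ranging 0 (all cells unstained)
#' to 300 (all cells at strong intensity). Percentages must sum to 100;
#' hand-entered distributions that sum to 99 or 101 can be renormalized
#' explicitly, but the default is strict so data-entry errors surface.
#'
#' @param pct numeric vector of length 4: percentage of cells at intensity
#'   0 (absent), 1 (weak), 2 (moderate), 3 (strong), each in \[0,100\].
#' @param tol tolerance on `sum(pct) == 100` (default 1e-6).
#' @param renormalize if TRUE, rescale `pct` to sum to 100 instead of
#'   erroring.
#' @return the score, a number in \[0, 300\].
#' @export
compute_ihc_score <- function(pct, tol = 1e-6, renormalize = FALSE) {
  stopifnot(is.numeric(pct), length(pct) == 4)
  if (any(pct < 0)) stop("negative intensity percentage")
  s <- sum(pct)
  if (abs(s - 100) > tol) {
    if (!renormalize) {
      stop("intensity percentages sum to ", format(s), ", not 100")
    }
    if (s == 0) stop("all-zero intensity distribution")
    pct <- pct * 100 / s
  }
  sum(0:3 * pct)
}

#' Derive the IHC dichotomization cutoff from normal-tissue scores
#'
#' The cutoff is a multiple (default 3) of the median score in non-cancerous
#' tissue; with a normal median of 50 this gives the cutoff of 150.
#'
#' @param normal_scores numeric vector of scores from normal tissue.
#' @param multiplier multiple of the normal median (default 3).
#' @return list with `normal_median`, `multiplier`, `cutoff`.
#' @export
derive_ihc_cutoff <- function(normal_scores, multiplier = 3) {
  if (length(normal_scores) == 0) stop("no normal-tissue scores supplied")
  stopifnot(is.numeric(normal_scores), multiplier >= 0)
  med <- stats::median(normal_scores)
  list(normal_median = med, multiplier = multiplier,
       cutoff = multiplier * med)
}

#' Dichotomize IHC scores at a cutoff
#'
#' High expression is a score strictly greater than the cutoff; a score equal
#' to the cutoff is low (low: score <= cutoff, high: score > cutoff).
#'
#' @param scores numeric vector of IHC scores.
#' @param cutoff a [derive_ihc_cutoff()] result or a single number.
#' @return list with `label` (character vector `"low"`/`"high"`), `n_low`,
#'   `n_high`, `cutoff`.
#' @export
dichotomize_ihc <- function(scores, cutoff) {
  if (is.list(cutoff)) cutoff <- cutoff$cutoff
  stopifnot(is.numeric(scores), is.numeric(cutoff), length(cutoff) == 1)
  label <- ifelse(scores > cutoff, "high", "low")
  list(label = label, n_low = sum(label == "low"),
       n_high = sum(label == "high"), cutoff = cutoff)
}
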