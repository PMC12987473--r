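#' Min-max normalize front objectives so 1 is always best
#'
#' Per objective, min-max normalization over the front to \[0, 1\],
#' oriented so that 1 is best: duration is inverted (shorter is better),
#' yield and Ci are kept increasing. An objective with zero range over the
#' front maps to 1 for every solution.
#'
#' Equal raw weights over days, t/hm^2 and a unitless score would let the
#' largest-scaled objective dominate; normalizing first is what makes
#' "equal weights" meaningful across units.
#'
#' @param front a `pareto_front` (or its `solutions` data.frame).
#' @return matrix with columns `duration`, `yield`, `ci`, entries in
#'   \[0, 1\].
#' @export
normalize_front_objectives <- function(front) {
  sol <- if (inherits(front, "pareto_front")) front$solutions else front
  if (!nrow(sol)) stop("empty front")
  norm_one <- function(v, higher_better) {
    rng <- max(v) - min(v)
    if (rng == 0) return(rep(1, length(v)))
    if (higher_better) (v - min(v)) / rng else (max(v) - v) / rng
  }
  cbind(duration = norm_one(sol$duration, FALSE),
        yield = norm_one(sol$yield, TRUE),
        ci = norm_one(sol$ci, TRUE))
}

#' Collapse a Pareto front to one recommendation by weighted sum
#'
#' Scores every front solution as the weighted sum of its normalized
#' objectives (see [normalize_front_objectives()]) and returns the argmax.
#' Equal weights (1, 1, 1) are the default. Score ties are broken in
#' favour of shorter duration, then higher yield, then higher Ci, then
#' input order — the stated goal ordering (early maturity, high yield,
#' superior quality).
#'
#' @param front a `pareto_front`.
#' @param weights positive length-3 weights for (duration, yield, ci).
#' @param normalize normalize objectives before summing (default TRUE);
#'   `FALSE` scores raw physical units, for sensitivity analysis only.
#' @return object of class `decision_result`: `chosen` (one-row
#'   data.frame), `scores`, `weights`, `normalized`.
#' @export
weighted_sum_select <- function(front, weights = c(1, 1, 1),
                                normalize = TRUE) {
  stopifnot(length(weights) == 3, all(weights > 0))
  sol <- if (inherits(front, "pareto_front")) front$solutions else front
  if (!nrow(sol)) stop("empty front")
  nrm <- if (normalize) normalize_front_objectives(sol) else
    cbind(duration = -sol$duration, yield = sol$yield, ci = sol$ci)
  scores <- as.vector(nrm %*% weights)
  best_score <- max(scores)
  cand <- which(scores >= best_score - 1e-12)
  if (length(cand) > 1) {
    o <- order(sol$duration[cand], -sol$yield[cand], -sol$ci[cand])
    cand <- cand[o]
  }
  chosen_idx <- cand[1]
  structure(list(
    chosen = sol[chosen_idx, , drop = FALSE],
    chosen_index = chosen_idx,
    scores = scores, weights = weights, normalized = nrm,
    tie = length(cand) > 1
  ), class = "decision_result")
}

#' @export
print.decision_result <- function(x, digits = 3, ...) {
  ch <- x$chosen
  cat("Recommended configuration (weighted-sum over the Pareto front):\n")
  cat(sprintf("  %g cm spacing, %s pruning\n", ch$spacing, ch$pruning))
  cat(sprintf("  predicted: %.1f days, %.2f t/hm2, Ci %.2f (score %.3f)\n",
              ch$duration, ch$yield, ch$ci, x$scores[x$chosen_index]))
  if (x$tie) cat("  note: score tie broken by (duration, yield, Ci)\n")
  invisible(x)
}

#' Write a decision result to JSON
#'
#' @param dec a `decision_result`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
decision_result_json <- function(dec, path = NULL) {
  stopifnot(inherits(dec, "decision_result"))
  js <- jsonlite::toJSON(list(chosen = dec$chosen, scores = dec$scores,
                              weights = dec$weights, tie = dec$tie),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
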