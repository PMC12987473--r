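#' Build a decision matrix for entropy-weight TOPSIS
#'
#' Rows are evaluation objects (treatments), columns are quality
#' indicators, entries the strictly positive indicator values in their
#' original units.
#'
#' @param values numeric matrix (or data.frame) of indicator values.
#' @param objects optional row labels (default rownames).
#' @param indicators optional column labels (default colnames).
#' @return object of class `decision_matrix` (a validated numeric matrix).
#' @export
decision_matrix <- function(values, objects = rownames(values),
                            indicators = colnames(values)) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (is.null(objects)) objects <- paste0("obj", seq_len(nrow(m)))
  if (is.null(indicators)) indicators <- paste0("ind", seq_len(ncol(m)))
  dimnames(m) <- list(objects, indicators)
  if (nrow(m) < 2) stop("decision matrix needs at least 2 objects")
  if (ncol(m) < 1) stop("decision matrix needs at least 1 indicator")
  if (anyNA(m)) stop("decision matrix has missing cells")
  if (any(m <= 0)) stop("decision matrix entries must be strictly positive")
  class(m) <- c("decision_matrix", class(m))
  m
}

#' Vector (sum-of-squares) normalization of a decision matrix
#'
#' Each column is divided by its Euclidean norm, removing units: every
#' column of the result has unit sum of squares.
#'
#' @param m a [decision_matrix()] (or positive numeric matrix).
#' @return normalized matrix `Y` with unit-norm columns.
#' @export
normalize_matrix <- function(m) {
  m <- unclass(as.matrix(m))
  norms <- sqrt(colSums(m^2))
  if (any(norms == 0)) {
    stop("degenerate all-zero indicator column: ",
         paste(colnames(m)[norms == 0], collapse = ", "))
  }
  sweep(m, 2, norms, "/")
}

#' Column-proportion matrix for entropy computation
#'
#' @param n normalized matrix from [normalize_matrix()].
#' @return matrix `P` whose columns each sum to 1.
#' @export
proportion_matrix <- function(n) {
  n <- as.matrix(n)
  sweep(n, 2, colSums(n), "/")
}

#' Information entropy of each indicator
#'
#' `H_j = -(1/ln a) * sum_i P_ij ln P_ij`, with `a` the number of
#' evaluation objects and the convention `0 * ln 0 = 0`. A uniform column
#' has maximum entropy 1; the more a column discriminates between objects,
#' the lower its entropy.
#'
#' @param p proportion matrix from [proportion_matrix()].
#' @param a number of evaluation objects (default `nrow(p)`).
#' @return numeric vector of entropies in \[0, 1\], one per indicator.
#' @export
entropy_values <- function(p, a = nrow(p)) {
  p <- as.matrix(p)
  if (a < 2) stop("entropy needs at least 2 evaluation objects (ln a > 0)")
  plogp <- ifelse(p > 0, p * log(p), 0)  # 0*ln0 := 0
  h <- -colSums(plogp) / log(a)
  pmin(pmax(h, 0), 1)
}

#' Entropy weights of the indicators
#'
#' `w_j = (1 - H_j) / (b - sum_j H_j)`: indicators with lower entropy
#' (more between-object contrast) receive more weight; the weights sum to
#' one.
#'
#' @param h vector of entropies in \[0, 1\] from [entropy_values()].
#' @return list with `entropies` and `weights` (class `entropy_weights`).
#' @export
entropy_weights <- function(h) {
  stopifnot(all(h >= 0 & h <= 1))
  b <- length(h)
  denom <- b - sum(h)
  if (denom <= 0 || all(h == 1)) {
    stop("degenerate weights: every indicator column is constant (H = 1)")
  }
  w <- (1 - h) / denom
  structure(list(entropies = h, weights = w), class = "entropy_weights")
}

#' Weighted decision matrix
#'
#' Scales each normalized column by its entropy weight: `Z_ij = w_j Y_ij`.
#'
#' @param n normalized matrix.
#' @param w an `entropy_weights` object or plain weight vector.
#' @return weighted matrix `Z`.
#' @export
weighted_matrix <- function(n, w) {
  n <- as.matrix(n)
  if (inherits(w, "entropy_weights")) w <- w$weights
  if (length(w) != ncol(n)) {
    stop("shape error: ", length(w), " weights for ", ncol(n), " columns")
  }
  sweep(n, 2, w, "*")
}

#' Positive and negative ideal solutions
#'
#' All indicators are treated as benefit-type: the positive ideal is the
#' vector of column maxima of the weighted matrix, the negative ideal the
#' column minima.
#'
#' @param z weighted matrix from [weighted_matrix()].
#' @return list with `positive` and `negative` vectors.
#' @export
ideal_solutions <- function(z) {
  z <- as.matrix(z)
  list(positive = apply(z, 2, max), negative = apply(z, 2, min))
}

#' Euclidean separations from the ideal solutions
#'
#' @param z weighted matrix.
#' @param ideals list from [ideal_solutions()].
#' @return list with vectors `d_plus` (distance to the positive ideal) and
#'   `d_minus` (distance to the negative ideal).
#' @export
separation_distances <- function(z, ideals) {
  z <- as.matrix(z)
  if (length(ideals$positive) != ncol(z)) {
    stop("shape error: ideal solutions do not match matrix columns")
  }
  list(
    d_plus = sqrt(rowSums(sweep(z, 2, ideals$positive)^2)),
    d_minus = sqrt(rowSums(sweep(z, 2, ideals$negative)^2))
  )
}

#' Relative closeness to the positive ideal
#'
#' `C_i = D_i^- / (D_i^+ + D_i^-)`, in \[0, 1\]; 1 means the object sits at
#' the positive ideal, 0 at the negative ideal.
#'
#' @param d_plus,d_minus separation vectors from [separation_distances()].
#' @return numeric vector of closeness coefficients.
#' @export
closeness <- function(d_plus, d_minus) {
  stopifnot(length(d_plus) == length(d_minus),
            all(d_plus >= 0), all(d_minus >= 0))
  tot <- d_plus + d_minus
  if (any(tot == 0)) {
    stop("degenerate object(s) at index ",
         paste(which(tot == 0), collapse = ", "),
         ": identical to every ideal (D+ = D- = 0)")
  }
  d_minus / tot
}

#' Entropy-weight TOPSIS scoring of a decision matrix
#'
#' Full chain: vector normalization, column proportions, indicator
#' entropies and entropy weights, weighted matrix, ideal solutions,
#' Euclidean separations, closeness, and ranking by descending closeness
#' (1 = best; ties broken by input order and flagged).
#'
#' @param m a [decision_matrix()], or a [trial_dataset()] whose
#'   `indicators` matrix is used.
#' @param separation_scale scale convention for the *reported* separations
#'   `Di+` / `Di-`. `"rms"` (default) divides each original column by its
#'   root-mean-square rather than its root-sum-of-squares before measuring
#'   distance, i.e. multiplies the unit-norm separations by `sqrt(a)`;
#'   `"unit"` reports raw Euclidean distances in the unit-norm space.
#'   Closeness and ranks are identical under either convention (a common
#'   positive factor cancels in `Ci`); the `"rms"` scale matches the
#'   convention of published melon-quality evaluation tables.
#' @return object of class `topsis_result`: list with `weights`
#'   (entropies + weights), `normalized`, `weighted`, `ideals`, `d_plus`,
#'   `d_minus`, `closeness`, `ranks`, `ties` flag, `objects`,
#'   `separation_scale`.
#' @examples
#' ds <- builtin_fixture("quality_table4")
#' res <- run_topsis(ds)
#' round(res$closeness, 3)
#' @export
run_topsis <- function(m, separation_scale = c("rms", "unit")) {
  separation_scale <- match.arg(separation_scale)
  if (inherits(m, "trial_dataset")) {
    if (is.null(m$indicators)) stop("trial dataset has no indicator table")
    m <- decision_matrix(m$indicators)
  } else if (!inherits(m, "decision_matrix")) {
    m <- decision_matrix(m)
  }
  a <- nrow(m)
  y <- normalize_matrix(m)
  p <- proportion_matrix(y)
  h <- entropy_values(p, a)
  w <- entropy_weights(h)
  z <- weighted_matrix(y, w)
  ideals <- ideal_solutions(z)
  sep <- separation_distances(z, ideals)
  scale <- if (separation_scale == "rms") sqrt(a) else 1
  d_plus <- scale * sep$d_plus
  d_minus <- scale * sep$d_minus
  ci <- closeness(d_plus, d_minus)
  ranks <- rank(-ci, ties.method = "first")
  names(ci) <- names(d_plus) <- names(d_minus) <- rownames(m)
  structure(list(
    weights = w, normalized = y, weighted = z, ideals = ideals,
    d_plus = d_plus, d_minus = d_minus, closeness = ci,
    ranks = stats::setNames(as.integer(ranks), rownames(m)),
    ties = anyDuplicated(ci) > 0,
    objects = rownames(m), separation_scale = separation_scale
  ), class = "topsis_result")
}

#' @export
print.topsis_result <- function(x, digits = 3, ...) {
  cat("Entropy-weight TOPSIS over", length(x$objects), "objects x",
      length(x$weights$weights), "indicators\n")
  cat("Indicator weights:\n")
  print(round(x$weights$weights, digits))
  tab <- as.data.frame(x)
  print(tab[order(tab$rank), ], row.names = FALSE, digits = digits)
  if (x$ties) cat("note: tied closeness values broken by input order\n")
  invisible(x)
}

#' @export
as.data.frame.topsis_result <- function(x, ...) {
  data.frame(object = x$objects, d_plus = x$d_plus, d_minus = x$d_minus,
             ci = x$closeness, rank = x$ranks,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a TOPSIS result to JSON
#'
#' Carries weights, separations, closeness and ranks at full precision,
#' plus 3-decimal display fields matching the published table layout.
#'
#' @param res a `topsis_result`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
topsis_result_json <- function(res, path = NULL) {
  stopifnot(inherits(res, "topsis_result"))
  payload <- list(
    objects = res$objects,
    entropies = unname(res$weights$entropies),
    weights = unname(res$weights$weights),
    d_plus = unname(res$d_plus),
    d_minus = unname(res$d_minus),
    ci = unname(res$closeness),
    rank = unname(res$ranks),
    separation_scale = res$separation_scale,
    display = data.frame(object = res$objects,
                         d_plus = sprintf("%.3f", res$d_plus),
                         d_minus = sprintf("%.3f", res$d_minus),
                         ci = sprintf("%.3f", res$closeness),
                         rank = unname(res$ranks))
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Pearson goodness of fit
#'
#' Product-moment correlation computed straight from its definition,
#' `R = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2))`;
#' used to report how well surrogate predictions track observations.
#'
#' @param x,y numeric vectors of equal length (>= 2), neither constant.
#' @return correlation in \[-1, 1\].
#' @export
goodness_of_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    stop("goodness of fit undefined for a constant vector")
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  min(max(r, -1), 1)
}
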