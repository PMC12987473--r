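#' @keywords internal
"_PACKAGE"

# Pruning-fruit-retention coding used throughout: the four methods are
# assigned ordinal codes 1..4.
PRUNING_LABELS <- c("1V1F", "2V2F", "3V3F", "3V2F")
PRUNING_VINES  <- c(1L, 2L, 3L, 3L)
PRUNING_FRUITS <- c(1L, 2L, 3L, 2L)

# Feasible design grid: spacing 30..80 cm in 5 cm steps, four pruning codes.
SPACING_MIN <- 30
SPACING_MAX <- 80
SPACING_STEP <- 5

#' Pruning-method code/label helpers
#'
#' The four pruning-fruit-retention methods (single vine one fruit, double
#' vine two fruits, three vines three fruits, three vines two fruits) are
#' encoded ordinally as 1, 2, 3, 4.
#'
#' @param code integer vector of codes in 1..4.
#' @param label character vector of labels ("1V1F", "2V2F", "3V3F", "3V2F").
#' @return `pruning_label()` returns labels; `pruning_code()` codes;
#'   `pruning_vines()` / `pruning_fruits()` the vine and fruit counts kept.
#' @examples
#' pruning_label(4)       # "3V2F"
#' pruning_vines(1:4)     # 1 2 3 3
#' @export
pruning_label <- function(code) {
  stopifnot(all(code %in% 1:4))
  PRUNING_LABELS[code]
}

#' @rdname pruning_label
#' @export
pruning_code <- function(label) {
  idx <- match(toupper(label), PRUNING_LABELS)
  if (anyNA(idx)) {
    stop("unknown pruning label(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "),
         "; expected one of ", paste(PRUNING_LABELS, collapse = ", "))
  }
  idx
}

#' @rdname pruning_label
#' @export
pruning_vines <- function(code) {
  stopifnot(all(code %in% 1:4))
  PRUNING_VINES[code]
}

#' @rdname pruning_label
#' @export
pruning_fruits <- function(code) {
  stopifnot(all(code %in% 1:4))
  PRUNING_FRUITS[code]
}

#' The feasible cultivation design grid
#'
#' Every feasible (spacing, pruning) combination: spacing an integer
#' multiple of 5 in \[30, 80\] cm (11 levels) crossed with the four pruning
#' codes, 44 designs in all.
#'
#' @return data.frame with columns `spacing`, `pruning_code`, `pruning`.
#' @export
design_grid <- function() {
  g <- expand.grid(spacing = seq(SPACING_MIN, SPACING_MAX, by = SPACING_STEP),
                   pruning_code = 1:4, KEEP.OUT.ATTRS = FALSE)
  g$pruning <- pruning_label(g$pruning_code)
  g
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded package internals never clobber user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a distinct 31-bit sub-seed from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647
}
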