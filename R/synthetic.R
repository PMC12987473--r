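#' Define a synthetic two-factor trial scenario
#'
#' A scenario fixes the response surfaces and noise model of a simulated
#' spacing x pruning field trial. The default surfaces emulate the
#' qualitative structure of real netted-melon trials: yield strictly
#' decreasing in plant spacing with the three-vine two-fruit method on
#' top; growth duration increasing with the number of retained vines (and
#' mildly with fruits); comprehensive quality (Ci) increasing and
#' saturating with spacing; and quality-indicator means increasing in
#' spacing with pruning offsets ordered 3V2F > 2V2F > 3V3F. Replicate
#' noise is independent Gaussian with sd equal to `noise_frac` times each
#' response's surface range over the full feasible grid.
#'
#' @param spacings spacing levels (cm), a subset of the 30..80 step-5 grid.
#' @param pruning_codes pruning codes used (subset of 1..4).
#' @param design `"published"` for the published 10-treatment layout (the
#'   single-vine control only at the smallest spacing, the three multi-vine
#'   methods crossed with all spacings) or `"factorial"` for the full
#'   crossing.
#' @param replicates replicates per treatment.
#' @param noise_frac replicate noise sd as a fraction of surface range
#'   (>= 0; 0 gives noiseless data).
#' @param coefficients optional list overriding surface coefficients; see
#'   Details.
#' @details Surface families (spacing `s` in cm, vines/fruits from the
#' pruning code): duration `d0 + dv*(vines-1) + df*(fruits-1) + ds*(s-55)`;
#' yield `y0 + ys*(s-55) + ys2*(s-55)^2 + ycode[code]`; Ci a logistic in
#' spacing,
#' `lo + (hi-lo)/(1+exp(-(s-mid)/tau)) + cs2*(s-speak)^2 + cicode[code]`,
#' clamped to \[0, 1\] (the optional quadratic term, default off, lets a
#' scenario plant a quality peak at an interior spacing); indicator k `base_k * (1 + slope_k*(s-55)/20 + off[code])`.
#' @return list of class `trial_scenario`.
#' @export
trial_scenario <- function(spacings = c(55, 65, 75), pruning_codes = 1:4,
                           design = c("published", "factorial"),
                           replicates = 3, noise_frac = 0.05,
                           coefficients = list()) {
  design <- match.arg(design)
  stopifnot(length(spacings) >= 2, length(pruning_codes) >= 2,
            all(spacings %in% seq(SPACING_MIN, SPACING_MAX, SPACING_STEP)),
            all(pruning_codes %in% 1:4), replicates >= 1, noise_frac >= 0)
  defaults <- list(
    duration = c(d0 = 101, dv = 8, df = 1, ds = -0.1),
    yield = list(y0 = 51, ys = -0.4, ys2 = 0, ycode = c(-22, 0, -1, 3)),
    ci = list(lo = 0.03, hi = 0.92, mid = 62, tau = 6,
              cs2 = 0, speak = 70, cicode = c(0.02, 0, -0.03, 0.03)),
    indicators = list(
      base = c(single_fruit_weight_kg = 2.5, fruit_shape_index = 1.4,
               moisture_pct = 88, hardness_N = 2.6,
               flesh_thickness_mm = 37, soluble_solids_pct = 14,
               soluble_sugar_mg_g = 1.1, soluble_sugar_pct = 13.5,
               vitamin_c_mg_kg = 3.5),
      slope = rep(0.08, 9),
      off = c(0.00, 0.01, -0.02, 0.03))
  )
  co <- utils::modifyList(defaults, coefficients)
  structure(list(spacings = sort(spacings),
                 pruning_codes = sort(as.integer(pruning_codes)),
                 design = design, replicates = as.integer(replicates),
                 noise_frac = noise_frac, coefficients = co),
            class = "trial_scenario")
}

# Noiseless response surfaces on arbitrary designs.
scenario_surface <- function(sc, spacing, code) {
  co <- sc$coefficients
  v <- pruning_vines(code)
  f <- pruning_fruits(code)
  dur <- co$duration["d0"] + co$duration["dv"] * (v - 1) +
    co$duration["df"] * (f - 1) + co$duration["ds"] * (spacing - 55)
  yld <- co$yield$y0 + co$yield$ys * (spacing - 55) +
    co$yield$ys2 * (spacing - 55)^2 + co$yield$ycode[code]
  ci <- co$ci$lo + (co$ci$hi - co$ci$lo) /
    (1 + exp(-(spacing - co$ci$mid) / co$ci$tau)) +
    co$ci$cs2 * (spacing - co$ci$speak)^2 + co$ci$cicode[code]
  data.frame(spacing = spacing, pruning_code = code,
             duration = unname(dur), yield = unname(yld),
             ci = pmin(pmax(ci, 0), 1))
}

scenario_indicator_means <- function(sc, spacing, code) {
  co <- sc$coefficients$indicators
  n <- length(spacing)
  out <- matrix(NA_real_, n, length(co$base),
                dimnames = list(NULL, names(co$base)))
  for (k in seq_along(co$base)) {
    out[, k] <- co$base[k] *
      (1 + co$slope[k] * (spacing - 55) / 20 + co$off[code])
  }
  out
}

# Per-response noise sd: noise_frac x surface range over the full grid.
scenario_noise_sd <- function(sc) {
  grid <- design_grid()
  surf <- scenario_surface(sc, grid$spacing, grid$pruning_code)
  ind <- scenario_indicator_means(sc, grid$spacing, grid$pruning_code)
  rng <- function(x) max(x) - min(x)
  list(duration = sc$noise_frac * rng(surf$duration),
       yield = sc$noise_frac * rng(surf$yield),
       ci = sc$noise_frac * rng(surf$ci),
       indicators = sc$noise_frac * apply(ind, 2, rng))
}

scenario_design <- function(sc) {
  if (sc$design == "published") {
    multi <- setdiff(sc$pruning_codes, 1L)
    d <- expand.grid(spacing = sc$spacings, pruning_code = multi,
                     KEEP.OUT.ATTRS = FALSE)
    d <- d[order(d$spacing, d$pruning_code), ]
    if (1L %in% sc$pruning_codes) {
      d <- rbind(data.frame(spacing = min(sc$spacings), pruning_code = 1L), d)
    }
    d$label <- c("CK", paste0("T", seq_len(nrow(d) - 1)))[seq_len(nrow(d))]
    if (!1L %in% sc$pruning_codes) d$label <- paste0("T", seq_len(nrow(d)))
  } else {
    d <- expand.grid(spacing = sc$spacings, pruning_code = sc$pruning_codes,
                     KEEP.OUT.ATTRS = FALSE)
    d$label <- sprintf("S%dP%d", d$spacing, d$pruning_code)
  }
  rownames(d) <- NULL
  d[, c("label", "spacing", "pruning_code")]
}

# Synthetic phenology: stage dates placed at fixed fractions of the total
# growth duration after a nominal mid-March sowing.
synthesize_phenology <- function(label, duration) {
  sowing <- as.Date("2023-03-18")
  frac <- c(0, 0.14, 0.42, 0.62, 0.68, 0.84, 1)
  off <- vapply(duration, function(d) round(frac * (d - 1)), numeric(7))
  ph <- data.frame(label = label,
                   sowing_date = sowing + off[1, ],
                   emergence_date = sowing + off[2, ],
                   vine_elongation_date = sowing + off[3, ],
                   female_flower_date = sowing + off[4, ],
                   fruit_set_date = sowing + off[5, ],
                   enlargement_date = sowing + off[6, ],
                   maturity_date = sowing + off[7, ],
                   stringsAsFactors = FALSE)
  ph
}

#' Generate a synthetic trial dataset from a scenario
#'
#' Builds the scenario's treatment design, computes noiseless mean
#' responses and indicator means from its surfaces, adds independent
#' Gaussian replicate noise, and averages replicates into a
#' [trial_dataset()] (with synthetic phenology dates consistent with each
#' treatment's rounded duration). Deterministic given `seed`.
#'
#' @param sc a [trial_scenario()].
#' @param seed integer seed for the replicate noise.
#' @return a [trial_dataset()] with `treatments`, `phenology`,
#'   `indicators`, `indicator_sd`, and complete `responses`.
#' @export
generate_trial <- function(sc, seed = 1L) {
  stopifnot(inherits(sc, "trial_scenario"))
  des <- scenario_design(sc)
  surf <- scenario_surface(sc, des$spacing, des$pruning_code)
  ind_mean <- scenario_indicator_means(sc, des$spacing, des$pruning_code)
  sds <- scenario_noise_sd(sc)
  n <- nrow(des)
  R <- sc$replicates
  with_seed(seed, {
    noisy_mean <- function(mu, sd) {
      if (sd == 0) return(mu)
      mu + stats::rnorm(length(mu), 0, sd / sqrt(R))
    }
    # replicate-mean noise: averaging R iid N(mu, sd) replicates
    duration <- noisy_mean(surf$duration, sds$duration)
    yield <- noisy_mean(surf$yield, sds$yield)
    ci <- pmin(pmax(noisy_mean(surf$ci, sds$ci), 0), 1)
    ind <- ind_mean
    ind_sd <- matrix(rep(sds$indicators, each = n), n,
                     dimnames = dimnames(ind_mean))
    for (k in seq_len(ncol(ind))) {
      ind[, k] <- noisy_mean(ind_mean[, k], sds$indicators[k])
    }
    ind[ind <= 0] <- .Machine$double.eps  # indicators are positive-valued
    rownames(ind) <- des$label
    resp <- data.frame(label = des$label, duration = duration,
                       yield = pmax(yield, .Machine$double.eps), ci = ci,
                       stringsAsFactors = FALSE)
    ds <- trial_dataset(des, phenology = synthesize_phenology(des$label,
                                                              round(duration)),
                        indicators = ind,
                        indicator_sd = if (sc$noise_frac > 0) ind_sd else NULL,
                        responses = resp)
    attr(ds, "scenario") <- sc
    attr(ds, "seed") <- seed
    ds
  })
}

#' True optimal design planted by a scenario
#'
#' Evaluates the noiseless objective triple on every feasible design (the
#' full 44-point grid), takes the exact Pareto set, and applies the
#' weighted-sum decision rule — the recovery target against which the
#' fitted pipeline is judged.
#'
#' @param sc a [trial_scenario()].
#' @param weights length-3 positive weights (default equal).
#' @return one-row data.frame: `spacing`, `pruning_code`, `pruning`,
#'   `duration`, `yield`, `ci`.
#' @export
planted_optimum <- function(sc, weights = c(1, 1, 1)) {
  stopifnot(inherits(sc, "trial_scenario"))
  grid <- design_grid()
  surf <- scenario_surface(sc, grid$spacing, grid$pruning_code)
  obj <- cbind(surf$duration, -surf$yield, -surf$ci)
  keep <- vapply(seq_len(nrow(obj)), function(i) {
    !any(vapply(seq_len(nrow(obj)), function(j) {
      j != i && dominates(obj[j, ], obj[i, ])
    }, logical(1)))
  }, logical(1))
  sol <- surf[keep, ]
  sol$pruning <- pruning_label(sol$pruning_code)
  sol <- sol[order(sol$duration, -sol$yield, -sol$ci), ]
  rownames(sol) <- NULL
  front <- structure(list(solutions = sol,
                          provenance = list(method = "scenario-exhaustive")),
                     class = "pareto_front")
  dec <- weighted_sum_select(front, weights)
  dec$chosen[, c("spacing", "pruning_code", "pruning", "duration", "yield",
                 "ci")]
}

#' End-to-end planted-optimum recovery study
#'
#' For each seed: generate a synthetic trial, fit the surrogate, evolve
#' the NSGA-II front, apply weighted-sum selection, and compare the chosen
#' design with the scenario's planted optimum. "Exact" means the same
#' (spacing, pruning); "adjacent" allows one grid step (spacing within
#' +/- 5 cm and pruning code within +/- 1).
#'
#' @param sc a [trial_scenario()] (typically `design = "factorial"` over
#'   the full grid).
#' @param seeds integer vector of simulation seeds.
#' @param cfg a [surrogate_config()]; its `seed` is re-derived per run.
#' @param params a [ga_params()]; its `seed` is re-derived per run.
#' @param weights selection weights.
#' @return data.frame with one row per seed: chosen and planted designs,
#'   `exact` and `adjacent` logicals.
#' @export
recovery_study <- function(sc, seeds,
                           cfg = surrogate_config(restarts = 2,
                                                  split_mode = "none"),
                           params = ga_params(), weights = c(1, 1, 1)) {
  target <- planted_optimum(sc, weights)
  out <- lapply(seeds, function(s) {
    ds <- generate_trial(sc, seed = s)
    cfg_s <- cfg
    cfg_s$seed <- as.integer(derive_seed(s, 101) %% 2^31)
    fit <- train_surrogate(ds, cfg_s)
    params_s <- params
    params_s$seed <- as.integer(derive_seed(s, 202) %% 2^31)
    front <- evolve(fit$model, params_s)
    dec <- weighted_sum_select(front, weights)
    ch <- dec$chosen
    data.frame(seed = s, chosen_spacing = ch$spacing,
               chosen_code = ch$pruning_code,
               planted_spacing = target$spacing,
               planted_code = target$pruning_code,
               exact = ch$spacing == target$spacing &&
                 ch$pruning_code == target$pruning_code,
               adjacent = abs(ch$spacing - target$spacing) <= 5 &&
                 abs(ch$pruning_code - target$pruning_code) <= 1)
  })
  do.call(rbind, out)
}

#' Scenario with a pronounced planted optimum, for recovery studies
#'
#' A factorial scenario over the full feasible grid whose noiseless
#' weighted-sum optimum (70 cm, double-vine two-fruit) is a pronounced
#' knee: the quality surface peaks at 70 cm (quadratic hill on top of the
#' logistic rise) while yield keeps falling with spacing and duration
#' rises mildly, so every other Pareto-front member trails the optimum's
#' equal-weight score by a clear margin (about 0.23 score units on a 0-3
#' scale). The margin was sized by propagating the replicate-noise sd
#' through the normalized scores, so that 5% replicate noise rarely
#' reorders the top of the front. Quality here is deliberately
#' non-monotone in spacing (a peak, not a plateau); yield decreasing in
#' spacing and duration non-decreasing in vine count still hold.
#'
#' @param noise_frac replicate noise level (default 0.05).
#' @return a [trial_scenario()].
#' @export
recovery_scenario <- function(noise_frac = 0.05) {
  trial_scenario(
    spacings = seq(SPACING_MIN, SPACING_MAX, SPACING_STEP),
    design = "factorial", noise_frac = noise_frac,
    coefficients = list(
      duration = c(d0 = 101, dv = 8, df = 1, ds = 0.1),
      yield = list(y0 = 51, ys = -0.45, ys2 = 0, ycode = c(-32, 0, -2, 3)),
      ci = list(lo = 0.1, hi = 0.9, mid = 60, tau = 4, cs2 = -0.012,
                speak = 70, cicode = c(-0.05, 0, -0.03, 0.03))
    ))
}
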