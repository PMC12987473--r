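#' Construct a trial dataset
#'
#' A `trial_dataset` bundles the tables of a two-factor cultivation trial:
#' the treatment design (plant spacing x pruning-fruit-retention method),
#' optional phenology stage dates, optional per-treatment quality-indicator
#' means (and sds), and optional responses (growth duration, yield,
#' comprehensive-quality closeness Ci).
#'
#' @param treatments data.frame with columns `label`, `spacing` (cm) and
#'   `pruning_code` (1..4); a `pruning` label column is added if absent.
#' @param phenology optional data.frame with `label` and the seven stage
#'   dates (`sowing_date`, `emergence_date`, `vine_elongation_date`,
#'   `female_flower_date`, `fruit_set_date`, `enlargement_date`,
#'   `maturity_date`) as `Date`s.
#' @param indicators optional numeric matrix of quality-indicator means,
#'   rownames = treatment labels.
#' @param indicator_sd optional matrix of replicate sds, same shape.
#' @param responses optional data.frame with `label` and any of
#'   `duration` (days), `yield` (t/hm^2), `ci` (unitless, in \[0,1\]).
#' @return object of class `trial_dataset`.
#' @seealso [validate_dataset()], [builtin_fixture()], [load_trial_table()]
#' @export
trial_dataset <- function(treatments, phenology = NULL, indicators = NULL,
                          indicator_sd = NULL, responses = NULL) {
  stopifnot(is.data.frame(treatments),
            all(c("label", "spacing", "pruning_code") %in% names(treatments)))
  treatments$label <- as.character(treatments$label)
  treatments$pruning_code <- as.integer(treatments$pruning_code)
  if (is.null(treatments[["pruning"]])) {
    # [[ avoids partial matching against pruning_code
    treatments$pruning <- ifelse(is.na(treatments$pruning_code),
                                 NA_character_,
                                 PRUNING_LABELS[treatments$pruning_code])
  }
  if (!is.null(indicators)) {
    indicators <- as.matrix(indicators)
    storage.mode(indicators) <- "double"
  }
  if (!is.null(indicator_sd)) {
    indicator_sd <- as.matrix(indicator_sd)
    storage.mode(indicator_sd) <- "double"
  }
  structure(list(treatments = treatments, phenology = phenology,
                 indicators = indicators, indicator_sd = indicator_sd,
                 responses = responses),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Two-factor cultivation trial:", nrow(x$treatments), "treatments\n")
  cat("  spacings (cm):", paste(sort(unique(x$treatments$spacing)),
                                collapse = ", "), "\n")
  cat("  pruning:", paste(sort(unique(x$treatments$pruning)),
                          collapse = ", "), "\n")
  cat("  phenology:", if (is.null(x$phenology)) "absent" else "present", "|",
      "indicators:", if (is.null(x$indicators)) "absent" else
        paste0(ncol(x$indicators), " cols"), "|",
      "responses:", if (is.null(x$responses)) "absent" else
        paste(setdiff(names(x$responses), "label"), collapse = "/"), "\n")
  invisible(x)
}

# ---- phenology arithmetic ---------------------------------------------------

#' Inclusive duration of a phenological stage, in days
#'
#' Day counts in the growth-period tables count both endpoints: the number
#' of days from sowing to maturity is the calendar difference plus one, so
#' a stage starting and ending on the same day lasts one day.
#'
#' @param start_date,end_date `Date` vectors (recycled to common length).
#' @return integer vector of inclusive day counts.
#' @examples
#' stage_duration(as.Date("2023-05-25"), as.Date("2023-06-26"))  # 33
#' stage_duration(as.Date("2023-03-18"), as.Date("2023-06-26"))  # 101
#' @export
stage_duration <- function(start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (anyNA(start_date) || anyNA(end_date)) {
    stop("stage_duration: missing or unparseable date")
  }
  bad <- end_date < start_date
  if (any(bad)) {
    stop(sprintf("stage_duration: end date %s precedes start date %s",
                 end_date[which(bad)[1]], start_date[which(bad)[1]]))
  }
  as.integer(end_date - start_date) + 1L
}

#' Fruit-development and total-growth durations from stage dates
#'
#' @param phenology data.frame of stage dates (see [trial_dataset()]), or a
#'   `trial_dataset` whose `phenology` element is used.
#' @return data.frame with `label`, `fruit_development_days` (inclusive
#'   fruit set -> maturity) and `total_growth_days` (inclusive sowing ->
#'   maturity).
#' @export
compute_phenology_durations <- function(phenology) {
  if (inherits(phenology, "trial_dataset")) phenology <- phenology$phenology
  if (is.null(phenology)) stop("no phenology records available")
  req <- c("label", "sowing_date", "fruit_set_date", "maturity_date")
  miss <- setdiff(req, names(phenology))
  if (length(miss)) {
    stop("phenology table is missing field(s): ", paste(miss, collapse = ", "))
  }
  data.frame(
    label = as.character(phenology$label),
    fruit_development_days = stage_duration(phenology$fruit_set_date,
                                            phenology$maturity_date),
    total_growth_days = stage_duration(phenology$sowing_date,
                                       phenology$maturity_date),
    stringsAsFactors = FALSE
  )
}

# ---- parsing helpers --------------------------------------------------------

# Dates arrive either as ISO 8601 (2023-05-25) or the field-book dialect
# YYYY/M/D (2023/5/25).
parse_trial_date <- function(x) {
  x <- trimws(as.character(x))
  out <- as.Date(rep(NA_character_, length(x)))
  iso <- grepl("^\\d{4}-\\d{1,2}-\\d{1,2}$", x)
  slash <- grepl("^\\d{4}/\\d{1,2}/\\d{1,2}$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  out[slash] <- as.Date(x[slash], format = "%Y/%m/%d")
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    stop("unparseable date(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Parse "mean +/- sd" table cells
#'
#' Quality tables print cells like `"2.79 ± 0.13a"`: a replicate mean, a
#' plus/minus sd, and trailing significance letters from a multiple range
#' test. The letters are stripped; plain numeric cells pass through with an
#' `NA` sd.
#'
#' @param x character (or numeric) vector of cells.
#' @return data.frame with numeric columns `mean` and `sd`.
#' @examples
#' parse_mean_sd("2.79 ± 0.13a")
#' @export
parse_mean_sd <- function(x) {
  if (is.numeric(x)) {
    return(data.frame(mean = as.numeric(x), sd = NA_real_))
  }
  x <- trimws(as.character(x))
  num <- "[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?"
  pm <- paste0("^(", num, ")\\s*(?:±|\\+/?-)\\s*(", num,
               ")\\s*[a-zA-Z ]*$")
  plain <- paste0("^(", num, ")\\s*[a-zA-Z ]*$")
  mean_v <- rep(NA_real_, length(x))
  sd_v <- rep(NA_real_, length(x))
  is_pm <- grepl(pm, x)
  is_plain <- !is_pm & grepl(plain, x)
  mean_v[is_pm] <- as.numeric(sub(pm, "\\1", x[is_pm]))
  sd_v[is_pm] <- as.numeric(sub(pm, "\\2", x[is_pm]))
  mean_v[is_plain] <- as.numeric(sub(plain, "\\1", x[is_plain]))
  bad <- !is_pm & !is_plain & !is.na(x) & x != ""
  if (any(bad)) {
    stop("unparseable numeric cell(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  data.frame(mean = mean_v, sd = sd_v)
}

PHENOLOGY_DATE_COLS <- c("sowing_date", "emergence_date",
                         "vine_elongation_date", "female_flower_date",
                         "fruit_set_date", "enlargement_date",
                         "maturity_date")

# ---- table I/O --------------------------------------------------------------

#' Read a trial table from CSV
#'
#' Four table kinds are supported. `design`: columns `treatment` (or
#' `label`), `spacing_cm` (or `spacing`), `pruning` (label or code).
#' `phenology`: `treatment` plus the seven stage-date columns (ISO 8601 or
#' `YYYY/M/D`); any printed duration columns are kept for cross-checking.
#' `indicators`: `treatment` plus one column per quality indicator, cells
#' numeric or `"mean ± sd"` with optional significance letters.
#' `responses`: `treatment` plus any of `duration`, `yield` (alias
#' `yield_t_hm2`), `ci`.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param schema one of `"design"`, `"phenology"`, `"indicators"`,
#'   `"responses"`.
#' @return a [trial_dataset()] populated for that table kind. For
#'   `phenology`, printed duration columns (if present) are attached as the
#'   attribute `"printed_durations"` of the returned dataset.
#' @export
load_trial_table <- function(path,
                             schema = c("design", "phenology", "indicators",
                                        "responses")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) {
      stop("schema error: cannot read ", path, ": ", conditionMessage(e))
    })
  if (nrow(df) == 0 || ncol(df) == 0) {
    stop("schema error: empty table in ", path)
  }
  names(df)[names(df) %in% c("treatment", "Treatment", "Treatments")] <- "label"
  if (!"label" %in% names(df)) {
    stop("schema error: expected a 'treatment' (or 'label') column; found: ",
         paste(names(df), collapse = ", "))
  }
  df$label <- as.character(df$label)

  if (schema == "design") {
    names(df)[names(df) == "spacing_cm"] <- "spacing"
    need <- c("label", "spacing", "pruning")
    extra <- setdiff(names(df), c(need, "pruning_code"))
    if (length(extra) || !all(need %in% names(df))) {
      stop("schema error: design table expects columns ",
           paste(need, collapse = ", "), "; found: ",
           paste(names(df), collapse = ", "))
    }
    code <- if (suppressWarnings(all(!is.na(as.integer(df$pruning))))) {
      as.integer(df$pruning)
    } else {
      pruning_code(df$pruning)
    }
    tr <- data.frame(label = df$label, spacing = as.numeric(df$spacing),
                     pruning_code = code, stringsAsFactors = FALSE)
    return(trial_dataset(tr))
  }

  if (schema == "phenology") {
    miss <- setdiff(PHENOLOGY_DATE_COLS, names(df))
    if (length(miss)) {
      stop("schema error: phenology table missing column(s): ",
           paste(miss, collapse = ", "))
    }
    ph <- df[, c("label", PHENOLOGY_DATE_COLS)]
    for (cn in PHENOLOGY_DATE_COLS) ph[[cn]] <- parse_trial_date(ph[[cn]])
    tr <- data.frame(label = ph$label, spacing = NA_real_,
                     pruning_code = NA_integer_, stringsAsFactors = FALSE)
    tr$pruning <- NA_character_
    ds <- trial_dataset(tr, phenology = ph)
    printed <- intersect(c("fruit_development_days", "total_growth_days"),
                         names(df))
    if (length(printed)) {
      attr(ds, "printed_durations") <-
        df[, c("label", printed), drop = FALSE]
    }
    return(ds)
  }

  if (schema == "indicators") {
    all_cols <- setdiff(names(df), "label")
    # `<name>_sd` companions (as written by write_trial_table) fold into
    # the sd matrix rather than becoming indicators of their own
    sd_cols <- all_cols[endsWith(all_cols, "_sd") &
                          sub("_sd$", "", all_cols) %in% all_cols]
    ind_cols <- setdiff(all_cols, sd_cols)
    if (!length(ind_cols)) stop("schema error: no indicator columns found")
    means <- sds <- matrix(NA_real_, nrow(df), length(ind_cols),
                           dimnames = list(df$label, ind_cols))
    for (j in seq_along(ind_cols)) {
      p <- tryCatch(parse_mean_sd(df[[ind_cols[j]]]), error = function(e) {
        stop("column '", ind_cols[j], "': ", conditionMessage(e))
      })
      means[, j] <- p$mean
      sds[, j] <- p$sd
      companion <- paste0(ind_cols[j], "_sd")
      if (companion %in% sd_cols) sds[, j] <- as.numeric(df[[companion]])
    }
    tr <- data.frame(label = df$label, spacing = NA_real_,
                     pruning_code = NA_integer_, stringsAsFactors = FALSE)
    tr$pruning <- NA_character_
    return(trial_dataset(tr, indicators = means,
                         indicator_sd = if (all(is.na(sds))) NULL else sds))
  }

  # responses
  names(df)[names(df) == "yield_t_hm2"] <- "yield"
  keep <- intersect(c("duration", "yield", "ci"), names(df))
  if (!length(keep)) {
    stop("schema error: responses table expects at least one of ",
         "'duration', 'yield' (or 'yield_t_hm2'), 'ci'")
  }
  resp <- df[, c("label", keep), drop = FALSE]
  for (cn in keep) resp[[cn]] <- as.numeric(resp[[cn]])
  tr <- data.frame(label = df$label, spacing = NA_real_,
                   pruning_code = NA_integer_, stringsAsFactors = FALSE)
  tr$pruning <- NA_character_
  trial_dataset(tr, responses = resp)
}

#' Write one table of a trial dataset to CSV
#'
#' Dates are written in ISO 8601; indicator tables are written as plain
#' numeric means (sds, when present, in `<name>_sd` companion columns).
#' `load_trial_table()` on the result round-trips values and labels.
#'
#' @param ds a [trial_dataset()].
#' @param path output CSV path.
#' @param schema which table to write (see [load_trial_table()]).
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(ds, path,
                              schema = c("design", "phenology", "indicators",
                                         "responses")) {
  schema <- match.arg(schema)
  df <- switch(schema,
    design = {
      d <- ds$treatments[, c("label", "spacing", "pruning")]
      names(d) <- c("treatment", "spacing_cm", "pruning")
      d
    },
    phenology = {
      if (is.null(ds$phenology)) stop("dataset has no phenology table")
      d <- ds$phenology
      for (cn in PHENOLOGY_DATE_COLS) d[[cn]] <- format(d[[cn]], "%Y-%m-%d")
      names(d)[names(d) == "label"] <- "treatment"
      d
    },
    indicators = {
      if (is.null(ds$indicators)) stop("dataset has no indicator table")
      d <- data.frame(treatment = rownames(ds$indicators),
                      ds$indicators, check.names = FALSE,
                      stringsAsFactors = FALSE)
      if (!is.null(ds$indicator_sd)) {
        sd <- as.data.frame(ds$indicator_sd)
        names(sd) <- paste0(names(sd), "_sd")
        d <- cbind(d, sd)
      }
      d
    },
    responses = {
      if (is.null(ds$responses)) stop("dataset has no responses table")
      d <- ds$responses
      names(d)[names(d) == "label"] <- "treatment"
      d
    })
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---- validation -------------------------------------------------------------

issue <- function(severity, message, location) {
  data.frame(severity = severity, message = message, location = location,
             stringsAsFactors = FALSE)
}

#' Validate a trial dataset against its structural invariants
#'
#' Checks treatment-label uniqueness; spacing within \[30, 80\] cm and
#' divisible by 5; pruning codes in 1..4; phenology dates non-decreasing in
#' stage order and within one calendar year of sowing; indicator
#' completeness; yield > 0 and duration >= 1 where present; Ci in \[0, 1\].
#' Problems are reported, never raised.
#'
#' @param ds a [trial_dataset()].
#' @return object of class `validation_report`: list with `ok` (TRUE iff no
#'   error-severity issue) and `issues` (data.frame of severity, message,
#'   location).
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "trial_dataset"))
  iss <- list()
  tr <- ds$treatments
  if (anyDuplicated(tr$label)) {
    iss <- c(iss, list(issue("error", paste0("duplicate treatment label(s): ",
      paste(unique(tr$label[duplicated(tr$label)]), collapse = ", ")),
      "treatments")))
  }
  sp <- tr$spacing[!is.na(tr$spacing)]
  for (s in unique(sp[sp < SPACING_MIN | sp > SPACING_MAX])) {
    iss <- c(iss, list(issue("error",
      sprintf("spacing %s cm outside [%d, %d]", s, SPACING_MIN, SPACING_MAX),
      "treatments$spacing")))
  }
  for (s in unique(sp[sp %% SPACING_STEP != 0])) {
    iss <- c(iss, list(issue("error",
      sprintf("spacing %s cm not divisible by %d", s, SPACING_STEP),
      "treatments$spacing")))
  }
  pc <- tr$pruning_code[!is.na(tr$pruning_code)]
  if (!all(pc %in% 1:4)) {
    iss <- c(iss, list(issue("error", "pruning code outside 1..4",
                             "treatments$pruning_code")))
  }
  if (!is.null(ds$phenology)) {
    ph <- ds$phenology
    for (i in seq_len(nrow(ph))) {
      dates <- as.Date(unlist(ph[i, PHENOLOGY_DATE_COLS]),
                       origin = "1970-01-01")
      if (anyNA(dates)) {
        iss <- c(iss, list(issue("error", "missing stage date",
                                 paste0("phenology[", ph$label[i], "]"))))
        next
      }
      if (any(diff(dates) < 0)) {
        k <- which(diff(dates) < 0)[1]
        iss <- c(iss, list(issue("error",
          sprintf("stage dates out of order: %s (%s) before %s (%s)",
                  PHENOLOGY_DATE_COLS[k + 1], dates[k + 1],
                  PHENOLOGY_DATE_COLS[k], dates[k]),
          paste0("phenology[", ph$label[i], "]"))))
      }
      if (max(dates) - min(dates) > 366) {
        iss <- c(iss, list(issue("error",
          "stage dates span more than one calendar year",
          paste0("phenology[", ph$label[i], "]"))))
      }
    }
  }
  if (!is.null(ds$indicators) && anyNA(ds$indicators)) {
    iss <- c(iss, list(issue("error", "missing indicator value(s)",
                             "indicators")))
  }
  if (!is.null(ds$responses)) {
    r <- ds$responses
    if (!is.null(r$yield) && any(r$yield <= 0, na.rm = TRUE)) {
      iss <- c(iss, list(issue("error", "non-positive yield", "responses$yield")))
    }
    if (!is.null(r$duration) && any(r$duration < 1, na.rm = TRUE)) {
      iss <- c(iss, list(issue("error", "duration below 1 day",
                               "responses$duration")))
    }
    if (!is.null(r$ci) && any(r$ci < 0 | r$ci > 1, na.rm = TRUE)) {
      iss <- c(iss, list(issue("error", "Ci outside [0, 1]", "responses$ci")))
    }
    for (cn in intersect(c("yield", "duration", "ci"), names(r))) {
      if (anyNA(r[[cn]])) {
        iss <- c(iss, list(issue("warning",
          paste0("missing ", cn, " for: ",
                 paste(r$label[is.na(r[[cn]])], collapse = ", ")),
          paste0("responses$", cn))))
      }
    }
  }
  issues <- if (length(iss)) do.call(rbind, iss) else
    data.frame(severity = character(0), message = character(0),
               location = character(0), stringsAsFactors = FALSE)
  structure(list(ok = !any(issues$severity == "error"), issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation:", if (x$ok) "OK" else "FAILED", "-",
      nrow(x$issues), "issue(s)\n")
  if (nrow(x$issues)) {
    print(x$issues, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report a `validation_report` from [validate_dataset()].
#' @param path optional file to write; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
validation_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  js <- jsonlite::toJSON(list(ok = report$ok, issues = report$issues),
                         auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# ---- bundled bundled published tables ----------------------------------------------

#' Bundled trial tables
#'
#' The published trial tables ship with the package: the 10-treatment
#' design (3 spacings x 3 multi-vine pruning methods plus a single-vine
#' control), the phenology stage dates with their printed duration columns,
#' the 10 x 9 quality-indicator means, the published entropy-TOPSIS
#' reference table (Di+, Di-, Ci, rank), and the yields printed in the main
#' text (T3 = 53.97, CK = 27.86 t/hm^2; the remaining eight are `NA`, with
#' the printed rank order kept in `yield_rank`).
#'
#' @param name one of `"design_table2"`, `"phenology_table3"`,
#'   `"quality_table4"`, `"topsis_table5"`, `"yields_text"`.
#' @return a [trial_dataset()] (with the design merged in), except
#'   `"topsis_table5"` which is a reference data.frame, not trial data.
#' @examples
#' ds <- builtin_fixture("quality_table4")
#' dim(ds$indicators)  # 10 x 9
#' @export
builtin_fixture <- function(name) {
  valid <- c("design_table2", "phenology_table3", "quality_table4",
             "topsis_table5", "yields_text")
  if (!is.character(name) || length(name) != 1 || !name %in% valid) {
    stop("unknown fixture tag '", paste(name, collapse = ","),
         "'; valid tags: ", paste(valid, collapse = ", "))
  }
  path <- function(f) system.file("extdata", f, package = "melonopt",
                                  mustWork = TRUE)
  design <- load_trial_table(path("design_table2.csv"), "design")
  switch(name,
    design_table2 = design,
    phenology_table3 = {
      ds <- load_trial_table(path("phenology_table3.csv"), "phenology")
      out <- trial_dataset(design$treatments, phenology = ds$phenology)
      attr(out, "printed_durations") <- attr(ds, "printed_durations")
      out
    },
    quality_table4 = {
      ds <- load_trial_table(path("quality_table4.csv"), "indicators")
      trial_dataset(design$treatments, indicators = ds$indicators,
                    indicator_sd = ds$indicator_sd)
    },
    yields_text = {
      ds <- load_trial_table(path("yields_text.csv"), "responses")
      trial_dataset(design$treatments,
                    responses = ds$responses[, c("label", "yield")])
    },
    topsis_table5 = utils::read.csv(path("topsis_table5.csv"),
                                    stringsAsFactors = FALSE)
  )
}

#' Assemble the full published trial dataset
#'
#' Convenience wrapper combining the bundled design, phenology (with
#' computed total growth durations), quality-indicator means, and the
#' printed yields into one dataset ready for the analysis pipeline. The Ci
#' response is left `NA` until computed by [run_topsis()].
#'
#' @return a [trial_dataset()] with `treatments`, `phenology`,
#'   `indicators`, and `responses` (duration, yield, ci) filled as far as
#'   the published tables allow.
#' @export
published_trial_dataset <- function() {
  design <- builtin_fixture("design_table2")
  phen <- builtin_fixture("phenology_table3")
  qual <- builtin_fixture("quality_table4")
  yields <- builtin_fixture("yields_text")
  dur <- compute_phenology_durations(phen)
  resp <- merge(dur[, c("label", "total_growth_days")],
                yields$responses, by = "label", sort = FALSE)
  names(resp)[names(resp) == "total_growth_days"] <- "duration"
  resp$ci <- NA_real_
  resp <- resp[match(design$treatments$label, resp$label), ]
  rownames(resp) <- NULL
  trial_dataset(design$treatments, phenology = phen$phenology,
                indicators = qual$indicators,
                indicator_sd = qual$indicator_sd, responses = resp)
}
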