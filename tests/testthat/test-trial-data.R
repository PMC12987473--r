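test_that("stage_duration counts both endpoints inclusively", {
  expect_identical(stage_duration(as.Date("2023-05-25"),
                                  as.Date("2023-06-26")), 33L)
  expect_identical(stage_duration(as.Date("2023-03-18"),
                                  as.Date("2023-06-26")), 101L)
  expect_identical(stage_duration(as.Date("2023-04-01"),
                                  as.Date("2023-04-01")), 1L)
  expect_error(stage_duration(as.Date("2023-06-26"), as.Date("2023-05-25")),
               "precedes")
})

test_that("inclusive counts are additive up to the shared endpoint", {
  set.seed(42)
  for (rep in 1:25) {
    base <- as.Date("2023-03-01") + sample.int(60, 1)
    a <- base
    b <- a + sample.int(50, 1)
    c <- b + sample.int(50, 1)
    expect_identical(stage_duration(a, b) + stage_duration(b, c),
                     stage_duration(a, c) + 1L)
  }
})

test_that("computed durations reproduce all printed growth-period columns", {
  ds <- builtin_fixture("phenology_table3")
  printed <- attr(ds, "printed_durations")
  got <- compute_phenology_durations(ds)
  got <- got[match(printed$label, got$label), ]
  expect_identical(got$fruit_development_days,
                   as.integer(printed$fruit_development_days))
  expect_identical(got$total_growth_days,
                   as.integer(printed$total_growth_days))
})

test_that("duration computation demands the required date fields", {
  ds <- builtin_fixture("phenology_table3")
  ph <- ds$phenology
  ph$maturity_date <- NULL
  expect_error(compute_phenology_durations(ph), "maturity_date")
  same <- data.frame(label = "X",
                     sowing_date = as.Date("2023-04-01"),
                     fruit_set_date = as.Date("2023-04-01"),
                     maturity_date = as.Date("2023-04-01"))
  got <- compute_phenology_durations(same)
  expect_identical(got$fruit_development_days, 1L)
  expect_identical(got$total_growth_days, 1L)
})

test_that("mean +/- sd cells parse with significance letters stripped", {
  p <- parse_mean_sd("2.79 ± 0.13a")
  expect_equal(p$mean, 2.79)
  expect_equal(p$sd, 0.13)
  p2 <- parse_mean_sd(c("1.02 ± 0.03 cd", "14.13", "2.87 ± 0.15a"))
  expect_equal(p2$mean, c(1.02, 14.13, 2.87))
  expect_equal(p2$sd, c(0.03, NA, 0.15))
  expect_error(parse_mean_sd("not a number"), "unparseable")
})

test_that("trial tables load with schema checks and parse both date styles", {
  qt <- builtin_fixture("quality_table4")
  expect_identical(dim(qt$indicators), c(10L, 9L))
  expect_equal(unname(qt$indicators["T3", "single_fruit_weight_kg"]), 2.79)
  expect_equal(unname(qt$indicator_sd["T3", "single_fruit_weight_kg"]), 0.13)

  # the bundled phenology table uses the YYYY/M/D dialect
  ph <- builtin_fixture("phenology_table3")$phenology
  expect_s3_class(ph$sowing_date, "Date")
  expect_identical(ph$maturity_date[ph$label == "CK"], as.Date("2023-06-26"))
  # ISO dates parse identically
  expect_identical(melonopt:::parse_trial_date("2023-06-26"),
                   as.Date("2023-06-26"))

  empty <- tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(load_trial_table(empty, "design"), "empty|schema")
  bad <- tempfile(fileext = ".csv")
  writeLines(c("treatment,foo", "CK,1"), bad)
  expect_error(load_trial_table(bad, "design"), "schema error")
  expect_error(load_trial_table(tempfile(), "design"), "not found")
})

test_that("write then reload round-trips values and labels", {
  for (schema in c("design", "phenology", "indicators", "responses")) {
    ds <- switch(schema,
      design = builtin_fixture("design_table2"),
      phenology = builtin_fixture("phenology_table3"),
      indicators = builtin_fixture("quality_table4"),
      responses = {
        d <- builtin_fixture("design_table2")
        d$responses <- data.frame(label = d$treatments$label,
                                  duration = 101:110,
                                  yield = seq(28, 55, length.out = 10),
                                  ci = seq(0.1, 0.9, length.out = 10))
        d
      })
    path <- tempfile(fileext = ".csv")
    write_trial_table(ds, path, schema)
    back <- load_trial_table(path, schema)
    switch(schema,
      design = expect_equal(back$treatments, ds$treatments),
      phenology = expect_equal(back$phenology, ds$phenology),
      indicators = {
        expect_equal(back$indicators, ds$indicators)
        expect_equal(back$indicator_sd, ds$indicator_sd)
      },
      responses = expect_equal(back$responses, ds$responses))
  }
})

test_that("validation flags the documented structural problems", {
  expect_true(validate_dataset(published_trial_dataset())$ok)

  bad_sp <- trial_dataset(data.frame(label = c("A", "B"),
                                     spacing = c(57, 200),
                                     pruning_code = c(1, 2)))
  rep <- validate_dataset(bad_sp)
  expect_false(rep$ok)
  expect_true(any(grepl("not divisible by 5", rep$issues$message)))
  expect_true(any(grepl("outside \\[30, 80\\]", rep$issues$message)))

  ds <- builtin_fixture("phenology_table3")
  ds$phenology$maturity_date[1] <- ds$phenology$fruit_set_date[1] - 5
  rep2 <- validate_dataset(ds)
  expect_false(rep2$ok)
  expect_true(any(grepl("out of order", rep2$issues$message)))

  dup <- trial_dataset(data.frame(label = c("A", "A"), spacing = c(55, 60),
                                  pruning_code = c(1, 2)))
  expect_false(validate_dataset(dup)$ok)

  js <- validation_report_json(rep)
  expect_true(jsonlite::validate(js))
  expect_false(jsonlite::fromJSON(js)$ok)
})

test_that("builtin fixtures carry the published design and yields", {
  expect_error(builtin_fixture("nope"), "valid tags")
  des <- builtin_fixture("design_table2")
  expect_identical(nrow(des$treatments), 10L)
  expect_setequal(unique(des$treatments$spacing), c(55, 65, 75))
  expect_identical(des$treatments$pruning[des$treatments$label == "CK"],
                   "1V1F")
  expect_identical(des$treatments$pruning[des$treatments$label == "T9"],
                   "3V2F")
  y <- builtin_fixture("yields_text")$responses
  expect_equal(y$yield[y$label == "T3"], 53.97)
  expect_equal(y$yield[y$label == "CK"], 27.86)
  expect_identical(sum(is.na(y$yield)), 8L)
})
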