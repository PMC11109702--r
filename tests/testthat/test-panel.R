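test_that("quarterly snapshots fall on the 15th of each quarter's middle month", {
  expect_identical(quarter_dates(as.Date(c("2004-01-01", "2004-12-31"))),
                   as.Date(c("2004-02-15", "2004-05-15", "2004-08-15",
                             "2004-11-15")))
  expect_identical(length(quarter_dates(as.Date(c("2004-03-01",
                                                  "2004-04-30")))), 0L)
  expect_identical(length(quarter_dates(as.Date(c("2004-01-01",
                                                  "2017-12-31")))), 56L)
  expect_error(quarter_dates(as.Date(c("2005-01-01", "2004-01-01"))),
               class = "hdssmove_data_error")
})

test_that("life stage and subgroup follow the sex-specific cut-points", {
  expect_identical(assign_life_stage("female", 11.9),
                   data.frame(life_stage = "child", age_subgroup = "oldest",
                              stringsAsFactors = FALSE))
  expect_identical(assign_life_stage("male", 16.0)$life_stage, "adolescent")
  expect_identical(assign_life_stage("male", 16.0)$age_subgroup, "youngest")
  expect_identical(assign_life_stage("female", 25.0)$life_stage, "excluded")
  expect_identical(assign_life_stage("female", 12.0)$life_stage,
                   "adolescent")
  expect_identical(assign_life_stage("male", 15.99)$life_stage, "child")
  expect_error(assign_life_stage("female", -1), "negative")
  # partition: every sex/age combination classifiable, exactly one stage
  set.seed(1)
  grid <- data.frame(sex = sample(c("female", "male"), 500, TRUE),
                     age = runif(500, 0, 90))
  ls <- assign_life_stage(grid$sex, grid$age)
  expect_true(all(ls$life_stage %in% c("child", "adolescent", "excluded")))
  expect_true(all(!is.na(ls$age_subgroup[ls$life_stage != "excluded"])))
})

test_that("two-year calendar bands cover the study period", {
  expect_identical(year_band(as.Date("2004-05-15")), "2004-05")
  expect_identical(year_band(as.Date("2017-11-15")), "2016-17")
  expect_identical(year_band(as.Date("2010-02-15")), "2010-11")
  expect_error(year_band(as.Date("2019-02-15")), "period")
})

test_that("a person appears at a quarter iff an episode covers the snapshot", {
  hh <- household_row("H1", "A", 34.0, -9.95)
  persons <- person_row("A", "male", "1980-01-01")
  episodes <- episode_row("A", "H1", "2004-01-01", "2004-07-01",
                          end_reason = "out_migration", to = "Mzuzu")
  reg <- make_register(persons, hh$hh, hh$geo, episodes)
  pan <- build_panel(reg, period = as.Date(c("2004-01-01", "2004-12-31")))
  expect_identical(pan$quarter_date,
                   as.Date(c("2004-02-15", "2004-05-15")))
  # no survey in window: survey-derived fields are missing, not defaulted
  expect_true(all(is.na(pan$mother_secondary_edu)))
  expect_true(all(is.na(pan$marital_status)))
})

test_that("a zero-hazard register yields persons x quarters records", {
  reg <- simulate_register(
    sim_config(seed = 5, n_founder_households = 12,
               fertility_rate = c("15-49" = 0),
               mortality_rate = c("0-110" = 0),
               marriage_hazard = list(female = c("15-34" = 0),
                                      male = c("20-39" = 0)),
               divorce_hazard = 0,
               fostering_hazard = list(female = c("5-17" = 0),
                                       male = c("5-17" = 0)),
               relocation_hazard = 0, external_inmarriage_hazard = 0,
               return_hazard = 0))
  pan <- build_panel(reg)
  n_res <- length(unique(reg$episodes$person_id))
  expect_identical(nrow(pan), n_res * 56L)
})

test_that("panel record count equals the per-quarter episode-coverage recount", {
  reg <- cached_register(seed = 11)
  pan <- cached_panel(seed = 11)
  qs <- quarter_dates(reg$config$period)
  recount <- sum(vapply(qs, function(q)
    length(unique(reg$episodes$person_id[reg$episodes$start_date <= q &
                                           reg$episodes$end_date > q])),
    integer(1)))
  expect_identical(nrow(pan), recount)
  expect_identical(anyDuplicated(paste(pan$person_id, pan$quarter_date)),
                   0L)
  # rebuilding is bit-identical
  expect_identical(pan, build_panel(reg))
})

test_that("panel coordinates track the household's geographic spell", {
  reg <- cached_register(seed = 11)
  pan <- cached_panel(seed = 11)
  hg <- reg$household_geo
  i <- sample(seq_len(nrow(pan)), 50)
  for (r in i) {
    g <- hg[hg$unique_household_id == pan$unique_household_id[r] &
              hg$valid_from <= pan$quarter_date[r] &
              hg$valid_to > pan$quarter_date[r], ]
    expect_identical(pan$geo_household_id[r], g$geo_household_id[1])
    expect_identical(pan$lon[r], g$lon[1])
  }
})

test_that("population density counts match a brute-force pairwise tally", {
  # grid fixture: 4x4 households, ~220 m spacing, varying sizes
  set.seed(9)
  grid <- expand.grid(gx = 0:3, gy = 0:3)
  hhs <- list(); geos <- list(); persons <- list(); episodes <- list()
  pid <- 0
  for (k in seq_len(nrow(grid))) {
    id <- sprintf("H%02d", k)
    h <- household_row(id, sprintf("P%03d", pid + 1),
                       34 + grid$gx[k] * 0.002, -9.95 + grid$gy[k] * 0.002)
    hhs[[k]] <- h$hh; geos[[k]] <- h$geo
    for (j in seq_len(sample(1:4, 1))) {
      pid <- pid + 1
      persons[[pid]] <- person_row(sprintf("P%03d", pid), "female",
                                   "1990-01-01")
      episodes[[pid]] <- episode_row(sprintf("P%03d", pid), id,
                                     "2004-01-01", "2018-01-01")
    }
  }
  reg <- make_register(do.call(rbind, persons), do.call(rbind, hhs),
                       do.call(rbind, geos), do.call(rbind, episodes))
  pan <- build_panel(reg, period = as.Date(c("2004-01-01", "2004-06-30")))
  q1 <- pan[pan$quarter_date == as.Date("2004-02-15"), ]
  # brute force with an independent geodesic distance
  skip_if_not_installed("geosphere")
  brute <- vapply(seq_len(nrow(q1)), function(i) {
    d <- geosphere::distGeo(c(q1$lon[i], q1$lat[i]),
                            cbind(q1$lon, q1$lat))
    sum(d <= 250) - 1L
  }, numeric(1))
  expect_identical(as.numeric(q1$pop_density_250m), brute)
  # members of one household share the count and exclude themselves
  one <- q1[q1$unique_household_id == "H01", ]
  expect_true(all(one$pop_density_250m == one$pop_density_250m[1]))
})

test_that("two households 300 m apart do not count each other", {
  h1 <- household_row("H1", "A", 34.0, -9.95)
  h2 <- household_row("H2", "B", 34.0, -9.95 + 0.0027)  # ~300 m north
  persons <- rbind(person_row("A", "male", "1980-01-01"),
                   person_row("B", "male", "1980-01-01"),
                   person_row("C", "female", "1985-01-01"))
  episodes <- rbind(episode_row("A", "H1", "2004-01-01", "2018-01-01"),
                    episode_row("B", "H2", "2004-01-01", "2018-01-01"),
                    episode_row("C", "H2", "2004-01-01", "2018-01-01"))
  reg <- make_register(persons, rbind(h1$hh, h2$hh), rbind(h1$geo, h2$geo),
                       episodes)
  pan <- build_panel(reg, period = as.Date(c("2004-01-01", "2004-03-31")))
  expect_identical(pan$pop_density_250m[pan$person_id == "A"], 0L)
  expect_identical(pan$pop_density_250m[pan$person_id == "B"], 1L)
})
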