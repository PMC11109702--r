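# Synthetic HDSS register: a continuous-time demographic microsimulation
# discretised to day resolution via monthly competing exponential hazards.
# The generator emulates the event structure a demographic surveillance site
# records: residence episodes bounded by births, deaths, internal moves and
# external migration; patrilocal marriage; divorce return-moves; child
# fostering toward kin (maternal-weighted); whole-household relocation; and
# annual survey rounds.

#' Configuration for the synthetic HDSS register
#'
#' All hazards are per-year rates; monthly event probabilities are
#' `1 - exp(-rate/12)` with the event day drawn uniformly within the month.
#' Age bands in rate names are half-open integer-year intervals
#' (`"15-19"` covers ages in `[15, 20)`).
#'
#' @param seed Integer RNG seed (mandatory); identical seed and config give a
#'   bit-identical register.
#' @param n_founder_households Number of founder households enumerated at the
#'   start of the period. Founders are generated as patrilocal clans
#'   (brothers' households clustered within ~300 m, wives married in from
#'   other clans) so kinship-derived variables are non-trivial from the first
#'   quarter.
#' @param area_bounds Named vector `lon_min, lon_max, lat_min, lat_max`
#'   (WGS84 decimal degrees).
#' @param period Date vector of length 2, surveillance start and end.
#' @param fertility_rate Named vector: births per woman-year by age band
#'   (applies to married women; scaled by `fertility_unmarried_mult`
#'   otherwise).
#' @param fertility_unmarried_mult Multiplier in `[0,1]` for unmarried women.
#' @param mortality_rate Named vector: deaths per person-year by age band.
#' @param marriage_hazard List with elements `female` and `male`: named
#'   vectors of marriages per person-year by age band. Marriage events are
#'   driven by the female hazard; the male hazard weights groom selection.
#' @param divorce_hazard Divorces per marriage-year.
#' @param patrilocality_prob Probability the bride moves to the groom's
#'   household; otherwise the groom joins hers.
#' @param fostering_hazard List (`female`, `male`): fostering events per
#'   child-year by age band; destination drawn among kin households with
#'   maternal-side weight `foster_maternal_weight`.
#' @param relocation_hazard Whole-household relocations per household-year.
#' @param external_move_prob Probability that a marriage, divorce return or
#'   household relocation leaves the surveillance area.
#' @param return_hazard Re-entries per person-year spent outside the area.
#' @param polygyny_prob Selection weight allowing an already-married man to be
#'   drawn as groom (polygynous marriage).
#' @param external_inmarriage_hazard Marriages to an in-migrating external
#'   bride per unmarried-male-year (these brides carry no parent IDs).
#' @param reloc_short_prob Probability an internal household relocation is
#'   local (log-normal displacement, median ~0.8 km) rather than a uniform
#'   draw over the area.
#' @param child_accompany_age Children under this age accompany their mother
#'   on marriage and divorce moves.
#' @param foster_maternal_weight Relative weight of maternal-kin households as
#'   fostering destinations.
#' @param survey_month Calendar month of the annual survey round (interview on
#'   the 15th).
#' @param gazetteer Data frame of external destinations (label, kind, lon,
#'   lat); defaults to the bundled gazetteer.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_founder_households = 150,
                       area_bounds = c(lon_min = 33.90, lon_max = 34.02,
                                       lat_min = -10.00, lat_max = -9.88),
                       period = as.Date(c("2004-01-01", "2017-12-31")),
                       fertility_rate = c("15-19" = 0.10, "20-24" = 0.22,
                                          "25-29" = 0.20, "30-34" = 0.15,
                                          "35-39" = 0.09, "40-44" = 0.03),
                       fertility_unmarried_mult = 0.25,
                       mortality_rate = c("0-0" = 0.04, "1-4" = 0.006,
                                          "5-14" = 0.0015, "15-49" = 0.004,
                                          "50-64" = 0.012, "65-110" = 0.06),
                       marriage_hazard = list(
                         female = c("15-19" = 0.12, "20-24" = 0.20,
                                    "25-34" = 0.10),
                         male = c("20-24" = 0.10, "25-39" = 0.15)),
                       divorce_hazard = 0.04,
                       patrilocality_prob = 0.85,
                       fostering_hazard = list(female = c("5-17" = 0.030),
                                               male = c("5-17" = 0.024)),
                       relocation_hazard = 0.05,
                       external_move_prob = 0.25,
                       return_hazard = 0.15,
                       polygyny_prob = 0.10,
                       external_inmarriage_hazard = 0.03,
                       reloc_short_prob = 0.6,
                       child_accompany_age = 10,
                       foster_maternal_weight = 2,
                       survey_month = 9,
                       gazetteer = NULL) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    config_error("seed", "a seed is mandatory")
  seed <- as.integer(seed)
  cfg <- list(seed = seed, n_founder_households = n_founder_households,
              area_bounds = area_bounds, period = as.Date(period),
              fertility_rate = fertility_rate,
              fertility_unmarried_mult = fertility_unmarried_mult,
              mortality_rate = mortality_rate,
              marriage_hazard = marriage_hazard,
              divorce_hazard = divorce_hazard,
              patrilocality_prob = patrilocality_prob,
              fostering_hazard = fostering_hazard,
              relocation_hazard = relocation_hazard,
              external_move_prob = external_move_prob,
              return_hazard = return_hazard,
              polygyny_prob = polygyny_prob,
              external_inmarriage_hazard = external_inmarriage_hazard,
              reloc_short_prob = reloc_short_prob,
              child_accompany_age = child_accompany_age,
              foster_maternal_weight = foster_maternal_weight,
              survey_month = survey_month,
              gazetteer = gazetteer %||% default_gazetteer())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  haz_fields <- c("fertility_rate", "mortality_rate", "divorce_hazard",
                  "relocation_hazard", "return_hazard",
                  "external_inmarriage_hazard")
  for (f in haz_fields) {
    v <- unlist(cfg[[f]])
    if (!all(is.finite(v)) || any(v < 0))
      config_error(f, "hazards must be finite and non-negative")
  }
  for (f in c("marriage_hazard", "fostering_hazard")) {
    v <- unlist(cfg[[f]])
    if (!all(is.finite(v)) || any(v < 0))
      config_error(f, "hazards must be finite and non-negative")
    if (!all(c("female", "male") %in% names(cfg[[f]])))
      config_error(f, "needs `female` and `male` components")
  }
  for (f in c("patrilocality_prob", "external_move_prob", "polygyny_prob",
              "reloc_short_prob", "fertility_unmarried_mult")) {
    v <- cfg[[f]]
    if (!is.finite(v) || v < 0 || v > 1)
      config_error(f, "probabilities must lie in [0, 1]")
  }
  b <- cfg$area_bounds
  if (!all(c("lon_min", "lon_max", "lat_min", "lat_max") %in% names(b)))
    config_error("area_bounds", "needs lon_min, lon_max, lat_min, lat_max")
  if (b["lon_min"] >= b["lon_max"] || b["lat_min"] >= b["lat_max"])
    config_error("area_bounds", "rectangle is degenerate")
  if (length(cfg$period) != 2 || cfg$period[1] >= cfg$period[2])
    config_error("period", "start must precede end")
  if (!(cfg$survey_month %in% 1:12))
    config_error("survey_month", "must be a calendar month 1..12")
  invisible(cfg)
}

# rate lookup by age for named bands "a-b" meaning [a, b+1)
rate_at <- function(age, rates) {
  if (length(rates) == 0) return(rep(0, length(age)))
  lim <- do.call(rbind, lapply(strsplit(names(rates), "-"), as.numeric))
  out <- rep(0, length(age))
  for (i in seq_len(nrow(lim))) {
    hit <- age >= lim[i, 1] & age < lim[i, 2] + 1
    out[hit] <- rates[i]
  }
  out
}

monthly_p <- function(rate) 1 - exp(-rate / 12)

#' Simulate a synthetic HDSS register
#'
#' Runs the demographic microsimulation described in [sim_config()] and
#' returns a closed, internally consistent register: persons with parent
#' links, households with geographic spells, half-open residence episodes
#' `[start_date, end_date)`, annual surveys, marriages, and the gazetteer
#' used for external places.
#'
#' @param config A [sim_config()] object.
#' @return List of class `hdss_register` with data-frame elements `persons`,
#'   `households`, `household_geo`, `episodes`, `surveys`, `marriages`,
#'   `gazetteer`, `schools`, and the `config`.
#' @export
simulate_register <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_local_seed(config$seed, simulate_register_impl(config))
}

simulate_register_impl <- function(cfg) {
  b <- cfg$area_bounds
  day0 <- as.numeric(cfg$period[1])
  day_end <- as.numeric(cfg$period[2])

  st <- new.env(parent = emptyenv())
  # person state (parallel vectors)
  st$pid <- character(); st$sex <- character(); st$birth <- numeric()
  st$mother <- character(); st$father <- character(); st$death <- numeric()
  st$edu <- logical(); st$alive <- logical(); st$in_area <- logical()
  st$cur_hh <- character(); st$outside <- character()
  st$out_since <- numeric()
  st$school_entry <- logical()
  st$marstat <- character()       # never/married/separated/widowed
  # open episode bookkeeping
  st$ep_hh <- character(); st$ep_start <- numeric()
  st$ep_reason <- character(); st$ep_from <- character()
  # households
  st$hid <- character(); st$head <- character(); st$rank <- character()
  st$tarmac <- numeric(); st$active <- logical()
  st$cur_gid <- character(); st$cur_lon <- numeric(); st$cur_lat <- numeric()
  st$geo_from <- numeric(); st$geo_n <- integer()
  # accumulators
  st$geo_rows <- list(); st$ep_rows <- list(); st$marr <- list()
  st$surv <- list()
  st$n_marr <- 0L

  new_person <- function(sex, birth, mother = NA_character_,
                         father = NA_character_, edu = NA) {
    i <- length(st$pid) + 1L
    st$pid[i] <- sprintf("P%05d", i)
    st$sex[i] <- sex; st$birth[i] <- floor(birth)   # day resolution
    st$mother[i] <- mother; st$father[i] <- father
    st$death[i] <- NA_real_
    st$edu[i] <- if (is.na(edu)) stats::runif(1) < 0.3 else edu
    st$alive[i] <- TRUE; st$in_area[i] <- FALSE
    st$cur_hh[i] <- NA_character_; st$outside[i] <- NA_character_
    st$out_since[i] <- NA_real_
    st$school_entry[i] <- stats::runif(1) < 0.92
    st$marstat[i] <- "never"
    st$ep_hh[i] <- NA_character_; st$ep_start[i] <- NA_real_
    st$ep_reason[i] <- NA_character_; st$ep_from[i] <- NA_character_
    st$pid[i]
  }
  new_household <- function(head, lon, lat, day) {
    i <- length(st$hid) + 1L
    st$hid[i] <- sprintf("H%04d", i)
    st$head[i] <- head
    st$rank[i] <- sample(c("low", "medium", "high"), 1,
                         prob = c(0.25, 0.55, 0.20))
    # distance to the tarmac road running along the western edge
    st$tarmac[i] <- great_circle_km(b["lon_min"], lat, lon, lat)
    st$active[i] <- TRUE
    st$geo_n[i] <- 1L
    st$cur_gid[i] <- sprintf("G%04d-1", i)
    st$cur_lon[i] <- lon; st$cur_lat[i] <- lat; st$geo_from[i] <- day
    st$hid[i]
  }
  close_geo <- function(h, day) {
    day <- max(day, st$geo_from[h])
    st$geo_rows[[length(st$geo_rows) + 1L]] <- data.frame(
      unique_household_id = st$hid[h], geo_household_id = st$cur_gid[h],
      lon = st$cur_lon[h], lat = st$cur_lat[h],
      valid_from = st$geo_from[h], valid_to = day,
      stringsAsFactors = FALSE)
  }
  pidx <- function(p) match(p, st$pid)
  hidx <- function(h) match(h, st$hid)

  open_episode <- function(i, h, day, reason, from = NA_character_) {
    st$ep_hh[i] <- h; st$ep_start[i] <- day
    st$ep_reason[i] <- reason; st$ep_from[i] <- from
    st$cur_hh[i] <- h; st$in_area[i] <- TRUE
  }
  close_episode <- function(i, day, reason, to = NA_character_) {
    # events are processed type-by-type within a month; clamp so a
    # later-processed event with an earlier day cannot invert an episode
    day <- max(day, st$ep_start[i])
    st$ep_rows[[length(st$ep_rows) + 1L]] <- data.frame(
      person_id = st$pid[i], unique_household_id = st$ep_hh[i],
      start_date = st$ep_start[i], end_date = day,
      start_reason = st$ep_reason[i], end_reason = reason,
      external_from = st$ep_from[i], external_to = to,
      stringsAsFactors = FALSE)
    st$ep_hh[i] <- NA_character_; st$cur_hh[i] <- NA_character_
    st$in_area[i] <- FALSE
    day
  }
  move_person <- function(i, h, day) {
    if (identical(st$cur_hh[i], h)) return(invisible())
    day <- close_episode(i, day, "internal_move")
    open_episode(i, h, day, "internal_move")
  }
  out_migrate <- function(i, day, place) {
    d2 <- close_episode(i, day, "out_migration", to = place)
    st$outside[i] <- place
    st$out_since[i] <- d2
  }
  members_of <- function(h) which(st$alive & st$in_area &
                                    !is.na(st$cur_hh) & st$cur_hh == h)
  sample_place <- function() sample(cfg$gazetteer$label, 1)
  runif_day <- function(m_start, m_end) floor(stats::runif(1, m_start, m_end + 1))

  active_marr <- function() {
    if (st$n_marr == 0) return(integer(0))
    which(vapply(st$marr, function(m) is.na(m$end), logical(1)))
  }
  husband_of <- function(p) {
    for (k in active_marr()) if (st$marr[[k]]$wife == p) return(st$marr[[k]]$husband)
    NA_character_
  }
  wives_of <- function(p) {
    out <- character()
    for (k in active_marr()) if (st$marr[[k]]$husband == p) out <- c(out, st$marr[[k]]$wife)
    out
  }
  end_marriages_of <- function(p, day, reason) {
    for (k in active_marr()) {
      m <- st$marr[[k]]
      if (m$wife == p || m$husband == p) {
        st$marr[[k]]$end <- day; st$marr[[k]]$end_reason <- reason
        other <- if (m$wife == p) m$husband else m$wife
        j <- pidx(other)
        if (!is.na(j) && st$alive[j]) {
          still <- length(wives_of(other)) > 0 ||
            !is.na(husband_of(other))
          if (!still)
            st$marstat[j] <- if (reason == "death") "widowed" else "separated"
        }
      }
    }
  }
  record_marriage <- function(wife, husband, day, polygynous) {
    st$n_marr <- st$n_marr + 1L
    st$marr[[st$n_marr]] <- list(
      marriage_id = sprintf("M%04d", st$n_marr), wife = wife,
      husband = husband, start = day, end = NA_real_,
      end_reason = NA_character_, polygynous = polygynous)
    st$marstat[pidx(wife)] <- "married"
    st$marstat[pidx(husband)] <- "married"
  }

  uniform_point <- function() {
    c(lon = stats::runif(1, b["lon_min"], b["lon_max"]),
      lat = stats::runif(1, b["lat_min"], b["lat_max"]))
  }
  offset_point <- function(lon, lat, min_m, max_m) {
    d_km <- stats::runif(1, min_m, max_m) / 1000
    ang <- stats::runif(1, 0, 2 * pi)
    dlat <- d_km * cos(ang) / 111.32
    dlon <- d_km * sin(ang) / (111.32 * cos(lat * pi / 180))
    c(lon = min(max(lon + dlon, b["lon_min"]), b["lon_max"]),
      lat = min(max(lat + dlat, b["lat_min"]), b["lat_max"]))
  }

  ## ---- founders: patrilocal clans -----------------------------------------
  yr <- 365.25
  ref <- day0
  n_target <- cfg$n_founder_households
  clan_daughters <- list()   # per clan: parent ids for brides married elsewhere
  son_rows <- list()
  clan <- 0L
  while (length(st$hid) < n_target) {
    clan <- clan + 1L
    centre <- uniform_point()
    gf_age <- stats::runif(1, 55, 80); gm_age <- gf_age - stats::runif(1, 0, 8)
    gf_alive <- stats::runif(1) < 0.35; gm_alive <- stats::runif(1) < 0.55
    gf <- new_person("male", ref - gf_age * yr)
    gm <- new_person("female", ref - gm_age * yr)
    if (!gf_alive) { i <- pidx(gf); st$alive[i] <- FALSE
      st$death[i] <- ref - floor(stats::runif(1, 1, 15 * yr)) }
    if (!gm_alive) { i <- pidx(gm); st$alive[i] <- FALSE
      st$death[i] <- ref - floor(stats::runif(1, 1, 15 * yr)) }
    n_sons <- 1L + stats::rpois(1, 1.2)
    first_hh <- NA_character_
    for (s in seq_len(n_sons)) {
      if (length(st$hid) >= n_target && s > 1) break
      son_age <- stats::runif(1, 24, min(gm_age - 19, 52))
      son <- new_person("male", ref - son_age * yr, mother = gm, father = gf)
      loc <- offset_point(centre["lon"], centre["lat"], 30, 300)
      hh <- new_household(son, loc["lon"], loc["lat"], day0)
      open_episode(pidx(son), hh, day0, "enumeration")
      if (is.na(first_hh)) first_hh <- hh
      son_rows[[length(son_rows) + 1L]] <-
        list(son = son, hh = hh, clan = clan, age = son_age)
    }
    # grandparents live with the eldest son
    for (g in c(gf, gm)) {
      i <- pidx(g)
      if (st$alive[i]) open_episode(i, first_hh, day0, "enumeration")
    }
    clan_daughters[[clan]] <- list(gm = gm, gf = gf, gm_age = gm_age)
  }
  # wives married in from other clans; children of each couple
  for (srow in son_rows) {
    i_son <- pidx(srow$son)
    if (stats::runif(1) < 0.12) next   # some household heads unmarried
    other <- sample(setdiff(seq_along(clan_daughters), srow$clan), 1)
    par <- clan_daughters[[other]]
    wife_age <- max(19, srow$age - stats::runif(1, 2, 10))
    wife_age <- min(wife_age, par$gm_age - 19)   # her mother was adult at birth
    wife <- new_person("female", ref - wife_age * yr,
                       mother = par$gm, father = par$gf)
    open_episode(pidx(wife), srow$hh, day0, "enumeration")
    record_marriage(wife, srow$son, day0 - floor(stats::runif(1, 0, 10 * yr)),
                    polygynous = FALSE)
    n_kids <- stats::rpois(1, min(0.30 * (wife_age - 18), 4.5))
    if (n_kids > 0) {
      for (k in seq_len(n_kids)) {
        kid_age <- stats::runif(1, 0, min(wife_age - 18, 17))
        kid <- new_person(sample(c("female", "male"), 1),
                          ref - kid_age * yr,
                          mother = wife, father = srow$son)
        open_episode(pidx(kid), srow$hh, day0, "enumeration")
      }
    }
  }

  ## ---- monthly event loop -------------------------------------------------
  months <- seq(cfg$period[1], cfg$period[2], by = "month")
  for (m in seq_along(months)) {
    m_start <- as.numeric(months[m])
    m_end <- if (m < length(months)) as.numeric(months[m + 1]) - 1 else day_end
    # recomputed per block: births during the month grow the person vectors
    age_now <- function() (m_start - st$birth) / yr
    age <- age_now()

    # deaths (anyone alive, in or out of the area)
    cand <- which(st$alive)
    if (length(cand)) {
      p <- monthly_p(rate_at(age[cand], cfg$mortality_rate))
      hit <- cand[stats::runif(length(cand)) < p]
      for (i in hit) {
        day <- runif_day(m_start, m_end)
        st$alive[i] <- FALSE; st$death[i] <- day
        end_marriages_of(st$pid[i], day, "death")
        if (st$in_area[i]) close_episode(i, day, "death")
      }
    }

    # births
    cand <- which(st$alive & st$in_area & st$sex == "female")
    if (length(cand)) {
      rate <- rate_at(age[cand], cfg$fertility_rate)
      unm <- st$marstat[cand] != "married"
      rate[unm] <- rate[unm] * cfg$fertility_unmarried_mult
      hit <- cand[stats::runif(length(cand)) < monthly_p(rate)]
      for (i in hit) {
        day <- runif_day(m_start, m_end)
        kid <- new_person(sample(c("female", "male"), 1), day,
                          mother = st$pid[i], father = husband_of(st$pid[i]))
        open_episode(pidx(kid), st$cur_hh[i], day, "birth")
      }
    }

    # marriages driven by the female hazard
    cand <- which(st$alive & st$in_area & st$sex == "female" &
                    st$marstat != "married")
    if (length(cand)) {
      p <- monthly_p(rate_at(age_now()[cand], cfg$marriage_hazard$female))
      brides <- cand[stats::runif(length(cand)) < p]
      for (i in brides) {
        if (!st$alive[i] || !st$in_area[i]) next
        day <- runif_day(m_start, m_end)
        if (stats::runif(1) < cfg$external_move_prob) {
          # marries outside the area and leaves surveillance
          out_migrate(i, day, sample_place())
          st$marstat[i] <- "married"
          next
        }
        males <- which(st$alive & st$in_area & st$sex == "male" &
                         (m_start - st$birth) / yr >= 18 &
                         (m_start - st$birth) / yr < 55)
        males <- males[st$cur_hh[males] != st$cur_hh[i]]
        # no marriage to her own father/brothers
        kin <- c(st$father[i],
                 st$pid[which(!is.na(st$mother) & st$mother %in% st$mother[i] &
                                !is.na(st$mother[i]))])
        males <- setdiff(males, pidx(kin[!is.na(kin)]))
        if (!length(males)) next
        w <- rate_at((m_start - st$birth[males]) / yr,
                     cfg$marriage_hazard$male) + 0.01
        w[st$marstat[males] == "married"] <-
          w[st$marstat[males] == "married"] * cfg$polygyny_prob
        j <- if (length(males) == 1) males else sample(males, 1, prob = w)
        poly <- st$marstat[j] == "married"
        # fission: a groom living in someone else's household founds his own
        hh_j <- hidx(st$cur_hh[j])
        if (st$head[hh_j] != st$pid[j]) {
          loc <- offset_point(st$cur_lon[hh_j], st$cur_lat[hh_j], 10, 500)
          hh_new <- new_household(st$pid[j], loc["lon"], loc["lat"], day)
          move_person(j, hh_new, day)
        }
        record_marriage(st$pid[i], st$pid[j], day, polygynous = poly)
        if (stats::runif(1) < cfg$patrilocality_prob) {
          dest <- st$cur_hh[j]
          kids <- which(st$alive & st$in_area & !is.na(st$mother) &
                          st$mother == st$pid[i] &
                          (m_start - st$birth) / yr < cfg$child_accompany_age &
                          st$cur_hh == st$cur_hh[i])
          move_person(i, dest, day)
          for (k in kids) move_person(k, dest, day)
        } else {
          move_person(j, st$cur_hh[i], day)
        }
      }
    }

    # marriages of local men to external in-migrating brides
    age <- age_now()
    cand <- which(st$alive & st$in_area & st$sex == "male" &
                    st$marstat != "married" & age >= 20 & age < 45)
    if (length(cand)) {
      hit <- cand[stats::runif(length(cand)) <
                    monthly_p(cfg$external_inmarriage_hazard)]
      for (j in hit) {
        day <- runif_day(m_start, m_end)
        hh_j <- hidx(st$cur_hh[j])
        if (st$head[hh_j] != st$pid[j]) {
          loc <- offset_point(st$cur_lon[hh_j], st$cur_lat[hh_j], 10, 500)
          hh_new <- new_household(st$pid[j], loc["lon"], loc["lat"], day)
          move_person(j, hh_new, day)
        }
        bride_age <- stats::runif(1, 16, 30)
        bride <- new_person("female", day - bride_age * yr,
                            edu = stats::runif(1) < 0.15)
        open_episode(pidx(bride), st$cur_hh[j], day, "in_migration",
                     from = sample_place())
        record_marriage(bride, st$pid[j], day, polygynous = FALSE)
      }
    }

    # divorces: wife returns to her natal household with young children
    for (k in active_marr()) {
      mr <- st$marr[[k]]
      if (stats::runif(1) >= monthly_p(cfg$divorce_hazard)) next
      day <- runif_day(m_start, m_end)
      st$marr[[k]]$end <- day; st$marr[[k]]$end_reason <- "divorce"
      iw <- pidx(mr$wife); ih <- pidx(mr$husband)
      st$marstat[iw] <- "separated"
      if (!length(wives_of(mr$husband))) st$marstat[ih] <- "separated"
      if (!st$alive[iw] || !st$in_area[iw]) next
      dest <- NA_character_
      for (par in c(st$mother[iw], st$father[iw])) {
        if (is.na(par)) next
        jp <- pidx(par)
        if (!is.na(jp) && st$alive[jp] && st$in_area[jp]) {
          dest <- st$cur_hh[jp]; break
        }
      }
      if (!is.na(dest) && dest != st$cur_hh[iw]) {
        kids <- which(st$alive & st$in_area & !is.na(st$mother) &
                        st$mother == mr$wife &
                        (m_start - st$birth) / yr < cfg$child_accompany_age &
                        st$cur_hh == st$cur_hh[iw])
        move_person(iw, dest, day)
        for (kk in kids) move_person(kk, dest, day)
      } else if (stats::runif(1) < cfg$external_move_prob) {
        out_migrate(iw, day, sample_place())
      }
    }

    # fostering of children toward kin households (maternal-weighted)
    cand <- which(st$alive & st$in_area)
    if (length(cand)) {
      age <- age_now()
      rate <- ifelse(st$sex[cand] == "female",
                     rate_at(age[cand], cfg$fostering_hazard$female),
                     rate_at(age[cand], cfg$fostering_hazard$male))
      hit <- cand[stats::runif(length(cand)) < monthly_p(rate)]
      for (i in hit) {
        if (!st$in_area[i]) next
        day <- runif_day(m_start, m_end)
        dests <- foster_destinations(st, i, day, cfg$foster_maternal_weight)
        dests <- dests[dests$hh != st$cur_hh[i], , drop = FALSE]
        if (!nrow(dests)) next
        hh <- if (nrow(dests) == 1) dests$hh else
          sample(dests$hh, 1, prob = dests$w)
        move_person(i, hh, day)
      }
    }

    # whole-household relocations
    hcand <- which(st$active)
    if (length(hcand)) {
      hit <- hcand[stats::runif(length(hcand)) < monthly_p(cfg$relocation_hazard)]
      for (h in hit) {
        mem <- members_of(st$hid[h])
        if (!length(mem)) next
        day <- runif_day(m_start, m_end)
        if (stats::runif(1) < cfg$external_move_prob) {
          place <- sample_place()
          for (i in mem) out_migrate(i, day, place)
          close_geo(h, day)
          st$active[h] <- FALSE
        } else {
          if (stats::runif(1) < cfg$reloc_short_prob) {
            d_km <- min(exp(stats::rnorm(1, log(0.8), 0.6)), 3.9)
            loc <- offset_point(st$cur_lon[h], st$cur_lat[h],
                                d_km * 1000, d_km * 1000)
          } else {
            loc <- uniform_point()
          }
          close_geo(h, day)
          st$geo_n[h] <- st$geo_n[h] + 1L
          st$cur_gid[h] <- sprintf("G%04d-%d", h, st$geo_n[h])
          st$cur_lon[h] <- loc["lon"]; st$cur_lat[h] <- loc["lat"]
          st$geo_from[h] <- day
          for (i in mem) {
            d2 <- close_episode(i, day, "internal_move")
            open_episode(i, st$hid[h], d2, "internal_move")
          }
        }
      }
    }

    # returns of out-migrants (only those already outside at month start, so
    # a return can never precede its own out-migration)
    cand <- which(st$alive & !st$in_area & !is.na(st$outside) &
                    st$out_since < m_start)
    if (length(cand)) {
      hit <- cand[stats::runif(length(cand)) < monthly_p(cfg$return_hazard)]
      for (i in hit) {
        day <- runif_day(m_start, m_end)
        dest <- NA_character_
        prev <- prev_household(st, i)
        if (!is.na(prev) && st$active[hidx(prev)]) dest <- prev
        if (is.na(dest)) {
          for (par in c(st$mother[i], st$father[i])) {
            if (is.na(par)) next
            jp <- pidx(par)
            if (!is.na(jp) && st$alive[jp] && st$in_area[jp]) {
              dest <- st$cur_hh[jp]; break
            }
          }
        }
        if (is.na(dest)) next
        open_episode(i, dest, day, "in_migration", from = st$outside[i])
        st$outside[i] <- NA_character_
      }
    }

    # annual survey round
    if (as.integer(format(months[m], "%m")) == cfg$survey_month) {
      sday <- m_start + 14
      res <- which(st$alive & st$in_area)
      for (i in res) {
        a <- (sday - st$birth[i]) / yr
        gr <- if (st$school_entry[i] && a >= 6) floor(a - 6) + 1 else NA_real_
        inp <- !is.na(gr) && gr >= 1 && gr <= 8
        h <- hidx(st$cur_hh[i])
        sid <- if (inp) nearest_school(st$cur_lon[h], st$cur_lat[h], b)
               else NA_character_
        im <- pidx(st$mother[i]); ifa <- pidx(st$father[i])
        sp <- if (st$sex[i] == "female") husband_of(st$pid[i]) else {
          w <- wives_of(st$pid[i]); if (length(w)) paste(w, collapse = ";")
          else NA_character_
        }
        st$surv[[length(st$surv) + 1L]] <- data.frame(
          person_id = st$pid[i], survey_date = sday,
          school_id = sid, grade = if (inp) gr else NA_real_,
          in_primary = inp, marital_status = st$marstat[i],
          spouse_ids = if (is.na(sp) || sp == "") NA_character_ else sp,
          mother_secondary_edu = if (is.na(im)) NA else st$edu[im],
          father_secondary_edu = if (is.na(ifa)) NA else st$edu[ifa],
          stringsAsFactors = FALSE)
      }
    }
  }

  ## ---- censor and assemble ------------------------------------------------
  cens <- day_end + 1
  for (i in which(st$in_area)) close_episode(i, cens, "censor")
  for (h in which(st$active)) close_geo(h, cens)

  persons <- data.frame(
    person_id = st$pid, sex = st$sex,
    birth_date = as.Date(st$birth, origin = "1970-01-01"),
    mother_id = st$mother, father_id = st$father,
    death_date = as.Date(st$death, origin = "1970-01-01"),
    secondary_edu = st$edu, stringsAsFactors = FALSE)
  households <- data.frame(
    unique_household_id = st$hid, head_id = st$head,
    head_employment_rank = st$rank, dist_tarmac_km = st$tarmac,
    stringsAsFactors = FALSE)
  household_geo <- do.call(rbind, st$geo_rows)
  household_geo$valid_from <- as.Date(household_geo$valid_from, origin = "1970-01-01")
  household_geo$valid_to <- as.Date(household_geo$valid_to, origin = "1970-01-01")
  household_geo <- household_geo[order(household_geo$unique_household_id,
                                       household_geo$valid_from), ]
  rownames(household_geo) <- NULL
  episodes <- do.call(rbind, st$ep_rows)
  episodes$start_date <- as.Date(episodes$start_date, origin = "1970-01-01")
  episodes$end_date <- as.Date(episodes$end_date, origin = "1970-01-01")
  episodes <- episodes[order(episodes$person_id, episodes$start_date), ]
  rownames(episodes) <- NULL
  surveys <- if (length(st$surv)) do.call(rbind, st$surv) else
    data.frame(person_id = character(), survey_date = numeric(),
               school_id = character(), grade = numeric(),
               in_primary = logical(), marital_status = character(),
               spouse_ids = character(), mother_secondary_edu = logical(),
               father_secondary_edu = logical(), stringsAsFactors = FALSE)
  if (nrow(surveys))
    surveys$survey_date <- as.Date(surveys$survey_date, origin = "1970-01-01")
  marriages <- if (st$n_marr) do.call(rbind, lapply(st$marr, function(m)
    data.frame(marriage_id = m$marriage_id, wife_id = m$wife,
               husband_id = m$husband,
               start_date = as.Date(m$start, origin = "1970-01-01"),
               end_date = as.Date(m$end, origin = "1970-01-01"),
               end_reason = m$end_reason, polygynous = m$polygynous,
               stringsAsFactors = FALSE))) else
    data.frame(marriage_id = character(), wife_id = character(),
               husband_id = character(), start_date = as.Date(character()),
               end_date = as.Date(character()), end_reason = character(),
               polygynous = logical(), stringsAsFactors = FALSE)

  reg <- list(persons = persons, households = households,
              household_geo = household_geo, episodes = episodes,
              surveys = surveys, marriages = marriages,
              gazetteer = cfg$gazetteer, config = cfg)
  class(reg) <- "hdss_register"
  validate_register(reg)
  reg
}

# kin households eligible as fostering destinations, with weights
foster_destinations <- function(st, i, day, maternal_w) {
  pid <- st$pid
  side <- function(parent, w) {
    if (is.na(parent)) return(NULL)
    j <- match(parent, pid)
    if (is.na(j)) return(NULL)
    ids <- c(st$mother[j], st$father[j],                    # grandparents
             pid[which((!is.na(st$mother) & !is.na(st$mother[j]) &
                          st$mother == st$mother[j]) |
                         (!is.na(st$father) & !is.na(st$father[j]) &
                            st$father == st$father[j]))])   # parent's siblings
    ids <- setdiff(ids[!is.na(ids)], c(parent, st$pid[i]))
    jj <- match(ids, pid)
    jj <- jj[!is.na(jj)]
    jj <- jj[st$alive[jj] & st$in_area[jj]]
    if (!length(jj)) return(NULL)
    data.frame(hh = st$cur_hh[jj], w = w, stringsAsFactors = FALSE)
  }
  sibs <- which(st$alive & st$in_area & pid != pid[i] &
                  ((!is.na(st$mother) & !is.na(st$mother[i]) &
                      st$mother == st$mother[i]) |
                     (!is.na(st$father) & !is.na(st$father[i]) &
                        st$father == st$father[i])))
  sib_adult <- sibs[(day - st$birth[sibs]) / 365.25 >= 18]
  out <- rbind(side(st$mother[i], maternal_w), side(st$father[i], 1),
               if (length(sib_adult))
                 data.frame(hh = st$cur_hh[sib_adult], w = 1,
                            stringsAsFactors = FALSE))
  if (is.null(out) || !nrow(out))
    return(data.frame(hh = character(), w = numeric()))
  stats::aggregate(w ~ hh, data = out, FUN = sum)
}

prev_household <- function(st, i) {
  rows <- st$ep_rows
  last <- NA_character_; last_end <- -Inf
  for (r in rows) {
    if (r$person_id == st$pid[i] && r$end_date > last_end) {
      last <- r$unique_household_id; last_end <- r$end_date
    }
  }
  last
}

nearest_school <- function(lon, lat, b) {
  lons <- seq(b["lon_min"] + 0.01, b["lon_max"], by = 0.02)
  lats <- seq(b["lat_min"] + 0.01, b["lat_max"], by = 0.02)
  grid <- expand.grid(lon = lons, lat = lats)
  d <- great_circle_km(lon, lat, grid$lon, grid$lat)
  sprintf("S%02d", which.min(d))
}

#' Validate internal consistency of a register
#'
#' Checks episode closure (per-person episodes non-overlapping and gap-free
#' between entry and exit), referential integrity of households and
#' marriages, and parent-link sanity.
#'
#' @param register An `hdss_register`.
#' @return The register, invisibly; inconsistencies raise a data error.
#' @export
validate_register <- function(register) {
  ep <- register$episodes
  if (any(!ep$unique_household_id %in% register$households$unique_household_id))
    data_error("episode references an unknown household")
  if (anyDuplicated(register$persons$person_id))
    data_error("duplicate person identifiers")
  ord <- order(ep$person_id, ep$start_date)
  ep <- ep[ord, ]
  same <- ep$person_id[-1] == ep$person_id[-nrow(ep)]
  if (nrow(ep) > 1) {
    prev_end <- ep$end_date[-nrow(ep)][same]
    nxt_start <- ep$start_date[-1][same]
    nxt_reason <- ep$start_reason[-1][same]
    if (any(nxt_start < prev_end))
      data_error("overlapping episodes for a person")
    # a within-area continuation must be seamless; re-entry may leave a gap
    bad_gap <- nxt_reason == "internal_move" & nxt_start != prev_end
    if (any(bad_gap)) data_error("gap at an internal move")
  }
  p <- register$persons
  both <- !is.na(p$birth_date) & !is.na(p$death_date)
  if (any(p$birth_date[both] >= p$death_date[both]))
    data_error("death precedes birth")
  mi <- match(p$mother_id, p$person_id)
  known <- !is.na(mi)
  if (any(p$sex[mi[known]] != "female"))
    data_error("a linked mother is not female")
  mo_age <- age_years(p$birth_date[mi[known]], p$birth_date[known])
  if (any(mo_age < 12)) data_error("a mother under 12 at child's birth")
  m <- register$marriages
  if (nrow(m) && (any(!m$wife_id %in% p$person_id) ||
                  any(!m$husband_id %in% p$person_id)))
    data_error("marriage references an unknown person")
  invisible(register)
}

#' Exhaustive ground-truth relocation events of a register
#'
#' Reads true move events straight off the episode table, independent of any
#' quarterly discretisation: one event per episode boundary whose end reason
#' is an internal move or an out-migration. Co-movers share the event date
#' and destination.
#'
#' @param register An `hdss_register`.
#' @return Data frame: `person_id`, `date`, `origin_household`,
#'   `dest_household` (NA for external), `dest_external` (NA for internal),
#'   `direction`, `n_co_movers`.
#' @export
ground_truth_moves <- function(register) {
  ep <- register$episodes
  mv <- ep[ep$end_reason %in% c("internal_move", "out_migration"), ]
  if (!nrow(mv)) {
    return(data.frame(person_id = character(), date = as.Date(character()),
                      origin_household = character(),
                      dest_household = character(),
                      dest_external = character(), direction = character(),
                      n_co_movers = integer(), stringsAsFactors = FALSE))
  }
  nxt <- ep[ep$start_reason == "internal_move", ]
  key <- paste(mv$person_id, mv$end_date)
  nkey <- paste(nxt$person_id, nxt$start_date)
  dest_hh <- nxt$unique_household_id[match(key, nkey)]
  out <- data.frame(
    person_id = mv$person_id, date = mv$end_date,
    origin_household = mv$unique_household_id,
    dest_household = ifelse(mv$end_reason == "internal_move", dest_hh,
                            NA_character_),
    dest_external = mv$external_to,
    direction = ifelse(mv$end_reason == "internal_move", "internal", "out"),
    stringsAsFactors = FALSE)
  grp <- paste(out$date, ifelse(is.na(out$dest_household),
                                paste0("ext:", out$dest_external),
                                out$dest_household))
  out$n_co_movers <- as.integer(ave(seq_len(nrow(out)), grp,
                                    FUN = length)) - 1L
  rownames(out) <- NULL
  out[order(out$person_id, out$date), ]
}
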