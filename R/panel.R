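# Quarterly panel construction: the episodic register is reduced to one
# observation per person per quarter, taken on the 15th of the middle month
# of each quarter, with time-varying covariates attached.

#' Quarterly snapshot dates of a period
#'
#' The snapshot is the 15th of the middle month of each quarter: Feb 15,
#' May 15, Aug 15 and Nov 15.
#'
#' @param period Date vector of length 2 (inclusive interval).
#' @return Ordered vector of snapshot dates falling inside the interval.
#' @export
quarter_dates <- function(period) {
  period <- as.Date(period)
  if (length(period) != 2 || is.na(period[1]) || is.na(period[2]) ||
      period[1] > period[2])
    data_error("period must be a non-empty date interval")
  years <- seq(as.integer(format(period[1], "%Y")),
               as.integer(format(period[2], "%Y")))
  d <- as.Date(outer(years, c("-02-15", "-05-15", "-08-15", "-11-15"),
                     paste0))
  sort(d[d >= period[1] & d <= period[2]])
}

#' Life stage and age subgroup from sex and age
#'
#' Sex-specific cut-points: females are children under 12 and adolescents at
#' 12-24; males are children under 16 and adolescents at 16-28; older ages
#' are excluded. Subgroups split each sex-by-stage range into four bands.
#' All intervals are half-open `[a, b)`, so a boundary age belongs to the
#' older category.
#'
#' @param sex Character vector, `"female"` or `"male"`.
#' @param age_years Non-negative numeric vector.
#' @return Data frame with columns `life_stage` (`child`, `adolescent`,
#'   `excluded`) and `age_subgroup` (`youngest`, `young`, `older`, `oldest`,
#'   or NA when excluded).
#' @export
assign_life_stage <- function(sex, age_years) {
  if (any(age_years < 0, na.rm = TRUE)) data_error("negative age")
  n <- max(length(sex), length(age_years))
  sex <- rep_len(sex, n); age <- rep_len(age_years, n)
  stage <- ifelse(sex == "female",
                  ifelse(age < 12, "child", ifelse(age < 25, "adolescent",
                                                   "excluded")),
                  ifelse(age < 16, "child", ifelse(age < 29, "adolescent",
                                                   "excluded")))
  cuts <- function(a, lo, c1, c2, c3, hi) {
    ifelse(a < c1, "youngest",
           ifelse(a < c2, "young", ifelse(a < c3, "older", "oldest")))
  }
  sub <- rep(NA_character_, n)
  i <- sex == "female" & stage == "child"
  sub[i] <- cuts(age[i], 0, 2, 6, 9, 12)
  i <- sex == "male" & stage == "child"
  sub[i] <- cuts(age[i], 0, 4, 8, 12, 16)
  i <- sex == "female" & stage == "adolescent"
  sub[i] <- cuts(age[i], 12, 15, 18, 21, 25)
  i <- sex == "male" & stage == "adolescent"
  sub[i] <- cuts(age[i], 16, 19, 22, 25, 29)
  data.frame(life_stage = stage, age_subgroup = sub,
             stringsAsFactors = FALSE)
}

#' Two-year calendar band of a snapshot date
#'
#' @param quarter_date Date vector within the study period.
#' @param period Date vector of length 2 delimiting valid dates.
#' @return Character vector of bands `"2004-05"`, `"2006-07"`, ...
#' @export
year_band <- function(quarter_date, period = as.Date(c("2004-01-01",
                                                       "2017-12-31"))) {
  quarter_date <- as.Date(quarter_date)
  if (any(quarter_date < period[1] | quarter_date > period[2]))
    data_error("date outside the study period")
  y0 <- as.integer(format(as.Date(period[1]), "%Y"))
  y <- as.integer(format(quarter_date, "%Y"))
  lo <- y0 + 2 * ((y - y0) %/% 2)
  sprintf("%d-%02d", lo, (lo + 1) %% 100)
}

#' Build the person-quarter panel from a register
#'
#' A person contributes a record at a snapshot iff a residence episode covers
#' that date (episodes are half-open `[start, end)`). Coordinates come from
#' the covering household's geographic spell at the snapshot. Survey-derived
#' fields use the most recent survey within the validity window and are left
#' missing (never defaulted) when no survey qualifies.
#'
#' @param register An `hdss_register`.
#' @param period Optional date interval; defaults to the register's
#'   simulation period.
#' @param survey_back_months,survey_fwd_months Validity window of a survey
#'   value: records are taken from surveys up to `survey_fwd_months` before
#'   the snapshot (value carried forward) or `survey_back_months` after it
#'   (value carried backward).
#' @return Data frame with one row per person-quarter; see the column
#'   dictionary in the package vignette.
#' @export
build_panel <- function(register, period = NULL,
                        survey_back_months = 6, survey_fwd_months = 12) {
  per <- as.Date(period %||% register$config$period %||%
                   c(min(register$episodes$start_date),
                     max(register$episodes$end_date) - 1))
  qd <- quarter_dates(per)
  ep <- register$episodes
  if (any(!ep$unique_household_id %in%
            register$households$unique_household_id))
    data_error("episode references an unknown household")
  p <- register$persons

  rows <- lapply(qd, function(q) {
    cov <- ep[ep$start_date <= q & ep$end_date > q, ]
    if (!nrow(cov)) return(NULL)
    if (anyDuplicated(cov$person_id))
      cov <- cov[!duplicated(cov$person_id), ]
    data.frame(person_id = cov$person_id,
               quarter_date = q,
               unique_household_id = cov$unique_household_id,
               stringsAsFactors = FALSE)
  })
  pan <- do.call(rbind, rows)
  if (is.null(pan)) data_error("no person-quarter is covered by any episode")

  pi <- match(pan$person_id, p$person_id)
  pan$sex <- p$sex[pi]
  pan$age_years <- age_years(p$birth_date[pi], pan$quarter_date)
  ls <- assign_life_stage(pan$sex, pan$age_years)
  pan$life_stage <- ls$life_stage
  pan$age_subgroup <- ls$age_subgroup
  pan$has_parent_ids <- !(is.na(p$mother_id[pi]) & is.na(p$father_id[pi]))

  # geographic spell covering the snapshot
  hg <- register$household_geo
  gi <- interval_match(pan$unique_household_id, pan$quarter_date,
                       hg$unique_household_id, hg$valid_from, hg$valid_to)
  pan$geo_household_id <- hg$geo_household_id[gi]
  pan$lon <- hg$lon[gi]
  pan$lat <- hg$lat[gi]

  hh <- register$households
  hi <- match(pan$unique_household_id, hh$unique_household_id)
  pan$head_employment_rank <- hh$head_employment_rank[hi]
  pan$dist_tarmac_km <- hh$dist_tarmac_km[hi]

  # parental vital status: the parent's own register record wins; survey
  # report fills in when the parent is not linked to a record
  mo <- match(p$mother_id[pi], p$person_id)
  fa <- match(p$father_id[pi], p$person_id)
  pan$mother_dead <- !is.na(mo) & !is.na(p$death_date[mo]) &
    p$death_date[mo] <= pan$quarter_date
  pan$mother_dead[is.na(p$mother_id[pi])] <- NA
  pan$father_dead <- !is.na(fa) & !is.na(p$death_date[fa]) &
    p$death_date[fa] <= pan$quarter_date
  pan$father_dead[is.na(p$father_id[pi])] <- NA

  # own child co-resident at the quarter
  pan$own_child_present <- own_child_flag(pan, p)

  pan$year_band <- year_band(pan$quarter_date, per)

  # survey-derived covariates within the validity window
  sv <- register$surveys
  pan$mother_secondary_edu <- NA
  pan$father_secondary_edu <- NA
  pan$in_primary <- NA
  pan$school_id <- NA_character_
  pan$marital_status <- NA_character_
  if (nrow(sv)) {
    sv <- sv[order(sv$person_id, sv$survey_date), ]
    cand <- merge(pan[, c("person_id", "quarter_date")], sv,
                  by = "person_id")
    dd <- as.numeric(cand$quarter_date - cand$survey_date)
    ok <- dd >= -survey_back_months * 30.44 & dd <= survey_fwd_months * 30.44
    cand <- cand[ok, ]
    dd <- abs(dd[ok])
    cand <- cand[order(cand$person_id, cand$quarter_date, dd), ]
    cand <- cand[!duplicated(cand[, c("person_id", "quarter_date")]), ]
    mk <- match(paste(pan$person_id, pan$quarter_date),
                paste(cand$person_id, cand$quarter_date))
    pan$mother_secondary_edu <- cand$mother_secondary_edu[mk]
    pan$father_secondary_edu <- cand$father_secondary_edu[mk]
    pan$in_primary <- cand$in_primary[mk]
    pan$school_id <- cand$school_id[mk]
    pan$marital_status <- cand$marital_status[mk]
  }

  pan <- pan[order(pan$person_id, pan$quarter_date), ]
  rownames(pan) <- NULL
  dens <- population_density(pan)
  pan$pop_density_250m <- dens$count
  pan$pop_density_cat <- dens$category
  pan
}

# interval match: for each (id, date) find row of (ids, from, to) with
# id equal and from <= date < to
interval_match <- function(id, date, ids, from, to) {
  out <- rep(NA_integer_, length(id))
  sp <- split(seq_along(ids), ids)
  q <- split(seq_along(id), id)
  for (nm in names(q)) {
    rows <- sp[[nm]]
    if (is.null(rows)) next
    for (i in q[[nm]]) {
      hit <- rows[from[rows] <= date[i] & to[rows] > date[i]]
      if (length(hit)) out[i] <- hit[1]
    }
  }
  out
}

# TRUE where a biological child of the index shares the household-quarter
own_child_flag <- function(pan, p) {
  kids <- rbind(
    data.frame(parent = p$mother_id, child = p$person_id,
               stringsAsFactors = FALSE),
    data.frame(parent = p$father_id, child = p$person_id,
               stringsAsFactors = FALSE))
  kids <- kids[!is.na(kids$parent), ]
  if (!nrow(kids)) return(rep(FALSE, nrow(pan)))
  loc <- pan[, c("person_id", "quarter_date", "unique_household_id")]
  kl <- merge(kids, loc, by.x = "child", by.y = "person_id")
  key <- paste(kl$parent, kl$quarter_date, kl$unique_household_id)
  paste(pan$person_id, pan$quarter_date, pan$unique_household_id) %in% key
}

#' Population density within a radius at each panel record
#'
#' Counts co-temporal surveillance residents within `radius_m` of the
#' record's household (the index person excluded), and categorises counts by
#' within-dataset tertiles. Distances use household coordinates, so all
#' members of one household share a count.
#'
#' @param panel Panel data frame from [build_panel()] (needs `person_id`,
#'   `quarter_date`, `unique_household_id`, `lon`, `lat`).
#' @param radius_m Radius in metres (inclusive).
#' @return Data frame with `count` and ordinal `category`
#'   (`low`/`medium`/`high`); tertile boundaries attached as attribute
#'   `breaks`.
#' @export
population_density <- function(panel, radius_m = 250) {
  count <- rep(NA_integer_, nrow(panel))
  for (q in unique(panel$quarter_date)) {
    idx <- which(panel$quarter_date == q & !is.na(panel$lon))
    if (!length(idx)) next
    hhs <- panel[idx, c("unique_household_id", "lon", "lat")]
    agg <- hhs[!duplicated(hhs$unique_household_id), ]
    nmem <- table(hhs$unique_household_id)
    m <- nrow(agg)
    near <- matrix(FALSE, m, m)
    for (i in seq_len(m)) {
      d <- great_circle_km(agg$lon[i], agg$lat[i], agg$lon, agg$lat)
      near[i, ] <- d <= radius_m / 1000
    }
    nm <- as.integer(nmem[agg$unique_household_id])
    tot <- as.vector(near %*% nm)   # residents within radius incl. own hh
    cnt <- tot[match(panel$unique_household_id[idx],
                     agg$unique_household_id)] - 1L
    count[idx] <- as.integer(cnt)
  }
  br <- stats::quantile(count, probs = c(1 / 3, 2 / 3), na.rm = TRUE,
                        names = FALSE, type = 7)
  breaks <- unique(c(-Inf, br, Inf))   # degenerate fixtures collapse tertiles
  category <- cut(count, breaks = breaks,
                  labels = c("low", "medium", "high")[seq_len(length(breaks)
                                                             - 1)],
                  right = TRUE)
  out <- data.frame(count = count, category = as.character(category),
                    stringsAsFactors = FALSE)
  attr(out, "breaks") <- br
  out
}
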