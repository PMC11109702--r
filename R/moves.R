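# Move detection between quarterly snapshots, distance computation and the
# four-way move typology (short/long x independent/accompanied).
#
# Detection rule: an internal move is a changed geographic household ID at
# the following snapshot; an out-migration is absence at the next snapshot
# with a recorded out-migration episode; an in-migration is absence at the
# previous snapshot with a recorded in-migration. Internal candidates whose
# straight-line displacement is under the minimum (default 5 m) are dropped
# as administrative artefacts of re-assigned geographic IDs; when several
# candidates attach to one person-quarter interval exactly one is kept
# uniformly at random under the run seed. Internal and outward moves are
# attributed to the snapshot preceding the move (exposure quarter);
# in-migrations to the arrival snapshot.

#' Detect moves between consecutive quarterly snapshots
#'
#' @param panel Panel from [build_panel()].
#' @param episodes Episode table of the same register.
#' @param register The register (for household geography and gazetteer).
#' @param seed Integer seed for the random single-move-per-quarter rule;
#'   draws are consumed in (person, quarter) order.
#' @param min_move_m Minimum displacement in metres for internal moves.
#' @return Data frame of untyped move records (no distance class yet); the
#'   attribute `n_dropped_short` counts sub-threshold internal candidates and
#'   `n_tie_broken` the person-quarters resolved by the random-keep rule.
#' @export
detect_moves <- function(panel, episodes, register, seed = 1L,
                         min_move_m = 5) {
  if (!all(panel$person_id %in% register$persons$person_id))
    data_error("panel and episodes come from different registers")
  qs <- sort(unique(panel$quarter_date))
  hg <- register$household_geo
  pkey <- paste(panel$person_id, panel$quarter_date)
  geo_at <- function(person, q) {
    k <- match(paste(person, q), pkey)
    if (is.na(k)) NULL else panel[k, c("geo_household_id", "lon", "lat",
                                       "unique_household_id")]
  }

  cands <- list()
  add <- function(...) cands[[length(cands) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  for (t in seq_len(length(qs) - 1)) {
    q0 <- qs[t]; q1 <- qs[t + 1]
    p0 <- panel[panel$quarter_date == q0, ]
    p1 <- panel[panel$quarter_date == q1, ]
    m <- match(p0$person_id, p1$person_id)
    both <- !is.na(m)
    # internal: different geographic household ID at the next snapshot
    diffg <- both & p0$geo_household_id != p1$geo_household_id[m]
    for (r in which(diffg)) {
      add(person_id = p0$person_id[r], quarter_date = q0,
          interval_index = t, direction = "internal",
          origin_geo_id = p0$geo_household_id[r],
          origin_hh = p0$unique_household_id[r],
          dest_geo_id = p1$geo_household_id[m[r]],
          dest_hh = p1$unique_household_id[m[r]],
          origin_lon = p0$lon[r], origin_lat = p0$lat[r],
          dest_lon = p1$lon[m[r]], dest_lat = p1$lat[m[r]],
          external_place = NA_character_)
    }
    # out-migration: absent at next snapshot, recorded migration out
    outs <- episodes[episodes$end_reason == "out_migration" &
                       episodes$end_date > q0 & episodes$end_date <= q1, ]
    for (r in seq_len(nrow(outs))) {
      pid <- outs$person_id[r]
      if (pid %in% p1$person_id) next
      org <- geo_at(pid, q0)
      if (is.null(org)) {
        gi <- which(hg$unique_household_id == outs$unique_household_id[r] &
                      hg$valid_from <= outs$end_date[r] &
                      hg$valid_to >= outs$end_date[r])[1]
        org <- data.frame(geo_household_id = hg$geo_household_id[gi],
                          lon = hg$lon[gi], lat = hg$lat[gi],
                          unique_household_id = outs$unique_household_id[r])
      }
      add(person_id = pid, quarter_date = q0, interval_index = t,
          direction = "out_migration",
          origin_geo_id = org$geo_household_id, origin_hh = org$unique_household_id,
          dest_geo_id = NA_character_, dest_hh = NA_character_,
          origin_lon = org$lon, origin_lat = org$lat,
          dest_lon = NA_real_, dest_lat = NA_real_,
          external_place = outs$external_to[r])
    }
    # in-migration: absent at previous snapshot, recorded migration in
    ins <- episodes[episodes$start_reason == "in_migration" &
                      episodes$start_date > q0 & episodes$start_date <= q1, ]
    for (r in seq_len(nrow(ins))) {
      pid <- ins$person_id[r]
      if (pid %in% p0$person_id) next
      dst <- geo_at(pid, q1)
      if (is.null(dst)) {
        gi <- which(hg$unique_household_id == ins$unique_household_id[r] &
                      hg$valid_from <= ins$start_date[r] &
                      hg$valid_to >= ins$start_date[r])[1]
        dst <- data.frame(geo_household_id = hg$geo_household_id[gi],
                          lon = hg$lon[gi], lat = hg$lat[gi],
                          unique_household_id = ins$unique_household_id[r])
      }
      add(person_id = pid, quarter_date = q1, interval_index = t,
          direction = "in_migration",
          origin_geo_id = NA_character_, origin_hh = NA_character_,
          dest_geo_id = dst$geo_household_id, dest_hh = dst$unique_household_id,
          origin_lon = NA_real_, origin_lat = NA_real_,
          dest_lon = dst$lon, dest_lat = dst$lat,
          external_place = ins$external_from[r])
    }
  }
  if (!length(cands)) {
    out <- empty_moves()
    attr(out, "n_dropped_short") <- 0L
    attr(out, "n_tie_broken") <- 0L
    return(out)
  }
  cand <- do.call(rbind, cands)

  # <5 m artefact filter, applied before the random keep
  disp <- great_circle_km(cand$origin_lon, cand$origin_lat,
                          cand$dest_lon, cand$dest_lat)
  short_art <- cand$direction == "internal" & !is.na(disp) &
    disp < min_move_m / 1000
  n_dropped <- sum(short_art)
  cand <- cand[!short_art, ]

  # one move per person-quarter interval, kept uniformly at random
  cand <- cand[order(cand$person_id, cand$interval_index,
                     cand$direction), ]
  grp <- paste(cand$person_id, cand$interval_index)
  n_tie <- 0L
  keep <- with_local_seed(seed, {
    k <- rep(TRUE, nrow(cand))
    for (g in unique(grp)) {
      rows <- which(grp == g)
      if (length(rows) > 1) {
        n_tie <<- n_tie + 1L
        k[rows] <- FALSE
        k[rows[sample.int(length(rows), 1)]] <- TRUE
      }
    }
    k
  })
  mv <- cand[keep, ]
  rownames(mv) <- NULL
  attr(mv, "n_dropped_short") <- n_dropped
  attr(mv, "n_tie_broken") <- n_tie
  mv
}

empty_moves <- function() {
  data.frame(person_id = character(), quarter_date = as.Date(character()),
             interval_index = integer(), direction = character(),
             origin_geo_id = character(), origin_hh = character(),
             dest_geo_id = character(), dest_hh = character(),
             origin_lon = numeric(), origin_lat = numeric(),
             dest_lon = numeric(), dest_lat = numeric(),
             external_place = character(), stringsAsFactors = FALSE)
}

#' Resolve distances and classify moves into the four-way typology
#'
#' Resolves external endpoints against the gazetteer, computes great-circle
#' distances, determines co-movers and independence, and crosses the
#' distance class with accompaniment. Moves whose distance cannot be
#' resolved are kept with `move_type` NA and counted in the attribute
#' `n_unresolved`.
#'
#' @param moves Output of [detect_moves()].
#' @param panel Panel of the same register.
#' @param register The register.
#' @param cutoff_km Short/long cutoff in kilometres; short is strictly below
#'   the cutoff.
#' @return The move table with `distance_km`, `n_co_movers`,
#'   `moved_with_mother`, `moved_with_father`, `accompanied`,
#'   `distance_class` and `move_type` columns.
#' @export
classify_moves <- function(moves, panel, register, cutoff_km = 4) {
  p <- register$persons
  qs <- sort(unique(panel$quarter_date))
  if (!nrow(moves)) {
    out <- cbind(moves, data.frame(
      distance_km = numeric(), n_co_movers = integer(),
      moved_with_mother = logical(), moved_with_father = logical(),
      accompanied = logical(), distance_class = character(),
      move_type = character(), stringsAsFactors = FALSE))
    attr(out, "n_unresolved") <- 0L
    return(out)
  }
  # resolve external endpoints
  ext <- !is.na(moves$external_place)
  res <- resolve_external(moves$external_place[ext], register$gazetteer,
                          strict = FALSE)
  moves$origin_lon[ext & moves$direction == "in_migration"] <-
    res$lon[moves$direction[ext] == "in_migration"]
  moves$origin_lat[ext & moves$direction == "in_migration"] <-
    res$lat[moves$direction[ext] == "in_migration"]
  moves$dest_lon[ext & moves$direction == "out_migration"] <-
    res$lon[moves$direction[ext] == "out_migration"]
  moves$dest_lat[ext & moves$direction == "out_migration"] <-
    res$lat[moves$direction[ext] == "out_migration"]

  moves$distance_km <- great_circle_km(moves$origin_lon, moves$origin_lat,
                                       moves$dest_lon, moves$dest_lat)

  pkey <- paste(panel$person_id, panel$quarter_date)
  ep <- register$episodes
  mo_of <- stats::setNames(p$mother_id, p$person_id)
  fa_of <- stats::setNames(p$father_id, p$person_id)
  birth_of <- stats::setNames(as.numeric(p$birth_date), p$person_id)

  n <- nrow(moves)
  n_co <- integer(n); w_mo <- logical(n); w_fa <- logical(n)
  acc <- logical(n)
  for (r in seq_len(n)) {
    dir <- moves$direction[r]
    id <- moves$person_id[r]
    t <- moves$interval_index[r]
    q0 <- qs[t]; q1 <- qs[t + 1]
    co <- character(0)
    if (dir == "internal") {
      roster <- panel$person_id[panel$quarter_date == q0 &
                                  panel$unique_household_id == moves$origin_hh[r]]
      roster <- setdiff(roster, id)
      if (length(roster)) {
        dest <- panel$unique_household_id[match(paste(roster, q1), pkey)]
        co <- roster[!is.na(dest) & dest == moves$dest_hh[r]]
      }
    } else if (dir == "out_migration") {
      roster <- panel$person_id[panel$quarter_date == q0 &
                                  panel$unique_household_id == moves$origin_hh[r]]
      roster <- setdiff(roster, id)
      if (length(roster)) {
        om <- ep[ep$end_reason == "out_migration" & ep$person_id %in% roster &
                   ep$end_date > q0 & ep$end_date <= q1, ]
        same <- normalise_place(om$external_to) ==
          normalise_place(moves$external_place[r])
        co <- unique(om$person_id[same])
      }
    } else {   # in_migration: co-arrivers from the same source place
      im <- ep[ep$start_reason == "in_migration" &
                 ep$start_date > q0 & ep$start_date <= q1 &
                 ep$unique_household_id == moves$dest_hh[r] &
                 ep$person_id != id, ]
      same <- normalise_place(im$external_from) ==
        normalise_place(moves$external_place[r])
      co <- unique(im$person_id[same])
    }
    n_co[r] <- length(co)
    if (length(co)) {
      ages <- (as.numeric(q0) - birth_of[co]) / 365.25
      is_par <- co %in% c(mo_of[[id]], fa_of[[id]])
      w_mo[r] <- !is.na(mo_of[[id]]) && mo_of[[id]] %in% co
      w_fa[r] <- !is.na(fa_of[[id]]) && fa_of[[id]] %in% co
      acc[r] <- any(is_par) || any(ages >= 18)
    }
  }
  moves$n_co_movers <- n_co
  moves$moved_with_mother <- w_mo
  moves$moved_with_father <- w_fa
  moves$accompanied <- acc
  cls <- classify_move_type(moves$distance_km, cutoff_km, acc)
  moves$distance_class <- cls$distance_class
  moves$move_type <- cls$move_type
  attr(moves, "n_unresolved") <- sum(is.na(moves$distance_km))
  moves
}

#' Cross distance class with accompaniment
#'
#' Short means strictly less than the cutoff; at or above is long.
#'
#' @param distance_km Numeric distances (NA allowed: yields NA type).
#' @param cutoff_km Cutoff in kilometres.
#' @param accompanied Logical vector.
#' @return Data frame with `distance_class` and `move_type`.
#' @export
classify_move_type <- function(distance_km, cutoff_km, accompanied) {
  dc <- ifelse(is.na(distance_km), NA_character_,
               ifelse(distance_km < cutoff_km, "short", "long"))
  mt <- ifelse(is.na(dc), NA_character_,
               paste(dc, ifelse(accompanied, "accompanied", "independent"),
                     sep = "_"))
  data.frame(distance_class = dc, move_type = mt, stringsAsFactors = FALSE)
}

#' Classify independence of a single move
#'
#' A move is accompanied when at least one co-mover is a parent of the index
#' (of any age) or an adult aged 18 or over; otherwise independent. The
#' index person's own age is irrelevant.
#'
#' @param co_mover_ages Numeric ages of co-movers at the move quarter.
#' @param co_mover_is_parent Logical vector, same length.
#' @return TRUE if accompanied.
#' @export
classify_independence <- function(co_mover_ages, co_mover_is_parent) {
  if (!length(co_mover_ages)) return(FALSE)
  any(co_mover_is_parent) || any(co_mover_ages >= 18)
}

#' Derive the short/long distance cutoff from school changes
#'
#' Pairs of consecutive-year survey records of the same child, both still in
#' primary school, whose geographic household ID changed between interviews,
#' split by whether the school changed. Group means carry 95% confidence
#' intervals cluster-robust by individual. The chosen cutoff is a
#' configuration value (default 4 km) reported alongside the diagnostics; it
#' is not re-estimated from the group means.
#'
#' @param register An `hdss_register`.
#' @param cutoff_km The configured cutoff to report.
#' @return List of class `cutoff_diagnostics`.
#' @export
derive_distance_cutoff <- function(register, cutoff_km = 4) {
  sv <- register$surveys
  sv <- sv[!is.na(sv$in_primary) & sv$in_primary, ]
  ep <- register$episodes
  hg <- register$household_geo
  geo_of <- function(person, date) {
    e <- ep[ep$person_id == person & ep$start_date <= date &
              ep$end_date > date, ]
    if (!nrow(e)) return(NULL)
    g <- hg[hg$unique_household_id == e$unique_household_id[1] &
              hg$valid_from <= date & hg$valid_to > date, ]
    if (!nrow(g)) return(NULL)
    g[1, c("geo_household_id", "lon", "lat")]
  }
  pairs <- list()
  if (nrow(sv)) {
    sv$year <- as.integer(format(sv$survey_date, "%Y"))
    sv <- sv[order(sv$person_id, sv$year), ]
    nr <- nrow(sv)
    prev <- seq_len(nr - 1)
    link <- which(sv$person_id[prev] == sv$person_id[prev + 1] &
                    sv$year[prev] + 1L == sv$year[prev + 1])
    for (k in link) {
      g1 <- geo_of(sv$person_id[k], sv$survey_date[k])
      g2 <- geo_of(sv$person_id[k + 1], sv$survey_date[k + 1])
      if (is.null(g1) || is.null(g2)) next
      if (g1$geo_household_id == g2$geo_household_id) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        person_id = sv$person_id[k],
        changed_school = !is.na(sv$school_id[k]) &
          !is.na(sv$school_id[k + 1]) &
          sv$school_id[k] != sv$school_id[k + 1],
        dist_km = great_circle_km(g1$lon, g1$lat, g2$lon, g2$lat),
        stringsAsFactors = FALSE)
    }
  }
  pr <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(person_id = character(), changed_school = logical(),
               dist_km = numeric(), stringsAsFactors = FALSE)
  grp_stats <- function(d) {
    if (!nrow(d)) return(list(mean = NA_real_, ci = c(NA_real_, NA_real_)))
    mu <- mean(d$dist_km)
    se <- cluster_se_mean(d$dist_km, d$person_id)
    list(mean = mu, ci = c(mu - 1.96 * se, mu + 1.96 * se))
  }
  same <- grp_stats(pr[!pr$changed_school, ])
  chg <- grp_stats(pr[pr$changed_school, ])
  structure(list(
    n_pairs = nrow(pr),
    n_individuals = length(unique(pr$person_id)),
    n_same_school = sum(!pr$changed_school),
    n_changed_school = sum(pr$changed_school),
    mean_km_same = same$mean, ci_same = same$ci,
    mean_km_changed = chg$mean, ci_changed = chg$ci,
    chosen_cutoff_km = cutoff_km), class = "cutoff_diagnostics")
}
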