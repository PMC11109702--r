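# Household-composition categories, household age-band counts and
# kin-proximity flags. The composition classifier is a total rule cascade
# over the index person's co-residents; precedence is documented in the
# package vignette.

composition_levels <- c("parents_siblings", "sisters_family",
                        "brothers_family", "mother_siblings",
                        "father_stepmother", "maternal", "paternal",
                        "spouse", "other", "external", "no_ids")

#' Classify the composition of an index person's household
#'
#' Assigns exactly one category from the rule cascade: `no_ids` when the
#' index lacks both parent identifiers; `external` when the household lies
#' outside the surveillance area; `spouse` when a current spouse is present;
#' then sister's/brother's family (at least one adult sibling of that sex or
#' a member of their family present, strictly more of that side than the
#' other if both, and a parent present or no maternal/paternal kin present);
#' then mother & siblings (mother present, no father, father's other wife or
#' maternal kin); father & stepmother (mother absent, father or his other
#' wife present); maternal / paternal (strict majority of that side's kin,
#' with the excluding-parent conditions of each rule); parents & siblings
#' (both parents present); else `other`. Strict-majority ties fall through.
#'
#' @param person_id Index person.
#' @param roster Character vector of co-resident person ids (index excluded).
#' @param graph A `kin_graph`.
#' @param at_date Date of evaluation.
#' @param external Logical: is the household outside the surveillance area?
#' @return One category string.
#' @export
classify_household_composition <- function(person_id, roster, graph, at_date,
                                           external = FALSE) {
  i <- graph$index[[person_id]]
  if (is.null(i) || is.na(i)) data_error("unknown person")
  if (!graph$has_parent_ids[i]) return("no_ids")
  if (external) return("external")
  roster <- setdiff(roster, person_id)
  ks <- kin_sets(person_id, graph, at_date)
  sp <- graph$person_id[spouses_at(graph, i, at_date)]
  if (length(intersect(sp, roster))) return("spouse")

  mother <- graph$person_id[graph$mother[i]]
  father <- graph$person_id[graph$father[i]]
  mo_in <- length(mother) == 1 && !is.na(mother) && mother %in% roster
  fa_in <- length(father) == 1 && !is.na(father) && father %in% roster
  # father's other wife: a current wife of the father other than the mother
  fow_in <- FALSE
  if (length(father) == 1 && !is.na(father)) {
    fw <- graph$person_id[spouses_at(graph, graph$index[[father]], at_date)]
    fow <- setdiff(fw, if (length(mother)) mother else character(0))
    fow_in <- length(intersect(fow, roster)) > 0
  }
  n_mat <- length(intersect(ks$maternal, roster))
  n_pat <- length(intersect(ks$paternal, roster))
  n_sis <- length(intersect(ks$sisters_fam, roster))
  n_bro <- length(intersect(ks$brothers_fam, roster))

  parent_cond <- mo_in || fa_in || (n_mat == 0 && n_pat == 0)
  if (n_sis >= 1 && (n_bro == 0 || n_sis > n_bro) && parent_cond)
    return("sisters_family")
  if (n_bro >= 1 && (n_sis == 0 || n_bro > n_sis) && parent_cond)
    return("brothers_family")
  if (mo_in && !fa_in && !fow_in && n_mat == 0) return("mother_siblings")
  if (!mo_in && (fa_in || fow_in)) return("father_stepmother")
  if (!fa_in && !fow_in && n_mat >= 1 && n_mat > n_pat) return("maternal")
  if (!mo_in && !fow_in && n_pat >= 1 && n_pat > n_mat) return("paternal")
  if (mo_in && fa_in) return("parents_siblings")
  "other"
}

#' Household age-band counts
#'
#' Counts of co-residents in seven age bands (under 1, 1-4, 5-11, 12-18,
#' 19-29, 30-59, 60+), half-open at the upper boundary, index excluded.
#'
#' @param roster_ages Numeric ages of co-residents (index already excluded).
#' @return Named integer vector of length 7.
#' @export
household_age_counts <- function(roster_ages) {
  br <- c(0, 1, 5, 12, 19, 30, 60, Inf)
  lab <- c("age_u1", "age_1_4", "age_5_11", "age_12_18", "age_19_29",
           "age_30_59", "age_60p")
  cnt <- table(cut(roster_ages, breaks = br, right = FALSE, labels = lab))
  out <- as.integer(cnt)
  names(out) <- lab
  out
}

#' Kin-proximity flags for one record
#'
#' TRUE when at least one member of the kin set resides within `radius_m`
#' (inclusive) of the index household but in a different household at that
#' time.
#'
#' @param kin_ids Character vector of kin person ids.
#' @param index_hh Index household id.
#' @param person_hh Named vector: household id per co-temporal resident.
#' @param hh_near Named list: for each household, the ids of other households
#'   within the radius.
#' @return Logical flag.
#' @keywords internal
kin_nearby <- function(kin_ids, index_hh, person_hh, hh_near) {
  hh <- person_hh[kin_ids]
  hh <- hh[!is.na(hh) & hh != index_hh]
  if (!length(hh)) return(FALSE)
  any(hh %in% hh_near[[index_hh]])
}

#' Family context of every person-quarter
#'
#' Computes, for each panel record, the household-composition category, the
#' five kin-nearby flags (maternal, paternal, sister's, brother's, nuclear
#' family within `radius_m` but not in the household) and the seven
#' household age-band counts.
#'
#' @param register An `hdss_register`.
#' @param panel Panel from [build_panel()].
#' @param graph Optional prebuilt `kin_graph`.
#' @param radius_m Proximity radius in metres (inclusive).
#' @return Data frame keyed by (`person_id`, `quarter_date`).
#' @export
build_family_context <- function(register, panel, graph = NULL,
                                 radius_m = 250) {
  graph <- graph %||% build_kin_graph(register$persons, register$marriages)
  out <- vector("list", length(unique(panel$quarter_date)))
  qs <- sort(unique(panel$quarter_date))
  for (qi in seq_along(qs)) {
    q <- qs[qi]
    pq <- panel[panel$quarter_date == q, ]
    person_hh <- stats::setNames(pq$unique_household_id, pq$person_id)
    # households within radius of each other
    agg <- pq[!duplicated(pq$unique_household_id),
              c("unique_household_id", "lon", "lat")]
    hh_near <- vector("list", nrow(agg))
    names(hh_near) <- agg$unique_household_id
    for (k in seq_len(nrow(agg))) {
      d <- great_circle_km(agg$lon[k], agg$lat[k], agg$lon, agg$lat)
      hh_near[[k]] <- agg$unique_household_id[d <= radius_m / 1000]
    }
    roster_by_hh <- split(pq$person_id, pq$unique_household_id)
    ages <- stats::setNames(age_years(
      register$persons$birth_date[match(pq$person_id,
                                        register$persons$person_id)], q),
      pq$person_id)
    n <- nrow(pq)
    comp <- character(n)
    flags <- matrix(FALSE, n, 5,
                    dimnames = list(NULL, c("nearby_maternal",
                                            "nearby_paternal",
                                            "nearby_sisters",
                                            "nearby_brothers",
                                            "nearby_nuclear")))
    acount <- matrix(0L, n, 7)
    for (r in seq_len(n)) {
      id <- pq$person_id[r]
      hh <- pq$unique_household_id[r]
      roster <- setdiff(roster_by_hh[[hh]], id)
      comp[r] <- classify_household_composition(id, roster, graph, q)
      ks <- kin_sets(id, graph, q)
      flags[r, ] <- c(
        kin_nearby(ks$maternal, hh, person_hh, hh_near),
        kin_nearby(ks$paternal, hh, person_hh, hh_near),
        kin_nearby(ks$sisters_fam, hh, person_hh, hh_near),
        kin_nearby(ks$brothers_fam, hh, person_hh, hh_near),
        kin_nearby(ks$nuclear, hh, person_hh, hh_near))
      acount[r, ] <- household_age_counts(unname(ages[roster]))
    }
    res <- data.frame(person_id = pq$person_id, quarter_date = q,
                      composition = comp, stringsAsFactors = FALSE)
    res <- cbind(res, as.data.frame(flags))
    colnames(acount) <- c("age_u1", "age_1_4", "age_5_11", "age_12_18",
                          "age_19_29", "age_30_59", "age_60p")
    res <- cbind(res, as.data.frame(acount))
    out[[qi]] <- res
  }
  fc <- do.call(rbind, out)
  fc <- fc[order(fc$person_id, fc$quarter_date), ]
  rownames(fc) <- NULL
  fc
}
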