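# Shared fixtures, built in code.

# assemble a register from hand-written tables
make_register <- function(persons, households, household_geo, episodes,
                          surveys = NULL, marriages = NULL,
                          gazetteer = NULL) {
  empty_surveys <- data.frame(
    person_id = character(), survey_date = as.Date(character()),
    school_id = character(), grade = numeric(), in_primary = logical(),
    marital_status = character(), spouse_ids = character(),
    mother_secondary_edu = logical(), father_secondary_edu = logical(),
    stringsAsFactors = FALSE)
  empty_marr <- data.frame(
    marriage_id = character(), wife_id = character(),
    husband_id = character(), start_date = as.Date(character()),
    end_date = as.Date(character()), end_reason = character(),
    polygynous = logical(), stringsAsFactors = FALSE)
  reg <- list(persons = persons, households = households,
              household_geo = household_geo, episodes = episodes,
              surveys = surveys %||% empty_surveys,
              marriages = marriages %||% empty_marr,
              gazetteer = gazetteer %||% default_gazetteer(),
              config = NULL)
  class(reg) <- "hdss_register"
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

person_row <- function(id, sex, birth, mother = NA, father = NA,
                       death = NA, edu = FALSE) {
  data.frame(person_id = id, sex = sex, birth_date = as.Date(birth),
             mother_id = mother, father_id = father,
             death_date = as.Date(death), secondary_edu = edu,
             stringsAsFactors = FALSE)
}

household_row <- function(id, head, lon, lat, rank = "medium",
                          tarmac = 1) {
  list(hh = data.frame(unique_household_id = id, head_id = head,
                       head_employment_rank = rank, dist_tarmac_km = tarmac,
                       stringsAsFactors = FALSE),
       geo = data.frame(unique_household_id = id,
                        geo_household_id = paste0(id, "-1"),
                        lon = lon, lat = lat,
                        valid_from = as.Date("2004-01-01"),
                        valid_to = as.Date("2018-01-01"),
                        stringsAsFactors = FALSE))
}

episode_row <- function(person, hh, start, end, start_reason = "enumeration",
                        end_reason = "censor", from = NA, to = NA) {
  data.frame(person_id = person, unique_household_id = hh,
             start_date = as.Date(start), end_date = as.Date(end),
             start_reason = start_reason, end_reason = end_reason,
             external_from = from, external_to = to,
             stringsAsFactors = FALSE)
}

# a small simulated register, cached across test files
cached_register <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 11, n = 50, end = "2009-12-31") {
    key <- paste(seed, n, end)
    if (is.null(cache[[key]])) {
      cfg <- sim_config(seed = seed, n_founder_households = n,
                        period = as.Date(c("2004-01-01", end)))
      cache[[key]] <- simulate_register(cfg)
    }
    cache[[key]]
  }
})

cached_panel <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 11, n = 50, end = "2009-12-31") {
    key <- paste(seed, n, end)
    if (is.null(cache[[key]]))
      cache[[key]] <- build_panel(cached_register(seed, n, end))
    cache[[key]]
  }
})

# fixed pedigree around an index person, for composition tests:
# exact kin-set membership is known by construction
pedigree_fixture <- function() {
  at <- as.Date("2010-08-15")
  bd <- function(age) at - round(age * 365.25)
  persons <- rbind(
    person_row("IX", "female", bd(16), mother = "M", father = "F"),
    person_row("M", "female", bd(35), mother = "MGM", father = "MGF"),
    person_row("F", "male", bd(38), mother = "PGM", father = "PGF"),
    person_row("W2", "female", bd(30)),                    # father's other wife
    person_row("SP", "male", bd(20)),                      # spouse of index
    person_row("S18", "female", bd(19), mother = "M", father = "F"),
    person_row("S17", "female", bd(17), mother = "M", father = "F"),
    person_row("B20", "male", bd(20), mother = "M", father = "F"),
    person_row("B10", "male", bd(9), mother = "M", father = "F"),
    person_row("MGM", "female", bd(60)),
    person_row("MGF", "male", bd(63)),
    person_row("MA", "female", bd(35), mother = "MGM", father = "MGF"),
    person_row("MAC", "male", bd(12), mother = "MA"),
    person_row("PGF", "male", bd(65)),
    person_row("PGM", "female", bd(62)),
    person_row("PU", "male", bd(40), mother = "PGM", father = "PGF"),
    person_row("SH", "male", bd(22)),                      # S18's husband
    person_row("SC", "female", bd(1), mother = "S18", father = "SH"),
    person_row("BW", "female", bd(19)),                    # B20's wife
    person_row("BC", "male", bd(0.5), mother = "BW", father = "B20"),
    person_row("U1", "male", bd(30)),
    person_row("U2", "female", bd(28)))
  marriages <- data.frame(
    marriage_id = c("M1", "M2", "M3", "M4", "M5"),
    wife_id = c("M", "W2", "S18", "BW", "IX"),
    husband_id = c("F", "F", "SH", "B20", "SP"),
    start_date = as.Date(rep("2000-01-01", 5)),
    end_date = as.Date(rep(NA, 5)), end_reason = NA_character_,
    polygynous = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  graph <- build_kin_graph(persons, marriages)
  # declarative kin sets, straight from the definitions
  sets <- list(
    maternal = c("MGM", "MGF", "MA", "MAC"),
    paternal = c("PGF", "PGM", "PU"),
    sisters_fam = c("S18", "SH", "SC"),
    brothers_fam = c("B20", "BW", "BC"),
    nuclear = c("M", "F", "S17", "B10"))
  list(graph = graph, persons = persons, marriages = marriages, at = at,
       sets = sets,
       universe = setdiff(persons$person_id, "IX"))
}

# independent declarative reading of the composition category bullets,
# specific to the pedigree fixture (membership hard-coded)
oracle_composition <- function(roster, px) {
  s <- px$sets
  present <- function(ids) length(intersect(ids, roster)) > 0
  n_of <- function(ids) length(intersect(ids, roster))
  if (present("SP")) return("spouse")
  mo <- "M" %in% roster; fa <- "F" %in% roster; fow <- "W2" %in% roster
  n_sis <- n_of(s$sisters_fam); n_bro <- n_of(s$brothers_fam)
  n_mat <- n_of(s$maternal); n_pat <- n_of(s$paternal)
  parent_ok <- mo || fa || (n_mat == 0 && n_pat == 0)
  if (n_sis >= 1 && (n_bro == 0 || n_sis > n_bro) && parent_ok)
    return("sisters_family")
  if (n_bro >= 1 && (n_sis == 0 || n_bro > n_sis) && parent_ok)
    return("brothers_family")
  if (mo && !fa && !fow && n_mat == 0) return("mother_siblings")
  if (!mo && (fa || fow)) return("father_stepmother")
  if (!fa && !fow && n_mat >= 1 && n_mat > n_pat) return("maternal")
  if (!mo && !fow && n_pat >= 1 && n_pat > n_mat) return("paternal")
  if (mo && fa) return("parents_siblings")
  "other"
}
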