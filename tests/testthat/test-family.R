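test_that("the kinship graph links siblings and flags missing parent ids", {
  px <- pedigree_fixture()
  g <- px$graph
  i <- g$index[["IX"]]
  sibs <- g$person_id[g$siblings[[i]]]
  expect_setequal(sibs, c("S18", "S17", "B20", "B10"))
  expect_false(g$has_parent_ids[g$index[["U1"]]])
  expect_true(g$has_parent_ids[g$index[["IX"]]])
  # cyclic parentage is rejected
  bad <- rbind(person_row("A", "female", "1970-01-01", mother = "B"),
               person_row("B", "female", "1990-01-01", mother = "A"))
  expect_error(build_kin_graph(bad, px$marriages), "cyclic")
})

test_that("kin sets at a date match the declarative pedigree enumeration", {
  px <- pedigree_fixture()
  ks <- kin_sets("IX", px$graph, px$at)
  for (nm in names(px$sets)) expect_setequal(ks[[nm]], px$sets[[nm]])
  # the 17-year-old sister is nuclear family, not sister's family
  expect_true("S17" %in% ks$nuclear)
  expect_false("S17" %in% ks$sisters_fam)
  # child with mother, maternal grandmother and aunt: set excludes the mother
  expect_false("M" %in% ks$maternal)
  # ten years later the 17-year-old sister has aged into sister's family
  ks2 <- kin_sets("IX", px$graph, px$at + 3653)
  expect_true("S17" %in% ks2$sisters_fam)
})

test_that("maternal kin equal a brute-force walk through the mother on a simulated register", {
  reg <- cached_register(seed = 11)
  g <- build_kin_graph(reg$persons, reg$marriages)
  p <- reg$persons
  # independent oracle: undirected parent-child BFS from the mother,
  # blocking the index and its siblings, depth 3
  adj_of <- function(id) {
    r <- p[p$person_id == id, ]
    kids <- p$person_id[(!is.na(p$mother_id) & p$mother_id == id) |
                          (!is.na(p$father_id) & p$father_id == id)]
    c(r$mother_id, r$father_id, kids)
  }
  oracle_maternal <- function(id) {
    r <- p[p$person_id == id, ]
    if (is.na(r$mother_id)) return(character(0))
    sibs <- p$person_id[(!is.na(p$mother_id) & !is.na(r$mother_id) &
                           p$mother_id == r$mother_id) |
                          (!is.na(p$father_id) & !is.na(r$father_id) &
                             p$father_id == r$father_id)]
    sibs <- setdiff(sibs, id)
    blocked <- c(id, sibs)
    seen <- r$mother_id; frontier <- r$mother_id
    for (d in 1:3) {
      frontier <- setdiff(unique(unlist(lapply(frontier, adj_of))),
                          c(seen, blocked, NA))
      if (!length(frontier)) break
      seen <- c(seen, frontier)
    }
    setdiff(seen, r$mother_id)
  }
  set.seed(3)
  for (id in sample(p$person_id[!is.na(p$mother_id)], 25)) {
    got <- kin_sets(id, g, as.Date("2008-02-15"))$maternal
    expect_setequal(got, oracle_maternal(id))
  }
})

test_that("composition classifier reproduces forced examples", {
  px <- pedigree_fixture()
  cls <- function(roster) classify_household_composition("IX", roster,
                                                         px$graph, px$at)
  expect_identical(cls(c("M", "F", "B10")), "parents_siblings")
  expect_identical(cls(c("M", "B10", "S17")), "mother_siblings")
  expect_identical(cls(c("MGM", "MA", "PGF", "PU")), "other")  # 2 vs 2 tie
  expect_identical(cls(c("SP", "M", "F")), "spouse")
  expect_identical(cls(c("F", "W2")), "father_stepmother")
  expect_identical(cls(c("W2")), "father_stepmother")
  expect_identical(cls(c("MGM", "MA")), "maternal")
  expect_identical(cls(c("PGF", "PU", "PGM")), "paternal")
  expect_identical(cls(c("S18", "SH")), "sisters_family")
  expect_identical(cls(c("B20", "BW", "BC")), "brothers_family")
  expect_identical(cls(character(0)), "other")
  expect_identical(classify_household_composition("U1", c("M", "F"),
                                                  px$graph, px$at), "no_ids")
  expect_identical(classify_household_composition("IX", c("M", "F"),
                                                  px$graph, px$at,
                                                  external = TRUE),
                   "external")
})

test_that("composition cascade is total and matches the declarative oracle", {
  px <- pedigree_fixture()
  set.seed(14)
  n_match <- 0L
  for (r in 1:2000) {
    k <- sample(0:8, 1)
    roster <- sample(px$universe, k)
    got <- classify_household_composition("IX", roster, px$graph, px$at)
    expect_true(got %in% hdssmove:::composition_levels)
    expect_identical(got, oracle_composition(roster, px))
    n_match <- n_match + 1L
  }
  expect_identical(n_match, 2000L)
})

test_that("household age counts use half-open seven-band boundaries", {
  expect_identical(unname(household_age_counts(c(0.5, 3, 25, 61))),
                   c(1L, 1L, 0L, 0L, 1L, 0L, 1L))
  expect_identical(unname(household_age_counts(numeric(0))), rep(0L, 7))
  expect_identical(unname(household_age_counts(19)),
                   c(0L, 0L, 0L, 0L, 1L, 0L, 0L))
  # every boundary age lands in the older band
  expect_identical(unname(household_age_counts(c(1, 5, 12, 19, 30, 60))),
                   c(0L, 1L, 1L, 1L, 1L, 1L, 1L))
  expect_identical(sum(household_age_counts(runif(23, 0, 80))), 23L)
})

test_that("kin-nearby flags equal a brute-force pairwise computation", {
  # grid of households ~220 m apart; pedigree members distributed across them
  px <- pedigree_fixture()
  ids <- px$persons$person_id
  set.seed(8)
  grid <- expand.grid(gx = 0:4, gy = 0:4)[seq_along(ids), ]
  hh_of <- sprintf("H%02d", sample(seq_len(12), length(ids), replace = TRUE))
  coords <- data.frame(
    unique_household_id = sprintf("H%02d", 1:12),
    lon = 34 + (0:11 %% 4) * 0.002, lat = -9.95 + (0:11 %/% 4) * 0.002)
  pan <- data.frame(person_id = ids, quarter_date = px$at,
                    unique_household_id = hh_of,
                    lon = coords$lon[match(hh_of,
                                           coords$unique_household_id)],
                    lat = coords$lat[match(hh_of,
                                           coords$unique_household_id)],
                    stringsAsFactors = FALSE)
  reg <- make_register(px$persons,
                       data.frame(unique_household_id = coords$unique_household_id,
                                  head_id = NA, head_employment_rank = "low",
                                  dist_tarmac_km = 1,
                                  stringsAsFactors = FALSE),
                       data.frame(unique_household_id = coords$unique_household_id,
                                  geo_household_id = paste0(coords$unique_household_id, "-1"),
                                  lon = coords$lon, lat = coords$lat,
                                  valid_from = as.Date("2004-01-01"),
                                  valid_to = as.Date("2018-01-01"),
                                  stringsAsFactors = FALSE),
                       do.call(rbind, lapply(seq_along(ids), function(i)
                         episode_row(ids[i], hh_of[i], "2004-01-01",
                                     "2018-01-01"))),
                       marriages = px$marriages)
  fc <- build_family_context(reg, pan, graph = px$graph)
  skip_if_not_installed("geosphere")
  flag_names <-c(maternal = "nearby_maternal", paternal = "nearby_paternal",
                  sisters_fam = "nearby_sisters",
                  brothers_fam = "nearby_brothers",
                  nuclear = "nearby_nuclear")
  for (r in seq_along(ids)) {
    ks <- kin_sets(ids[r], px$graph, px$at)
    for (nm in names(flag_names)) {
      brute <- FALSE
      for (kin in ks[[nm]]) {
        j <- match(kin, pan$person_id)
        if (is.na(j)) next
        if (pan$unique_household_id[j] == pan$unique_household_id[r]) next
        d <- geosphere::distGeo(c(pan$lon[r], pan$lat[r]),
                                c(pan$lon[j], pan$lat[j]))
        if (d <= 250) brute <- TRUE
      }
      expect_identical(fc[[flag_names[[nm]]]][fc$person_id == ids[r]],
                       brute)
    }
  }
})

test_that("enlarging the radius never clears a nearby flag", {
  reg <- cached_register(seed = 11)
  pan <- cached_panel(seed = 11)
  q <- pan[pan$quarter_date == as.Date("2006-08-15"), ]
  fc1 <- build_family_context(reg, q, radius_m = 250)
  fc2 <- build_family_context(reg, q, radius_m = 600)
  for (nm in c("nearby_maternal", "nearby_paternal", "nearby_sisters",
               "nearby_brothers", "nearby_nuclear"))
    expect_true(all(fc2[[nm]] >= fc1[[nm]]))
})
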