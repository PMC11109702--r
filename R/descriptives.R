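# Descriptive machinery: age-sex risk curves, sending/receiving composition
# flow tables with Sankey export, and parent-accompaniment tables, all with
# two-way cluster-robust uncertainty.

#' Column percents of a count vector
#'
#' Percent of the column total, rounded half-up to one decimal — the
#' tabulation convention of the printed flow and accompaniment tables.
#'
#' @param n Integer counts.
#' @param digits Decimals to round to (NULL for unrounded).
#' @return Numeric percents.
#' @export
tabulate_percents <- function(n, digits = 1) {
  p <- 100 * n / sum(n)
  if (is.null(digits)) p else round_half_up(p, digits)
}

#' Move risk by age year and sex
#'
#' Percent of person-quarters experiencing each move type at each age year
#' (ages 0-34), by sex, with 95% confidence intervals allowing for
#' clustering by unique household id and unique individual id.
#'
#' @param panel Panel data frame.
#' @param moves Classified moves from [classify_moves()].
#' @param max_age Upper age limit (years).
#' @return Data frame: sex, move_type, age_year, n_moves, n_at_risk,
#'   percent, ci_lo, ci_hi (NA percent rows flag empty denominators).
#' @export
move_risk_by_age <- function(panel, moves, max_age = 34) {
  mkey <- paste(moves$person_id, moves$quarter_date)
  mt <- moves$move_type[match(paste(panel$person_id, panel$quarter_date),
                              mkey)]
  age <- floor(panel$age_years)
  keep <- age <= max_age
  types <- c("short_independent", "long_independent", "short_accompanied",
             "long_accompanied")
  out <- list()
  for (s in c("female", "male")) {
    for (ty in types) {
      for (a in 0:max_age) {
        i <- which(keep & panel$sex == s & age == a)
        if (!length(i)) {
          out[[length(out) + 1L]] <- data.frame(
            sex = s, move_type = ty, age_year = a, n_moves = 0L,
            n_at_risk = 0L, percent = NA_real_, ci_lo = NA_real_,
            ci_hi = NA_real_, stringsAsFactors = FALSE)
          next
        }
        y <- !is.na(mt[i]) & mt[i] == ty
        cp <- clustered_proportion(y, panel$unique_household_id[i],
                                   panel$person_id[i])
        out[[length(out) + 1L]] <- data.frame(
          sex = s, move_type = ty, age_year = a, n_moves = sum(y),
          n_at_risk = length(i), percent = cp$percent,
          ci_lo = cp$ci[1], ci_hi = cp$ci[2], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# annotate short/long classified moves with stage, sex and sending/receiving
# household composition (receiving = composition at the post-move quarter)
annotate_moves <- function(moves, panel, family_context) {
  qs <- sort(unique(panel$quarter_date))
  pkey <- paste(panel$person_id, panel$quarter_date)
  fkey <- paste(family_context$person_id, family_context$quarter_date)
  mv <- moves
  pi <- match(paste(mv$person_id, mv$quarter_date), pkey)
  mv$sex <- panel$sex[pi]
  mv$life_stage <- panel$life_stage[pi]
  # sending composition at the exposure quarter; external for in-migrations
  send <- family_context$composition[match(paste(mv$person_id,
                                                 mv$quarter_date), fkey)]
  send[mv$direction == "in_migration"] <- "external"
  mv$sending <- send
  # receiving composition at the following snapshot; external when absent
  qnext <- qs[mv$interval_index + 1L]
  recv <- family_context$composition[match(paste(mv$person_id, qnext), fkey)]
  recv[mv$direction == "in_migration"] <-
    family_context$composition[match(paste(mv$person_id, mv$quarter_date),
                                     fkey)][mv$direction == "in_migration"]
  recv[is.na(recv)] <- "external"
  mv$receiving <- recv
  # clustering household: the sending household, else the receiving one
  mv$cluster_hh <- ifelse(!is.na(mv$origin_hh), mv$origin_hh, mv$dest_hh)
  mv
}

#' Sending/receiving household-composition flow tables
#'
#' For short moves only (full information on both ends), counts of moves by
#' sending and receiving composition per stage x independence stratum, with
#' per-sex column percents (95% CI) and a Wald comparison of the sexes, both
#' allowing for clustering by unique household and unique individual id, and
#' a nodes/links structure per stratum suitable for Sankey rendering.
#'
#' @param moves Classified moves.
#' @param panel Panel data frame.
#' @param family_context Output of [build_family_context()].
#' @return List with `moves` (annotated short moves), `table` (long counts,
#'   percents, CIs, p-values), and `sankey` (per-stratum list of nodes and
#'   links).
#' @export
build_flow_table <- function(moves, panel, family_context) {
  mv <- annotate_moves(moves, panel, family_context)
  mv <- mv[!is.na(mv$distance_class) & mv$distance_class == "short" &
             !is.na(mv$life_stage) & mv$life_stage %in% c("child",
                                                          "adolescent"), ]
  rows <- list()
  sankey <- list()
  for (stage in c("child", "adolescent")) {
    for (ind in c("independent", "accompanied")) {
      sub <- mv[mv$life_stage == stage &
                  mv$accompanied == (ind == "accompanied"), ]
      if (!nrow(sub)) next
      strat <- paste(stage, ind, sep = "_")
      mat <- table(factor(sub$sending, composition_levels),
                   factor(sub$receiving, composition_levels))
      sankey[[strat]] <- sankey_links(mat)
      for (side in c("sending", "receiving")) {
        val <- sub[[side]]
        for (cat in composition_levels) {
          if (!any(val == cat)) next
          res <- compare_proportions_by_sex(val == cat, sub$sex,
                                            sub$cluster_hh, sub$person_id)
          for (s in c("female", "male")) {
            i <- sub$sex == s
            if (!any(i)) next
            cp <- clustered_proportion(val[i] == cat, sub$cluster_hh[i],
                                       sub$person_id[i])
            rows[[length(rows) + 1L]] <- data.frame(
              stage = stage, independence = ind, side = side, sex = s,
              category = cat, n = sum(val[i] == cat),
              percent = cp$percent, ci_lo = cp$ci[1], ci_hi = cp$ci[2],
              p_sex = res$p_value, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  list(moves = mv,
       table = if (length(rows)) do.call(rbind, rows) else NULL,
       sankey = sankey)
}

# nodes/links representation of a sending x receiving count matrix
sankey_links <- function(mat) {
  snames <- paste0("send_", rownames(mat))
  rnames <- paste0("recv_", colnames(mat))
  nodes <- c(snames, rnames)
  links <- which(mat > 0, arr.ind = TRUE)
  list(nodes = nodes,
       links = data.frame(
         source = links[, 1] - 1L,
         target = length(snames) + links[, 2] - 1L,
         value = mat[links], stringsAsFactors = FALSE))
}

#' Parent accompaniment of accompanied moves
#'
#' Classifies each accompanied move by which biological parents are among
#' the co-movers (neither, mother only, father only, both), tabulated by
#' stage, move length and sex with clustered percents and sex comparisons.
#'
#' @param moves Classified moves.
#' @param panel Panel data frame.
#' @return Data frame of counts, percents, CIs and sex-comparison p-values.
#' @export
parent_accompaniment <- function(moves, panel) {
  pkey <- paste(panel$person_id, panel$quarter_date)
  pi <- match(paste(moves$person_id, moves$quarter_date), pkey)
  mv <- moves
  mv$sex <- panel$sex[pi]
  mv$life_stage <- panel$life_stage[pi]
  mv$cluster_hh <- ifelse(!is.na(mv$origin_hh), mv$origin_hh, mv$dest_hh)
  mv <- mv[mv$accompanied & !is.na(mv$distance_class) &
             !is.na(mv$life_stage) & mv$life_stage %in% c("child",
                                                          "adolescent"), ]
  mv$with_parents <- ifelse(mv$moved_with_mother & mv$moved_with_father,
                            "both",
                     ifelse(mv$moved_with_mother, "mother_only",
                     ifelse(mv$moved_with_father, "father_only", "neither")))
  cats <- c("neither", "mother_only", "father_only", "both")
  rows <- list()
  for (stage in c("child", "adolescent")) {
    for (len in c("short", "long")) {
      sub <- mv[mv$life_stage == stage & mv$distance_class == len, ]
      if (!nrow(sub)) next
      for (cat in cats) {
        res <- compare_proportions_by_sex(sub$with_parents == cat, sub$sex,
                                          sub$cluster_hh, sub$person_id)
        for (s in c("female", "male")) {
          i <- sub$sex == s
          if (!any(i)) next
          cp <- clustered_proportion(sub$with_parents[i] == cat,
                                     sub$cluster_hh[i], sub$person_id[i])
          rows[[length(rows) + 1L]] <- data.frame(
            stage = stage, length = len, sex = s, category = cat,
            n = sum(sub$with_parents[i] == cat), percent = cp$percent,
            ci_lo = cp$ci[1], ci_hi = cp$ci[2], p_sex = res$p_value,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}
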