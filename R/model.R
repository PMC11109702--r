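# Multilevel multinomial logit of move type. The outcome per person-quarter
# is `none` (baseline) or one of the four move types; for each non-baseline
# category k the model is
#   log P(y = k) / P(y = none) = x' b_k + u_household,k + v_individual,k
# with independent Gaussian random intercepts. Estimation decomposes the
# multinomial into per-category binary logits on the rows with outcome in
# {none, k} (Begg & Gray 1984): conditional on the random effects the other
# categories cancel from the ratio, so each component is a correctly
# specified binary logistic mixed model, fitted with lme4::glmer with
# crossed random intercepts. With random effects disabled each component is
# a plain binary logit, which coincides with the multinomial MLE whenever
# the design is saturated (used as a cross-check in the tests).

outcome_levels <- c("none", "short_independent", "long_independent",
                    "short_accompanied", "long_accompanied")

default_covariates <- function(stage) {
  c("composition", "age_u1", "age_1_4", "age_5_11", "age_12_18",
    "age_19_29", "age_30_59", "age_60p",
    "nearby_maternal", "nearby_paternal", "nearby_sisters",
    "nearby_brothers", "nearby_nuclear",
    if (stage == "adolescent") "own_child_present",
    "mother_dead", "father_dead", "age_subgroup", "year_band",
    "dist_tarmac_km", "pop_density_cat",
    "mother_secondary_edu", "father_secondary_edu",
    "head_employment_rank")
}

#' Build the regression dataset for one sex-stage stratum
#'
#' One row per person-quarter in the stratum with the five-category outcome.
#' Exclusions follow the analysis design: moves from outside the area
#' (in-migrations) carry no sending-household information and are dropped;
#' persons with no record of either parent identifier are excluded; rows
#' with composition `other`, `no_ids` or `external`, or with missing
#' household socio-economic fields, are dropped. Counts per reason are
#' attached as the `exclusions` attribute.
#'
#' @param panel Panel data frame.
#' @param moves Classified moves.
#' @param family_context Output of [build_family_context()].
#' @param sex `"female"` or `"male"`.
#' @param stage `"child"` or `"adolescent"`.
#' @return Model data frame with an `outcome` factor and covariates.
#' @export
build_model_dataset <- function(panel, moves, family_context, sex, stage) {
  d <- panel[panel$sex == sex & panel$life_stage == stage, ]
  excl <- c(in_migration_outcome = 0L, untyped_move = 0L,
            no_parent_ids = 0L, composition_unknown = 0L, ses_missing = 0L)

  mkey <- paste(moves$person_id, moves$quarter_date)
  mi <- match(paste(d$person_id, d$quarter_date), mkey)
  d$outcome <- ifelse(is.na(mi), "none", moves$move_type[mi])
  dir <- moves$direction[mi]
  drop_in <- !is.na(mi) & dir == "in_migration"
  excl["in_migration_outcome"] <- sum(drop_in)
  drop_untyped <- !is.na(mi) & !drop_in & is.na(d$outcome)
  excl["untyped_move"] <- sum(drop_untyped)
  d <- d[!drop_in & !drop_untyped, ]

  no_par <- !d$has_parent_ids
  excl["no_parent_ids"] <- sum(no_par)
  d <- d[!no_par, ]

  fkey <- paste(family_context$person_id, family_context$quarter_date)
  fi <- match(paste(d$person_id, d$quarter_date), fkey)
  fc <- family_context[fi, setdiff(names(family_context),
                                   c("person_id", "quarter_date"))]
  d <- cbind(d, fc)
  bad_comp <- is.na(d$composition) |
    d$composition %in% c("other", "no_ids", "external")
  excl["composition_unknown"] <- sum(bad_comp)
  d <- d[!bad_comp, ]

  ses_na <- is.na(d$head_employment_rank) | is.na(d$mother_secondary_edu) |
    is.na(d$father_secondary_edu) | is.na(d$pop_density_cat) |
    is.na(d$dist_tarmac_km)
  excl["ses_missing"] <- sum(ses_na)
  d <- d[!ses_na, ]
  if (!nrow(d)) {
    binding <- names(excl)[which.max(excl)]
    data_error(sprintf("empty model table; binding filter: %s", binding))
  }

  d$outcome <- factor(d$outcome, levels = outcome_levels)
  d$composition <- stats::relevel(factor(d$composition), "parents_siblings")
  d$age_subgroup <- factor(d$age_subgroup,
                           levels = c("youngest", "young", "older",
                                      "oldest"))
  d$year_band <- factor(d$year_band)
  d$pop_density_cat <- factor(d$pop_density_cat,
                              levels = c("low", "medium", "high"))
  d$head_employment_rank <- factor(d$head_employment_rank,
                                   levels = c("low", "medium", "high"))
  # orphanhood: "known to be dead" — unknown vital status counts as FALSE
  d$mother_dead[is.na(d$mother_dead)] <- FALSE
  d$father_dead[is.na(d$father_dead)] <- FALSE
  attr(d, "exclusions") <- excl
  d
}

#' Fit the multilevel multinomial logit of move type
#'
#' Per-category binary-logit decomposition with crossed Gaussian random
#' intercepts for unique individual and unique household (see the package
#' vignette for the estimator's rationale). With `random_effects = FALSE`
#' each component is an ordinary logistic regression.
#'
#' @param data Model table from [build_model_dataset()], or any data frame
#'   with an `outcome` factor whose first level is the baseline.
#' @param covariates Character vector of right-hand-side terms.
#' @param random_effects Fit crossed random intercepts?
#' @param categories Non-baseline outcome categories to fit (default: all
#'   observed).
#' @param individual,household Column names of the two cluster identifiers.
#' @param nAGQ Integer passed to [lme4::glmer()] (0 for the faster penalised
#'   least-squares approximation, 1 for the Laplace approximation).
#' @return List of class `multinomial_fit`: per-category coefficient tables
#'   (estimate, SE, odds ratio), random-intercept variances, convergence
#'   diagnostics, and the record/individual/household counts.
#' @export
fit_multinomial_multilevel <- function(data, covariates,
                                       random_effects = TRUE,
                                       categories = NULL,
                                       individual = "person_id",
                                       household = "unique_household_id",
                                       nAGQ = 1L) {
  stopifnot(is.factor(data$outcome))
  base <- levels(data$outcome)[1]
  obs <- levels(droplevels(data$outcome))
  categories <- categories %||% setdiff(obs, base)
  if (!length(categories)) data_error("no non-baseline outcome observed")
  rhs <- paste(covariates, collapse = " + ")
  fits <- list()
  for (k in categories) {
    sub <- data[data$outcome %in% c(base, k), , drop = FALSE]
    sub$.y <- as.numeric(sub$outcome == k)
    if (length(unique(sub$.y)) < 2)
      data_error(sprintf("outcome category %s unobserved in subset", k))
    if (random_effects) {
      f <- stats::as.formula(sprintf(
        ".y ~ %s + (1 | %s) + (1 | %s)", rhs, individual, household))
      m <- lme4::glmer(f, data = sub, family = stats::binomial(),
                       nAGQ = nAGQ,
                       control = lme4::glmerControl(
                         calc.derivs = FALSE,
                         check.conv.singular = "ignore"))
      co <- summary(m)$coefficients
      vc <- lme4::VarCorr(m)
      fits[[k]] <- list(
        coefficients = data.frame(
          term = rownames(co), estimate = co[, 1], se = co[, 2],
          odds_ratio = exp(co[, 1]), z = co[, 3],
          row.names = NULL, stringsAsFactors = FALSE),
        var_individual = as.numeric(vc[[individual]]),
        var_household = as.numeric(vc[[household]]),
        converged = length(m@optinfo$conv$lme4$messages) == 0,
        logLik = as.numeric(stats::logLik(m)),
        n = nrow(sub))
    } else {
      f <- stats::as.formula(paste(".y ~", rhs))
      m <- stats::glm(f, data = sub, family = stats::binomial())
      co <- summary(m)$coefficients
      fits[[k]] <- list(
        coefficients = data.frame(
          term = rownames(co), estimate = co[, 1], se = co[, 2],
          odds_ratio = exp(co[, 1]), z = co[, 3],
          row.names = NULL, stringsAsFactors = FALSE),
        var_individual = 0, var_household = 0,
        converged = m$converged,
        logLik = as.numeric(stats::logLik(m)),
        n = nrow(sub))
    }
    # quasi-separated covariates show up as runaway coefficients
    big <- abs(fits[[k]]$coefficients$estimate) > 15
    fits[[k]]$separation_flagged <- fits[[k]]$coefficients$term[big]
    if (any(big))
      warning(sprintf("possible separation in category %s: %s", k,
                      paste(fits[[k]]$coefficients$term[big],
                            collapse = ", ")))
  }
  structure(list(
    baseline = base, categories = categories, fits = fits,
    estimator = if (random_effects)
      "per-category binary logit with crossed Gaussian random intercepts (Laplace)"
    else "per-category binary logit (no random effects)",
    n_records = nrow(data),
    n_individuals = length(unique(data[[individual]])),
    n_households = length(unique(data[[household]]))),
    class = "multinomial_fit")
}

#' Fitted category probabilities from fixed effects
#'
#' Softmax over the per-category linear predictors with the baseline pinned
#' at zero (random effects set to their zero mean); rows sum to one.
#'
#' @param fit A `multinomial_fit`.
#' @param X Model matrix whose columns match the fitted coefficient terms.
#' @return Matrix of probabilities, one column per outcome level.
#' @export
predict_category_probs <- function(fit, X) {
  eta <- sapply(fit$categories, function(k) {
    co <- fit$fits[[k]]$coefficients
    drop(X[, co$term, drop = FALSE] %*% co$estimate)
  })
  if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1)
  denom <- 1 + rowSums(exp(eta))
  p <- cbind(1 / denom, exp(eta) / denom)
  colnames(p) <- c(fit$baseline, fit$categories)
  p
}

#' Simulate outcomes from the multilevel multinomial model
#'
#' Draws Gaussian random intercepts per individual and household for each
#' non-baseline category and samples outcome categories from the implied
#' multinomial probabilities.
#'
#' @param X Model matrix (n rows).
#' @param beta Named list: per non-baseline category, a coefficient vector
#'   matching `colnames(X)`.
#' @param var_individual,var_household Random-intercept variances (scalar,
#'   shared across categories, or named vectors per category).
#' @param individual,household Cluster label vectors of length n.
#' @param seed Integer seed.
#' @return Factor of outcomes with baseline level `"none"`.
#' @export
simulate_from_model <- function(X, beta, var_individual, var_household,
                                individual, household, seed) {
  cats <- names(beta)
  n <- nrow(X)
  vi <- rep_len(unlist(var_individual), length(cats))
  vh <- rep_len(unlist(var_household), length(cats))
  with_local_seed(seed, {
    eta <- matrix(0, n, length(cats))
    for (j in seq_along(cats)) {
      u <- stats::rnorm(length(unique(household)), 0, sqrt(vh[j]))
      names(u) <- unique(household)
      v <- stats::rnorm(length(unique(individual)), 0, sqrt(vi[j]))
      names(v) <- unique(individual)
      eta[, j] <- drop(X %*% beta[[cats[j]]]) + u[household] + v[individual]
    }
    denom <- 1 + rowSums(exp(eta))
    p <- cbind(1 / denom, exp(eta) / denom)
    draw <- apply(p, 1, function(pr) sample.int(length(pr), 1, prob = pr))
    factor(c("none", cats)[draw], levels = c("none", cats))
  })
}
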