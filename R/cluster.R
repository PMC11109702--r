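# Cluster-robust variances. Surveillance person-quarters are correlated
# within unique household IDs and within unique individual IDs, and the two
# clusterings are crossed (people change households). Two-way variances use
# the Cameron-Gelbach-Miller combination
#   V = V(household) + V(individual) - V(household x individual),
# where each term is a one-way cluster-robust sandwich.

# one-way cluster-robust standard error of a mean
cluster_se_mean <- function(x, cluster) {
  n <- length(x)
  e <- x - mean(x)
  s <- rowsum(e, cluster)
  sqrt(sum(s^2)) / n
}

#' Two-way cluster-robust standard error of a mean or proportion
#'
#' @param x Numeric (or 0/1) observations.
#' @param cluster_a,cluster_b The two crossed cluster labels (e.g. unique
#'   household id and unique individual id).
#' @return Standard error of `mean(x)`.
#' @export
cluster2_se_mean <- function(x, cluster_a, cluster_b) {
  n <- length(x)
  e <- x - mean(x)
  term <- function(cl) sum(rowsum(e, cl)^2)
  v <- (term(cluster_a) + term(cluster_b) -
          term(paste(cluster_a, cluster_b))) / n^2
  sqrt(max(v, 0))
}

#' Proportion with a two-way cluster-robust confidence interval
#'
#' Normal-approximation interval on the percent scale, truncated to
#' `[0, 100]`.
#'
#' @param y Logical or 0/1 vector.
#' @param cluster_a,cluster_b Crossed cluster labels.
#' @param level Confidence level.
#' @return List with `percent`, `se_percent`, `ci` (length 2), `n`.
#' @export
clustered_proportion <- function(y, cluster_a, cluster_b, level = 0.95) {
  y <- as.numeric(y)
  p <- mean(y) * 100
  se <- cluster2_se_mean(y, cluster_a, cluster_b) * 100
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(percent = p, se_percent = se,
       ci = c(max(0, p - z * se), min(100, p + z * se)), n = length(y))
}

# two-way clustered sandwich vcov for an OLS fit y ~ X (X includes intercept)
lm_cluster2_vcov <- function(X, e, cluster_a, cluster_b) {
  bread <- solve(crossprod(X))
  meat <- function(cl) {
    s <- rowsum(X * e, cl)     # cluster-summed score contributions
    crossprod(s)
  }
  m <- meat(cluster_a) + meat(cluster_b) - meat(paste(cluster_a, cluster_b))
  bread %*% m %*% bread
}

#' Wald comparison of a proportion between the sexes
#'
#' Two-sided Wald test of equal proportions via a linear probability model
#' with two-way cluster-robust variance (household and individual).
#'
#' @param y Logical or 0/1 outcome.
#' @param sex Character vector (`"female"`/`"male"`).
#' @param cluster_a,cluster_b Crossed cluster labels.
#' @return List with the female and male percents, `diff` (female minus
#'   male, percent points), `se_diff`, `statistic` (z), `p_value`; or
#'   `degenerate = TRUE` with no p-value when a sex is absent.
#' @export
compare_proportions_by_sex <- function(y, sex, cluster_a, cluster_b) {
  y <- as.numeric(y)
  if (length(unique(sex)) < 2) {
    return(list(degenerate = TRUE, p_value = NA_real_,
                statistic = NA_real_))
  }
  d <- as.numeric(sex == "male")
  X <- cbind(1, d)
  b <- solve(crossprod(X), crossprod(X, y))
  e <- as.vector(y - X %*% b)
  V <- lm_cluster2_vcov(X, e, cluster_a, cluster_b)
  se <- sqrt(max(V[2, 2], 0))
  z <- if (se > 0) -b[2] / se else 0   # female minus male
  list(degenerate = FALSE,
       percent_female = 100 * b[1],
       percent_male = 100 * (b[1] + b[2]),
       diff = -100 * b[2], se_diff = 100 * se,
       statistic = z,
       p_value = if (se > 0) 2 * stats::pnorm(-abs(z)) else 1)
}
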