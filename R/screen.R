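#' Disorders eligible for the acceleration screen
#'
#' A disorder enters the screen only with at least `min_n` samples, of which
#' at least `min_adults` have age >= `adult_age` years. Exclusions are
#' reported via message.
#'
#' @param sheet Sample sheet.
#' @param min_n Minimum number of samples per disorder (default 5).
#' @param min_adults Minimum number of adult samples (default 2).
#' @param adult_age Adult age threshold in years (default 20).
#' @return Character vector of eligible disorder labels.
#' @export
filter_disorders <- function(sheet, min_n = 5, min_adults = 2, adult_age = 20) {
  sheet <- validate_sample_sheet(sheet)
  cases <- sheet[sheet$group != "control", , drop = FALSE]
  eligible <- character(0)
  for (g in unique(cases$group)) {
    ages <- cases$age[cases$group == g]
    n <- length(ages)
    n_adult <- sum(ages >= adult_age)
    if (n >= min_n && n_adult >= min_adults) {
      eligible <- c(eligible, g)
    } else {
      message(sprintf("excluding '%s': n=%d (need >= %d), adults=%d (need >= %d)",
                      g, n, min_n, n_adult, min_adults))
    }
  }
  eligible
}

# Two-sided rank-sum test. Exact enumeration when the smaller group has
# <= exact_max samples and there are no ties; otherwise the normal
# approximation with continuity correction.
rank_sum_test <- function(x, y, exact_max = 10) {
  use_exact <- min(length(x), length(y)) <= exact_max &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(p = wt$p.value, statistic = unname(wt$statistic), exact = use_exact)
}

#' Screen disorders for acceleration
#'
#' For each eligible disorder, the case acceleration distribution is compared
#' with the control distribution by a two-sided Wilcoxon rank-sum test (exact
#' enumeration when the smaller group has at most 10 samples and no ties;
#' normal approximation with continuity correction otherwise). P-values are
#' Bonferroni-adjusted across the disorders tested in this run and flagged at
#' level `alpha`.
#'
#' @param model A fitted [eaa_model()] / [control_model()], or the data.frame
#'   returned by [acceleration()].
#' @param alpha Significance level after Bonferroni correction (default 0.01).
#' @param min_n,min_adults,adult_age Eligibility rules (see
#'   [filter_disorders()]).
#' @return data.frame of class `eaa_screen`: one row per disorder with `n`,
#'   `median_acceleration`, `p`, `p_adjusted`, `significant`, `exact`.
#' @export
screen_disorders <- function(model, alpha = 0.01, min_n = 5, min_adults = 2,
                             adult_age = 20) {
  a <- if (inherits(model, "control_model")) acceleration(model) else model
  sheet_like <- data.frame(sample_id = a$sample_id, age = a$age,
                           sex = "female", batch = "0", group = a$group,
                           stringsAsFactors = FALSE)
  eligible <- filter_disorders(sheet_like, min_n, min_adults, adult_age)
  if (length(eligible) == 0) {
    out <- data.frame(group = character(0), n = integer(0),
                      median_acceleration = numeric(0), p = numeric(0),
                      p_adjusted = numeric(0), significant = logical(0),
                      exact = logical(0))
    class(out) <- c("eaa_screen", class(out))
    return(out)
  }
  ctrl <- a$acceleration[a$group == "control"]
  if (length(ctrl) == 0) stop("no control accelerations available")
  rows <- lapply(eligible, function(g) {
    v <- a$acceleration[a$group == g]
    if (length(v) == 0) stop("disorder with no samples after joining: ", g)
    t <- rank_sum_test(v, ctrl)
    data.frame(group = g, n = length(v),
               median_acceleration = stats::median(v),
               p = t$p, exact = t$exact, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_adjusted < alpha
  out <- out[, c("group", "n", "median_acceleration", "p", "p_adjusted",
                 "significant", "exact")]
  attr(out, "alpha") <- alpha
  class(out) <- c("eaa_screen", class(out))
  out
}

#' @export
print.eaa_screen <- function(x, ...) {
  cat(sprintf("Acceleration screen: %d disorder(s), Bonferroni alpha = %g\n",
              nrow(x), attr(x, "alpha")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Regression of acceleration on age within a group
#'
#' Ordinary least-squares slope of acceleration on chronological age for one
#' group, with the two-sided t-test p-value for the slope. `exclude` supports
#' leave-one-out sensitivity checks (e.g. dropping the oldest patient).
#'
#' @param model A fitted `control_model`, or an [acceleration()] data.frame.
#' @param group Group label to analyze.
#' @param exclude Optional sample ids to drop.
#' @return list with `slope` (years/year for EAA), `p`, `n`, `fit`.
#' @export
eaa_age_slope <- function(model, group, exclude = NULL) {
  a <- if (inherits(model, "control_model")) acceleration(model) else model
  a <- a[a$group == group & !(a$sample_id %in% exclude), , drop = FALSE]
  if (nrow(a) < 3) stop("need >= 3 samples in group")
  if (stats::sd(a$age) == 0) stop("constant age in group")
  fit <- stats::lm(acceleration ~ age, data = a)
  s <- summary(fit)$coefficients
  list(slope = unname(s["age", "Estimate"]), p = unname(s["age", "Pr(>|t|)"]),
       n = nrow(a), fit = fit)
}
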