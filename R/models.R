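# Diel activity modelling and behaviour-level VeDBA comparison.
#
# Diel cycles are modelled with penalised cyclic cubic splines over hour of
# day plus random intercepts for individuals (a GAMM fitted by REML);
# cyclicity is enforced by the spline basis, so predictions at hour 0 and
# hour 24 coincide by construction.

#' Fit a cyclic diel activity curve
#'
#' Models a bin-level response (VeDBA_max by default) as a cyclic cubic
#' spline of hour of day with random intercepts for individuals. With a
#' single individual the random intercept is dropped and the fit flagged.
#'
#' @param bins behaviour-bin tibble
#' @param response name of the response column
#' @param k basis dimension of the cyclic smooth
#' @return object of class `cyclic_fit`: the mgcv fit, hourly predictions
#'   (population level, random effects excluded) with SE and a +/- 1
#'   residual-SD ribbon, smooth edf, and flags
#' @export
fit_cyclic_activity <- function(bins, response = "vedba_max_mean", k = 10) {
  d <- data.frame(
    y = bins[[response]],
    hour = hour_of_day(bins$start_s),
    individual = factor(bins$individual)
  )
  d <- d[stats::complete.cases(d), ]
  single <- nlevels(droplevels(d$individual)) < 2
  knots <- list(hour = c(0, 24))
  # a constant response has no diel signal (and no REML solution): return
  # the flat curve directly
  if (sd(d$y) < 1e-10) {
    grid_h <- seq(0, 24, by = 0.25)
    return(structure(
      list(
        fit = NULL,
        predictions = tibble::tibble(
          hour = grid_h, mean = mean(d$y), se = 0,
          lower = mean(d$y), upper = mean(d$y)
        ),
        resid_sd = 0, smooth_edf = 1, r_sq = 0,
        single_individual = single, response = response
      ),
      class = "cyclic_fit"
    ))
  }
  fit <- if (single) {
    mgcv::gam(y ~ s(hour, bs = "cc", k = k), data = d, knots = knots,
              method = "REML")
  } else {
    mgcv::gam(y ~ s(hour, bs = "cc", k = k) + s(individual, bs = "re"),
              data = d, knots = knots, method = "REML")
  }
  grid <- data.frame(hour = seq(0, 24, by = 0.25),
                     individual = d$individual[1])
  pr <- predict(fit, newdata = grid, se.fit = TRUE,
                exclude = if (!single) "s(individual)" else NULL,
                newdata.guaranteed = TRUE)
  resid_sd <- sd(stats::residuals(fit))
  preds <- tibble::tibble(
    hour = grid$hour,
    mean = as.numeric(pr$fit),
    se = as.numeric(pr$se.fit),
    lower = as.numeric(pr$fit) - resid_sd,
    upper = as.numeric(pr$fit) + resid_sd
  )
  structure(
    list(
      fit = fit,
      predictions = preds,
      resid_sd = resid_sd,
      smooth_edf = summary(fit)$s.table[1, "edf"],
      r_sq = summary(fit)$r.sq,
      single_individual = single,
      response = response
    ),
    class = "cyclic_fit"
  )
}

#' @export
print.cyclic_fit <- function(x, ...) {
  cat(sprintf(
    "<cyclic_fit> %s ~ s(hour, cc)%s: smooth edf %.2f, adj-R2 %.3f\n",
    x$response,
    if (x$single_individual) "" else " + (1|individual)",
    x$smooth_edf, x$r_sq
  ))
  invisible(x)
}

#' Hour at which a cyclic fit predicts its maximum
#' @param fit a `cyclic_fit`
#' @return hour in [0, 24)
#' @export
peak_of_fit <- function(fit) {
  p <- fit$predictions
  p$hour[which.max(p$mean)] %% 24
}

#' Fit the diel curve of the Walking proportion
#'
#' The response is the per (individual, day, hour) count of Walking bins out
#' of labelled bins, modelled as a binomial GAMM (logit link) with a cyclic
#' smooth of hour of day and random intercepts for individuals. Returns
#' predictions with 95% CI ribbons on the proportion scale.
#'
#' @param bins behaviour-bin tibble (regrouped labels)
#' @param category behaviour category to model
#' @param k basis dimension of the cyclic smooth
#' @return a `cyclic_fit` whose predictions are proportions
#' @export
fit_walking_curve <- function(bins, category = "Walking", k = 10) {
  b <- bins[!is.na(bins$label), ]
  if (!category %in% b$label) {
    stop("no ", category, " bins present; cannot fit diel curve")
  }
  b$hour <- floor(hour_of_day(b$start_s))
  b$day <- b$start_s %/% DAY_S
  d <- dplyr::summarise(
    dplyr::group_by(b, .data$individual, .data$day, .data$hour),
    n_cat = sum(.data$label == category),
    n_tot = dplyr::n(),
    .groups = "drop"
  )
  d$individual <- factor(d$individual)
  single <- nlevels(droplevels(d$individual)) < 2
  knots <- list(hour = c(0, 24))
  form <- if (single) {
    cbind(n_cat, n_tot - n_cat) ~ s(hour, bs = "cc", k = k)
  } else {
    cbind(n_cat, n_tot - n_cat) ~ s(hour, bs = "cc", k = k) +
      s(individual, bs = "re")
  }
  fit <- mgcv::gam(form, family = stats::binomial(), data = d, knots = knots,
                   method = "REML")
  grid <- data.frame(hour = seq(0, 24, by = 0.25),
                     individual = d$individual[1])
  pr <- predict(fit, newdata = grid, se.fit = TRUE, type = "link",
                exclude = if (!single) "s(individual)" else NULL,
                newdata.guaranteed = TRUE)
  inv <- stats::binomial()$linkinv
  preds <- tibble::tibble(
    hour = grid$hour,
    mean = inv(as.numeric(pr$fit)),
    se = as.numeric(pr$se.fit),
    lower = inv(as.numeric(pr$fit) - 1.96 * as.numeric(pr$se.fit)),
    upper = inv(as.numeric(pr$fit) + 1.96 * as.numeric(pr$se.fit))
  )
  structure(
    list(fit = fit, predictions = preds,
         resid_sd = sd(stats::residuals(fit)),
         smooth_edf = summary(fit)$s.table[1, "edf"],
         r_sq = summary(fit)$r.sq,
         single_individual = single,
         response = paste(category, "proportion")),
    class = "cyclic_fit"
  )
}

#' Compare VeDBA across behaviour categories with rank tests
#'
#' Log-transforms the response (to address right skew), runs a
#' Kruskal-Wallis omnibus test across categories, then all pairwise
#' two-sided Wilcoxon rank-sum tests with Benjamini-Hochberg correction.
#'
#' @param bins behaviour-bin tibble
#' @param response response column (default VeDBA_max bin means)
#' @return list: `omnibus` (statistic, df, p.value), `pairwise` tibble
#'   (group1, group2, statistic, p, p_adj), `summary` per-category median
#'   and IQR of the untransformed response
#' @export
compare_vedba <- function(bins, response = "vedba_max_mean") {
  b <- bins[!is.na(bins$label) & !is.na(bins[[response]]) &
              bins[[response]] > 0, ]
  groups <- split(log(b[[response]]), b$label)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(groups) < 2) stop("need >= 2 categories with >= 2 observations")
  kw <- stats::kruskal.test(groups)
  pairs <- utils::combn(names(groups), 2)
  pw <- lapply(seq_len(ncol(pairs)), function(j) {
    wt <- stats::wilcox.test(groups[[pairs[1, j]]], groups[[pairs[2, j]]],
                             exact = FALSE, correct = TRUE)
    tibble::tibble(group1 = pairs[1, j], group2 = pairs[2, j],
                   statistic = unname(wt$statistic), p = wt$p.value)
  })
  pw <- dplyr::bind_rows(pw)
  pw$p_adj <- stats::p.adjust(pw$p, method = "BH")
  summ <- dplyr::summarise(
    dplyr::group_by(b, .data$label),
    median = median(.data[[response]]),
    q25 = quantile(.data[[response]], 0.25),
    q75 = quantile(.data[[response]], 0.75),
    n = dplyr::n(),
    .groups = "drop"
  )
  list(
    omnibus = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p.value = kw$p.value),
    pairwise = pw,
    summary = summ
  )
}

#' Test sex and habitat effects on daily Walking time
#'
#' Linear mixed-effects model of daily Walking minutes with fixed effects
#' for sex and habitat (patch vs linear) and a random intercept per
#' individual; F statistics use Satterthwaite degrees of freedom.
#'
#' @param budget output of [daily_budget()] joined with per-individual sex
#'   and habitat columns
#' @param category category whose daily minutes are modelled
#' @return list: `anova` tibble (term, F, df1, df2, p), the fitted model as
#'   `fit`
#' @export
walking_covariate_test <- function(budget, category = "Walking") {
  d <- budget[budget$category == category, ]
  stopifnot(all(c("sex", "habitat") %in% names(d)))
  if (sd(d$minutes_1440) == 0) {
    stop("constant response; covariate test is degenerate")
  }
  fit <- lmerTest::lmer(
    minutes_1440 ~ sex + habitat + (1 | individual), data = d
  )
  an <- stats::anova(fit, type = 3)
  list(
    anova = tibble::tibble(
      term = rownames(an),
      F = an[, "F value"],
      df1 = an[, "NumDF"],
      df2 = an[, "DenDF"],
      p = an[, "Pr(>F)"]
    ),
    fit = fit
  )
}
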