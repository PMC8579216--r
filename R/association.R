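#' Daily behavioral features and their sensor domains
#'
#' The eleven daily features analyzed as participant-level means: four
#' mobility features (GPS), four social-interaction features (call log), two
#' phone-use features (screen events) and one sleep proxy (nighttime ambient
#' light). The domain mapping drives domain-specific extreme-outlier
#' exclusion: a participant flagged on a GPS feature is excluded from GPS
#' analyses only.
#'
#' @format Named character vector: feature name -> domain
#'   (`gps`, `calls`, `screen`, `light`).
#' @export
feature_domains <- c(
  time_sedentary_h = "gps", time_moving_h = "gps", distance_km = "gps",
  entropy_norm = "gps",
  call_duration_min = "calls", n_incoming = "calls", n_outgoing = "calls",
  n_connected = "calls",
  screen_time_min = "screen", n_unlocks = "screen",
  mean_night_lux = "light")

#' Participant-level feature means
#'
#' Averages each daily feature over a participant's non-missing days
#' (unweighted), recording per-feature day counts. Participants with no
#' non-missing day for a feature get `NA` there and drop out of analyses
#' using that feature pairwise.
#'
#' @param daily Tibble of daily feature rows with `participant_id`, `date`,
#'   and feature columns.
#' @param features Feature columns to average (default: those of
#'   [feature_domains] present in `daily`).
#' @return Tibble with one row per participant: feature means plus
#'   `n_days_<feature>` counts.
#' @export
participant_averages <- function(daily, features = NULL) {
  if (is.null(features)) {
    features <- intersect(names(feature_domains), names(daily))
  }
  daily |>
    dplyr::group_by(participant_id = .data$participant_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(features),
                    list(mean = ~ if (all(is.na(.x))) NA_real_ else
                      mean(.x, na.rm = TRUE),
                      days = ~ sum(!is.na(.x))),
                    .names = "{.col}__{.fn}"),
      .groups = "drop") |>
    dplyr::rename_with(~ sub("__mean$", "", .x)) |>
    dplyr::rename_with(~ sub("^(.*)__days$", "n_days_\\1", .x))
}

#' Flag extreme outliers by Tukey far-out fences
#'
#' Flags participants whose feature value lies outside
#' `[Q1 - k * IQR, Q3 + k * IQR]` with `k = 3` (Tukey's "far out" fences).
#' The fences are affine-equivariant, so flagging is invariant to rescaling
#' a feature's units. With a domain map, a participant flagged on any feature
#' of a domain is excluded from that domain's analyses only.
#'
#' @param data Tibble with `participant_id` and feature columns.
#' @param features Feature columns to screen (default: [feature_domains]
#'   entries present in `data`).
#' @param fence_k IQR multiplier (default 3).
#' @return Tibble of flags: `participant_id`, `feature`, `domain`, `value`,
#'   `lower`, `upper` — one row per flagged participant x feature.
#' @export
flag_extreme_outliers <- function(data, features = NULL, fence_k = 3) {
  if (is.null(features)) {
    features <- intersect(names(feature_domains), names(data))
  }
  purrr::map_dfr(features, function(f) {
    v <- data[[f]]
    ok <- !is.na(v)
    if (sum(ok) < 4) return(NULL)
    q <- quantile(v[ok], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    lower <- q[1] - fence_k * iqr
    upper <- q[2] + fence_k * iqr
    out <- ok & (v < lower | v > upper)
    if (!any(out)) return(NULL)
    tibble::tibble(participant_id = data$participant_id[out], feature = f,
                   domain = unname(feature_domains[f]) %||% NA_character_,
                   value = v[out], lower = lower, upper = upper)
  })
}

# expand a covariate data frame to a full-rank design with intercept;
# character/factor columns become indicator columns, constants are dropped
covariate_design <- function(covariates) {
  if (is.null(covariates) || ncol(covariates) == 0) {
    return(NULL)
  }
  df <- as.data.frame(covariates)
  df[] <- lapply(df, function(x) if (is.character(x) || is.logical(x)) factor(x) else x)
  # drop single-level factors / zero-variance columns (residualization no-ops)
  keep <- vapply(df, function(x) {
    if (is.factor(x)) nlevels(droplevels(x)) > 1 else sd(x) > 0
  }, logical(1))
  df <- df[, keep, drop = FALSE]
  if (ncol(df) == 0) return(NULL)
  df[] <- lapply(df, function(x) if (is.factor(x)) droplevels(x) else x)
  stats::model.matrix(~ ., data = df)
}

#' Covariate-adjusted Spearman correlation
#'
#' Partial Spearman correlation by rank residualization: both variables are
#' rank-transformed (average ranks for ties), each rank vector is
#' residualized on the covariate design (categorical covariates expanded to
#' indicators), and the Pearson correlation of the residuals is taken. The
#' p-value uses the t reference distribution with
#' `df = n - 2 - (covariate columns)`. With no (or constant) covariates this
#' reduces exactly to the plain Spearman coefficient, and it is invariant to
#' strictly monotone transforms of either variable.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame of covariates (numeric, character,
#'   factor or logical columns).
#' @return An `adj_spearman` object: list with `r`, `p`, `n`, `df`,
#'   `n_covariate_cols`, and the unadjusted `r_unadj`, `p_unadj`. Supports
#'   [tidy()] and [glance()].
#' @export
adjusted_spearman <- function(x, y, covariates = NULL) {
  cc <- complete.cases(x, y, if (!is.null(covariates)) covariates)
  x <- x[cc]; y <- y[cc]
  if (!is.null(covariates)) covariates <- covariates[cc, , drop = FALSE]
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) {
    stop_bad_arg("adjusted_spearman: zero variance in x or y")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  X <- covariate_design(covariates)
  k <- 0L
  if (!is.null(X)) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
      stop_bad_arg("singular covariate design; collinear column(s): %s",
                   paste(bad, collapse = ", "))
    }
    rx <- qr.resid(qrX, rx)
    ry <- qr.resid(qrX, ry)
    k <- ncol(X) - 1L
  }
  if (n < k + 3) stop_bad_arg("too few complete cases (%d) for %d covariate columns", n, k)
  r <- cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tval), df)
  un <- cor(rank(x), rank(y))
  t_un <- un * sqrt((n - 2) / (1 - un^2))
  structure(list(r = r, p = p, n = n, df = df, n_covariate_cols = k,
                 statistic = tval, r_unadj = un,
                 p_unadj = 2 * pt(-abs(t_un), n - 2)),
            class = "adj_spearman")
}

#' @export
print.adj_spearman <- function(x, ...) {
  cat(sprintf("Adjusted Spearman: r = %.3f, p = %.4g (n = %d, %d covariate cols; unadjusted r = %.3f)\n",
              x$r, x$p, x$n, x$n_covariate_cols, x$r_unadj))
  invisible(x)
}

#' Feature-outcome association table
#'
#' Runs the covariate-adjusted Spearman correlation of every behavioral
#' feature mean against each symptom outcome, with domain-specific extreme
#' outlier exclusion, pairwise-complete cases and Benjamini-Hochberg q-values
#' alongside the raw p-values. When `adjust_comorbidity` is `TRUE` the other
#' instruments' totals join the covariate set for each outcome (so anxiety
#' associations are adjusted for comorbid depression and ADHD symptoms, and
#' vice versa).
#'
#' @param data Tibble with one row per participant: feature means, outcome
#'   totals, and covariate columns.
#' @param outcomes Outcome columns (default `scared_total`, `cesdc_total`).
#' @param covariates Covariate column names (default age, sex, maternal
#'   education, OS, assessment month).
#' @param features Feature columns (default: [feature_domains] entries
#'   present).
#' @param adjust_comorbidity Add the other instruments' totals to the
#'   covariates of each outcome (default `TRUE`, matching the headline
#'   analysis).
#' @param comorbidity_map Named list: outcome -> comorbidity covariate
#'   columns.
#' @param outlier_fence_k IQR multiplier for [flag_extreme_outliers()]
#'   (default 3); `NULL` disables exclusion.
#' @return Tibble of class `digiphen_associations`: `feature`, `domain`,
#'   `outcome`, `r`, `p`, `q`, `n`, `r_unadj`, `p_unadj`.
#' @export
associate_features <- function(data,
                               outcomes = c("scared_total", "cesdc_total"),
                               covariates = c("age", "sex", "maternal_education",
                                              "os", "assessment_month"),
                               features = NULL,
                               adjust_comorbidity = TRUE,
                               comorbidity_map = list(
                                 scared_total = c("cesdc_total", "asrs_total"),
                                 cesdc_total = c("scared_total", "asrs_total")),
                               outlier_fence_k = 3) {
  if (is.null(features)) {
    features <- intersect(names(feature_domains), names(data))
  }
  excluded <- list()
  if (!is.null(outlier_fence_k)) {
    flags <- flag_extreme_outliers(data, features, fence_k = outlier_fence_k)
    if (nrow(flags)) {
      excluded <- split(flags$participant_id, flags$domain) |> lapply(unique)
    }
  }
  res <- purrr::map_dfr(features, function(f) {
    dom <- unname(feature_domains[f]) %||% NA_character_
    rows <- data
    if (!is.na(dom) && !is.null(excluded[[dom]])) {
      rows <- rows[!rows$participant_id %in% excluded[[dom]], , drop = FALSE]
    }
    purrr::map_dfr(outcomes, function(oc) {
      covs <- covariates
      if (adjust_comorbidity && !is.null(comorbidity_map[[oc]])) {
        covs <- c(covs, intersect(comorbidity_map[[oc]], names(rows)))
      }
      fit <- adjusted_spearman(rows[[f]], rows[[oc]],
                               rows[, covs, drop = FALSE])
      tibble::tibble(feature = f, domain = dom, outcome = oc, r = fit$r,
                     p = fit$p, n = fit$n, r_unadj = fit$r_unadj,
                     p_unadj = fit$p_unadj)
    })
  })
  res <- res |>
    dplyr::group_by(.data$outcome) |>
    dplyr::mutate(q = stats::p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::select("feature", "domain", "outcome", "r", "p", "q", "n",
                  "r_unadj", "p_unadj")
  attr(res, "excluded") <- excluded
  class(res) <- c("digiphen_associations", class(res))
  res
}

#' Nested linear-model comparison (F test)
#'
#' Fits a base ordinary-least-squares model of an outcome on covariates and a
#' full model adding the sensor-feature predictors, on listwise-complete
#' cases, and compares them with the RSS-reduction F statistic
#' `F = ((RSS0 - RSS1)/df1) / (RSS1/df2)` with `df1` the number of added
#' columns and `df2` the residual degrees of freedom of the full model.
#'
#' @param data Tibble with outcome, covariate and feature columns.
#' @param outcome Outcome column name.
#' @param base Covariate column names for the base model.
#' @param added Feature column names added in the full model.
#' @return A `nested_f` object: `F`, `df1`, `df2`, `p`, `n`, `rss0`, `rss1`,
#'   `r2_base`, `r2_full`, plus the fitted values of both models. Supports
#'   [tidy()] and [glance()].
#' @export
nested_model_test <- function(data, outcome, base, added) {
  cols <- c(outcome, base, added)
  cc <- complete.cases(data[, cols, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  y <- d[[outcome]]
  X0 <- covariate_design(d[, base, drop = FALSE])
  if (is.null(X0)) X0 <- matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
  Xadd <- covariate_design(d[, added, drop = FALSE])
  if (is.null(Xadd)) stop_bad_arg("no usable added predictors")
  Xadd <- Xadd[, -1, drop = FALSE]  # intercept already in the base design
  X1 <- cbind(X0, Xadd)
  if (qr(X1)$rank < ncol(X1)) {
    stop_bad_arg("rank-deficient full design: added predictors collinear with the base model")
  }
  n <- length(y)
  if (n <= ncol(X1)) stop_bad_arg("complete cases (%d) must exceed full-model parameters (%d)", n, ncol(X1))
  fit0 <- lm.fit(X0, y)
  fit1 <- lm.fit(X1, y)
  rss0 <- sum(fit0$residuals^2)
  rss1 <- sum(fit1$residuals^2)
  tss <- sum((y - mean(y))^2)
  df1 <- ncol(X1) - ncol(X0)
  df2 <- n - ncol(X1)
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  structure(list(outcome = outcome, F = Fstat, df1 = df1, df2 = df2,
                 p = pf(Fstat, df1, df2, lower.tail = FALSE), n = n,
                 rss0 = rss0, rss1 = rss1,
                 r2_base = 1 - rss0 / tss, r2_full = 1 - rss1 / tss,
                 fitted_base = unname(fit0$fitted.values),
                 fitted_full = unname(fit1$fitted.values),
                 participant_id = d[["participant_id"]]),
            class = "nested_f")
}

#' @export
print.nested_f <- function(x, ...) {
  cat(sprintf("Nested model comparison for %s: F(%d, %d) = %.3f, p = %.4g (n = %d)\n",
              x$outcome, x$df1, x$df2, x$F, x$p, x$n))
  cat(sprintf("  R^2 base = %.3f, full = %.3f\n", x$r2_base, x$r2_full))
  invisible(x)
}

#' Discriminant validity of sensor-predicted symptom scores
#'
#' Predicts each internalizing outcome from the full linear model (covariates
#' plus all sensor features), then correlates the predicted score with the
#' *other* observed instruments (Spearman). Discriminant validity holds when
#' a predicted internalizing score tracks the other internalizing instrument
#' but not the externalizing comparator (ASRS).
#'
#' @param data Tibble with outcomes, covariates and features per participant.
#' @param outcomes Outcomes to predict (default SCARED and CES-DC totals).
#' @param compare_with Observed scores to correlate predictions against
#'   (default the two internalizing totals and ASRS).
#' @param base Covariate columns of the base model.
#' @param features Sensor-feature columns (default [feature_domains] entries
#'   present).
#' @return Tibble: `predicted_outcome`, `observed_score`, `r`, `p`, `n`.
#' @export
discriminant_validity <- function(data,
                                  outcomes = c("scared_total", "cesdc_total"),
                                  compare_with = c("scared_total", "cesdc_total",
                                                   "asrs_total"),
                                  base = c("age", "sex", "maternal_education",
                                           "os", "assessment_month"),
                                  features = NULL) {
  if (is.null(features)) {
    features <- intersect(names(feature_domains), names(data))
  }
  purrr::map_dfr(outcomes, function(oc) {
    fit <- nested_model_test(data, oc, base, features)
    pred <- tibble::tibble(participant_id = fit$participant_id,
                           .pred = fit$fitted_full)
    d <- dplyr::inner_join(data, pred, by = "participant_id")
    purrr::map_dfr(setdiff(compare_with, character(0)), function(sc) {
      cc <- complete.cases(d$.pred, d[[sc]])
      ct <- suppressWarnings(
        stats::cor.test(d$.pred[cc], d[[sc]][cc], method = "spearman",
                        exact = FALSE))
      tibble::tibble(predicted_outcome = oc, observed_score = sc,
                     r = unname(ct$estimate), p = ct$p.value, n = sum(cc))
    })
  })
}
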