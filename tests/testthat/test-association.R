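test_that("participant averages match a brute-force recomputation", {
  cfg <- small_config(n = 12)
  study <- simulate_study(cfg)
  daily <- purrr::map_dfr(study$bundles[1:10], extract_features)
  fm <- participant_averages(daily)
  # spreadsheet-style recompute: split by participant, plain colMeans
  for (id in unique(daily$participant_id)) {
    d <- daily[daily$participant_id == id, ]
    for (f in intersect(names(feature_domains), names(daily))) {
      expected <- mean(d[[f]], na.rm = TRUE)
      if (is.nan(expected)) expected <- NA_real_
      expect_equal(fm[[f]][fm$participant_id == id], expected, info = f)
    }
  }
  # explicit small cases
  two <- tibble::tibble(participant_id = "a", date = Sys.Date() + 0:1,
                        distance_km = c(2, 4))
  expect_equal(participant_averages(two, "distance_km")$distance_km, 3)
  same <- tibble::tibble(participant_id = "a", date = Sys.Date() + 0:13,
                         distance_km = rep(7, 14))
  avg <- participant_averages(same, "distance_km")
  expect_equal(avg$distance_km, 7)
  expect_equal(avg$n_days_distance_km, 14L)
})

test_that("Tukey far-out fences flag extreme outliers, invariant to scale", {
  d <- tibble::tibble(participant_id = sprintf("p%02d", 1:20),
                      distance_km = c(runif(19, 1, 5), 1000))
  fl <- flag_extreme_outliers(d, "distance_km")
  expect_equal(fl$participant_id, "p20")
  expect_equal(fl$domain, "gps")
  # all-equal values produce no flags
  expect_equal(nrow(flag_extreme_outliers(
    tibble::tibble(participant_id = letters[1:6], distance_km = rep(2, 6)),
    "distance_km")), 0L)
  # affine rescaling leaves flagging unchanged
  set.seed(11)
  for (rep in 1:10) {
    v <- c(rnorm(30), rnorm(2, 0, 20))
    d1 <- tibble::tibble(participant_id = sprintf("q%02d", 1:32),
                         screen_time_min = v)
    d2 <- dplyr::mutate(d1, screen_time_min = 3.7 * screen_time_min - 11)
    expect_equal(flag_extreme_outliers(d1, "screen_time_min")$participant_id,
                 flag_extreme_outliers(d2, "screen_time_min")$participant_id)
  }
})

test_that("adjusted Spearman reduces to plain Spearman and respects ranks", {
  set.seed(12)
  x <- rnorm(50)
  y <- exp(x) + 0  # strictly increasing transform of x
  fit <- adjusted_spearman(x, y)
  expect_equal(fit$r, 1)
  # constant covariates are a residualization no-op
  covs <- data.frame(z = rep(1, 50), w = rep("a", 50))
  y2 <- rnorm(50)
  plain <- cor(rank(x), rank(y2))
  expect_equal(adjusted_spearman(x, y2, covs)$r, plain)
  expect_equal(adjusted_spearman(x, y2)$r, plain)
  # invariance to strictly monotone maps of either margin
  covs2 <- data.frame(z = rnorm(50))
  base <- adjusted_spearman(x, y2, covs2)
  for (f in list(function(v) v^3, function(v) rank(v), exp)) {
    expect_equal(adjusted_spearman(f(x), y2, covs2)$r, base$r, tolerance = 1e-12)
    expect_equal(adjusted_spearman(x, f(y2), covs2)$r, base$r, tolerance = 1e-12)
  }
  expect_error(adjusted_spearman(rep(1, 50), y2), "zero variance")
  # collinear covariates are reported by name
  covs3 <- data.frame(z = rnorm(50))
  covs3$z2 <- 2 * covs3$z
  expect_error(adjusted_spearman(x, y2, covs3), "collinear")
})

test_that("adjusting for a shared covariate removes its induced correlation", {
  set.seed(13)
  n <- 2000
  z <- rnorm(n)
  x <- z + rnorm(n)
  y <- z + rnorm(n)
  un <- adjusted_spearman(x, y)
  ad <- adjusted_spearman(x, y, data.frame(z = z))
  expect_gt(un$r, 0.3)
  expect_lt(abs(ad$r), 0.05)
  # independent residualization oracle: explicit normal equations on ranks
  rx <- rank(x); ry <- rank(y)
  X <- cbind(1, z)
  bx <- solve(crossprod(X), crossprod(X, rx))
  by <- solve(crossprod(X), crossprod(X, ry))
  r_oracle <- cor(rx - X %*% bx, ry - X %*% by)
  expect_equal(ad$r, as.numeric(r_oracle), tolerance = 1e-10)
})

test_that("tidiers expose estimates in broom shape", {
  set.seed(14)
  fit <- adjusted_spearman(rnorm(40), rnorm(40), data.frame(z = rnorm(40)))
  td <- tidy(fit)
  expect_named(td, c("estimate", "statistic", "p.value", "parameter",
                     "estimate.unadjusted", "p.value.unadjusted"))
  expect_equal(glance(fit)$nobs, 40L)
  d <- tibble::tibble(y = rnorm(40), a = rnorm(40), b = rnorm(40),
                      participant_id = as.character(1:40))
  nf <- nested_model_test(d, "y", "a", "b")
  expect_named(tidy(nf), c("statistic", "df", "df.residual", "p.value"))
  expect_equal(glance(nf)$nobs, 40L)
})

test_that("nested F equals explicit normal-equations RSS computation", {
  set.seed(15)
  n <- 60
  d <- tibble::tibble(participant_id = as.character(1:n),
                      y = rnorm(n), a = rnorm(n), b = rnorm(n),
                      f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  fit <- nested_model_test(d, "y", c("a", "b"), c("f1", "f2", "f3"))
  # oracle: explicit normal equations, no shared code with the implementation
  X0 <- cbind(1, d$a, d$b)
  X1 <- cbind(X0, d$f1, d$f2, d$f3)
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% d$y)
    sum((d$y - X %*% beta)^2)
  }
  rss0 <- rss(X0); rss1 <- rss(X1)
  F_oracle <- ((rss0 - rss1) / 3) / (rss1 / (n - ncol(X1)))
  expect_equal(fit$F, F_oracle, tolerance = 1e-8)
  expect_equal(fit$df1, 3L)
  expect_equal(fit$df2, n - 6L)
  # second cross-check: stats::anova on lm fits
  a <- anova(lm(y ~ a + b, d), lm(y ~ a + b + f1 + f2 + f3, d))
  expect_equal(fit$F, a$F[2], tolerance = 1e-10)
  expect_equal(fit$p, a$`Pr(>F)`[2], tolerance = 1e-10)
  # degenerate: added predictors identical to base columns
  expect_error(nested_model_test(d, "y", c("a", "b"), "a"), "rank-deficient")
  # perfect fit: y exactly linear in an added predictor
  d2 <- dplyr::mutate(d, y = 2 * f1 + 1)
  fit2 <- nested_model_test(d2, "y", c("a", "b"), c("f1", "f2", "f3"))
  expect_lt(fit2$rss1, 1e-16)
  expect_lt(fit2$p, 1e-12)
})

test_that("discriminant validity separates planted from independent outcomes", {
  set.seed(16)
  n <- 500
  latent <- rnorm(n)
  d <- tibble::tibble(
    participant_id = as.character(1:n),
    age = runif(n, 10, 21), sex = sample(c("f", "m"), n, TRUE),
    f1 = latent + rnorm(n), f2 = latent + rnorm(n), f3 = rnorm(n),
    scared_total = 10 * latent + rnorm(n, sd = 5),
    cesdc_total = 8 * latent + rnorm(n, sd = 5),
    asrs_total = rnorm(n, 30, 10)) # independent of the sensor features
  dv <- discriminant_validity(d, base = c("age", "sex"),
                              features = c("f1", "f2", "f3"))
  own <- dv[dv$predicted_outcome == "scared_total" &
              dv$observed_score == "scared_total", ]
  other <- dv[dv$predicted_outcome == "scared_total" &
                dv$observed_score == "cesdc_total", ]
  null <- dv[dv$predicted_outcome == "scared_total" &
               dv$observed_score == "asrs_total", ]
  expect_gt(own$r, 0.3)
  expect_gt(other$r, 0.3)
  expect_lt(abs(null$r), 0.1)
  # deterministic: identical inputs give identical tables
  expect_equal(dv, discriminant_validity(d, base = c("age", "sex"),
                                         features = c("f1", "f2", "f3")))
})
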