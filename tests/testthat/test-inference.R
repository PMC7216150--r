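# Correlation table, standardization, VIF and the multilevel layer.

# minimal frame with s schools and n students per school
sim_frame <- function(n_per = 40, schools = 6, seed = 1, u_sd = 0,
                      beta = c(x = 0.5), resid_sd = 1) {
  set.seed(seed)
  n <- n_per * schools
  school_id <- rep(sprintf("S%02d", seq_len(schools)), each = n_per)
  u <- rnorm(schools, 0, u_sd)[as.integer(factor(school_id))]
  df <- data.frame(school_id = school_id, country = "XX",
                   stringsAsFactors = FALSE)
  lin <- 0
  for (nm in names(beta)) {
    df[[nm]] <- rnorm(n)
    lin <- lin + beta[[nm]] * df[[nm]]
  }
  df$y <- lin + u + rnorm(n, 0, resid_sd)
  df
}

test_that("standardize_frame z-scores with the n-1 denominator", {
  df <- data.frame(a = c(1, 2, 3, 4), b = c(10, 10, 10, 10), z = rnorm(4))
  out <- standardize_frame(df, "a")
  expect_equal(mean(out$a), 0)
  expect_equal(sd(out$a), 1)
  expect_error(standardize_frame(df, "b"), "constant column: b")
  zz <- (df$z - mean(df$z)) / sd(df$z)
  df$z <- zz
  expect_equal(standardize_frame(df, "z")$z, zz, tolerance = 1e-12)
})

test_that("pearson_table reports r, p and stars from pairwise complete cases", {
  set.seed(2)
  df <- data.frame(burnout = rnorm(1e4))
  df$engagement <- rnorm(1e4)          # independent: |r| < 0.05
  df$lin <- 2 * df$burnout             # exact: r = 1
  tab <- pearson_table(df, covariates = c("lin", "engagement"),
                       outcomes = c("burnout"))
  expect_equal(tab$r[tab$covariate == "lin"], 1, tolerance = 1e-12)
  expect_lt(abs(tab$r[tab$covariate == "engagement"]), 0.05)
  expect_equal(tab$stars[tab$covariate == "lin"], "***")
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})

test_that("VIF: orthogonal terms, an exact R^2 = 0.75 construction, collinearity", {
  u <- rep(c(1, 1, -1, -1), 25)
  w <- rep(c(1, -1, 1, -1), 25)
  v <- rep(c(1, -1, -1, 1), 25)
  df <- data.frame(u = u, w = w, x3 = sqrt(3) * u + v)
  expect_equal(unname(vif(df[c("u", "w")], c("u", "w"))), c(1, 1))
  # x3 = sqrt(3) u + v with u,w,v mutually orthogonal: auxiliary R^2 = 3/4
  out <- vif(df, c("x3", "u", "w"))
  expect_equal(unname(out["x3"]), 4)
  df$dup <- df$u
  expect_warning(out2 <- vif(df, c("u", "dup", "w")), "collinearity")
  expect_true(is.infinite(out2[["u"]]))
})

test_that("VIF agrees with the standard regression-based implementation", {
  set.seed(3)
  df <- as.data.frame(matrix(rnorm(400), ncol = 4))
  df$V2 <- df$V2 + 0.6 * df$V1
  fit <- lm(rnorm(100) ~ V1 + V2 + V3 + V4, data = df)
  expect_equal(unname(vif(df, paste0("V", 1:4))), unname(car::vif(fit)),
               tolerance = 1e-8)
})

test_that("noiseless standardized effect is recovered to 1e-6", {
  df <- sim_frame(beta = c(x = 0.5), resid_sd = 0, u_sd = 0)
  # outcome built with an exactly orthogonal unit-variance remainder, so the
  # standardized coefficient of x is 0.5 by construction
  e <- resid(lm(rnorm(nrow(df)) ~ df$x))
  zx <- as.numeric(scale(df$x))
  ze <- as.numeric(scale(e))
  df$y <- 0.5 * zx + sqrt(1 - 0.25) * ze
  res <- suppressWarnings(
    fit_multilevel(df, "y", "x", controls = character(0)))
  expect_equal(get_beta(res, "x"), 0.5, tolerance = 1e-6)
})

test_that("with zero school and country effects the fit matches OLS", {
  df <- sim_frame(beta = c(x = 0.3, z = -0.2), u_sd = 0, seed = 4)
  res <- suppressWarnings(
    fit_multilevel(df, "y", c("x", "z"), controls = character(0)))
  sdat <- standardize_frame(df, c("y", "x", "z"))
  ols <- coef(lm(y ~ x + z, data = sdat))
  expect_equal(get_beta(res, "x"), unname(ols["x"]), tolerance = 1e-6)
  expect_equal(get_beta(res, "z"), unname(ols["z"]), tolerance = 1e-6)
})

test_that("the school variance component is recovered across replicates", {
  u_sd <- 0.5
  est <- vapply(1:100, function(r) {
    df <- sim_frame(n_per = 25, schools = 25, seed = 100 + r, u_sd = u_sd,
                    beta = c(x = 0.2))
    # unstandardized variance recovery: fit on raw y via lmer directly
    # (REML, so the variance component is not shrunk by the fixed effects)
    fit <- lme4::lmer(y ~ x + (1 | school_id), data = df, REML = TRUE)
    as.numeric(lme4::VarCorr(fit)$school_id)
  }, 0)
  # Monte-Carlo error of the mean over 100 replicates of a chi-square-like
  # estimate with 24 df is about 0.008; 3 standard errors
  expect_lt(abs(mean(est) - u_sd^2), 0.025)
})

test_that("singular fits return a result with a warning, not an error", {
  df <- sim_frame(u_sd = 0, seed = 6)
  # remove all between-school outcome variation: the school variance is then
  # estimated at exactly zero (a boundary fit)
  df$y <- df$y - ave(df$y, df$school_id)
  expect_warning(res <- fit_multilevel(df, "y", "x", controls = character(0)),
                 "singular")
  expect_s3_class(res, "ml_result")
})

test_that("-2LL improves when a truly predictive term is added", {
  df <- sim_frame(beta = c(x = 0.6, z = 0.4), resid_sd = 0.2, u_sd = 0.1,
                  seed = 7)
  m1 <- suppressWarnings(fit_multilevel(df, "y", "x", controls = character(0)))
  m2 <- suppressWarnings(fit_multilevel(df, "y", c("x", "z"),
                                        controls = character(0)))
  expect_lt(m2$minus2ll, m1$minus2ll)
})

test_that("standardized betas are invariant to affine rescaling of a predictor", {
  df <- sim_frame(beta = c(x = 0.4), u_sd = 0.2, seed = 8)
  r1 <- suppressWarnings(fit_multilevel(df, "y", "x", controls = character(0)))
  df$x <- 100 * df$x - 7
  r2 <- suppressWarnings(fit_multilevel(df, "y", "x", controls = character(0)))
  expect_equal(get_beta(r1, "x"), get_beta(r2, "x"), tolerance = 1e-10)
})

test_that("CIs bracket the estimate and stars follow the p thresholds", {
  df <- sim_frame(beta = c(x = 0.3), u_sd = 0.1, seed = 9)
  res <- suppressWarnings(fit_multilevel(df, "y", "x", controls = character(0)))
  co <- res$coefficients
  expect_true(all(co$ci_lo <= co$beta & co$beta <= co$ci_hi))
  expected <- ifelse(co$p < 0.01, "***",
                     ifelse(co$p < 0.05, "**", ifelse(co$p < 0.1, "*", "")))
  expect_equal(co$stars, expected)
})

test_that("model guards: schools, observations per term, constant predictors", {
  df <- sim_frame(n_per = 40, schools = 1, seed = 10)
  expect_error(fit_multilevel(df, "y", "x", controls = character(0)),
               "at least 2 schools")
  df2 <- sim_frame(n_per = 5, schools = 2, seed = 11,
                   beta = c(x = 0.2, z = 0.2))
  expect_error(fit_multilevel(df2, "y", c("x", "z"), controls = character(0)),
               "too few observations")
  df3 <- sim_frame(seed = 12)
  df3$flat <- 1
  expect_warning(res <- fit_multilevel(df3, "y", c("x", "flat"),
                                       controls = character(0)),
                 "constant")
  expect_false("flat" %in% res$coefficients$term)
})

test_that("country-nested and country-fixed variants both fit", {
  df <- sim_frame(beta = c(x = 0.3), u_sd = 0.3, seed = 13)
  df$country <- rep(c("AA", "BB"), length.out = nrow(df))
  df$country[df$school_id <= "S03"] <- "AA"
  df$country[df$school_id > "S03"] <- "BB"
  r1 <- suppressWarnings(fit_multilevel(df, "y", "x", controls = character(0),
                                        nesting = "country_fixed"))
  r2 <- suppressWarnings(fit_multilevel(df, "y", "x", controls = character(0),
                                        nesting = "country_nested"))
  expect_equal(get_beta(r1, "x"), get_beta(r2, "x"), tolerance = 0.05)
  expect_match(r2$formula, "country/school_id", fixed = TRUE)
})

test_that("report tables carry both model columns and the fit footer", {
  cohort <- generate_cohort(tiny_config(seed = 5))
  scores <- score_scales(cohort$items, cohort$roster)
  pos <- cohort_positions(cohort$roster, cohort$nominations)
  summ <- summarize_schools(cohort$roster, cohort$nominations, scores)
  frame <- build_analysis_frame(cohort$roster, scores, pos, summ)
  terms <- c("activity", "popularity", "connectedness")
  bat <- suppressWarnings(fit_battery(frame, "burnout", terms = terms))
  tabs <- render_tables(frame, pearson_table(frame),
                        list(burnout = bat, engagement = bat))
  expect_equal(tabs$table2$term, terms)
  expect_true(all(c("beta_bivariate", "beta_multivariate") %in%
                    names(tabs$table2)))
  expect_equal(attr(tabs$table2, "minus2ll"), bat$multivariate$minus2ll)
  txt <- format_regression_table(tabs$table2, "burnout")
  expect_equal(txt[1], "burnout")
  expect_length(txt, 2 + length(terms) + 1)
  # rendering the same results twice is byte-stable
  expect_identical(txt, format_regression_table(tabs$table2, "burnout"))
})
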