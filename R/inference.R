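# Statistical layer: Pearson correlation tables, standardization, multilevel
# random-intercept regressions with standardized coefficients, VIF and
# goodness of fit. Models are fitted by maximum likelihood (not REML) so that
# -2 log-likelihood values are comparable across fixed-effect specifications.

.star_label <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

#' Assemble the analysis frame
#'
#' Merges scores, ego positions and school summaries into one row per
#' participating student, the unit of analysis for the correlation and
#' regression layers: outcomes (`burnout`, `engagement`), ego-level
#' predictors (`activity` = out-degree, `popularity` = in-degree,
#' `isolated` as 0/1), school-level predictors (`density`,
#' `centralization`, `clustering`, `connectedness` = school connectedness
#' climate), controls (`fas`, `age`, `sex` with female = 1) and grouping
#' (`school_id`, `country`). Missing values are retained; each model applies
#' its own complete-case rule.
#'
#' @param roster roster `data.frame`.
#' @param scores per-student scores from [score_scales()].
#' @param positions pooled ego positions from [cohort_positions()].
#' @param summaries school summaries from [summarize_schools()].
#' @return A `data.frame`, one row per participating student.
#' @export
build_analysis_frame <- function(roster, scores, positions, summaries) {
  df <- roster[roster$participated,
               c("student_id", "school_id", "country_code", "sex", "age")]
  names(df)[names(df) == "country_code"] <- "country"
  i <- match(df$student_id, scores$student_id)
  df$burnout <- scores$burnout[i]
  df$engagement <- scores$engagement[i]
  df$fas <- scores$fas[i]
  j <- match(df$student_id, positions$student_id)
  df$activity <- positions$out_degree[j]
  df$popularity <- positions$in_degree[j]
  df$isolated <- as.numeric(positions$isolated[j])
  k <- match(df$school_id, summaries$school_id)
  df$density <- summaries$density_pct[k]
  df$centralization <- summaries$centralization_pct[k]
  df$clustering <- summaries$clustering_pct[k]
  df$connectedness <- summaries$mean_connectedness[k]
  df$sex <- as.numeric(df$sex == "female")
  rownames(df) <- NULL
  df
}

#' Z-score columns of a frame
#'
#' Standardizes the given columns to mean 0 and standard deviation 1
#' (sample SD, `n - 1` denominator) on the rows present, so that regression
#' coefficients are in SD units. Binary columns are z-scored like continuous
#' ones. The original means and SDs are attached for back-transformation.
#'
#' @param frame a `data.frame`.
#' @param cols character vector of column names to standardize.
#' @return The frame with the columns replaced by their z-scores and an
#'   attribute `"scaling"` (data.frame of `col`, `mean`, `sd`). A constant
#'   column is an error.
#' @export
standardize_frame <- function(frame, cols) {
  scaling <- data.frame(col = cols, mean = NA_real_, sd = NA_real_,
                        stringsAsFactors = FALSE)
  for (i in seq_along(cols)) {
    x <- as.numeric(frame[[cols[i]]])
    mu <- mean(x, na.rm = TRUE)
    sdv <- sd(x, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) {
      stop("cannot standardize constant column: ", cols[i], call. = FALSE)
    }
    frame[[cols[i]]] <- (x - mu) / sdv
    scaling$mean[i] <- mu
    scaling$sd[i] <- sdv
  }
  attr(frame, "scaling") <- scaling
  frame
}

#' Pearson correlation table
#'
#' Pairwise complete-case Pearson correlations of each covariate with the
#' two academic well-being outcomes, with two-sided p-values from the t
#' transform and significance stars (`***` p < 0.01, `**` p < 0.05,
#' `*` p < 0.1).
#'
#' @param frame analysis frame from [build_analysis_frame()].
#' @param covariates covariate columns to correlate.
#' @param outcomes outcome columns (default burnout and engagement).
#' @return A `data.frame` with `covariate`, `outcome`, `r`, `p`, `n`,
#'   `stars`.
#' @export
pearson_table <- function(frame,
                          covariates = c("sex", "age", "burnout",
                                         "engagement", "activity",
                                         "popularity", "isolated", "density",
                                         "centralization", "clustering",
                                         "connectedness"),
                          outcomes = c("burnout", "engagement")) {
  rows <- list()
  for (cv in covariates) {
    for (out in outcomes) {
      if (cv == out) next
      ok <- !is.na(frame[[cv]]) & !is.na(frame[[out]])
      ct <- cor.test(frame[[cv]][ok], frame[[out]][ok])
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cv, outcome = out, r = unname(ct$estimate),
        p = ct$p.value, n = sum(ok), stars = .star_label(ct$p.value),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1 / (1 - R_j^2)} where \eqn{R_j^2} is from the auxiliary
#' ordinary regression of predictor `j` on the other predictors. Perfect
#' collinearity yields `Inf` with a warning naming the offending pair.
#'
#' @param frame data with the predictor columns (complete cases are used).
#' @param terms predictor column names.
#' @return Named numeric vector of VIFs (all 1 when only one term).
#' @export
vif <- function(frame, terms) {
  dat <- frame[terms]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  out <- setNames(rep(1, length(terms)), terms)
  if (length(terms) < 2) return(out)
  for (j in seq_along(terms)) {
    others <- terms[-j]
    fml <- as.formula(paste(terms[j], "~",
                            paste(sprintf("`%s`", others), collapse = " + ")))
    r2 <- summary(lm(fml, data = dat))$r.squared
    if (r2 > 1 - 1e-10) {
      cors <- abs(vapply(others, function(o) cor(dat[[terms[j]]], dat[[o]]), 0))
      warning("perfect collinearity: ", terms[j], " ~ ",
              others[which.max(cors)], call. = FALSE)
      out[j] <- Inf
    } else {
      out[j] <- 1 / (1 - r2)
    }
  }
  out
}

#' Fit a standardized multilevel regression
#'
#' Linear mixed model of one academic well-being outcome on network terms
#' and controls, with a random intercept per school, fitted by maximum
#' likelihood via [lme4::lmer()]. Outcome, terms and controls are z-scored
#' on the estimation sample (complete cases for the model's columns), so the
#' fixed-effect estimates are standardized betas. Country enters as
#' fixed-effect dummies by default; `nesting = "country_nested"` fits nested
#' random intercepts (country/school) instead. Wald 95% confidence intervals
#' and normal-approximation p-values are reported, appropriate at the sample
#' sizes these cohort surveys have. A singular fit (school variance zero) is
#' returned with a warning, not an error.
#'
#' @param frame analysis frame from [build_analysis_frame()].
#' @param outcome `"burnout"` or `"engagement"`.
#' @param terms network predictor columns for this model (one for a
#'   bivariate model, all seven for the multivariate model).
#' @param controls control columns (z-scored like the terms).
#' @param nesting `"country_fixed"` (country dummies, default) or
#'   `"country_nested"` (random intercepts for country and school within
#'   country).
#' @param reml fit by REML instead of ML; off by default so that
#'   -2 log-likelihood is comparable across fixed-effect specifications.
#' @param label optional model label for reports.
#' @return An object of class `ml_result`: list with `label`, `outcome`,
#'   `type`, `coefficients` (term, beta, se, ci_lo, ci_hi, p, stars),
#'   `minus2ll`, `vif`, `n`, `n_schools`, `formula`, `scaling` and the
#'   underlying `fit`.
#' @export
fit_multilevel <- function(frame, outcome, terms,
                           controls = c("fas", "age", "sex"),
                           nesting = c("country_fixed", "country_nested"),
                           reml = FALSE, label = NULL) {
  nesting <- match.arg(nesting)
  stopifnot(outcome %in% names(frame), all(terms %in% names(frame)))
  z_cols <- c(outcome, terms, controls)
  used <- c(z_cols, "school_id", "country")
  dat <- frame[complete.cases(frame[z_cols]), used, drop = FALSE]
  n <- nrow(dat)
  if (length(unique(dat$school_id)) < 2) {
    stop("multilevel model needs at least 2 schools", call. = FALSE)
  }
  if (n < 10 * (length(terms) + length(controls))) {
    stop("too few observations (", n, ") for ",
         length(terms) + length(controls), " terms", call. = FALSE)
  }
  sds <- vapply(z_cols, function(cl) sd(as.numeric(dat[[cl]])), 0)
  if (sds[outcome] == 0) stop("outcome is constant", call. = FALSE)
  constant <- names(sds)[sds == 0]
  if (length(constant)) {
    warning("dropping constant predictor(s): ",
            paste(constant, collapse = ", "), call. = FALSE)
    terms <- setdiff(terms, constant)
    controls <- setdiff(controls, constant)
    if (!length(terms)) stop("no non-constant term left", call. = FALSE)
    z_cols <- c(outcome, terms, controls)
  }
  dat <- standardize_frame(dat, z_cols)
  dat$country <- factor(dat$country)

  fixed <- paste(c(terms, controls), collapse = " + ")
  re <- if (nesting == "country_fixed") "(1 | school_id)"
        else "(1 | country/school_id)"
  fe_country <- if (nesting == "country_fixed" &&
                    length(unique(dat$country)) > 1) " + country" else ""
  fml <- paste0(outcome, " ~ ", fixed, fe_country, " + ", re)
  fit <- lme4::lmer(as.formula(fml), data = dat, REML = reml)
  if (lme4::isSingular(fit)) {
    warning("singular fit: school-level variance estimated as zero",
            call. = FALSE)
  }

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  zval <- beta / se
  p <- 2 * pnorm(-abs(zval))
  ci <- qnorm(0.975) * se
  coefs <- data.frame(term = names(beta), beta = unname(beta),
                      se = unname(se), ci_lo = unname(beta - ci),
                      ci_hi = unname(beta + ci), p = unname(p),
                      stars = .star_label(unname(p)),
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL

  structure(list(
    label = label %||% paste0(outcome, " ~ ", paste(terms, collapse = "+")),
    outcome = outcome,
    type = if (length(terms) == 1) "bivariate" else "multivariate",
    terms = terms,
    coefficients = coefs,
    minus2ll = -2 * as.numeric(logLik(fit)),
    vif = vif(dat, c(terms, controls)),
    n = n,
    n_schools = length(unique(dat$school_id)),
    formula = fml,
    reml = reml,
    nesting = nesting,
    scaling = attr(dat, "scaling"),
    fit = fit
  ), class = "ml_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ml_result <- function(x, digits = 3, ...) {
  cat(sprintf("Multilevel model (%s, %s): %s\n", x$type,
              if (x$reml) "REML" else "ML", x$formula))
  cat(sprintf("  n = %d students in %d schools, -2LL = %.1f\n",
              x$n, x$n_schools, x$minus2ll))
  show <- x$coefficients[x$coefficients$term %in% x$terms, ]
  for (i in seq_len(nrow(show))) {
    cat(sprintf("  %-15s beta = %6.3f  [%6.3f, %6.3f] %s\n",
                show$term[i], show$beta[i], show$ci_lo[i], show$ci_hi[i],
                show$stars[i]))
  }
  invisible(x)
}

#' Extract one standardized beta from a fitted model
#'
#' @param result an `ml_result`.
#' @param term term name.
#' @return The standardized coefficient (numeric scalar).
#' @export
get_beta <- function(result, term) {
  i <- match(term, result$coefficients$term)
  if (is.na(i)) stop("term not in model: ", term, call. = FALSE)
  result$coefficients$beta[i]
}

#' Fit the full model battery for one outcome
#'
#' Seven bivariate models (one per network term, each adjusted for the
#' controls) followed by the multivariate model with all seven terms,
#' mirroring the bivariate/multivariate report layout.
#'
#' @inheritParams fit_multilevel
#' @param terms the seven network predictors.
#' @return Named list of `ml_result` objects (`bivariate_<term>`, ...,
#'   `multivariate`).
#' @export
fit_battery <- function(frame, outcome,
                        terms = c("activity", "popularity", "isolated",
                                  "density", "centralization", "clustering",
                                  "connectedness"),
                        controls = c("fas", "age", "sex"),
                        nesting = "country_fixed", reml = FALSE) {
  out <- list()
  for (tm in terms) {
    out[[paste0("bivariate_", tm)]] <-
      fit_multilevel(frame, outcome, tm, controls, nesting, reml,
                     label = paste0(outcome, " ~ ", tm, " (bivariate)"))
  }
  out$multivariate <-
    fit_multilevel(frame, outcome, terms, controls, nesting, reml,
                   label = paste0(outcome, " (multivariate)"))
  out
}

#' Render report tables
#'
#' Builds the descriptive table (mean or %, SD, n and the correlation of
#' each covariate with the two outcomes) and one regression table per
#' outcome with the bivariate and multivariate columns side by side
#' (standardized beta, 95% CI, stars; -2 log-likelihood of the multivariate
#' model as a footer attribute).
#'
#' @param frame analysis frame.
#' @param pearson correlation table from [pearson_table()].
#' @param batteries named list with elements `burnout` and `engagement`,
#'   each a battery from [fit_battery()].
#' @return List with `table1`, `table2` (burnout), `table3` (engagement),
#'   each a `data.frame`; regression tables carry a `minus2ll` attribute.
#' @export
render_tables <- function(frame, pearson, batteries) {
  covs <- c("sex", "age", "burnout", "engagement", "activity", "popularity",
            "isolated", "density", "centralization", "clustering",
            "connectedness")
  pct_cov <- c(sex = TRUE, isolated = TRUE)
  t1 <- do.call(rbind, lapply(covs, function(cv) {
    x <- frame[[cv]]
    ok <- !is.na(x)
    val <- if (isTRUE(pct_cov[cv])) 100 * mean(x[ok]) else mean(x[ok])
    data.frame(covariate = cv, mean_or_pct = val, sd = sd(x[ok]),
               n = sum(ok),
               r_burnout = .lookup_r(pearson, cv, "burnout"),
               r_engagement = .lookup_r(pearson, cv, "engagement"),
               stringsAsFactors = FALSE)
  }))
  rownames(t1) <- NULL
  list(table1 = t1,
       table2 = .regression_table(batteries$burnout),
       table3 = .regression_table(batteries$engagement))
}

.lookup_r <- function(pearson, cv, out) {
  i <- which(pearson$covariate == cv & pearson$outcome == out)
  if (!length(i)) return(NA_real_)
  pearson$r[i[1]]
}

.regression_table <- function(battery) {
  multi <- battery$multivariate
  terms <- multi$terms
  fmt <- function(res, tm) {
    i <- match(tm, res$coefficients$term)
    if (is.na(i)) {
      return(list(beta = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                  stars = ""))
    }
    with(res$coefficients[i, ],
         list(beta = beta, ci_lo = ci_lo, ci_hi = ci_hi, stars = stars))
  }
  rows <- lapply(terms, function(tm) {
    bi <- battery[[paste0("bivariate_", tm)]]
    b <- fmt(bi, tm); m <- fmt(multi, tm)
    data.frame(term = tm,
               beta_bivariate = b$beta, ci_lo_bivariate = b$ci_lo,
               ci_hi_bivariate = b$ci_hi, stars_bivariate = b$stars,
               beta_multivariate = m$beta, ci_lo_multivariate = m$ci_lo,
               ci_hi_multivariate = m$ci_hi, stars_multivariate = m$stars,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "minus2ll") <- multi$minus2ll
  attr(out, "n") <- multi$n
  out
}

#' Format a regression table as text lines
#'
#' Stable plain-text rendering of a regression table (used for the
#' human-readable report files).
#'
#' @param tbl a regression table from [render_tables()].
#' @param title heading line.
#' @return Character vector of lines.
#' @export
format_regression_table <- function(tbl, title = "Regression table") {
  lines <- c(title,
             sprintf("%-15s %28s %28s", "term", "bivariate", "multivariate"))
  fmt1 <- function(b, lo, hi, st) {
    if (is.na(b)) return(sprintf("%28s", ""))
    sprintf("%6.2f [%6.2f,%6.2f] %-3s", b, lo, hi, st)
  }
  for (i in seq_len(nrow(tbl))) {
    lines <- c(lines, sprintf(
      "%-15s %s %s", tbl$term[i],
      fmt1(tbl$beta_bivariate[i], tbl$ci_lo_bivariate[i],
           tbl$ci_hi_bivariate[i], tbl$stars_bivariate[i]),
      fmt1(tbl$beta_multivariate[i], tbl$ci_lo_multivariate[i],
           tbl$ci_hi_multivariate[i], tbl$stars_multivariate[i])))
  }
  if (!is.null(attr(tbl, "minus2ll"))) {
    lines <- c(lines, sprintf("-2 log likelihood = %.1f (n = %d)",
                              attr(tbl, "minus2ll"), attr(tbl, "n")))
  }
  lines
}
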