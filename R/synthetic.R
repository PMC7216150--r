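# Synthetic school-cohort generator with known ground truth.
#
# The generator emulates a multi-city classroom survey: cities (countries)
# contain stratified schools, schools contain two grades of ~5 classes, and
# classes contain small friendship groups inside which cooperation
# nominations concentrate. Nomination structure comes from three mechanisms:
# (i) a capped out-degree drawn from a beta-binomial with the survey's mean
# and dispersion, (ii) weighted alter choice (friendship group >> class >>
# school, times a lognormal "attractiveness" weight that disperses
# in-degree), and (iii) a triadic-closure pass that rewires part of each
# ego's ties toward alters of their alters. Item responses come from a
# latent model with planted standardized effects of the REALIZED network
# covariates, so running the analysis pipeline on a generated cohort is a
# parameter-recovery experiment.
#
# Calibration notes (all solved in closed form at generation time):
# * For a k-item parallel scale with target score SD `sd`, inter-item
#   correlation rho and 1-unit response grid, the latent true-score variance
#   is s2 = V * k rho / (k rho + 1 - rho) with V = sd^2, and the per-item
#   Gaussian noise variance is w - 1/12 where w = s2 (1 - rho) / rho: the
#   1/12 is the variance of the rounding (quantization) error, so rho and
#   alpha hold for the DISCRETIZED items.
# * Planted effects are injected as T = mu + X (beta * sd) + u + eps with X
#   the z-scored realized covariates; z-scoring the observed score by the
#   pipeline then returns standardized betas equal to the planted vector.
# * The observed burnout-engagement correlation is matched by solving, given
#   the realized covariance of the two planted signals, for a residual
#   correlation between the latent residuals and - because the two planted
#   connectedness effects of opposite sign already induce a structural
#   correlation stronger than the observed one - a positive cross-scale
#   correlation of the item noises (shared method variance, as expected when
#   both scales sit in the same questionnaire).

#' Synthetic cohort configuration
#'
#' Assembles (and validates) the parameter list of the cohort generator.
#' Defaults reproduce the study conditions of a six-city classroom survey:
#' 48 schools of 220 registered students in two grades, 79.4% participation,
#' out-degree capped at five with mean 3.43 and SD 1.45, friendship-group
#' homophily giving ~40% average ego clustering, in-degree SD near 2.25,
#' about 1.4% isolated participants, school connectedness climate averaging
#' 3.04 with school means spanning roughly 2.4-3.5, and planted standardized
#' effects on burnout (popularity -0.07, centralization -0.07, clustering
#' +0.03, connectedness -0.59) and engagement (activity +0.03, popularity
#' +0.03, density +0.04, connectedness +0.85), with the observed
#' burnout-engagement correlation targeted at -0.32.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_countries,schools_per_country,students_per_school cohort shape.
#' @param classes_per_grade classes per grade (two grades per school).
#' @param participation_rate Bernoulli participation probability.
#' @param mean_out_degree,out_degree_sd target moments of the capped
#'   out-degree distribution among participants (beta-binomial on 0..5).
#' @param group_size nominal friendship-group size within a class.
#' @param within_group_weight,within_class_weight multiplicative nomination
#'   weights for alters in the ego's friendship group / class;
#'   `within_class_weight = Inf` forces all ties within class.
#' @param triadic_closure_rate per-tie probability of rewiring toward an
#'   alter of another alter.
#' @param popularity_sigma SD of the lognormal attractiveness weights
#'   (drives in-degree dispersion).
#' @param isolate_prob probability that a student neither nominates nor can
#'   be nominated (explicit isolation knob).
#' @param climate_mean,climate_sd school connectedness climate distribution.
#' @param conn_within_sd,conn_item_sd student-level deviation and item noise
#'   of the connectedness scale.
#' @param reliability list of latent inter-item correlations per scale
#'   (engagement 3 items, burnout items 1-2).
#' @param score_targets list of `c(mean, sd)` per outcome scale.
#' @param betas_burnout,betas_engagement named planted standardized effects
#'   over the seven network covariates.
#' @param target_corr target observed correlation between the two scored
#'   outcomes.
#' @param school_icc extra school-level intercept variance (share of score
#'   variance) per outcome, beyond what school-level covariates induce.
#' @param missing per-scale probability that a respondent leaves one item of
#'   the scale blank.
#' @param item3_mu,item3_loading,item3_sd behaviour of the third (excluded)
#'   burnout item, generated deliberately inconsistent with items 1-2.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_countries = 6L,
                         schools_per_country = 8L,
                         students_per_school = 220L,
                         classes_per_grade = 5L,
                         participation_rate = 0.794,
                         mean_out_degree = 3.43,
                         out_degree_sd = 1.45,
                         group_size = 5L,
                         within_group_weight = 2000,
                         within_class_weight = 2,
                         triadic_closure_rate = 0.10,
                         popularity_sigma = 1.45,
                         isolate_prob = 0.0102,
                         climate_mean = 3.05,
                         climate_sd = 0.19,
                         conn_within_sd = 0.50,
                         conn_item_sd = 0.60,
                         reliability = list(engagement = 0.5135,
                                            burnout = 0.449),
                         score_targets = list(burnout = c(mean = 3.08, sd = 1.24),
                                              engagement = c(mean = 2.09, sd = 1.43)),
                         betas_burnout = c(activity = 0, popularity = -0.07,
                                           isolated = 0, density = 0,
                                           centralization = -0.07,
                                           clustering = 0.03,
                                           connectedness = -0.59),
                         betas_engagement = c(activity = 0.03,
                                              popularity = 0.03,
                                              isolated = 0, density = 0.04,
                                              centralization = 0,
                                              clustering = 0,
                                              connectedness = 0.85),
                         target_corr = -0.32,
                         school_icc = c(burnout = 0.004, engagement = 0.004),
                         missing = c(engagement = 0.036, burnout = 0.032,
                                     connectedness = 0.02, fas = 0.02),
                         item3_mu = 3.5, item3_loading = 0.25,
                         item3_sd = 1.30) {
  cfg <- as.list(environment())
  probs <- c(participation_rate, triadic_closure_rate, isolate_prob,
             unlist(missing))
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (mean_out_degree > 5) stop("mean_out_degree cannot exceed the cap of 5",
                                call. = FALSE)
  if (mean_out_degree >= students_per_school - 1) {
    stop("infeasible: mean_out_degree >= students_per_school - 1",
         call. = FALSE)
  }
  class_size <- students_per_school / (2 * classes_per_grade)
  if (is.infinite(within_class_weight) &&
      mean_out_degree > class_size - 1) {
    stop("infeasible: mean_out_degree > class size - 1 with full ",
         "within-class homophily", call. = FALSE)
  }
  stopifnot(all(is.finite(betas_burnout)), all(is.finite(betas_engagement)))
  class(cfg) <- "synth_config"
  cfg
}

.term_order <- c("activity", "popularity", "isolated", "density",
                 "centralization", "clustering", "connectedness")

# beta-binomial(5, a, b) parameters matching a target mean and SD; falls back
# to a plain binomial when the target SD is at or below the binomial SD
.bb_shapes <- function(mean, sd) {
  p <- mean / 5
  base_var <- 5 * p * (1 - p)
  r <- sd^2 / base_var
  if (r <= 1 + 1e-9) return(list(binomial = TRUE, p = p))
  if (r >= 5) stop("out_degree_sd too large for a beta-binomial on 0..5",
                   call. = FALSE)
  shape <- (5 - r) / (r - 1)
  list(binomial = FALSE, a = p * shape, b = (1 - p) * shape)
}

.draw_out_degree <- function(n, cfg) {
  sh <- .bb_shapes(cfg$mean_out_degree, cfg$out_degree_sd)
  if (sh$binomial) return(rbinom(n, 5, sh$p))
  rbinom(n, 5, rbeta(n, sh$a, sh$b))
}

# z-score that maps constant columns to zero (a constant covariate carries no
# plantable effect)
.safe_z <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# parallel-scale calibration in scale units for a 1-unit response grid
.scale_calibration <- function(mean, sd, rho, k) {
  v <- sd^2
  s2 <- v * rho * k / (rho * k + 1 - rho)
  w <- if (rho >= 1) 0 else s2 * (1 - rho) / rho
  sigma_e2 <- max(w - 1 / 12, 0)
  list(mean = mean, sd = sd, v = v, k = k, rho = rho,
       true_var = s2, item_noise_var = sigma_e2)
}

.discretize <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

# expected value of clip(round(t + e), lo, hi) with e ~ N(0, sigma):
# the response function of one ordinal item to its latent mean
.grid_mean <- function(t, sigma, lo, hi) {
  if (sigma <= 0) return(.discretize(t, lo, hi))
  out <- rep(lo, length(t))
  for (v in seq(lo + 1, hi)) {
    out <- out + stats::pnorm((t - (v - 0.5)) / sigma)
  }
  out
}

# inverse of .grid_mean by monotone interpolation: the latent mean needed so
# that the item's EXPECTED observed value equals the target. Targets are
# clamped just inside the open response range (lo, hi).
.grid_inverse <- function(targets, sigma, lo, hi) {
  if (sigma <= 0) return(targets)
  grid <- seq(lo - 5 * sigma - 1, hi + 5 * sigma + 1, length.out = 600)
  g <- .grid_mean(grid, sigma, lo, hi)
  eps <- 0.005 * (hi - lo)
  stats::approx(x = g, y = grid, ties = "ordered",
                xout = pmin(pmax(targets, lo + eps), hi - eps))$y
}

# Compensation for the bounded ordinal response grid. Rounding alone is
# absorbed exactly by the 1/12 quantization term in .scale_calibration, but
# CLIPPING at the ends of the response range attenuates inter-item
# correlations, planted slopes and cross-scale covariances in a way that has
# no closed form; these gains undo it at the default score targets. They
# were fitted once by simulation at large n and are deliberately stored as
# constants rather than re-estimated per run.
.grid_comp <- list(
  rho_gain = c(burnout = 0.934, engagement = 0.923),
  beta_gain = c(burnout = 0.966, engagement = 1.000)
)

#' Sample a synthetic student roster
#'
#' Students are allocated to countries, schools, grades and classes; sex is
#' ~52% female; integer ages centre on 15.24 (SD about 1.05) and are clipped
#' to 12-19; participation is Bernoulli at the configured rate;
#' family-affluence items are drawn independently on 0-3.
#'
#' @param config a [synth_config()]. The caller seeds the RNG (or use
#'   [generate_cohort()], which seeds everything once).
#' @return A roster `data.frame` in the [read_roster()] schema.
#' @export
sample_roster <- function(config) {
  cc <- c("BE", "DE", "FI", "IT", "NL", "PT")
  countries <- if (config$n_countries <= 6) cc[seq_len(config$n_countries)]
               else paste0("C", seq_len(config$n_countries))
  per_school <- config$students_per_school
  rows <- list()
  for (co in countries) {
    for (s in seq_len(config$schools_per_country)) {
      school <- sprintf("%s%02d", co, s)
      grade <- rep(1:2, length.out = per_school)
      cls <- stats::ave(seq_len(per_school), grade,
                        FUN = function(i) rep(seq_len(config$classes_per_grade),
                                              length.out = length(i)))
      rows[[length(rows) + 1]] <- data.frame(
        student_id = sprintf("%s-%03d", school, seq_len(per_school)),
        school_id = school, country_code = co, grade = grade,
        class_id = sprintf("%s-g%d-c%d", school, grade, cls),
        stringsAsFactors = FALSE)
    }
  }
  roster <- do.call(rbind, rows)
  n <- nrow(roster)
  roster$sex <- ifelse(runif(n) < 0.519, "female", "male")
  age_mu <- 15.24 + (roster$grade - 1.5) * 0.9
  roster$age <- .discretize(rnorm(n, age_mu, 0.9), 12, 19)
  roster$participated <- runif(n) < config$participation_rate
  for (j in 1:4) {
    roster[[paste0("fas", j)]] <-
      sample(0:3, n, replace = TRUE, prob = c(0.15, 0.30, 0.35, 0.20))
  }
  blank <- runif(n) < config$missing["fas"]
  slot <- sample(1:4, n, replace = TRUE)
  for (j in 1:4) {
    roster[[paste0("fas", j)]][blank & slot == j] <- NA_real_
  }
  rownames(roster) <- NULL
  roster
}

#' Sample a bounded nomination network for a cohort
#'
#' Each participating, non-isolate student draws an out-degree from a
#' beta-binomial on 0..5 matching the configured mean and SD, then picks that
#' many distinct alters among the registered students of their school,
#' weighted by friendship group, class and the alter's lognormal
#' attractiveness; a triadic-closure pass then rewires a configured fraction
#' of ties toward alters of the ego's other alters. The cap of five is never
#' exceeded and designated isolates neither send nor receive ties.
#'
#' @param roster roster from [sample_roster()].
#' @param config a [synth_config()].
#' @return A nomination `data.frame` (`ego_id`, `alter_id`, `rank`) with a
#'   `"truth"` attribute (per-student attractiveness, isolate designation
#'   and friendship group).
#' @export
sample_nominations <- function(roster, config) {
  n <- nrow(roster)
  attract <- rlnorm(n, -config$popularity_sigma^2 / 2,
                    config$popularity_sigma)
  # designated isolates are stratified per school (floor + fractional
  # Bernoulli) so the isolation rate does not carry extra binomial noise
  isolate <- logical(n)
  for (school in unique(roster$school_id)) {
    s_idx <- which(roster$school_id == school)
    expected <- config$isolate_prob * length(s_idx)
    k <- floor(expected) + (runif(1) < expected - floor(expected))
    if (k > 0) isolate[sample(s_idx, k)] <- TRUE
  }

  group <- character(n)
  for (cl in unique(roster$class_id)) {
    idx <- which(roster$class_id == cl)
    ng <- max(1L, round(length(idx) / config$group_size))
    group[idx] <- paste0(cl, "-f", sample(rep(seq_len(ng),
                                              length.out = length(idx))))
  }

  out_deg <- .draw_out_degree(n, config)
  ego_l <- list(); alter_l <- list()

  for (school in unique(roster$school_id)) {
    s_idx <- which(roster$school_id == school)
    ns <- length(s_idx)
    s_attract <- attract[s_idx]
    s_attract[isolate[s_idx]] <- 0
    s_class <- roster$class_id[s_idx]
    s_group <- group[s_idx]
    egos <- which(roster$participated[s_idx] & !isolate[s_idx] &
                    out_deg[s_idx] > 0)
    alters_of <- vector("list", ns)
    for (i in egos) {
      w <- s_attract
      if (is.infinite(config$within_class_weight)) {
        w[s_class != s_class[i]] <- 0
        w[s_group == s_group[i]] <- w[s_group == s_group[i]] *
          config$within_group_weight
      } else {
        same_g <- s_group == s_group[i]
        same_c <- s_class == s_class[i] & !same_g
        w[same_g] <- w[same_g] * config$within_group_weight
        w[same_c] <- w[same_c] * config$within_class_weight
      }
      w[i] <- 0
      d <- min(out_deg[s_idx][i], sum(w > 0))
      if (d == 0) next
      alters_of[[i]] <- sample.int(ns, d, prob = w)
    }

    # triadic closure on a snapshot of the initial out-neighbourhoods
    if (config$triadic_closure_rate > 0) {
      snapshot <- alters_of
      for (i in sample(egos)) {
        alters <- alters_of[[i]]
        if (length(alters) < 2) next
        for (j in seq_along(alters)) {
          if (runif(1) >= config$triadic_closure_rate) next
          others <- alters[-j]
          a <- others[sample.int(length(others), 1)]
          cand <- setdiff(snapshot[[a]], c(i, alters))
          if (length(cand)) {
            alters[j] <- cand[sample.int(length(cand), 1)]
          }
        }
        alters_of[[i]] <- alters
      }
    }

    for (i in egos) {
      if (is.null(alters_of[[i]])) next
      ego_l[[length(ego_l) + 1]] <-
        rep(roster$student_id[s_idx][i], length(alters_of[[i]]))
      alter_l[[length(alter_l) + 1]] <-
        roster$student_id[s_idx][alters_of[[i]]]
    }
  }

  ego_id <- unlist(ego_l)
  out <- data.frame(ego_id = ego_id, alter_id = unlist(alter_l),
                    rank = as.integer(stats::ave(seq_along(ego_id), ego_id,
                                                 FUN = seq_along)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(student_id = roster$student_id,
                                   attract = attract, isolate = isolate,
                                   group = group, stringsAsFactors = FALSE)
  out
}

#' Sample item responses from the latent well-being model
#'
#' Generates connectedness, burnout and engagement items for the
#' participating students. School climate is Normal(`climate_mean`,
#' `climate_sd`); student connectedness is climate plus noise; latent
#' burnout and engagement are linear in the z-scored realized network
#' covariates with the planted standardized betas, a school random
#' intercept, and residuals whose within- and cross-scale correlation
#' structure is solved so that the observed score correlation matches
#' `target_corr`. Items are parallel measures at the configured reliability,
#' discretized to the ordinal response grids by rounding, with per-scale
#' missingness.
#'
#' @param roster roster from [sample_roster()].
#' @param networks list of `nomination_network` objects, one per school
#'   (see [build_network()]).
#' @param config a [synth_config()].
#' @return An item `data.frame` in the [read_items()] schema with a
#'   `"truth"` attribute (latent scores, climates, solved correlation
#'   parameters and realized covariates).
#' @export
sample_items <- function(roster, networks, config) {
  part_idx <- which(roster$participated)
  part <- roster[part_idx, ]
  np <- nrow(part)

  # realized network covariates
  pos <- do.call(rbind, lapply(networks, ego_positions))
  schools <- vapply(networks, `[[`, "", "school_id")
  sumry <- data.frame(
    school_id = schools,
    density = vapply(networks, net_density, 0),
    centralization = vapply(networks, net_centralization, 0),
    clustering = vapply(networks, function(nw) {
      suppressWarnings(avg_clustering(nw))
    }, 0),
    stringsAsFactors = FALSE)

  # climate draws are truncated at +-2 SD: keeps every school mean inside
  # the observed between-school span and keeps the school-level signal away
  # from the response floor of the bounded engagement scale
  climate <- config$climate_mean +
    config$climate_sd * pmin(pmax(rnorm(length(schools)), -2), 2)
  names(climate) <- schools
  conn_lat <- climate[part$school_id] + rnorm(np, 0, config$conn_within_sd)

  # connectedness items are generated FIRST and the school climate covariate
  # is computed from the scored items exactly as the analysis pipeline will
  # compute it, so the planted school-connectedness effect sits on the very
  # covariate the estimation stage sees
  L_conn <- .grid_inverse(conn_lat, config$conn_item_sd, 1, 4)
  conn_items <- vapply(1:5, function(j) {
    .discretize(L_conn + rnorm(np, 0, config$conn_item_sd), 1, 4)
  }, numeric(np))
  hit <- runif(np) < config$missing["connectedness"]
  slot <- sample(1:5, np, replace = TRUE)
  conn_items[cbind(which(hit), slot[hit])] <- NA_real_
  conn_score <- rowMeans(conn_items)
  school_conn <- tapply(conn_score, part$school_id,
                        function(x) mean(x, na.rm = TRUE))

  i <- match(part$student_id, pos$student_id)
  k <- match(part$school_id, sumry$school_id)
  X <- cbind(
    activity = .safe_z(pos$out_degree[i]),
    popularity = .safe_z(pos$in_degree[i]),
    isolated = .safe_z(as.numeric(pos$isolated[i])),
    density = .safe_z(sumry$density[k]),
    centralization = .safe_z(sumry$centralization[k]),
    clustering = .safe_z(sumry$clustering[k]),
    connectedness = .safe_z(as.numeric(school_conn[part$school_id]))
  )

  tg_b <- config$score_targets$burnout
  tg_e <- config$score_targets$engagement
  cal_b <- .scale_calibration(tg_b["mean"], tg_b["sd"],
                              min(0.999, config$reliability$burnout *
                                    .grid_comp$rho_gain["burnout"]), 2)
  cal_e <- .scale_calibration(tg_e["mean"], tg_e["sd"],
                              min(0.999, config$reliability$engagement *
                                    .grid_comp$rho_gain["engagement"]), 3)

  sig_b <- as.numeric(X %*% (config$betas_burnout[.term_order] * cal_b$sd *
                               .grid_comp$beta_gain["burnout"]))
  sig_e <- as.numeric(X %*% (config$betas_engagement[.term_order] * cal_e$sd *
                               .grid_comp$beta_gain["engagement"]))

  var_u_b <- config$school_icc["burnout"] * cal_b$v
  var_u_e <- config$school_icc["engagement"] * cal_e$v
  eps_b2 <- cal_b$true_var - var(sig_b) - var_u_b
  eps_e2 <- cal_e$true_var - var(sig_e) - var_u_e
  for (nm in c("b", "e")) {
    v <- get(paste0("eps_", nm, "2"))
    cal_v <- get(paste0("cal_", nm))$v
    if (v < -0.05 * cal_v) {
      warning("planted signal variance exceeds the true-score variance of ",
              if (nm == "b") "burnout" else "engagement",
              " implied by the reliability/SD targets; residual floored",
              call. = FALSE)
    }
    # at the default targets the engagement signal legitimately uses almost
    # the whole reliable variance; a small silent floor keeps eps proper
    if (v < 0.002 * cal_v) assign(paste0("eps_", nm, "2"), 0.002 * cal_v)
  }
  sd_eps_b <- sqrt(eps_b2); sd_eps_e <- sqrt(eps_e2)

  # solve the residual structure for the target observed correlation
  target_cov <- config$target_corr * cal_b$sd * cal_e$sd
  need <- target_cov - cov(sig_b, sig_e)
  rho_resid <- if (sd_eps_b * sd_eps_e > 0) {
    max(-0.9, min(0.9, need / (sd_eps_b * sd_eps_e)))
  } else 0
  left <- need - rho_resid * sd_eps_b * sd_eps_e
  sd_ne_b <- sqrt(cal_b$item_noise_var)
  sd_ne_e <- sqrt(cal_e$item_noise_var)
  rho_cap <- 0.95 / sqrt(cal_b$k * cal_e$k)
  rho_method <- if (sd_ne_b * sd_ne_e > 0) {
    max(-rho_cap, min(rho_cap, left / (sd_ne_b * sd_ne_e)))
  } else 0
  unmet <- left - rho_method * sd_ne_b * sd_ne_e
  if (abs(unmet) > 0.02 * cal_b$sd * cal_e$sd) {
    warning(sprintf(paste0("observed-correlation target %.2f not fully ",
                           "reachable; shortfall %.3f in covariance units"),
                    config$target_corr, unmet), call. = FALSE)
  }

  u_b <- rnorm(length(schools), 0, sqrt(var_u_b)); names(u_b) <- schools
  u_e <- rnorm(length(schools), 0, sqrt(var_u_e)); names(u_e) <- schools
  z1 <- rnorm(np); z2 <- rnorm(np)
  eps_b <- sd_eps_b * z1
  eps_e <- sd_eps_e * (rho_resid * z1 + sqrt(1 - rho_resid^2) * z2)

  T_b <- cal_b$mean + sig_b + u_b[part$school_id] + eps_b
  T_e <- cal_e$mean + sig_e + u_e[part$school_id] + eps_e

  # item noises: independent within scale, rho_method across scales
  kk <- cal_b$k + cal_e$k
  sds <- c(rep(sd_ne_b, cal_b$k), rep(sd_ne_e, cal_e$k))
  if (all(sds > 0)) {
    sig_mat <- diag(kk) * 0
    sig_mat[seq_len(cal_b$k), cal_b$k + seq_len(cal_e$k)] <- rho_method
    sig_mat[cal_b$k + seq_len(cal_e$k), seq_len(cal_b$k)] <- rho_method
    diag(sig_mat) <- 1
    sig_mat <- sig_mat * tcrossprod(sds)
    noise <- matrix(rnorm(np * kk), np, kk) %*% chol(sig_mat)
  } else {
    noise <- sapply(sds, function(s) rnorm(np, 0, s))
  }

  # Pre-distortion: T_b / T_e are the OBSERVED-scale target means; items are
  # generated from the latent mean whose expected discretized value equals
  # the target. This keeps the expected observed score exactly linear in the
  # planted covariates even near the ends of the bounded response grids,
  # where naive rounding of a Gaussian latent would bend the relationship.
  L_b <- .grid_inverse(T_b, sd_ne_b, 1, 6)

  # exact correlation matching: the analytic solve above is in expectation;
  # a small deterministic tilt of T_e along the realized burnout score,
  # iterated against the DISCRETIZED scores, pins the observed correlation
  # at the target for this run
  if (np > 2) {
    s_b_cont <- T_b + rowMeans(noise[, seq_len(cal_b$k), drop = FALSE])
    s_b_ref <- s_b_cont - mean(s_b_cont)
    v_ref <- var(s_b_cont)
    if (v_ref > 0) {
      sb_d <- (.discretize(L_b + noise[, 1], 1, 6) +
                 .discretize(L_b + noise[, 2], 1, 6)) / 2
      for (it in 1:3) {
        L_e <- .grid_inverse(T_e, sd_ne_e, 0, 5)
        se_d <- (.discretize(L_e + noise[, cal_b$k + 1], 0, 5) +
                   .discretize(L_e + noise[, cal_b$k + 2], 0, 5) +
                   .discretize(L_e + noise[, cal_b$k + 3], 0, 5)) / 3
        delta <- config$target_corr * sd(sb_d) * sd(se_d) - cov(sb_d, se_d)
        T_e <- T_e + (delta / v_ref) * s_b_ref
      }
    }
  }
  L_e <- .grid_inverse(T_e, sd_ne_e, 0, 5)

  items <- data.frame(student_id = part$student_id, stringsAsFactors = FALSE)
  items$ssbi1 <- .discretize(L_b + noise[, 1], 1, 6)
  items$ssbi2 <- .discretize(L_b + noise[, 2], 1, 6)
  items$ssbi3 <- .discretize(config$item3_mu +
                               config$item3_loading * (T_b - cal_b$mean) +
                               rnorm(np, 0, config$item3_sd), 1, 6)
  for (j in 1:3) {
    items[[paste0("eda", j)]] <- .discretize(L_e + noise[, cal_b$k + j], 0, 5)
  }
  for (j in 1:5) {
    items[[paste0("conn", j)]] <- conn_items[, j]
  }
  items <- items[c("student_id", paste0("eda", 1:3), paste0("ssbi", 1:3),
                   paste0("conn", 1:5))]

  # per-scale missingness: a respondent leaves one item of the scale blank
  blank_one <- function(cols, p) {
    hit <- runif(np) < p
    slot <- sample(seq_along(cols), np, replace = TRUE)
    for (j in seq_along(cols)) {
      items[[cols[j]]][hit & slot == j] <<- NA_real_
    }
  }
  blank_one(paste0("eda", 1:3), config$missing["engagement"])
  blank_one(paste0("ssbi", 1:2), config$missing["burnout"])

  rownames(items) <- NULL
  attr(items, "truth") <- list(
    planted = list(burnout = as.list(config$betas_burnout),
                   engagement = as.list(config$betas_engagement)),
    solved = list(rho_resid = rho_resid, rho_method = rho_method,
                  eps_var_burnout = eps_b2, eps_var_engagement = eps_e2,
                  signal_cov = cov(sig_b, sig_e),
                  item_noise_var = c(burnout = cal_b$item_noise_var,
                                     engagement = cal_e$item_noise_var)),
    schools = data.frame(school_id = schools, climate = unname(climate),
                         u_burnout = unname(u_b), u_engagement = unname(u_e),
                         school_connectedness =
                           as.numeric(school_conn[schools]),
                         stringsAsFactors = FALSE),
    students = data.frame(student_id = part$student_id,
                          latent_burnout = T_b, latent_engagement = T_e,
                          latent_connectedness = conn_lat,
                          stringsAsFactors = FALSE)
  )
  items
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generative model - roster, nominations, within-school
#' networks, item responses - from a single seeded RNG, so that identical
#' `(config, seed)` yield identical datasets (byte-identical CSV files when
#' written). The ground truth (planted effects, latent scores, solved
#' residual-correlation parameters, designated isolates) is returned
#' alongside and is never read by the analysis pipeline.
#'
#' @param config a [synth_config()].
#' @param dir optional directory; when given, `roster.csv`,
#'   `nominations.csv`, `items.csv`, `truth.json` and `manifest.json` are
#'   written there.
#' @return An object of class `peer_cohort`: list with `roster`,
#'   `nominations`, `items`, `networks`, `truth`, `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(synth_config(seed = 7, n_countries = 2,
#'   schools_per_country = 2, students_per_school = 60))
#' sapply(cohort$networks, function(nw) nrow(nw$edges))
generate_cohort <- function(config = synth_config(), dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  roster <- sample_roster(config)
  nominations <- sample_nominations(roster, config)
  schools <- sort(unique(roster$school_id))
  networks <- lapply(schools, function(s) build_network(roster, nominations, s))
  names(networks) <- schools
  items <- sample_items(roster, networks, config)

  truth <- attr(items, "truth")
  nm_truth <- attr(nominations, "truth")
  truth$students <- merge(truth$students, nm_truth, by = "student_id",
                          all = TRUE, sort = TRUE)
  attr(items, "truth") <- NULL
  attr(nominations, "truth") <- NULL

  cohort <- structure(list(roster = roster, nominations = nominations,
                           items = items, networks = networks, truth = truth,
                           config = config),
                      class = "peer_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.peer_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic school cohort: %d students in %d schools ",
                     "(%d countries), %d nominations, seed %d\n"),
              nrow(x$roster), length(x$networks),
              length(unique(x$roster$country_code)), nrow(x$nominations),
              x$config$seed))
  invisible(x)
}

#' Simulate items of one scale in isolation
#'
#' Draws `n` respondents' items for one scale under the parallel-item model
#' at the configured reliability and score targets, without any network
#' structure - the direct way to study the psychometric layer (for example,
#' the Cronbach's alpha implied by a reliability setting after
#' discretization).
#'
#' @param n number of respondents.
#' @param scale `"engagement"` (3 items on 0-5) or `"burnout"` (2 items on
#'   1-6).
#' @param config a [synth_config()]; the caller seeds the RNG.
#' @param rho optional override of the latent inter-item correlation.
#' @return Numeric matrix `n x k` of discretized items.
#' @export
simulate_scale_items <- function(n, scale = c("engagement", "burnout"),
                                 config = synth_config(), rho = NULL) {
  scale <- match.arg(scale)
  tg <- config$score_targets[[scale]]
  k <- if (scale == "engagement") 3L else 2L
  rng <- if (scale == "engagement") c(0, 5) else c(1, 6)
  rho <- rho %||% min(0.999, config$reliability[[scale]] *
                        .grid_comp$rho_gain[[scale]])
  cal <- .scale_calibration(tg["mean"], tg["sd"], rho, k)
  t_score <- rnorm(n, cal$mean, sqrt(cal$true_var))
  latent <- .grid_inverse(t_score, sqrt(cal$item_noise_var), rng[1], rng[2])
  items <- vapply(seq_len(k), function(j) {
    .discretize(latent + rnorm(n, 0, sqrt(cal$item_noise_var)),
                rng[1], rng[2])
  }, numeric(n))
  colnames(items) <- paste0(if (scale == "engagement") "eda" else "ssbi",
                            seq_len(k))
  items
}
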