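# Scale scoring. All four instruments are scored with complete-case rules:
# a score exists only when every contributing item was answered. Burnout is
# the one positional scale: only items 1 (inadequacy) and 2 (cynicism) enter
# the score; item 3 (exhaustion) is excluded because its consistency with the
# first two is too poor to pool.

.as_items <- function(x, k, what) {
  if (is.null(dim(x))) {
    if (length(x) %% k != 0) {
      stop(what, " expects ", k, " items per respondent", call. = FALSE)
    }
    x <- matrix(as.numeric(x), ncol = k, byrow = FALSE,
                nrow = length(x) / k)
    if (nrow(x) == 1 || length(x) == k) x <- matrix(as.numeric(x), ncol = k)
  }
  x <- as.matrix(x)
  if (ncol(x) < k) stop(what, " expects ", k, " item columns", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Score schoolwork engagement (EDA-3)
#'
#' Mean of the three engagement items (absorption, energy, dedication), each
#' on 0 = "Never" to 5 = "Daily". Complete-case: the score is missing
#' whenever any of the three items is missing.
#'
#' @param eda_items numeric vector of 3 items (one respondent) or a matrix /
#'   data.frame with 3 columns (one row per respondent).
#' @return Numeric vector of scores in `[0, 5]`, `NA` where incomplete.
#' @export
#' @examples
#' score_engagement(c(0, 2, 4))        # 2
#' score_engagement(c(1, NA, 3))       # NA: all three items are required
score_engagement <- function(eda_items) {
  m <- .as_items(eda_items, 3, "score_engagement")
  rowMeans(m[, 1:3, drop = FALSE])
}

#' Score school burnout (SSBI, items 1-2)
#'
#' Mean of burnout items 1 (inadequacy) and 2 (cynicism), each on
#' 1 = "Completely disagree" to 6 = "Completely agree". Item 3 (exhaustion)
#' is ignored entirely; the score is missing if item 1 or item 2 is missing.
#' Item order is therefore meaningful for this scale, unlike the others.
#'
#' @param ssbi_items numeric vector of 2 or 3 items, or a matrix /
#'   data.frame whose first two columns are items 1 and 2.
#' @return Numeric vector of scores in `[1, 6]`, `NA` where incomplete.
#' @export
#' @examples
#' score_burnout(c(4, 2, 6))   # 3: item 3 never enters
#' score_burnout(c(1, 1, NA))  # 1
score_burnout <- function(ssbi_items) {
  if (is.null(dim(ssbi_items)) && length(ssbi_items) %in% c(2, 3)) {
    ssbi_items <- matrix(as.numeric(ssbi_items), nrow = 1)
  }
  m <- as.matrix(ssbi_items)
  if (ncol(m) < 2) stop("score_burnout expects at least 2 item columns",
                        call. = FALSE)
  storage.mode(m) <- "double"
  (m[, 1] + m[, 2]) / 2
}

#' Score school connectedness
#'
#' Mean of the five connectedness items (feeling close to people at school,
#' happy, part of the school, fairly treated by teachers, safe), each on
#' 1 = "strongly disagree" to 4 = "strongly agree". Complete-case.
#'
#' @param conn_items numeric vector of 5 items or a matrix / data.frame with
#'   5 columns.
#' @return Numeric vector of scores in `[1, 4]`, `NA` where incomplete.
#' @export
score_connectedness <- function(conn_items) {
  m <- .as_items(conn_items, 5, "score_connectedness")
  rowMeans(m[, 1:5, drop = FALSE])
}

#' Score family affluence (FAS)
#'
#' Sum of the four family-affluence items (each 0--3 here), a household
#' socioeconomic-status proxy. Complete-case; the sum score is the default
#' (no tertile categorisation).
#'
#' @param fas_items numeric vector of 4 items or a matrix / data.frame with
#'   4 columns.
#' @return Numeric vector of sum scores, `NA` where incomplete.
#' @export
score_fas <- function(fas_items) {
  m <- .as_items(fas_items, 4, "score_fas")
  rowSums(m[, 1:4, drop = FALSE])
}

#' Score all scales for a cohort
#'
#' Applies the four scale scorers to an item table (and, for family
#' affluence, to the roster's `fas1`..`fas4` columns).
#'
#' @param items item table from [read_items()] or [generate_cohort()].
#' @param roster optional roster; when given, a `fas` column is added.
#' @return A `data.frame` with columns `student_id`, `engagement`,
#'   `burnout`, `connectedness` and (if a roster was given) `fas`.
#' @export
score_scales <- function(items, roster = NULL) {
  out <- data.frame(
    student_id = items$student_id,
    engagement = score_engagement(items[.pw_item_cols$eda]),
    burnout = score_burnout(items[.pw_item_cols$ssbi]),
    connectedness = score_connectedness(items[.pw_item_cols$conn]),
    stringsAsFactors = FALSE
  )
  if (!is.null(roster)) {
    fas <- score_fas(roster[.pw_item_cols$fas])
    out$fas <- fas[match(out$student_id, roster$student_id)]
  }
  out
}

#' School-level connectedness climate
#'
#' Unweighted mean of the student connectedness scores over the
#' participating students of each school that have a score; the school value
#' ranges from 1 to 4 and serves as the school's connectedness climate in
#' the analysis models.
#'
#' @param scores per-student scores from [score_scales()].
#' @param roster roster giving `school_id` and participation.
#' @return A `data.frame` with `school_id`, `mean_connectedness`,
#'   `n_scored`. Schools with no scorable student get `NA` with a warning.
#' @export
school_connectedness <- function(scores, roster) {
  part <- roster[roster$participated, c("student_id", "school_id")]
  part$connectedness <- scores$connectedness[
    match(part$student_id, scores$student_id)]
  schools <- sort(unique(roster$school_id))
  vals <- vapply(schools, function(s) {
    x <- part$connectedness[part$school_id == s]
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, 0))
    c(mean(x), length(x))
  }, numeric(2))
  out <- data.frame(school_id = schools, mean_connectedness = vals[1, ],
                    n_scored = as.integer(vals[2, ]), stringsAsFactors = FALSE)
  if (anyNA(out$mean_connectedness)) {
    warning("school(s) with no scorable connectedness: ",
            paste(out$school_id[is.na(out$mean_connectedness)],
                  collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale,
#' \eqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_j s_j^2}{s_T^2}\right)},
#' where \eqn{s_j^2} are the sample item variances and \eqn{s_T^2} the sample
#' variance of the item sums (both with the \eqn{n-1} denominator). Computed
#' on complete cases only; the `n` actually used is attached as an attribute.
#'
#' @param item_matrix numeric matrix or data.frame, respondents in rows,
#'   items in columns (`k >= 2`); rows with any missing item are dropped.
#' @return The alpha value with attributes `k` and `n`.
#' @export
#' @examples
#' set.seed(1)
#' t_score <- rnorm(500)
#' items <- sapply(1:3, function(j) t_score + rnorm(500))
#' cronbach_alpha(items)
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  storage.mode(m) <- "double"
  m <- m[complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  n <- nrow(m)
  if (k < 2) stop("cronbach_alpha needs at least 2 items", call. = FALSE)
  if (n < 2) stop("cronbach_alpha needs at least 2 complete cases",
                  call. = FALSE)
  total_var <- var(rowSums(m))
  if (total_var == 0) {
    stop("total-score variance is zero; alpha is undefined", call. = FALSE)
  }
  item_vars <- apply(m, 2, var)
  alpha <- (k / (k - 1)) * (1 - sum(item_vars) / total_var)
  structure(alpha, k = k, n = n)
}

#' Reliability report for the cohort scales
#'
#' Cronbach's alpha for each multi-item scale as scored by the pipeline:
#' the 3 engagement items, burnout items 1--2, the 5 connectedness items and
#' the 4 family-affluence items; complete cases per scale.
#'
#' @inheritParams score_scales
#' @return A `data.frame` with columns `scale`, `k`, `n`, `alpha`.
#' @export
reliability_report <- function(items, roster = NULL) {
  sets <- list(
    engagement = items[.pw_item_cols$eda],
    burnout = items[.pw_item_cols$ssbi][, 1:2],
    connectedness = items[.pw_item_cols$conn]
  )
  if (!is.null(roster)) {
    sets$fas <- roster[roster$participated, .pw_item_cols$fas]
  }
  rows <- lapply(names(sets), function(nm) {
    a <- cronbach_alpha(sets[[nm]])
    data.frame(scale = nm, k = attr(a, "k"), n = attr(a, "n"),
               alpha = as.numeric(a), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
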