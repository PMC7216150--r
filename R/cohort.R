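# Reading, cleaning and validating the three cohort tables:
#   roster.csv       one row per registered student in the two surveyed grades
#   nominations.csv  directed ego -> alter ties, at most five per ego
#   items.csv        survey item responses for participating students
#
# CSV dialect: comma-separated, UTF-8, mandatory header, missing = empty cell.
# All identifiers are opaque strings.

.roster_cols <- c("student_id", "school_id", "country_code", "grade",
                  "class_id", "sex", "age", "participated",
                  paste0("fas", 1:4))
.nomination_cols <- c("ego_id", "alter_id", "rank")
.item_file_cols <- c("student_id", paste0("eda", 1:3), paste0("ssbi", 1:3),
                     paste0("conn", 1:5))

.check_header <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file '", path, "' is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

.as_num <- function(x) suppressWarnings(as.numeric(x))

# coerce to numeric and blank values outside [lo, hi]; returns list(x, n_bad)
.validate_range <- function(x, lo, hi) {
  num <- .as_num(x)
  bad_parse <- !is.na(x) & x != "" & is.na(num)
  out_of_range <- !is.na(num) & (num < lo | num > hi)
  num[out_of_range] <- NA_real_
  list(x = num, n_bad = sum(bad_parse) + sum(out_of_range))
}

.cleaning_log <- function(df) {
  log <- attr(df, "cleaning")
  if (is.null(log)) integer(0) else log
}

#' Read and validate a student roster
#'
#' Parses `roster.csv` (columns `student_id`, `school_id`, `country_code`,
#' `grade`, `class_id`, `sex`, `age`, `participated`, `fas1`..`fas4`).
#' Every registered student of a school's two surveyed grades has a row,
#' whether or not they answered the survey; non-participants are legitimate
#' nomination targets and therefore legitimate network nodes.
#'
#' Malformed field values are blanked and tallied rather than dropped:
#' ages outside 12--19 and family-affluence items outside 0--3 are set
#' missing with a warning. A duplicated `student_id` is a hard error.
#'
#' @param path path to the roster CSV file.
#' @return A `data.frame` with typed columns (`age` integer years, `grade`
#'   integer, `participated` logical, `fas1`..`fas4` numeric) and a
#'   `"cleaning"` attribute holding named counts of the repairs applied.
#' @export
#' @examples
#' dir <- tempfile(); cohort <- generate_cohort(synth_config(seed = 1,
#'   n_countries = 1, schools_per_country = 1, students_per_school = 40))
#' write_cohort(cohort, dir)
#' roster <- read_roster(file.path(dir, "roster.csv"))
#' table(roster$participated)
read_roster <- function(path) {
  if (!file.exists(path)) stop("roster file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "",
                         check.names = FALSE)
  .check_header(raw, .roster_cols, path)
  raw <- raw[.roster_cols]

  dup <- raw$student_id[duplicated(raw$student_id)]
  if (length(dup)) {
    stop("duplicate student_id in roster: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  log <- c(age_out_of_range = 0L, bad_grade = 0L, bad_sex = 0L,
           bad_participated = 0L, fas_out_of_range = 0L)

  grade <- suppressWarnings(as.integer(raw$grade))
  bad_grade <- is.na(grade) | !(grade %in% c(1L, 2L))
  grade[bad_grade] <- NA_integer_
  log["bad_grade"] <- sum(bad_grade & !is.na(raw$grade))

  sex <- raw$sex
  bad_sex <- !is.na(sex) & !(sex %in% c("female", "male"))
  sex[bad_sex] <- NA_character_
  log["bad_sex"] <- sum(bad_sex)

  age_chk <- .validate_range(raw$age, .pw_ranges$age[1], .pw_ranges$age[2])
  log["age_out_of_range"] <- age_chk$n_bad

  part <- tolower(raw$participated)
  part_lgl <- part %in% c("true", "1", "yes")
  bad_part <- !is.na(part) & !(part %in% c("true", "false", "1", "0", "yes", "no"))
  part_lgl[is.na(part)] <- FALSE
  log["bad_participated"] <- sum(bad_part) + sum(is.na(part))

  fas <- lapply(paste0("fas", 1:4), function(cl) {
    .validate_range(raw[[cl]], .pw_ranges$fas[1], .pw_ranges$fas[2])
  })
  log["fas_out_of_range"] <- sum(vapply(fas, `[[`, 0, "n_bad"))

  out <- data.frame(
    student_id = raw$student_id, school_id = raw$school_id,
    country_code = raw$country_code, grade = grade, class_id = raw$class_id,
    sex = sex, age = age_chk$x, participated = part_lgl,
    stringsAsFactors = FALSE
  )
  for (j in 1:4) out[[paste0("fas", j)]] <- fas[[j]]$x

  if (any(log > 0)) {
    warning("roster cleaning applied: ",
            paste(names(log)[log > 0], log[log > 0], sep = "=", collapse = ", "),
            call. = FALSE)
  }
  attr(out, "cleaning") <- log
  out
}

#' Read and clean a nomination edge list
#'
#' Parses `nominations.csv` (columns `ego_id`, `alter_id`, `rank`) against a
#' roster and applies the cleaning rules of the sociometric instrument: each
#' participant may name up to five schoolmates registered in their own
#' school's two surveyed grades. Rows are dropped (and tallied) when the ego
#' is unknown or did not participate, when the alter is unknown or attends a
#' different school, when ego and alter coincide, or when an (ego, alter)
#' pair repeats; egos with more than five surviving rows are truncated to the
#' five lowest ranks. Cleaning is idempotent.
#'
#' @param path path to the nominations CSV file.
#' @param roster a roster `data.frame` as returned by [read_roster()].
#' @return A `data.frame` with columns `ego_id`, `alter_id`, `rank`
#'   (integer 1--5) and a `"cleaning"` attribute of named drop counts.
#' @export
read_nominations <- function(path, roster) {
  if (!file.exists(path)) stop("nominations file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "",
                         check.names = FALSE)
  .check_header(raw, .nomination_cols, path)
  df <- raw[.nomination_cols]
  df$rank <- suppressWarnings(as.integer(df$rank))
  df$rank[is.na(df$rank)] <- 99L   # unranked rows sort last for truncation
  clean_nominations(df, roster)
}

#' @rdname read_nominations
#' @param nominations a raw nomination `data.frame` (`ego_id`, `alter_id`,
#'   `rank`) to clean in memory.
#' @export
clean_nominations <- function(nominations, roster) {
  df <- nominations
  log <- c(unknown_ego = 0L, nonparticipant_ego = 0L, unknown_alter = 0L,
           cross_school = 0L, self_nomination = 0L, duplicate_pair = 0L,
           over_cap = 0L)

  known <- roster$student_id
  keep <- df$ego_id %in% known
  log["unknown_ego"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  part <- roster$student_id[roster$participated]
  keep <- df$ego_id %in% part
  log["nonparticipant_ego"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  keep <- df$alter_id %in% known
  log["unknown_alter"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  school_of <- setNames(roster$school_id, roster$student_id)
  keep <- school_of[df$ego_id] == school_of[df$alter_id]
  log["cross_school"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  keep <- df$ego_id != df$alter_id
  log["self_nomination"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  # stable order: ego, then rank, then original position; dedup keeps best rank
  df <- df[order(df$ego_id, df$rank), , drop = FALSE]
  keep <- !duplicated(df[c("ego_id", "alter_id")])
  log["duplicate_pair"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  within_ego <- stats::ave(seq_len(nrow(df)), df$ego_id, FUN = seq_along)
  keep <- within_ego <= 5L
  log["over_cap"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  df$rank <- stats::ave(seq_len(nrow(df)), df$ego_id, FUN = seq_along)

  rownames(df) <- NULL
  if (any(log > 0)) {
    warning("nomination cleaning applied: ",
            paste(names(log)[log > 0], log[log > 0], sep = "=", collapse = ", "),
            call. = FALSE)
  }
  attr(df, "cleaning") <- log
  df
}

#' Read and validate survey item responses
#'
#' Parses `items.csv` (columns `student_id`, `eda1`..`eda3`, `ssbi1`..`ssbi3`,
#' `conn1`..`conn5`). Values outside the stated response ranges
#' (engagement 0--5, burnout 1--6, connectedness 1--4) are set missing with a
#' warning; empty cells are missing without warning; rows whose `student_id`
#' is absent from the roster are dropped and tallied.
#'
#' @param path path to the items CSV file.
#' @inheritParams read_nominations
#' @return A `data.frame` of numeric item columns with a `"cleaning"`
#'   attribute of named counts.
#' @export
read_items <- function(path, roster) {
  if (!file.exists(path)) stop("items file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "",
                         check.names = FALSE)
  .check_header(raw, .item_file_cols, path)
  df <- raw[.item_file_cols]

  log <- c(unknown_student = 0L, out_of_range = 0L)
  keep <- df$student_id %in% roster$student_id
  log["unknown_student"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  out <- data.frame(student_id = df$student_id, stringsAsFactors = FALSE)
  for (scale in c("eda", "ssbi", "conn")) {
    rng <- .pw_ranges[[scale]]
    for (cl in .pw_item_cols[[scale]]) {
      chk <- .validate_range(df[[cl]], rng[1], rng[2])
      out[[cl]] <- chk$x
      log["out_of_range"] <- log["out_of_range"] + chk$n_bad
    }
  }
  rownames(out) <- NULL
  if (any(log > 0)) {
    warning("item cleaning applied: ",
            paste(names(log)[log > 0], log[log > 0], sep = "=", collapse = ", "),
            call. = FALSE)
  }
  attr(out, "cleaning") <- log
  out
}

#' Validate a cohort dataset
#'
#' Cross-checks the three cohort tables and assembles a validation report:
#' per-school registration and participation counts, the pooled participation
#' rate, the cleaning tallies carried by the nomination and item tables, item
#' missingness rates, and a count of remaining rule violations (which is zero
#' for a dataset that has passed the readers). A school with fewer than two
#' registered students is a hard error because its network metrics are
#' undefined.
#'
#' @param roster,nominations,items cohort tables as returned by the readers.
#' @return An object of class `cohort_validation`: a list with elements
#'   `schools` (per-school counts), `participation_rate` (percent),
#'   `cleaning` (tallies), `item_missingness` (per item, fraction),
#'   `violations` (named integer vector).
#' @export
validate_cohort <- function(roster, nominations, items) {
  n_school <- table(roster$school_id)
  if (any(n_school < 2)) {
    stop("school(s) with fewer than 2 registered students (network metrics ",
         "undefined): ", paste(names(n_school)[n_school < 2], collapse = ", "),
         call. = FALSE)
  }

  schools <- aggregate(participated ~ school_id, roster,
                       FUN = function(p) c(n = length(p), n_part = sum(p)))
  schools <- data.frame(school_id = schools$school_id,
                        n_registered = schools$participated[, "n"],
                        n_participants = schools$participated[, "n_part"],
                        stringsAsFactors = FALSE)
  schools$participation_pct <-
    100 * schools$n_participants / schools$n_registered

  violations <- c(
    self_nomination = sum(nominations$ego_id == nominations$alter_id),
    duplicate_pair = sum(duplicated(nominations[c("ego_id", "alter_id")])),
    over_cap = sum(table(nominations$ego_id) > 5),
    unknown_ego = sum(!nominations$ego_id %in% roster$student_id),
    unknown_alter = sum(!nominations$alter_id %in% roster$student_id),
    nonparticipant_ego = sum(!nominations$ego_id %in%
                               roster$student_id[roster$participated]),
    unknown_item_student = sum(!items$student_id %in% roster$student_id)
  )
  school_of <- setNames(roster$school_id, roster$student_id)
  ok <- nominations$ego_id %in% roster$student_id &
    nominations$alter_id %in% roster$student_id
  violations["cross_school"] <- sum(
    school_of[nominations$ego_id[ok]] != school_of[nominations$alter_id[ok]])

  item_cols <- setdiff(names(items), "student_id")
  missingness <- vapply(items[item_cols], function(x) mean(is.na(x)), 0)

  out <- list(
    schools = schools,
    participation_rate = 100 * mean(roster$participated),
    cleaning = list(nominations = .cleaning_log(nominations),
                    items = .cleaning_log(items),
                    roster = .cleaning_log(roster)),
    item_missingness = missingness,
    violations = violations
  )
  class(out) <- "cohort_validation"
  out
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort validation report\n")
  cat(sprintf("  schools: %d, registered students: %d, participation: %.1f%%\n",
              nrow(x$schools), sum(x$schools$n_registered),
              x$participation_rate))
  cat(sprintf("  remaining rule violations: %d\n", sum(x$violations)))
  if (sum(x$violations) > 0) {
    v <- x$violations[x$violations > 0]
    cat("   ", paste(names(v), v, sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  item missingness: %.1f%% (max over items)\n",
              100 * max(x$item_missingness)))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `roster.csv`, `nominations.csv` and `items.csv` (plus, for
#' synthetic cohorts, `truth.json` with the generating ground truth) into a
#' directory, together with a `manifest.json` binding the three files.
#' Writing then reading a valid dataset reproduces it field for field.
#'
#' @param cohort a list with elements `roster`, `nominations`, `items` and
#'   optionally `truth`/`config` (see [generate_cohort()]), or a roster
#'   `data.frame` when `nominations` and `items` are given separately.
#' @param dir output directory, created if needed.
#' @param nominations,items optional tables when `cohort` is a roster.
#' @return Invisibly, the manifest as a list.
#' @export
write_cohort <- function(cohort, dir, nominations = NULL, items = NULL) {
  if (is.data.frame(cohort)) {
    cohort <- list(roster = cohort, nominations = nominations, items = items)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(roster = file.path(dir, "roster.csv"),
             nominations = file.path(dir, "nominations.csv"),
             items = file.path(dir, "items.csv"))
  utils::write.csv(cohort$roster, paths["roster"], row.names = FALSE, na = "")
  utils::write.csv(cohort$nominations, paths["nominations"],
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$items, paths["items"], row.names = FALSE, na = "")
  manifest <- list(
    files = as.list(basename(paths)),
    n_students = nrow(cohort$roster),
    n_nominations = nrow(cohort$nominations),
    n_item_rows = nrow(cohort$items),
    package_version = as.character(utils::packageVersion("peerwell"))
  )
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$files <- c(manifest$files, "truth.json")
  }
  if (!is.null(cohort$config)) {
    manifest$seed <- cohort$config$seed
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
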