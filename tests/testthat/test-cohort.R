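# Readers, cleaning rules and validation for the three cohort tables.

make_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

roster_header <- paste(c("student_id", "school_id", "country_code", "grade",
                         "class_id", "sex", "age", "participated",
                         paste0("fas", 1:4)), collapse = ",")

test_that("a well-formed roster parses row for row", {
  path <- make_csv(c(
    roster_header,
    "a1,S1,BE,1,S1-c1,female,15,TRUE,1,2,0,3",
    "a2,S1,BE,1,S1-c1,male,14,TRUE,0,0,1,1",
    "a3,S1,BE,2,S1-c2,female,16,FALSE,2,3,3,2"))
  roster <- read_roster(path)
  expect_equal(nrow(roster), 3)
  expect_equal(roster$student_id, c("a1", "a2", "a3"))
  expect_equal(roster$age, c(15, 14, 16))
  expect_equal(roster$participated, c(TRUE, TRUE, FALSE))
  expect_equal(roster$fas3, c(0, 1, 3))
  expect_true(all(attr(roster, "cleaning") == 0))
})

test_that("a duplicated student id is a hard error naming the id", {
  path <- make_csv(c(
    roster_header,
    "a1,S1,BE,1,S1-c1,female,15,TRUE,1,2,0,3",
    "a1,S1,BE,1,S1-c1,male,14,TRUE,0,0,1,1"))
  expect_error(read_roster(path), "a1")
})

test_that("out-of-range age is kept as a record, blanked and warned about", {
  path <- make_csv(c(
    roster_header,
    "a1,S1,BE,1,S1-c1,female,25,TRUE,1,2,0,3",
    "a2,S1,BE,1,S1-c1,male,14,TRUE,0,0,1,1"))
  expect_warning(roster <- read_roster(path), "age_out_of_range")
  expect_equal(nrow(roster), 2)
  expect_true(is.na(roster$age[1]))
  expect_equal(unname(attr(roster, "cleaning")["age_out_of_range"]), 1L)
})

test_that("missing columns are reported by name", {
  path <- make_csv(c("student_id,school_id", "a1,S1"))
  expect_error(read_roster(path), "country_code")
})

nom_fixture_roster <- function() {
  r <- toy_roster(c("a", "b", "c", "d", "e"), school = "S1")
  r2 <- toy_roster(c("x", "y"), school = "S2")
  r <- rbind(r, r2)
  r$participated[r$student_id == "e"] <- FALSE
  r
}

test_that("nomination cleaning: dedup, self-loops, cap, cross-school, unknowns", {
  roster <- nom_fixture_roster()
  raw <- data.frame(
    ego_id = c("a", "a", "a",      # duplicate pair a->b
               "b", "b",           # self-loop + valid
               "c", "c", "c", "c", "c", "c",  # 6 ranked -> keep 5
               "zz",               # unknown ego
               "e",                # non-participating ego
               "d"),               # cross-school alter
    alter_id = c("b", "b", "c",
                 "b", "a",
                 "a", "b", "d", "e", "x2", "y2",
                 "a",
                 "a",
                 "x"),
    rank = c(1, 2, 3, 1, 2, 1, 2, 3, 4, 5, 6, 1, 1, 1),
    stringsAsFactors = FALSE)
  raw$alter_id[raw$alter_id == "x2"] <- "x"   # cross-school rows for ego c
  raw$alter_id[raw$alter_id == "y2"] <- "y"
  expect_warning(cleaned <- clean_nominations(raw, roster))
  log <- attr(cleaned, "cleaning")
  expect_equal(unname(log["duplicate_pair"]), 1L)
  expect_equal(unname(log["self_nomination"]), 1L)
  expect_equal(unname(log["unknown_ego"]), 1L)
  expect_equal(unname(log["nonparticipant_ego"]), 1L)
  expect_equal(unname(log["cross_school"]), 3L)
  expect_equal(sort(cleaned$alter_id[cleaned$ego_id == "a"]), c("b", "c"))
  expect_equal(cleaned$alter_id[cleaned$ego_id == "b"], "a")
  expect_true(all(table(cleaned$ego_id) <= 5))
  expect_false(any(cleaned$ego_id == cleaned$alter_id))
})

test_that("an ego with six ranked nominations keeps the first five by rank", {
  roster <- toy_roster(letters[1:8])
  raw <- data.frame(ego_id = "a", alter_id = letters[2:7], rank = 6:1,
                    stringsAsFactors = FALSE)
  expect_warning(cleaned <- clean_nominations(raw, roster), "over_cap")
  expect_equal(nrow(cleaned), 5)
  # rank 6 (alter b) is the one dropped
  expect_false("b" %in% cleaned$alter_id)
})

test_that("cleaning is idempotent", {
  cohort <- generate_cohort(tiny_config())
  once <- cohort$nominations
  again <- clean_nominations(once, cohort$roster)
  attr(again, "cleaning") <- NULL
  attr(once, "cleaning") <- NULL
  expect_equal(again, once)
})

test_that("item values outside their ranges are blanked with a warning", {
  roster <- toy_roster(c("a", "b"))
  path <- make_csv(c(
    "student_id,eda1,eda2,eda3,ssbi1,ssbi2,ssbi3,conn1,conn2,conn3,conn4,conn5",
    "a,0,5,3,1,7,2,1,4,2,3,1",
    "b,2,,4,6,6,6,5,1,1,1,1"))
  expect_warning(items <- read_items(path, roster), "out_of_range")
  expect_equal(items$eda1, c(0, 2))
  expect_true(is.na(items$ssbi2[1]))   # 7 out of 1-6
  expect_true(is.na(items$eda2[2]))    # empty cell
  expect_true(is.na(items$conn1[2]))   # 5 out of 1-4
  expect_equal(unname(attr(items, "cleaning")["out_of_range"]), 2L)
})

test_that("item rows for unknown students are dropped and tallied", {
  roster <- toy_roster("a")
  path <- make_csv(c(
    "student_id,eda1,eda2,eda3,ssbi1,ssbi2,ssbi3,conn1,conn2,conn3,conn4,conn5",
    "a,1,1,1,1,1,1,1,1,1,1,1",
    "ghost,1,1,1,1,1,1,1,1,1,1,1"))
  expect_warning(items <- read_items(path, roster), "unknown_student")
  expect_equal(items$student_id, "a")
})

test_that("validation reports participation and flags degenerate schools", {
  roster <- toy_roster(sprintf("s%03d", 1:100))
  roster$participated <- rep(c(TRUE, FALSE), times = c(79, 21))
  noms <- data.frame(ego_id = character(), alter_id = character(),
                     rank = integer(), stringsAsFactors = FALSE)
  items <- data.frame(student_id = roster$student_id[1])
  for (cl in c(paste0("eda", 1:3), paste0("ssbi", 1:3), paste0("conn", 1:5))) {
    items[[cl]] <- 1
  }
  rep <- validate_cohort(roster, noms, items)
  expect_equal(rep$participation_rate, 79)
  expect_equal(sum(rep$violations), 0)

  solo <- rbind(roster, toy_roster("only-one", school = "S9"))
  expect_error(validate_cohort(solo, noms, items), "fewer than 2")
})

test_that("writing then reading a cohort reproduces it field for field", {
  cohort <- generate_cohort(tiny_config(seed = 7))
  p <- write_temp_cohort(cohort)
  roster <- read_roster(p$roster)
  noms <- read_nominations(p$nominations, roster)
  items <- read_items(p$items, roster)
  expect_equal(roster, cohort$roster, ignore_attr = TRUE)
  expect_equal(noms, cohort$nominations, ignore_attr = TRUE)
  expect_equal(items, cohort$items, ignore_attr = TRUE)
  # and validation of the already-clean dataset finds nothing to fix
  rep <- validate_cohort(roster, noms, items)
  expect_equal(sum(rep$violations), 0)
})
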