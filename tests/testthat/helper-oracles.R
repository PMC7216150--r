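# Brute-force reference implementations of the network metrics (plain loops
# over node/edge/pair sets, independent of the package's vectorized code)
# and small fixture builders shared across test files.

bf_density <- function(nodes, edges) {
  n <- length(nodes)
  100 * nrow(edges) / (n * (n - 1))
}

bf_in_degrees <- function(nodes, edges) {
  vapply(nodes, function(v) sum(edges$alter_id == v), 0L)
}

bf_centralization_in <- function(nodes, edges) {
  n <- length(nodes)
  d <- bf_in_degrees(nodes, edges)
  100 * sum(max(d) - d) / (n - 1)^2
}

bf_ego_clustering <- function(nodes, edges, ego) {
  alters <- edges$alter_id[edges$ego_id == ego]
  a <- length(alters)
  if (a < 2) return(NA_real_)
  m <- 0L
  for (x in alters) for (y in alters) {
    if (x != y && any(edges$ego_id == x & edges$alter_id == y)) m <- m + 1L
  }
  100 * m / (a * (a - 1))
}

bf_avg_clustering <- function(nodes, edges) {
  vals <- vapply(nodes, function(v) bf_ego_clustering(nodes, edges, v), 0)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

# a one-school roster over given student ids
toy_roster <- function(ids, school = "S1", participated = TRUE) {
  n <- length(ids)
  df <- data.frame(
    student_id = ids, school_id = school, country_code = "XX",
    grade = rep(1:2, length.out = n),
    class_id = paste0(school, "-c", rep(1:2, length.out = n)),
    sex = rep(c("female", "male"), length.out = n),
    age = 15, participated = rep_len(participated, n),
    stringsAsFactors = FALSE)
  for (j in 1:4) df[[paste0("fas", j)]] <- 1
  df
}

toy_edges <- function(...) {
  pairs <- list(...)
  data.frame(ego_id = vapply(pairs, `[`, "", 1),
             alter_id = vapply(pairs, `[`, "", 2),
             rank = unlist(lapply(vapply(pairs, `[`, "", 1), function(x) 1L)),
             stringsAsFactors = FALSE)
}

toy_network <- function(ids, edges, school = "S1") {
  build_network(toy_roster(ids, school), edges, school)
}

# random directed graph with the survey's out-degree cap, as an edge table
random_edges <- function(ids, max_out = 5) {
  n <- length(ids)
  rows <- list()
  for (i in seq_len(n)) {
    k <- sample(0:min(max_out, n - 1), 1)
    if (k == 0) next
    alters <- sample(ids[-i], k)
    rows[[length(rows) + 1]] <- data.frame(
      ego_id = ids[i], alter_id = alters, rank = seq_len(k),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(ego_id = character(), alter_id = character(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# small synthetic cohort used by the pipeline-level tests
tiny_config <- function(seed = 42, ...) {
  synth_config(seed = seed, n_countries = 2L, schools_per_country = 2L,
               students_per_school = 60L, classes_per_grade = 2L, ...)
}

# write a cohort's tables to a temp dir and return the paths
write_temp_cohort <- function(cohort) {
  dir <- tempfile("cohort")
  write_cohort(cohort, dir)
  list(dir = dir,
       roster = file.path(dir, "roster.csv"),
       nominations = file.path(dir, "nominations.csv"),
       items = file.path(dir, "items.csv"))
}
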