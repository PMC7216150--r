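# Directed within-school nomination networks and the structural indicators
# used in the analysis. The node set is ALL students registered in the
# school's two surveyed grades, including non-respondents (who can receive
# nominations); metrics are computed directly from the edge table so that
# igraph can serve as an independent cross-check in the tests.

#' Build a within-school nomination network
#'
#' Assembles the directed nomination graph of one school: nodes are all
#' registered students of that school's two surveyed grades (participants
#' and non-participants alike), edges are the cleaned ego-to-alter
#' nominations between them. Self-loops and parallel edges are removed
#' defensively, so building from an already clean edge list changes nothing.
#'
#' @param roster roster `data.frame` from [read_roster()].
#' @param nominations cleaned nomination `data.frame`.
#' @param school_id school to build; must occur in the roster.
#' @return An object of class `nomination_network`: a list with
#'   `school_id`, `nodes` (character vector), `edges` (`data.frame` with
#'   `ego_id`, `alter_id`) and `n` (node count).
#' @export
build_network <- function(roster, nominations, school_id) {
  nodes <- roster$student_id[roster$school_id == school_id]
  if (!length(nodes)) stop("school not in roster: ", school_id, call. = FALSE)
  e <- nominations[nominations$ego_id %in% nodes &
                     nominations$alter_id %in% nodes,
                   c("ego_id", "alter_id"), drop = FALSE]
  e <- e[e$ego_id != e$alter_id, , drop = FALSE]
  e <- e[!duplicated(e), , drop = FALSE]
  if (nrow(e) && max(table(e$ego_id)) > 5) {
    stop("out-degree cap of 5 violated in school ", school_id,
         "; clean the nominations first", call. = FALSE)
  }
  rownames(e) <- NULL
  structure(list(school_id = school_id, nodes = nodes, edges = e,
                 n = length(nodes)),
            class = "nomination_network")
}

#' @export
print.nomination_network <- function(x, ...) {
  cat(sprintf("Nomination network of school %s: %d students, %d ties\n",
              x$school_id, x$n, nrow(x$edges)))
  invisible(x)
}

#' Convert a nomination network to an igraph object
#'
#' @param network a `nomination_network`.
#' @return An [igraph::graph] with the full registered node set.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = network$nodes)
}

.degrees <- function(network) {
  idx_out <- match(network$edges$ego_id, network$nodes)
  idx_in <- match(network$edges$alter_id, network$nodes)
  list(out = tabulate(idx_out, nbins = network$n),
       `in` = tabulate(idx_in, nbins = network$n))
}

#' Ego network positions
#'
#' Per-student position in the school network: social activity (out-degree,
#' the number of schoolmates nominated, capped at five by the instrument),
#' popularity (in-degree, nominations received, uncapped) and the isolation
#' flag (no incoming and no outgoing ties). Degrees are computed on the full
#' registered node set.
#'
#' @param network a `nomination_network`.
#' @return A `data.frame` with `student_id`, `out_degree`, `in_degree`,
#'   `isolated`.
#' @export
ego_positions <- function(network) {
  d <- .degrees(network)
  data.frame(student_id = network$nodes,
             out_degree = d$out, in_degree = d$`in`,
             isolated = d$out == 0L & d$`in` == 0L,
             stringsAsFactors = FALSE)
}

#' Percentage of isolated students
#'
#' Share of students with neither incoming nor outgoing nominations. The
#' denominator is the participating students (a non-respondent necessarily
#' has out-degree zero, so counting them would conflate isolation with
#' non-response); pass `participants = NULL` to use all nodes instead.
#'
#' @param positions ego positions from [ego_positions()].
#' @param participants character vector of participating student ids, or
#'   `NULL` for all.
#' @return Percentage in `[0, 100]`.
#' @export
pct_isolated <- function(positions, participants = NULL) {
  x <- positions
  if (!is.null(participants)) x <- x[x$student_id %in% participants, ]
  100 * mean(x$isolated)
}

#' Network density
#'
#' Realized directed ties as a percentage of all ordered pairs:
#' \eqn{100 \cdot E / (n (n - 1))}. 0 means no ties; 100 means every student
#' nominated every other student.
#'
#' @param network a `nomination_network` with at least 2 nodes.
#' @return Percentage in `[0, 100]`.
#' @export
net_density <- function(network) {
  n <- network$n
  if (n < 2) stop("density undefined for networks with fewer than 2 nodes",
                  call. = FALSE)
  100 * nrow(network$edges) / (n * (n - 1))
}

#' Freeman degree centralization
#'
#' Concentration of nominations on a few students:
#' \eqn{100 \cdot \sum_i (c_{\max} - c_i) / (n-1)^2}, with \eqn{c_i} the
#' in-degree of student \eqn{i} by default. 0 for degree-regular networks
#' (every student with the same number of nominations); 100 when a single
#' student receives a nomination from every other student and no other tie
#' exists (the in-star). In-degree is the default direction because
#' nominations received are the unbounded, inequality-bearing quantity
#' (out-degree is capped at five by the instrument); `mode = "out"` and
#' `mode = "total"` variants are provided for sensitivity analyses, the
#' total-degree variant being normalised by its own maximum
#' \eqn{2 (n-1)(n-2)} (attained by the mutual star).
#'
#' @param network a `nomination_network` with at least 3 nodes.
#' @param mode degree direction: `"in"` (default), `"out"` or `"total"`.
#' @return Percentage in `[0, 100]`.
#' @export
net_centralization <- function(network, mode = c("in", "out", "total")) {
  mode <- match.arg(mode)
  n <- network$n
  if (n < 3) stop("centralization undefined for networks with fewer than ",
                  "3 nodes", call. = FALSE)
  d <- .degrees(network)
  deg <- switch(mode, "in" = d$`in`, "out" = d$out,
                "total" = d$`in` + d$out)
  denom <- switch(mode, "in" = (n - 1)^2, "out" = (n - 1)^2,
                  "total" = 2 * (n - 1) * (n - 2))
  100 * sum(max(deg) - deg) / denom
}

# index-based helpers shared by the clustering functions
.alter_index <- function(network) {
  ei <- match(network$edges$ego_id, network$nodes)
  ai <- match(network$edges$alter_id, network$nodes)
  list(ei = ei, ai = ai, out = split(ai, factor(ei, levels = seq_len(network$n))))
}

.adjacency <- function(network) {
  a <- matrix(FALSE, network$n, network$n)
  if (nrow(network$edges)) {
    a[cbind(match(network$edges$ego_id, network$nodes),
            match(network$edges$alter_id, network$nodes))] <- TRUE
  }
  a
}

#' Ego-network clustering
#'
#' Density of ties among an ego's alters: the alter set is the ego's
#' out-neighbours (the schoolmates the ego wants to do schoolwork with), and
#' the value is \eqn{100 \cdot m / (a (a - 1))} where \eqn{m} counts the
#' directed ties among the \eqn{a} alters. Egos with fewer than two alters
#' are excluded (`NA`): the tie density of an empty pair set is undefined.
#'
#' @param network a `nomination_network`.
#' @param ego student id of the ego; must be a node.
#' @return Percentage in `[0, 100]`, or `NA` for egos with `< 2` alters.
#' @export
ego_clustering <- function(network, ego) {
  if (!ego %in% network$nodes) stop("ego not in network: ", ego, call. = FALSE)
  alters <- network$edges$alter_id[network$edges$ego_id == ego]
  a <- length(alters)
  if (a < 2) return(NA_real_)
  m <- sum(network$edges$ego_id %in% alters &
             network$edges$alter_id %in% alters)
  100 * m / (a * (a - 1))
}

#' Average ego-network clustering of a school
#'
#' Unweighted mean of [ego_clustering()] over the eligible egos (those with
#' at least two alters); captures network closure, i.e. how often the
#' schoolmates one wants to work with also want to work with each other.
#'
#' @param network a `nomination_network`.
#' @return Percentage in `[0, 100]`; `NA` with a warning when no ego is
#'   eligible.
#' @export
avg_clustering <- function(network) {
  vals <- .all_ego_clustering(network)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) {
    warning("no ego with >= 2 alters in school ", network$school_id,
            call. = FALSE)
    return(NA_real_)
  }
  mean(vals)
}

# clustering for every node at once (adjacency-matrix backed, O(sum a^2))
.all_ego_clustering <- function(network) {
  adj <- .adjacency(network)
  idx <- .alter_index(network)
  vapply(seq_len(network$n), function(i) {
    v <- idx$out[[i]]
    a <- length(v)
    if (a < 2) return(NA_real_)
    100 * sum(adj[v, v]) / (a * (a - 1))
  }, 0)
}

#' Summarize one school's network
#'
#' Assembles the school-level row used throughout the analysis: node count,
#' density, in-degree centralization, average ego clustering, percentage of
#' isolated participants and the school connectedness climate.
#'
#' @param network a `nomination_network`.
#' @param roster roster (for participation).
#' @param scores optional per-student scores from [score_scales()]; needed
#'   for `mean_connectedness`.
#' @param centralization_mode degree direction passed to
#'   [net_centralization()].
#' @return A one-row `data.frame` with columns `school_id`, `n_nodes`,
#'   `density_pct`, `centralization_pct`, `clustering_pct`, `pct_isolated`,
#'   `mean_connectedness`.
#' @export
summarize_school <- function(network, roster, scores = NULL,
                             centralization_mode = "in") {
  pos <- ego_positions(network)
  part <- roster$student_id[roster$participated &
                              roster$school_id == network$school_id]
  conn <- NA_real_
  if (!is.null(scores)) {
    x <- scores$connectedness[scores$student_id %in% part]
    x <- x[!is.na(x)]
    if (length(x)) conn <- mean(x)
  }
  clustering <- if (nrow(network$edges)) {
    suppressWarnings(avg_clustering(network))
  } else {
    NA_real_
  }
  data.frame(
    school_id = network$school_id,
    n_nodes = network$n,
    density_pct = net_density(network),
    centralization_pct = net_centralization(network, centralization_mode),
    clustering_pct = clustering,
    pct_isolated = pct_isolated(pos, part),
    mean_connectedness = conn,
    stringsAsFactors = FALSE
  )
}

#' Summarize every school in a cohort
#'
#' @param roster,nominations cohort tables.
#' @param scores optional per-student scores.
#' @inheritParams summarize_school
#' @return A `data.frame` with one row per school (see
#'   [summarize_school()]).
#' @export
summarize_schools <- function(roster, nominations, scores = NULL,
                              centralization_mode = "in") {
  schools <- sort(unique(roster$school_id))
  rows <- lapply(schools, function(s) {
    summarize_school(build_network(roster, nominations, s), roster, scores,
                     centralization_mode)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ego positions for every school in a cohort
#'
#' @inheritParams summarize_schools
#' @return A `data.frame` of [ego_positions()] rows for all registered
#'   students, with a `school_id` column.
#' @export
cohort_positions <- function(roster, nominations) {
  schools <- sort(unique(roster$school_id))
  rows <- lapply(schools, function(s) {
    p <- ego_positions(build_network(roster, nominations, s))
    p$school_id <- s
    p
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
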