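#' Pairwise co-detection scores between cell states
#'
#' The co-detection score of two states is the Pearson correlation of their
#' per-spot predicted proportions: states that repeatedly occupy the same
#' spots score high. Two aggregation modes are provided because
#' between-section composition shifts can manufacture correlation when
#' spots are pooled naively: `per_section_weighted` (default) computes the
#' correlation within each section and averages across sections weighted by
#' unmasked spot count; `pooled` concatenates all unmasked spots first.
#' States with zero variance yield missing (NA) entries -- never 0 -- with
#' a warning.
#'
#' @param maps List of [fit_proportions()] results sharing one state set.
#' @param aggregation `"per_section_weighted"` or `"pooled"`.
#' @return An object of class `codetection_matrix`: `scores` (states x
#'   states, symmetric, diagonal 1 for non-degenerate states), plus
#'   `n_spots_used`, `sections_used`, `aggregation`.
#' @export
codetection_matrix <- function(maps,
                               aggregation = c("per_section_weighted",
                                               "pooled")) {
  aggregation <- match.arg(aggregation)
  if (inherits(maps, "proportion_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, TRUE, "proportion_map")))
  states <- colnames(maps[[1L]]$proportions)
  if (length(states) < 2L) stop("need at least 2 states")
  for (m in maps)
    if (!identical(colnames(m$proportions), states))
      stop("all proportion maps must share the same state set")
  spots <- lapply(maps, function(m)
    m$proportions[!m$mask, , drop = FALSE])
  n_used <- vapply(spots, nrow, 1L)
  if (sum(n_used) < 3L) stop("need at least 3 unmasked spots in total")
  if (aggregation == "pooled") {
    X <- do.call(rbind, spots)
    scores <- pearson_matrix(X)
  } else {
    per <- lapply(spots[n_used >= 3L], pearson_matrix)
    w <- n_used[n_used >= 3L]
    if (!length(per)) stop("no section has >= 3 unmasked spots")
    scores <- weighted_mean_matrices(per, w)
  }
  if (any(is.na(scores[upper.tri(scores, diag = TRUE)])))
    warning("zero-variance state(s) produced missing co-detection entries")
  structure(list(scores = scores, n_spots_used = sum(n_used),
                 sections_used = vapply(maps, `[[`, "", "section_id"),
                 aggregation = aggregation),
            class = "codetection_matrix")
}

# Pearson correlation matrix with zero-variance columns as NA (diagonal
# included); stats::cor warns on zero sd, which we silence deliberately.
pearson_matrix <- function(X) {
  sdev <- apply(X, 2, stats::sd)
  r <- suppressWarnings(stats::cor(X))
  r[sdev == 0, ] <- NA_real_
  r[, sdev == 0] <- NA_real_
  diag(r)[sdev > 0] <- 1
  r
}

# elementwise weighted mean over matrices, NA excluded pairwise
weighted_mean_matrices <- function(mats, w) {
  num <- matrix(0, nrow(mats[[1L]]), ncol(mats[[1L]]),
                dimnames = dimnames(mats[[1L]]))
  den <- num
  for (i in seq_along(mats)) {
    ok <- !is.na(mats[[i]])
    num[ok] <- num[ok] + w[i] * mats[[i]][ok]
    den[ok] <- den[ok] + w[i]
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' @export
print.codetection_matrix <- function(x, ...) {
  cat(sprintf("<codetection_matrix> %d states, %d spots (%s over %d sections)\n",
              ncol(x$scores), x$n_spots_used, x$aggregation,
              length(x$sections_used)))
  invisible(x)
}

#' Thresholded niche graph
#'
#' Builds the undirected niche network: an edge joins two states if and
#' only if their co-detection score is strictly greater than `threshold`
#' (a pair scoring exactly the threshold gets no edge). Missing entries
#' never create edges. Node degree counts each state's co-detected
#' partners; the connected components of the graph are the discovered
#' niches.
#'
#' @param matrix A [codetection_matrix()] result.
#' @param threshold Score cutoff; edges require score > threshold, strictly.
#' @return An object of class `niche_graph`: `graph` (igraph), `edges`
#'   (data.frame: state_a, state_b, score), `degree`, `threshold`.
#' @export
niche_graph <- function(matrix, threshold = 0.07) {
  stopifnot(inherits(matrix, "codetection_matrix"))
  sc <- matrix$scores
  states <- colnames(sc)
  pairs <- which(upper.tri(sc) & !is.na(sc) & sc > threshold, arr.ind = TRUE)
  edges <- data.frame(state_a = states[pairs[, 1L]],
                      state_b = states[pairs[, 2L]],
                      score = sc[pairs],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = states))
  structure(list(graph = g, edges = edges,
                 degree = igraph::degree(g), threshold = threshold),
            class = "niche_graph")
}

#' @export
print.niche_graph <- function(x, ...) {
  cat(sprintf("<niche_graph> %d states, %d edges at score > %g\n",
              length(x$degree), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Connected components of a niche graph
#'
#' @param graph A [niche_graph()].
#' @return Named integer vector: component membership per state.
#' @export
niche_components <- function(graph) {
  stopifnot(inherits(graph, "niche_graph"))
  igraph::components(graph$graph)$membership
}

default_age_bounds <- function() {
  list(`5.5-6` = c(5.5, 6), `7-8` = c(7, 8), `9-14` = c(9, 14))
}

#' Assign sections to developmental age groups
#'
#' Sections are binned by PCW into ordered intervals. Printed interval
#' schemes for human development commonly leave gaps (e.g. 5.5-6 then
#' 7-8 leaves 6-7 uncovered, yet PCW 6.5 samples exist); each interval's
#' upper boundary is therefore extended to the next interval's start, so
#' the effective bins here are \[5.5, 7), \[7, 9), \[9, 14\].
#'
#' @param pcw Numeric PCW per section.
#' @param section_ids Section identifiers, one per pcw value.
#' @param bounds Named list of `c(lo, hi)` intervals in increasing order;
#'   defaults to the three-group scheme 5.5-6, 7-8, 9-14.
#' @return An object of class `age_group_partition`: `bounds`,
#'   `assignment` (section_id -> group index), `labels`.
#' @export
assign_age_groups <- function(pcw, section_ids,
                              bounds = default_age_bounds()) {
  stopifnot(length(pcw) == length(section_ids))
  lo <- vapply(bounds, `[`, 1, 1)
  hi <- vapply(bounds, `[`, 1, 2)
  if (is.unsorted(lo, strictly = TRUE) || any(hi < lo))
    stop("bounds must be ordered, non-overlapping intervals")
  lo_glob <- lo[1L]; hi_glob <- hi[length(hi)]
  if (any(pcw < lo_glob | pcw > hi_glob))
    stop("pcw value(s) outside the global range [", lo_glob, ", ",
         hi_glob, "]: ",
         paste(pcw[pcw < lo_glob | pcw > hi_glob], collapse = ", "))
  # gap-closing: interval i runs to the start of interval i+1
  breaks <- c(lo, hi[length(hi)])
  grp <- findInterval(pcw, breaks, rightmost.closed = TRUE)
  structure(list(bounds = bounds,
                 assignment = stats::setNames(grp, section_ids),
                 labels = names(bounds)),
            class = "age_group_partition")
}

#' Co-detection stability across age groups
#'
#' Recomputes the co-detection matrix within each age group and quantifies
#' agreement between groups two ways: the Pearson correlation of the
#' upper-triangle scores (missing entries excluded pairwise) and the
#' Jaccard index of the edge sets of the thresholded niche graphs.
#'
#' @param maps List of [fit_proportions()] results (one per section).
#' @param partition An [assign_age_groups()] partition covering every map's
#'   section id.
#' @param threshold Niche-graph threshold used for the Jaccard comparison.
#' @param aggregation Passed to [codetection_matrix()].
#' @return List with `matrices` (one [codetection_matrix()] per group) and
#'   `stability` (data.frame: group_a, group_b, score_correlation,
#'   edge_jaccard).
#' @export
group_stability <- function(maps, partition, threshold = 0.07,
                            aggregation = "per_section_weighted") {
  stopifnot(inherits(partition, "age_group_partition"))
  sec <- vapply(maps, `[[`, "", "section_id")
  missing <- setdiff(sec, names(partition$assignment))
  if (length(missing))
    stop("section(s) not in the partition: ", paste(missing, collapse = ", "))
  grp <- partition$assignment[sec]
  groups <- sort(unique(grp))
  empty <- setdiff(seq_along(partition$labels), groups)
  if (length(empty))
    stop("age group(s) with no sections: ",
         paste(partition$labels[empty], collapse = ", "))
  mats <- lapply(groups, function(gi)
    codetection_matrix(maps[grp == gi], aggregation = aggregation))
  names(mats) <- partition$labels[groups]
  combos <- expand.grid(a = seq_along(mats), b = seq_along(mats))
  combos <- combos[combos$a <= combos$b, , drop = FALSE]
  stab <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    a <- combos$a[i]; b <- combos$b[i]
    data.frame(group_a = names(mats)[a], group_b = names(mats)[b],
               score_correlation = upper_tri_correlation(
                 mats[[a]]$scores, mats[[b]]$scores),
               edge_jaccard = edge_jaccard(
                 niche_graph(mats[[a]], threshold),
                 niche_graph(mats[[b]], threshold)),
               stringsAsFactors = FALSE)
  }))
  list(matrices = mats, stability = stab)
}

upper_tri_correlation <- function(m1, m2) {
  v1 <- m1[upper.tri(m1)]
  v2 <- m2[upper.tri(m2)]
  ok <- !is.na(v1) & !is.na(v2)
  if (sum(ok) < 3L) return(NA_real_)
  stats::cor(v1[ok], v2[ok])
}

edge_jaccard <- function(g1, g2) {
  key <- function(g) {
    if (!nrow(g$edges)) return(character())
    apply(cbind(pmin(g$edges$state_a, g$edges$state_b),
                pmax(g$edges$state_a, g$edges$state_b)), 1,
          paste, collapse = "|")
  }
  e1 <- key(g1); e2 <- key(g2)
  if (!length(e1) && !length(e2)) return(1)
  length(intersect(e1, e2)) / length(union(e1, e2))
}
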