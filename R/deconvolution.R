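#' Deconvolve a spatial section into cell-state proportions
#'
#' Estimates, for every spot, a non-negative composition over the reference
#' states by non-negative least squares (NNLS): the spot's counts are
#' normalized to counts-per-`scale` (no log transform -- a log would break
#' mixture linearity), regressed against the reference's linear-scale mean
#' profiles over the shared genes, and the fitted non-negative weights are
#' renormalized onto the simplex. Spots whose total counts fall below
#' `min_counts` are masked (all-zero row, mask bit set) rather than fitted.
#'
#' @param section A [spatial_section()].
#' @param profiles A [build_profiles()] reference.
#' @param gene_subset Optional gene ids to restrict the fit to (e.g. a
#'   marker panel).
#' @param min_counts Spots with fewer total counts are masked.
#' @param ridge Optional non-negative ridge penalty on the NNLS weights
#'   (default 0: plain NNLS; collinear references are returned as-is with
#'   a conditioning warning).
#' @param scale Normalization target for spot vectors.
#' @return An object of class `proportion_map`: `proportions` (spots x
#'   states, rows on the simplex or all-zero when masked), `mask` (logical,
#'   TRUE = masked), `coords`, `section_id`, `pcw`.
#' @export
fit_proportions <- function(section, profiles, gene_subset = NULL,
                            min_counts = 100, ridge = 0, scale = 1e4) {
  stopifnot(inherits(section, "spatial_section"),
            inherits(profiles, "state_profiles"))
  counts <- section$counts
  if (any(!is.finite(counts))) stop("non-finite values in spot counts")
  shared <- intersect(colnames(counts), rownames(profiles$mean_counts))
  if (!is.null(gene_subset)) shared <- intersect(shared, gene_subset)
  if (length(shared) < 2L)
    stop("fewer than 2 shared genes between section and reference")
  A <- profiles$mean_counts[shared, , drop = FALSE]
  if (ncol(A) < 2L) stop("reference must contain at least 2 states")
  kap <- kappa(A, exact = FALSE)
  if (is.finite(kap) && kap > 1e8)
    warning("reference profiles are near-collinear (condition number ",
            format(kap, digits = 3), "); proportions may be unstable")
  if (ridge > 0)
    A <- rbind(A, sqrt(ridge) * diag(ncol(A)))
  X <- as.matrix(counts[, shared, drop = FALSE])
  totals <- Matrix::rowSums(counts)
  mask <- totals < min_counts | Matrix::rowSums(X) == 0
  n <- nrow(X); k <- ncol(profiles$mean_counts)
  P <- matrix(0, n, k, dimnames = list(rownames(counts),
                                       colnames(profiles$mean_counts)))
  for (i in which(!mask)) {
    b <- scale * X[i, ] / sum(X[i, ])
    if (ridge > 0) b <- c(b, numeric(k))
    w <- pracma::lsqnonneg(A, b)$x
    s <- sum(w)
    if (s > 0) P[i, ] <- w / s else mask[i] <- TRUE
  }
  structure(list(proportions = P, mask = mask, coords = section$coords,
                 section_id = section$section_id, pcw = section$pcw),
            class = "proportion_map")
}

#' @export
print.proportion_map <- function(x, ...) {
  cat(sprintf("<proportion_map> %s: %d spots x %d states (%d masked), PCW %.1f\n",
              x$section_id, nrow(x$proportions), ncol(x$proportions),
              sum(x$mask), x$pcw))
  invisible(x)
}

#' Long-format prediction map table
#'
#' Joins per-spot proportions with spot coordinates for the requested
#' states, excluding masked spots -- the serialization behind spatial
#' localization maps.
#'
#' @param map A [fit_proportions()] result.
#' @param states States to include; defaults to all.
#' @return data.frame with columns `spot`, `x`, `y`, `state`, `proportion`.
#' @export
prediction_map_table <- function(map, states = colnames(map$proportions)) {
  stopifnot(inherits(map, "proportion_map"))
  bad <- setdiff(states, colnames(map$proportions))
  if (length(bad)) stop("unknown state(s): ", paste(bad, collapse = ", "))
  keep <- !map$mask
  P <- map$proportions[keep, states, drop = FALSE]
  co <- map$coords[keep, , drop = FALSE]
  data.frame(
    spot = rep(rownames(P), times = length(states)),
    x = rep(co$x, times = length(states)),
    y = rep(co$y, times = length(states)),
    state = rep(states, each = nrow(P)),
    proportion = as.vector(P),
    stringsAsFactors = FALSE)
}
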