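#' Library-size normalize a count matrix
#'
#' Scales each cell (row) to `scale` total counts, then applies
#' `log1p`. Cells with zero total counts pass through as all-zero rows
#' with a warning.
#'
#' @param counts cells x genes non-negative count matrix (dense or
#'   `Matrix` sparse).
#' @param scale Target total per cell before the log transform.
#' @return Matrix of the same shape, `log1p(scale * x / rowsum)`.
#' @export
normalize_counts <- function(counts, scale = 1e4) {
  if (any(counts < 0)) stop("input error: counts must be non-negative")
  if (scale <= 0) stop("input error: scale must be positive")
  rs <- Matrix::rowSums(counts)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) have zero total counts; passed through as zero")
    rs[zero] <- 1
  }
  log1p(row_scale(counts, scale / rs))
}

# multiply row i of m by f[i]; keeps sparse matrices sparse
row_scale <- function(m, f) {
  if (inherits(m, "sparseMatrix")) Matrix::Diagonal(x = f) %*% m
  else m * f
}

#' Build per-state reference expression profiles
#'
#' Computes, for every cell state, the mean normalized expression
#' (log scale and linear counts-per-`scale` scale) and the fraction of the
#' state's cells expressing each gene. The linear means (`mean_counts`)
#' are the deconvolution reference; the log means (`mean_expr`) feed the
#' dot-plot and heatmap summaries; `frac_expr` is computed on raw
#' counts > 0, the conventional "percent expressing" semantics.
#'
#' @param counts cells x genes raw count matrix with gene ids as column
#'   names.
#' @param labels Character/factor vector of state labels, one per cell.
#' @param scale Normalization target, see [normalize_counts()].
#' @return An object of class `state_profiles` with elements `mean_expr`,
#'   `mean_counts`, `frac_expr` (all genes x states), `n_cells` and
#'   `states`.
#' @export
build_profiles <- function(counts, labels, scale = 1e4) {
  labels <- as.character(labels)
  if (length(labels) != nrow(counts))
    stop("labels must have one entry per cell")
  states <- sort(unique(labels))
  empty <- setdiff(states, labels)
  if (length(empty))
    stop("state(s) with 0 cells: ", paste(empty, collapse = ", "))
  norm <- normalize_counts(counts, scale)
  rs <- Matrix::rowSums(counts)
  rs[rs == 0] <- 1
  lin <- row_scale(counts, scale / rs)
  ind <- outer(labels, states, "==") * 1          # cells x states
  ncell <- colSums(ind)
  ind <- sweep(ind, 2, ncell, "/")
  mean_expr <- as.matrix(Matrix::crossprod(norm, ind))
  mean_counts <- as.matrix(Matrix::crossprod(lin, ind))
  frac_expr <- as.matrix(Matrix::crossprod((counts > 0) * 1, ind))
  dimnames(mean_expr) <- dimnames(mean_counts) <- dimnames(frac_expr) <-
    list(colnames(counts), states)
  structure(list(mean_expr = mean_expr, mean_counts = mean_counts,
                 frac_expr = frac_expr,
                 n_cells = stats::setNames(ncell, states), states = states),
            class = "state_profiles")
}

#' @export
print.state_profiles <- function(x, ...) {
  cat(sprintf("<state_profiles> %d genes x %d states (%s cells)\n",
              nrow(x$mean_expr), length(x$states), sum(x$n_cells)))
  invisible(x)
}

# per-gene z-score across the selected states; population SD; constant
# rows map to 0 rather than NaN so heatmaps stay finite
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))
  z <- (m - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  z
}

check_profile_subset <- function(profiles, genes, states) {
  stopifnot(inherits(profiles, "state_profiles"))
  bad_g <- setdiff(genes, rownames(profiles$mean_expr))
  if (length(bad_g)) stop("unknown gene(s): ", paste(bad_g, collapse = ", "))
  bad_s <- setdiff(states, profiles$states)
  if (length(bad_s)) stop("unknown state(s): ", paste(bad_s, collapse = ", "))
}

#' Dot-plot enrichment table
#'
#' The classic marker dot-plot substrate: for each requested gene and
#' state, the percentage of the state's cells expressing the gene and the
#' gene's mean expression z-scored across the selected states (population
#' SD; a gene constant across the selection scores 0 everywhere).
#' Duplicate gene requests collapse to a single entry.
#'
#' @param profiles A [build_profiles()] object.
#' @param genes Genes to tabulate.
#' @param states States to tabulate; defaults to all.
#' @return data.frame with columns `gene`, `state`, `pct_expressing`,
#'   `scaled_avg_expression`.
#' @export
dotplot_table <- function(profiles, genes, states = profiles$states) {
  genes <- unique(genes)
  states <- unique(states)
  check_profile_subset(profiles, genes, states)
  z <- zscore_rows(profiles$mean_expr[genes, states, drop = FALSE])
  pct <- 100 * profiles$frac_expr[genes, states, drop = FALSE]
  data.frame(
    gene = rep(genes, times = length(states)),
    state = rep(states, each = length(genes)),
    pct_expressing = as.vector(pct),
    scaled_avg_expression = as.vector(z),
    stringsAsFactors = FALSE)
}

#' Per-gene z-scaled expression matrix
#'
#' Heatmap substrate: mean expression of each gene z-scaled across the
#' selected states (population SD, constant genes map to a zero row).
#'
#' @inheritParams dotplot_table
#' @return genes x states numeric matrix.
#' @export
zscale_heatmap_table <- function(profiles, genes, states = profiles$states) {
  genes <- unique(genes)
  states <- unique(states)
  check_profile_subset(profiles, genes, states)
  zscore_rows(profiles$mean_expr[genes, states, drop = FALSE])
}
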