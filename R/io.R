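#' Write a count matrix as a 10x-style Matrix Market triplet
#'
#' Writes `matrix.mtx` (genes x barcodes, the on-disk 10x orientation),
#' `features.tsv` and `barcodes.tsv` into `dir`. The in-memory convention
#' throughout the package is barcodes (cells or spots) x genes.
#'
#' @param counts barcodes x genes matrix with dimnames.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_counts_triplet <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(t(counts), sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "features.tsv"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a 10x-style Matrix Market triplet
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return barcodes x genes sparse matrix (`dgCMatrix`).
#' @export
read_counts_triplet <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  features <- readLines(file.path(dir, "features.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(features, barcodes)
  Matrix::t(m)
}

#' Write an ISS signal tensor as a long-format CSV
#'
#' Columns: `spot_id`, `x`, `y`, `round`, `channel`, `intensity`
#' (round and channel 1-based).
#'
#' @param tensor A `signal_tensor` (see [generate_iss()]).
#' @param path Output CSV path.
#' @export
write_signal_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "signal_tensor"))
  d <- dim(tensor$intensities)
  spot_ids <- rownames(tensor$intensities)
  df <- data.frame(
    spot_id = rep(spot_ids, times = d[2L] * d[3L]),
    x = rep(tensor$coords$x, times = d[2L] * d[3L]),
    y = rep(tensor$coords$y, times = d[2L] * d[3L]),
    round = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    channel = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    intensity = as.vector(tensor$intensities))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ISS signal tensor from long-format CSV
#'
#' @param path CSV written by [write_signal_tensor()] (or any file with
#'   columns spot_id, x, y, round, channel, intensity).
#' @return A `signal_tensor`.
#' @export
read_signal_tensor <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spot_id", "x", "y", "round", "channel", "intensity")
  if (!all(need %in% names(df)))
    stop("tensor CSV must have columns: ", paste(need, collapse = ", "))
  spot_ids <- unique(df$spot_id)
  R <- max(df$round); C <- max(df$channel)
  intens <- array(0, dim = c(length(spot_ids), R, C),
                  dimnames = list(spot_ids, NULL, NULL))
  intens[cbind(match(df$spot_id, spot_ids), df$round, df$channel)] <-
    df$intensity
  first <- !duplicated(df$spot_id)
  coords <- data.frame(x = df$x[first], y = df$y[first],
                       row.names = df$spot_id[first])[spot_ids, ]
  structure(list(intensities = intens, coords = coords),
            class = "signal_tensor")
}

#' Write a proportion map to CSV
#'
#' Wide spot x state matrix with `spot`, `x`, `y`, `masked` columns
#' prepended; round-trips through [read_proportion_map()].
#'
#' @param map A [fit_proportions()] result.
#' @param path Output CSV path.
#' @export
write_proportion_map <- function(map, path) {
  stopifnot(inherits(map, "proportion_map"))
  df <- data.frame(spot = rownames(map$proportions),
                   x = map$coords$x, y = map$coords$y,
                   masked = map$mask,
                   section_id = map$section_id, pcw = map$pcw,
                   map$proportions, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a proportion map written by [write_proportion_map()]
#'
#' @param path CSV path.
#' @return A `proportion_map`.
#' @export
read_proportion_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("spot", "x", "y", "masked", "section_id", "pcw")
  states <- setdiff(names(df), meta)
  P <- as.matrix(df[states])
  rownames(P) <- df$spot
  structure(list(proportions = P, mask = df$masked,
                 coords = data.frame(x = df$x, y = df$y,
                                     row.names = df$spot),
                 section_id = df$section_id[1L], pcw = df$pcw[1L]),
            class = "proportion_map")
}

#' Write a niche graph as GraphML plus an edge list CSV
#'
#' @param graph A [niche_graph()].
#' @param graphml_path,edges_path Output paths (either may be NULL to
#'   skip).
#' @export
write_niche_graph <- function(graph, graphml_path = NULL,
                              edges_path = NULL) {
  stopifnot(inherits(graph, "niche_graph"))
  if (!is.null(graphml_path))
    igraph::write_graph(graph$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    utils::write.csv(graph$edges, edges_path, row.names = FALSE,
                     quote = FALSE)
  invisible(graph)
}

write_matrix_csv <- function(m, path, rowname_col = "id") {
  df <- data.frame(rn = rownames(m), m, check.names = FALSE)
  names(df)[1L] <- rowname_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
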