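#' Construct an ISS codebook
#'
#' A codebook maps each target gene to a combinatorial barcode: one
#' fluorescence channel per sequencing round (one-hot per round). Codes
#' must be unique across genes and channel indices must be valid.
#'
#' @param genes Character vector of gene names.
#' @param code genes x rounds integer matrix of 1-based channel indices.
#' @param n_channels Number of fluorescence channels.
#' @return An object of class `codebook`.
#' @export
codebook <- function(genes, code, n_channels) {
  genes <- as.character(genes)
  code <- as.matrix(code)
  if (anyDuplicated(genes))
    stop("duplicate gene(s) in codebook: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (nrow(code) != length(genes))
    stop("code must have one row per gene")
  if (any(code < 1L | code > n_channels))
    stop("channel index out of range [1, ", n_channels, "]")
  keys <- apply(code, 1, paste, collapse = "-")
  if (anyDuplicated(keys))
    stop("duplicate barcode(s) shared by genes: ",
         paste(genes[keys %in% keys[duplicated(keys)]], collapse = ", "))
  dimnames(code) <- list(genes, NULL)
  structure(list(genes = genes, code = code,
                 n_rounds = ncol(code), n_channels = as.integer(n_channels)),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> %d genes, %d rounds x %d channels\n",
              length(x$genes), x$n_rounds, x$n_channels))
  invisible(x)
}

#' Load a codebook from CSV
#'
#' Expects columns `gene`, `round_1` .. `round_R` holding 0-based channel
#' indices (the on-disk convention; channels are 1-based in memory).
#'
#' @param path CSV file path.
#' @param n_channels Number of channels the codes index into.
#' @return A [codebook()].
#' @export
load_codebook <- function(path, n_channels = 5L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rcols <- grep("^round_", names(df), value = TRUE)
  if (!"gene" %in% names(df) || !length(rcols))
    stop("codebook CSV needs a 'gene' column and round_1..round_R columns")
  rcols <- rcols[order(as.integer(sub("round_", "", rcols)))]
  codebook(df$gene, as.matrix(df[rcols]) + 1L, n_channels)
}

#' Write a codebook to CSV (0-based channel indices on disk)
#'
#' @param cb A [codebook()].
#' @param path Output CSV path.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  df <- data.frame(gene = cb$genes, cb$code - 1L)
  names(df) <- c("gene", paste0("round_", seq_len(cb$n_rounds)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a random collision-free codebook
#'
#' Samples `n_genes` distinct barcodes from the `n_channels^n_rounds`
#' possible one-hot-per-round codes (the default mirrors a 150-target
#' panel read over 5 rounds and 5 channels).
#'
#' @param n_genes Number of gene targets (must not exceed
#'   `n_channels^n_rounds`).
#' @param n_rounds,n_channels Barcode geometry.
#' @param seed Integer seed.
#' @return A [codebook()].
#' @export
make_codebook <- function(n_genes = 150L, n_rounds = 5L, n_channels = 5L,
                          seed = 1L) {
  total <- n_channels^n_rounds
  if (n_genes > total)
    stop("cannot draw ", n_genes, " unique codes from ", total)
  set.seed(as.integer(seed))
  ids <- sample.int(total, n_genes) - 1L
  code <- matrix(0L, n_genes, n_rounds)
  x <- ids
  for (r in seq_len(n_rounds)) {   # base-n_channels digits
    code[, r] <- x %% n_channels
    x <- x %/% n_channels
  }
  codebook(sprintf("target_%03d", seq_len(n_genes)), code + 1L, n_channels)
}

#' Decode ISS spots by per-round max channel
#'
#' For each spot and round the winning channel is the intensity argmax
#' (ties break to the lowest channel index and are flagged); the barcode is
#' the winning-channel sequence, and a gene is called on an exact codebook
#' match (no nearest-barcode rescue). The per-round quality is the winning
#' intensity normalized by the round's channel sum (`"l1"`, default:
#' q = I_max / sum_c I_c, so uniform noise scores 1/C) or by the channel
#' L2 norm (`"l2"`). All-zero rounds are defined to the uniform quality
#' 1/C and flagged, so dropout spots are filtered rather than fatal.
#'
#' @param tensor A `signal_tensor` (see [generate_iss()]) or a plain
#'   spots x rounds x channels array.
#' @param codebook A [codebook()].
#' @param quality_norm `"l1"` or `"l2"` per-round quality normalization.
#' @return A `spot_calls` data.frame: `spot_id`, `x`, `y`, `barcode`
#'   (dash-separated 1-based channels), `called_gene` (NA when the barcode
#'   is not in the codebook), `quality_r1..R`, `mean_quality`,
#'   `min_quality`, `flagged` (tie or all-zero round encountered).
#' @export
decode_spots <- function(tensor, codebook, quality_norm = c("l1", "l2")) {
  quality_norm <- match.arg(quality_norm)
  stopifnot(inherits(codebook, "codebook"))
  if (inherits(tensor, "signal_tensor")) {
    intens <- tensor$intensities
    coords <- tensor$coords
  } else {
    intens <- tensor
    coords <- data.frame(x = rep(NA_real_, dim(intens)[1L]),
                         y = rep(NA_real_, dim(intens)[1L]))
  }
  if (any(!is.finite(intens)) || any(intens < 0))
    stop("intensities must be finite and non-negative")
  d <- dim(intens)
  if (d[2L] != codebook$n_rounds || d[3L] != codebook$n_channels)
    stop("tensor dimensions (", d[2L], " rounds x ", d[3L],
         " channels) do not match the codebook (", codebook$n_rounds,
         " x ", codebook$n_channels, ")")
  S <- d[1L]; R <- d[2L]; C <- d[3L]
  win <- matrix(NA_integer_, S, R)
  qual <- matrix(NA_real_, S, R)
  flagged <- rep(FALSE, S)
  for (r in seq_len(R)) {
    sl <- intens[, r, , drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, nrow = S)
    w <- max.col(sl, ties.method = "first")
    mx <- sl[cbind(seq_len(S), w)]
    tie <- rowSums(sl == mx) > 1L
    tot <- rowSums(sl)
    zero <- tot == 0
    q <- if (quality_norm == "l1") mx / tot else mx / sqrt(rowSums(sl^2))
    q[zero] <- 1 / C
    win[, r] <- w
    qual[, r] <- q
    flagged <- flagged | tie | zero
  }
  barcode <- apply(win, 1, paste, collapse = "-")
  keys <- apply(codebook$code, 1, paste, collapse = "-")
  called <- codebook$genes[match(barcode, keys)]
  spot_ids <- rownames(intens)
  if (is.null(spot_ids)) spot_ids <- sprintf("spot_%05d", seq_len(S))
  out <- data.frame(spot_id = spot_ids, x = coords$x, y = coords$y,
                    barcode = barcode, called_gene = called,
                    stringsAsFactors = FALSE)
  qdf <- as.data.frame(qual)
  names(qdf) <- paste0("quality_r", seq_len(R))
  out <- cbind(out, qdf)
  out$mean_quality <- rowMeans(qual)
  out$min_quality <- apply(qual, 1, min)
  out$flagged <- flagged
  class(out) <- c("spot_calls", "data.frame")
  out
}

#' Quality-filter decoded spot calls
#'
#' Retains calls whose minimum per-round quality strictly exceeds the
#' threshold (a spot at exactly the threshold is removed) and that decoded
#' to a codebook gene. Removal counts by reason are attached as the
#' `"removed"` attribute and reported via message.
#'
#' @param table A [decode_spots()] result.
#' @param min_quality_threshold Minimum-quality cutoff (strict).
#' @return Filtered `spot_calls` table.
#' @export
filter_calls <- function(table, min_quality_threshold = 0.4) {
  stopifnot(is.data.frame(table))
  undecoded <- is.na(table$called_gene)
  low_q <- !undecoded & table$min_quality <= min_quality_threshold
  keep <- !undecoded & !low_q
  removed <- c(undecoded = sum(undecoded), low_quality = sum(low_q))
  message("filter_calls: kept ", sum(keep), "/", nrow(table),
          " (removed ", removed[["undecoded"]], " undecoded, ",
          removed[["low_quality"]], " low-quality)")
  out <- table[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Assemble per-gene expression maps
#'
#' Groups filtered calls by gene, preserving coordinates: the spatial
#' expression map of each target.
#'
#' @param table A filtered [decode_spots()] table.
#' @return List with `positions` (per-gene data.frame of x, y) and
#'   `counts` (named integer vector of calls per gene).
#' @export
expression_map <- function(table) {
  stopifnot(is.data.frame(table))
  tab <- table[!is.na(table$called_gene), , drop = FALSE]
  positions <- split(tab[, c("x", "y")], tab$called_gene)
  counts <- vapply(positions, nrow, 1L)
  list(positions = positions, counts = counts)
}
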