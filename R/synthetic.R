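#' Configuration for the synthetic atlas generator
#'
#' Builds and validates the single configuration object driving all three
#' synthetic generators: the labeled single-cell reference
#' ([generate_reference()]), the spatial spot sections
#' ([generate_sections()]) and the ISS signal tensor ([generate_iss()]).
#' Defaults emulate the structure of a developmental heart atlas: a handful
#' of discrete cell states with dedicated marker genes, square-lattice
#' sections whose spots are Dirichlet mixtures of states organized into
#' contiguous rectangular niches, and sections spanning postconceptional
#' weeks (PCW) 5.5-14.
#'
#' @param n_states Number of discrete cell states.
#' @param n_genes Number of genes in the simulated panel.
#' @param markers_per_state Dedicated marker genes per state. Must satisfy
#'   `markers_per_state * n_states <= n_genes`.
#' @param marker_fold Fold-enrichment of a state's markers over the baseline
#'   expression level. Values above 3 guarantee that every marker is strictly
#'   the top-expressed gene of its state (baselines are drawn in
#'   \[0.5, 1.5\]).
#' @param n_cells_per_state Cells simulated per state in the reference.
#' @param n_sections Number of spatial sections.
#' @param spots_per_section Spots per section; must fit on the lattice
#'   (`grid_side^2 >= spots_per_section`).
#' @param grid_side Side length of the square spot lattice.
#' @param n_niches Number of contiguous spatial niches per section
#'   (`n_niches <= n_states`).
#' @param dirichlet_concentration Total concentration of the per-niche
#'   Dirichlet over states; larger values concentrate spot compositions
#'   around the niche mean.
#' @param spot_depth Expected total counts per cell / spot.
#' @param count_noise Count noise model: `"poisson"`, `"nb"`
#'   (negative binomial with shared dispersion) or `"none"` (expected
#'   values passed through exactly).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); used only when `count_noise = "nb"`.
#' @param pcw_per_section Postconceptional week of each section, in
#'   \[5.5, 14\]; defaults to an even spread over that range.
#' @param fixed_mixture If `TRUE`, every spot in a niche uses the niche mean
#'   composition exactly (the infinite-concentration limit of the Dirichlet).
#' @param seed Integer seed; all generators derive their own deterministic
#'   substream from it, so reference, sections and ISS data can be
#'   regenerated independently.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_states = 6L,
                             n_genes = 200L,
                             markers_per_state = 10L,
                             marker_fold = 5,
                             n_cells_per_state = 100L,
                             n_sections = 3L,
                             spots_per_section = 400L,
                             grid_side = 20L,
                             n_niches = 3L,
                             dirichlet_concentration = 30,
                             spot_depth = 5000,
                             count_noise = c("poisson", "none", "nb"),
                             nb_dispersion = 0.5,
                             pcw_per_section = NULL,
                             fixed_mixture = FALSE,
                             seed = 1L) {
  count_noise <- match.arg(count_noise)
  if (is.null(pcw_per_section)) {
    pcw_per_section <- if (n_sections == 1L) 9 else
      seq(5.5, 14, length.out = n_sections)
  }
  cfg <- list(
    n_states = as.integer(n_states),
    n_genes = as.integer(n_genes),
    markers_per_state = as.integer(markers_per_state),
    marker_fold = marker_fold,
    n_cells_per_state = as.integer(n_cells_per_state),
    n_sections = as.integer(n_sections),
    spots_per_section = as.integer(spots_per_section),
    grid_side = as.integer(grid_side),
    n_niches = as.integer(n_niches),
    dirichlet_concentration = dirichlet_concentration,
    spot_depth = spot_depth,
    count_noise = count_noise,
    nb_dispersion = nb_dispersion,
    pcw_per_section = as.numeric(pcw_per_section),
    fixed_mixture = isTRUE(fixed_mixture),
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  counts <- c(n_states = cfg$n_states, n_genes = cfg$n_genes,
              markers_per_state = cfg$markers_per_state,
              n_cells_per_state = cfg$n_cells_per_state,
              n_sections = cfg$n_sections,
              spots_per_section = cfg$spots_per_section,
              grid_side = cfg$grid_side, n_niches = cfg$n_niches)
  if (any(counts < 1L))
    stop("configuration error: all counts must be >= 1 (",
         paste(names(counts)[counts < 1L], collapse = ", "), ")")
  if (cfg$markers_per_state * cfg$n_states > cfg$n_genes)
    stop("configuration error: marker budget exceeds gene count (",
         cfg$markers_per_state, " x ", cfg$n_states, " > ", cfg$n_genes, ")")
  if (cfg$n_niches > cfg$n_states)
    stop("configuration error: n_niches (", cfg$n_niches,
         ") must not exceed n_states (", cfg$n_states, ")")
  if (cfg$grid_side^2 < cfg$spots_per_section)
    stop("configuration error: grid too small; grid_side^2 = ",
         cfg$grid_side^2, " < spots_per_section = ", cfg$spots_per_section)
  if (length(cfg$pcw_per_section) != cfg$n_sections)
    stop("configuration error: pcw_per_section must have length n_sections")
  if (any(cfg$pcw_per_section < 5.5 | cfg$pcw_per_section > 14))
    stop("configuration error: pcw values must lie in [5.5, 14]")
  if (cfg$marker_fold <= 1)
    stop("configuration error: marker_fold must exceed 1")
  if (cfg$dirichlet_concentration <= 0 || cfg$nb_dispersion <= 0)
    stop("configuration error: concentration and dispersion must be positive")
  invisible(cfg)
}

# Deterministic substreams: each generator seeds from a fixed offset of the
# global seed so modules can be regenerated independently of one another.
derive_seed <- function(seed, stream) {
  offset <- c(reference = 0L, sections = 1000003L, iss = 2000003L,
              profiles = 3000017L)[[stream]]
  as.integer((as.numeric(seed) + offset) %% 2147483587)
}

#' Ground-truth state expression profiles
#'
#' Per-gene baseline relative expression is drawn uniformly in \[0.5, 1.5\]
#' and shared across states; each state's dedicated markers are enriched to
#' `marker_fold` times their baseline. Columns are normalized to sum to 1,
#' so a profile is the expected fraction of a cell's (or pure spot's)
#' counts falling on each gene.
#'
#' @param config A [synthetic_config()].
#' @return genes x states matrix of relative expression, columns summing
#'   to 1, with a `marker_of` attribute mapping each marker gene to its
#'   owner state.
#' @export
truth_profiles <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "reference"))
  g <- config$n_genes; k <- config$n_states; m <- config$markers_per_state
  genes <- sprintf("gene_%04d", seq_len(g))
  states <- sprintf("state_%02d", seq_len(k))
  baseline <- stats::runif(g, 0.5, 1.5)
  prof <- matrix(baseline, nrow = g, ncol = k,
                 dimnames = list(genes, states))
  marker_of <- rep(NA_character_, g)
  for (j in seq_len(k)) {
    idx <- ((j - 1L) * m + 1L):(j * m)
    prof[idx, j] <- config$marker_fold * baseline[idx]
    marker_of[idx] <- states[j]
  }
  prof <- sweep(prof, 2, colSums(prof), "/")
  attr(prof, "marker_of") <- stats::setNames(marker_of, genes)
  prof
}

draw_counts <- function(expected, noise, nb_dispersion) {
  n <- length(expected)
  out <- switch(noise,
    none = as.numeric(expected),
    poisson = stats::rpois(n, lambda = expected),
    nb = stats::rnbinom(n, mu = expected, size = 1 / nb_dispersion))
  array(out, dim = dim(expected), dimnames = dimnames(expected))
}

#' Generate a labeled single-cell reference
#'
#' Simulates `n_cells_per_state` cells per state. Each cell's expected
#' counts are `spot_depth` times its state's truth profile; observed counts
#' are drawn under the configured noise model (`none` returns expectations
#' exactly). Deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A list with `counts` (cells x genes), `cell_meta`
#'   (data.frame: barcode, state, donor, pcw) and `truth` (a
#'   `synthetic_truth` list carrying `state_profiles`).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  prof <- truth_profiles(config)
  set.seed(derive_seed(config$seed, "reference") + 1L)
  k <- config$n_states; n <- config$n_cells_per_state
  states <- colnames(prof)
  labels <- rep(states, each = n)
  expected <- config$spot_depth * t(prof)[rep(seq_len(k), each = n), ,
                                          drop = FALSE]
  counts <- draw_counts(expected, config$count_noise, config$nb_dispersion)
  barcodes <- sprintf("cell_%05d", seq_len(nrow(counts)))
  rownames(counts) <- barcodes
  donors <- sprintf("donor_%02d", 1L + (seq_along(barcodes) - 1L) %%
                      config$n_sections)
  pcw <- config$pcw_per_section[1L + (seq_along(barcodes) - 1L) %%
                                  config$n_sections]
  meta <- data.frame(barcode = barcodes, state = labels, donor = donors,
                     pcw = pcw, stringsAsFactors = FALSE)
  truth <- list(state_profiles = prof)
  class(truth) <- "synthetic_truth"
  list(counts = counts, cell_meta = meta, truth = truth)
}

# Dirichlet mean composition of each niche: states are dealt round-robin to
# niches; a niche's dominant states share 75% of the mass, the rest is
# spread evenly over the remaining states.
niche_means <- function(n_states, n_niches) {
  owner <- (seq_len(n_states) - 1L) %% n_niches + 1L
  means <- matrix(0, n_niches, n_states)
  for (j in seq_len(n_niches)) {
    dom <- owner == j
    means[j, dom] <- 0.75 / sum(dom)
    if (any(!dom)) means[j, !dom] <- 0.25 / sum(!dom)
    else means[j, dom] <- 1 / sum(dom)
  }
  means
}

rdirichlet_rows <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Generate spatially structured spot sections
#'
#' Spots occupy the first `spots_per_section` sites of a `grid_side` x
#' `grid_side` lattice (row-major). The lattice is partitioned into
#' `n_niches` contiguous vertical bands; each niche has its own Dirichlet
#' mean over states ([niche means][generate_sections] deal dominant states
#' round-robin), per-spot compositions are drawn from the niche's Dirichlet
#' (or fixed at the mean when `fixed_mixture = TRUE`), and spot counts are
#' drawn from `spot_depth` times the mixed profile under the noise model.
#' Sections carry their PCW metadata.
#'
#' @param config A [synthetic_config()].
#' @param profiles Optional genes x states truth profile matrix (columns
#'   summing to 1); defaults to [truth_profiles()] of the config.
#' @return A list with `sections` (list of `spatial_section`) and `truth`
#'   (`synthetic_truth` with `state_profiles`, per-section `proportions`
#'   and `niche_of_spot`).
#' @export
generate_sections <- function(config, profiles = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(profiles)) profiles <- truth_profiles(config)
  if (ncol(profiles) != config$n_states)
    stop("profiles must cover all ", config$n_states, " states")
  set.seed(derive_seed(config$seed, "sections"))
  ns <- config$spots_per_section
  side <- config$grid_side
  ix <- seq_len(ns) - 1L
  x <- ix %% side + 1L
  y <- ix %/% side + 1L
  # contiguous vertical bands of lattice columns -> rectangular niche blocks
  band <- cut(x, breaks = round(seq(0.5, side + 0.5,
                                    length.out = config$n_niches + 1L)),
              labels = FALSE)
  means <- niche_means(config$n_states, config$n_niches)
  sections <- vector("list", config$n_sections)
  props_truth <- vector("list", config$n_sections)
  niche_truth <- vector("list", config$n_sections)
  for (s in seq_len(config$n_sections)) {
    sec_id <- sprintf("section_%02d", s)
    if (config$fixed_mixture) {
      p <- means[band, , drop = FALSE]
    } else {
      p <- matrix(0, ns, config$n_states)
      for (j in seq_len(config$n_niches)) {
        rows <- which(band == j)
        if (length(rows))
          p[rows, ] <- rdirichlet_rows(length(rows),
                                       config$dirichlet_concentration *
                                         means[j, ])
      }
    }
    colnames(p) <- colnames(profiles)
    expected <- config$spot_depth * (p %*% t(profiles))
    counts <- draw_counts(expected, config$count_noise, config$nb_dispersion)
    spot_ids <- sprintf("%s_spot_%04d", sec_id, seq_len(ns))
    rownames(counts) <- spot_ids
    rownames(p) <- spot_ids
    sections[[s]] <- spatial_section(
      counts = counts,
      coords = data.frame(x = x, y = y, row.names = spot_ids),
      section_id = sec_id,
      pcw = config$pcw_per_section[s])
    props_truth[[s]] <- p
    niche_truth[[s]] <- stats::setNames(band, spot_ids)
  }
  names(sections) <- vapply(sections, `[[`, "", "section_id")
  truth <- list(state_profiles = profiles,
                proportions = stats::setNames(props_truth, names(sections)),
                niche_of_spot = stats::setNames(niche_truth, names(sections)))
  class(truth) <- "synthetic_truth"
  list(sections = sections, truth = truth)
}

#' A spatial section of barcoded spots
#'
#' @param counts spots x genes non-negative count matrix with spot ids as
#'   row names and gene ids as column names.
#' @param coords data.frame with columns `x`, `y`, one row per spot.
#' @param section_id Section identifier.
#' @param pcw Postconceptional week of the section.
#' @return An object of class `spatial_section`.
#' @export
spatial_section <- function(counts, coords, section_id, pcw) {
  stopifnot(nrow(counts) == nrow(coords),
            all(is.finite(as.matrix(coords))))
  structure(list(counts = counts, coords = coords,
                 section_id = section_id, pcw = as.numeric(pcw)),
            class = "spatial_section")
}

#' @export
print.spatial_section <- function(x, ...) {
  cat(sprintf("<spatial_section> %s: %d spots x %d genes, PCW %.1f\n",
              x$section_id, nrow(x$counts), ncol(x$counts), x$pcw))
  invisible(x)
}

#' Generate a synthetic ISS signal tensor
#'
#' Each simulated spot is assigned a gene uniformly at random from the
#' codebook; its intensity tensor carries `signal + background` on the
#' coded channel of each round and `background` elsewhere, plus independent
#' additive half-normal noise (absolute value of a centered normal, keeping
#' intensities non-negative). Coordinates are uniform on a plane.
#'
#' @param codebook A [codebook] object (see [load_codebook()] /
#'   [make_codebook()]).
#' @param n_spots Number of spots to simulate.
#' @param background Uniform background intensity added to every channel.
#' @param signal Intensity added on the coded channel each round.
#' @param noise_sd Standard deviation of the half-normal noise (0 disables).
#' @param seed Integer seed.
#' @return A list with `tensor` (a `signal_tensor`: spots x rounds x
#'   channels array plus coordinates) and `truth` (`synthetic_truth` with
#'   `iss_gene_of_spot`).
#' @export
generate_iss <- function(codebook, n_spots, background = 0, signal = 10,
                         noise_sd = 0, seed = 1L) {
  stopifnot(inherits(codebook, "codebook"))
  if (length(codebook$genes) == 0L) stop("codebook is empty")
  if (signal <= 0) stop("signal must be positive")
  if (background < 0 || noise_sd < 0)
    stop("background and noise_sd must be non-negative")
  set.seed(derive_seed(seed, "iss"))
  R <- codebook$n_rounds; C <- codebook$n_channels
  gene <- sample(codebook$genes, n_spots, replace = TRUE)
  intens <- array(background, dim = c(n_spots, R, C))
  code <- codebook$code  # genes x rounds, 1-based channel index
  gi <- match(gene, codebook$genes)
  for (r in seq_len(R)) {
    intens[cbind(seq_len(n_spots), r, code[gi, r])] <-
      intens[cbind(seq_len(n_spots), r, code[gi, r])] + signal
  }
  if (noise_sd > 0)
    intens <- intens + abs(array(stats::rnorm(length(intens), 0, noise_sd),
                                 dim = dim(intens)))
  spot_ids <- sprintf("iss_spot_%05d", seq_len(n_spots))
  dimnames(intens) <- list(spot_ids, NULL, NULL)
  coords <- data.frame(x = stats::runif(n_spots, 0, 1000),
                       y = stats::runif(n_spots, 0, 1000),
                       row.names = spot_ids)
  tensor <- structure(list(intensities = intens, coords = coords),
                      class = "signal_tensor")
  truth <- list(iss_gene_of_spot = stats::setNames(gene, spot_ids))
  class(truth) <- "synthetic_truth"
  list(tensor = tensor, truth = truth)
}
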