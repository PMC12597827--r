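#' Default pipeline configuration
#'
#' One flat list per stage: simulation parameters (see
#' [synthetic_config()]), profile/deconvolution settings, the co-detection
#' threshold (0.07, strict), ISS geometry and the minimum-quality cutoff
#' (0.4, strict), the LR-score expression gate (0.1), the aggregation mode
#' and the three developmental age groups. Values supplied in `...` or via
#' a YAML file override the defaults key by key.
#'
#' @param ... Named overrides of individual keys.
#' @param yaml Optional path to a YAML file of overrides (applied before
#'   `...`).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(..., yaml = NULL) {
  cfg <- list(
    stages = c("simulate", "profiles", "deconvolve", "codetect",
               "decode", "lrscore"),
    seed = 1L,
    # synthetic
    n_states = 6L, n_genes = 200L, markers_per_state = 10L,
    marker_fold = 5, n_cells_per_state = 100L, n_sections = 3L,
    spots_per_section = 400L, grid_side = 20L, n_niches = 3L,
    dirichlet_concentration = 30, spot_depth = 5000,
    count_noise = "poisson", nb_dispersion = 0.5,
    pcw_per_section = NULL, fixed_mixture = FALSE,
    # iss
    iss_n_genes = 150L, iss_n_rounds = 5L, iss_n_channels = 5L,
    iss_n_spots = 2000L, iss_background = 1, iss_signal = 10,
    iss_noise_sd = 0.5, min_quality = 0.4,
    # profiles / deconvolution
    normalize_scale = 1e4, min_counts = 100, ridge = 0,
    # codetection
    threshold = 0.07, aggregation = "per_section_weighted",
    # lr score
    min_frac = 0.1, lr_method = "mean")
  if (!is.null(yaml)) {
    ov <- yaml::read_yaml(yaml)
    cfg[names(ov)] <- ov
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$threshold >= -1, cfg$min_quality >= 0, cfg$min_frac >= 0)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis chain
#'
#' Executes the enabled stages in dependency order -- simulate (reference,
#' sections, ISS tensor), profiles, deconvolve, codetect, decode,
#' lrscore -- writing every output as CSV/GraphML under `out_dir` and a
#' JSON run manifest listing parameters, seed, output files and wall-clock
#' time. Re-running with the same config and seed reproduces all CSV
#' outputs bit-identically. The LR stage scores each state's first
#' synthetic marker gene as the sender enzyme against every other state's
#' first marker as the receiver receptor, exercising the scoring surface
#' on generated data.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  stages <- config$stages
  outputs <- character()
  log <- function(...) message("[cardioniche] ", ...)
  add <- function(...) outputs <<- c(outputs, ...)

  need <- function(stage, dep)
    if (!dep %in% stages)
      stop("stage '", stage, "' requires upstream stage '", dep, "'")
  for (s in intersect(c("profiles", "deconvolve"), stages))
    need(s, "simulate")
  if ("codetect" %in% stages) need("codetect", "deconvolve")
  if ("deconvolve" %in% stages) need("deconvolve", "profiles")
  if ("decode" %in% stages) need("decode", "simulate")
  if ("lrscore" %in% stages) need("lrscore", "profiles")

  scfg <- NULL; ref <- NULL; secs <- NULL; cb <- NULL; iss <- NULL
  profiles <- NULL; maps <- NULL

  if ("simulate" %in% stages) {
    log("simulate: reference + ", config$n_sections, " sections + ISS")
    scfg <- synthetic_config(
      n_states = config$n_states, n_genes = config$n_genes,
      markers_per_state = config$markers_per_state,
      marker_fold = config$marker_fold,
      n_cells_per_state = config$n_cells_per_state,
      n_sections = config$n_sections,
      spots_per_section = config$spots_per_section,
      grid_side = config$grid_side, n_niches = config$n_niches,
      dirichlet_concentration = config$dirichlet_concentration,
      spot_depth = config$spot_depth, count_noise = config$count_noise,
      nb_dispersion = config$nb_dispersion,
      pcw_per_section = config$pcw_per_section,
      fixed_mixture = config$fixed_mixture, seed = config$seed)
    ref <- generate_reference(scfg)
    secs <- generate_sections(scfg, ref$truth$state_profiles)
    cb <- make_codebook(config$iss_n_genes, config$iss_n_rounds,
                        config$iss_n_channels, seed = config$seed)
    iss <- generate_iss(cb, config$iss_n_spots,
                        background = config$iss_background,
                        signal = config$iss_signal,
                        noise_sd = config$iss_noise_sd, seed = config$seed)
    refdir <- file.path(out_dir, "reference")
    write_counts_triplet(ref$counts, refdir)
    utils::write.csv(ref$cell_meta, file.path(out_dir, "cell_meta.csv"),
                     row.names = FALSE, quote = FALSE)
    write_matrix_csv(ref$truth$state_profiles,
                     file.path(out_dir, "truth_state_profiles.csv"), "gene")
    pos <- do.call(rbind, lapply(secs$sections, function(sec)
      data.frame(barcode = rownames(sec$counts), section = sec$section_id,
                 x = sec$coords$x, y = sec$coords$y)))
    utils::write.csv(pos, file.path(out_dir, "spot_positions.csv"),
                     row.names = FALSE, quote = FALSE)
    for (sec in secs$sections)
      write_counts_triplet(sec$counts, file.path(out_dir, sec$section_id))
    for (nm in names(secs$truth$proportions))
      write_matrix_csv(secs$truth$proportions[[nm]],
                       file.path(out_dir,
                                 paste0("truth_proportions_", nm, ".csv")),
                       "spot")
    write_codebook(cb, file.path(out_dir, "codebook.csv"))
    write_signal_tensor(iss$tensor, file.path(out_dir, "iss_intensities.csv"))
    utils::write.csv(
      data.frame(spot_id = names(iss$truth$iss_gene_of_spot),
                 gene = iss$truth$iss_gene_of_spot),
      file.path(out_dir, "truth_iss_genes.csv"),
      row.names = FALSE, quote = FALSE)
    add("reference/matrix.mtx", "cell_meta.csv", "truth_state_profiles.csv",
        "spot_positions.csv", "codebook.csv", "iss_intensities.csv",
        "truth_iss_genes.csv",
        paste0(names(secs$sections), "/matrix.mtx"),
        paste0("truth_proportions_", names(secs$sections), ".csv"))
  }

  if ("profiles" %in% stages) {
    log("profiles: ", config$n_states, " states")
    profiles <- build_profiles(ref$counts, ref$cell_meta$state,
                               scale = config$normalize_scale)
    write_matrix_csv(profiles$mean_expr,
                     file.path(out_dir, "profiles_mean_expr.csv"), "gene")
    write_matrix_csv(profiles$frac_expr,
                     file.path(out_dir, "profiles_frac_expr.csv"), "gene")
    add("profiles_mean_expr.csv", "profiles_frac_expr.csv")
  }

  if ("deconvolve" %in% stages) {
    log("deconvolve: ", length(secs$sections), " sections")
    maps <- lapply(secs$sections, fit_proportions, profiles = profiles,
                   min_counts = config$min_counts, ridge = config$ridge,
                   scale = config$normalize_scale)
    for (m in maps)
      write_proportion_map(m, file.path(out_dir,
                                        paste0("proportions_",
                                               m$section_id, ".csv")))
    add(paste0("proportions_", names(secs$sections), ".csv"))
  }

  if ("codetect" %in% stages) {
    cdm <- codetection_matrix(maps, aggregation = config$aggregation)
    ng <- niche_graph(cdm, threshold = config$threshold)
    log("codetect: ", nrow(ng$edges), " edges at > ", config$threshold)
    write_matrix_csv(cdm$scores,
                     file.path(out_dir, "codetection_scores.csv"), "state")
    write_niche_graph(ng, file.path(out_dir, "niche_graph.graphml"),
                      file.path(out_dir, "niche_edges.csv"))
    add("codetection_scores.csv", "niche_graph.graphml", "niche_edges.csv")
    pcw <- vapply(maps, `[[`, 1, "pcw")
    grp <- tryCatch(
      assign_age_groups(pcw, vapply(maps, `[[`, "", "section_id")),
      error = function(e) NULL)
    if (!is.null(grp) && length(unique(grp$assignment)) >= 2L &&
        length(unique(grp$assignment)) == length(grp$labels)) {
      st <- group_stability(maps, grp, threshold = config$threshold,
                            aggregation = config$aggregation)
      utils::write.csv(st$stability,
                       file.path(out_dir, "stability_report.csv"),
                       row.names = FALSE, quote = FALSE)
      add("stability_report.csv")
    }
  }

  if ("decode" %in% stages) {
    calls <- decode_spots(iss$tensor, cb)
    kept <- suppressMessages(filter_calls(calls, config$min_quality))
    log("decode: ", nrow(kept), "/", nrow(calls),
        " spots pass min quality > ", config$min_quality)
    utils::write.csv(as.data.frame(kept),
                     file.path(out_dir, "spot_calls.csv"),
                     row.names = FALSE, quote = FALSE)
    em <- expression_map(kept)
    utils::write.csv(data.frame(gene = names(em$counts),
                                n_spots = as.integer(em$counts)),
                     file.path(out_dir, "gene_map_counts.csv"),
                     row.names = FALSE, quote = FALSE)
    add("spot_calls.csv", "gene_map_counts.csv")
  }

  if ("lrscore" %in% stages) {
    states <- profiles$states
    first_marker <- unname(vapply(states, function(s) {
      mo <- attr(ref$truth$state_profiles, "marker_of")
      names(mo)[which(mo == s)[1L]]
    }, ""))
    pairs <- do.call(rbind, lapply(seq_along(states), function(i)
      data.frame(sender_gene = first_marker[i],
                 receiver_gene = first_marker[-i],
                 label = paste0(first_marker[i], "->", first_marker[-i]))))
    tab <- lr_score(profiles, pairs, senders = states, receivers = states,
                    min_frac = config$min_frac, method = config$lr_method)
    ranked <- rank_interactions(tab)
    log("lrscore: ", nrow(ranked), " directed state pairs scored")
    utils::write.csv(ranked, file.path(out_dir, "lr_scores.csv"),
                     row.names = FALSE, quote = FALSE)
    add("lr_scores.csv")
  }

  manifest <- list(
    package = "cardioniche",
    version = as.character(utils::packageVersion("cardioniche")),
    seed = config$seed,
    stages = stages,
    parameters = unclass(config)[setdiff(names(config), "stages")],
    outputs = sort(outputs),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
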