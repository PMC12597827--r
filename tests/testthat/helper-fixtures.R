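# Shared fixtures: small seeded synthetic configurations and independent
# oracles used across the suite.

tiny_config <- function(...) {
  defaults <- list(n_states = 4L, n_genes = 60L, markers_per_state = 5L,
                   marker_fold = 5, n_cells_per_state = 20L,
                   n_sections = 2L, spots_per_section = 100L,
                   grid_side = 10L, n_niches = 2L,
                   dirichlet_concentration = 30, spot_depth = 2000,
                   count_noise = "none", seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

# independent textbook Pearson: explicit sums, no stats::cor
brute_pearson <- function(a, b) {
  n <- length(a)
  am <- sum(a) / n; bm <- sum(b) / n
  num <- sum((a - am) * (b - bm))
  den <- sqrt(sum((a - am)^2)) * sqrt(sum((b - bm)^2))
  if (den == 0) return(NA_real_)
  num / den
}

brute_pearson_matrix <- function(X) {
  k <- ncol(X)
  out <- matrix(NA_real_, k, k, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(k)) for (j in seq_len(k))
    out[i, j] <- brute_pearson(X[, i], X[, j])
  out
}

# brute-force edge enumeration at a strict threshold
brute_edges <- function(scores, threshold) {
  states <- colnames(scores)
  out <- character()
  for (i in seq_along(states)) for (j in seq_along(states)) {
    if (i < j && !is.na(scores[i, j]) && scores[i, j] > threshold)
      out <- c(out, paste(states[i], states[j], sep = "|"))
  }
  sort(out)
}

edge_keys <- function(graph) {
  if (!nrow(graph$edges)) return(character())
  sort(apply(cbind(pmin(graph$edges$state_a, graph$edges$state_b),
                   pmax(graph$edges$state_a, graph$edges$state_b)), 1,
             paste, collapse = "|"))
}

# minimal two-state reference with disjoint marker support, for
# deconvolution oracles
toy_two_state_profiles <- function() {
  counts <- rbind(
    s1_a = c(10, 10, 0, 0),
    s1_b = c(10, 10, 0, 0),
    s2_a = c(0, 0, 10, 10),
    s2_b = c(0, 0, 10, 10))
  colnames(counts) <- paste0("g", 1:4)
  build_profiles(counts, c("s1", "s1", "s2", "s2"))
}

make_section <- function(counts, pcw = 9, section_id = "sec_test") {
  spatial_section(counts,
                  data.frame(x = seq_len(nrow(counts)),
                             y = rep(1, nrow(counts)),
                             row.names = rownames(counts)),
                  section_id, pcw)
}

# proportion_map built directly from a matrix (bypasses fitting) so
# co-detection can be tested on exact columns
manual_map <- function(P, section_id = "sec_manual", pcw = 9) {
  if (is.null(rownames(P)))
    rownames(P) <- sprintf("%s_spot_%03d", section_id, seq_len(nrow(P)))
  structure(list(proportions = P, mask = rep(FALSE, nrow(P)),
                 coords = data.frame(x = seq_len(nrow(P)),
                                     y = rep(1, nrow(P)),
                                     row.names = rownames(P)),
                 section_id = section_id, pcw = pcw),
            class = "proportion_map")
}
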