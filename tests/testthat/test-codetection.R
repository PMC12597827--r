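test_that("co-detection reproduces hand and brute-force Pearson values", {
  # 4-spot toy, frozen hand value: r = 0.48 / 0.5 = 0.96
  P <- cbind(a = c(0.9, 0.8, 0.1, 0.2), b = c(0.8, 0.9, 0.2, 0.1))
  cdm <- codetection_matrix(manual_map(P), aggregation = "pooled")
  expect_equal(cdm$scores["a", "b"], 0.96, tolerance = 1e-12)
  # identical columns -> 1; compositional complement p vs 1-p -> -1
  Q <- cbind(u = c(0.2, 0.7, 0.4), v = c(0.2, 0.7, 0.4))
  expect_equal(codetection_matrix(manual_map(Q),
                                  aggregation = "pooled")$scores["u", "v"], 1)
  Rm <- cbind(p = c(0.2, 0.7, 0.4), q = 1 - c(0.2, 0.7, 0.4))
  expect_equal(codetection_matrix(manual_map(Rm),
                                  aggregation = "pooled")$scores["p", "q"], -1)
})

test_that("pooled co-detection equals an independent brute-force Pearson matrix", {
  set.seed(31)
  maps <- lapply(1:3, function(s) {
    X <- matrix(rgamma(200 * 6, 1), 200, 6)
    P <- X / rowSums(X)
    colnames(P) <- paste0("st", 1:6)
    manual_map(P, section_id = paste0("sec", s))
  })
  cdm <- codetection_matrix(maps, aggregation = "pooled")
  X <- do.call(rbind, lapply(maps, `[[`, "proportions"))
  expect_equal(cdm$scores, brute_pearson_matrix(X), tolerance = 1e-10)
  expect_equal(cdm$scores, t(cdm$scores), tolerance = 1e-12)
  expect_true(all(abs(cdm$scores) <= 1 + 1e-12))
  # per-section weighted mode agrees with the manual weighted average
  cdw <- codetection_matrix(maps)
  per <- lapply(maps, function(m) brute_pearson_matrix(m$proportions))
  manual <- Reduce(`+`, Map(`*`, per, 200)) / 600
  expect_equal(cdw$scores, manual, tolerance = 1e-10)
})

test_that("zero-variance states yield missing scores, never zero, and masked spots change nothing", {
  P <- cbind(a = c(0.3, 0.5, 0.2, 0.4), b = c(0.2, 0.1, 0.3, 0.2),
             const = rep(0.25, 4))
  expect_warning(cdm <- codetection_matrix(manual_map(P),
                                           aggregation = "pooled"),
                 "zero-variance")
  expect_true(is.na(cdm$scores["const", "a"]))
  expect_false(any(cdm$scores["const", ] %in% 0))
  # adding a masked spot leaves scores unchanged
  m2 <- manual_map(rbind(P, c(0.9, 0.05, 0.05)))
  m2$mask[5] <- TRUE
  expect_warning(cdm2 <- codetection_matrix(m2, aggregation = "pooled"))
  expect_equal(cdm2$scores, cdm$scores)
})

test_that("state relabeling permutes the score matrix consistently", {
  set.seed(7)
  X <- matrix(rgamma(50 * 4, 1), 50, 4)
  P <- X / rowSums(X); colnames(P) <- paste0("st", 1:4)
  cdm <- codetection_matrix(manual_map(P), aggregation = "pooled")
  perm <- c(4, 2, 1, 3)
  cdmp <- codetection_matrix(manual_map(P[, perm]), aggregation = "pooled")
  expect_equal(cdmp$scores, cdm$scores[perm, perm])
})

test_that("input contracts are enforced", {
  P <- cbind(a = c(0.5, 0.5), b = c(0.5, 0.5))
  expect_error(codetection_matrix(manual_map(P)), "at least 3")
  P3 <- cbind(a = c(0.4, 0.5, 0.6))
  expect_error(codetection_matrix(manual_map(P3)), "at least 2 states")
  m1 <- manual_map(cbind(a = c(0.4, 0.5, 0.1), b = c(0.6, 0.5, 0.9)))
  m2 <- manual_map(cbind(x = c(0.4, 0.5, 0.1), y = c(0.6, 0.5, 0.9)))
  expect_error(codetection_matrix(list(m1, m2)), "same state set")
})

test_that("niche graph uses a strict threshold and matches brute-force enumeration", {
  states <- paste0("st", 1:4)
  sc <- diag(4); dimnames(sc) <- list(states, states)
  vals <- c(0.10, 0.05, 0.071, 0.069, -0.2, 0.3)
  sc[upper.tri(sc)] <- vals
  sc[lower.tri(sc)] <- t(sc)[lower.tri(sc)]
  cdm <- structure(list(scores = sc, n_spots_used = 100L,
                        sections_used = "s", aggregation = "pooled"),
                   class = "codetection_matrix")
  g <- niche_graph(cdm, threshold = 0.07)
  expect_equal(edge_keys(g), brute_edges(sc, 0.07))
  # boundary: a pair at exactly 0.07 gets no edge
  sc2 <- sc; sc2["st1", "st2"] <- sc2["st2", "st1"] <- 0.07
  cdm2 <- cdm; cdm2$scores <- sc2
  g2 <- niche_graph(cdm2, threshold = 0.07)
  expect_false("st1|st2" %in% edge_keys(g2))
  # degrees count co-detected partners; NA entries never create edges
  expect_equal(sum(g$degree), 2 * nrow(g$edges))
  sc3 <- sc; sc3["st1", "st3"] <- sc3["st3", "st1"] <- NA
  cdm3 <- cdm; cdm3$scores <- sc3
  expect_equal(edge_keys(niche_graph(cdm3, 0.07)),
               brute_edges(sc3, 0.07))
  # all off-diagonal zero -> empty graph
  sc0 <- diag(4); dimnames(sc0) <- list(states, states)
  cdm0 <- cdm; cdm0$scores <- sc0
  g0 <- niche_graph(cdm0, 0.07)
  expect_equal(nrow(g0$edges), 0)
  expect_true(all(g0$degree == 0))
})

test_that("planted niches are recovered: within-niche scores dominate and components match", {
  cfg <- tiny_config(n_states = 6L, n_niches = 3L, n_sections = 2L,
                     spots_per_section = 200L, grid_side = 15L,
                     pcw_per_section = c(8, 10),
                     count_noise = "poisson", seed = 17L)
  ref <- generate_reference(cfg)
  secs <- generate_sections(cfg, ref$truth$state_profiles)
  prof <- build_profiles(ref$counts, ref$cell_meta$state)
  maps <- lapply(secs$sections, fit_proportions, profiles = prof)
  cdm <- codetection_matrix(maps)
  # planted partition: states dealt round-robin to niches
  owner <- (seq_len(cfg$n_states) - 1L) %% cfg$n_niches + 1L
  within <- cross <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    if (owner[i] == owner[j]) within <- c(within, cdm$scores[i, j])
    else cross <- c(cross, cdm$scores[i, j])
  }
  expect_gt(min(within), max(cross))
  comp <- niche_components(niche_graph(cdm, threshold = 0.07))
  expect_equal(length(unique(comp)), 3)
  split_states <- split(names(comp), comp)
  planted <- split(colnames(cdm$scores), owner)
  expect_setequal(unname(lapply(split_states, sort)),
                  unname(lapply(planted, sort)))
})

test_that("age groups follow the three-interval scheme with gap closing", {
  part <- assign_age_groups(c(5.5, 6.5, 8, 9, 14),
                            paste0("s", 1:5))
  expect_equal(unname(part$assignment), c(1, 1, 2, 3, 3))
  expect_equal(part$labels, c("5.5-6", "7-8", "9-14"))
  expect_error(assign_age_groups(c(5, 9), c("a", "b")), "outside")
  expect_error(assign_age_groups(15, "a"), "outside")
})

test_that("group stability is exact on self-comparison and zero for disjoint graphs", {
  set.seed(41)
  mk <- function(sec, pcw) {
    X <- matrix(rgamma(100 * 4, 1), 100, 4)
    P <- X / rowSums(X); colnames(P) <- paste0("st", 1:4)
    manual_map(P, section_id = sec, pcw = pcw)
  }
  maps <- list(mk("s1", 6), mk("s2", 6), mk("s3", 6))
  part <- assign_age_groups(c(6, 6, 6), c("s1", "s2", "s3"),
                            bounds = list(`5.5-6` = c(5.5, 6)))
  st <- group_stability(maps, part, threshold = -2)  # every pair an edge
  self <- st$stability[st$stability$group_a == st$stability$group_b, ]
  expect_equal(self$score_correlation, 1)
  expect_equal(self$edge_jaccard, 1)
  # disjoint edge sets -> Jaccard 0
  ga <- niche_graph(codetection_matrix(maps[1:2]), threshold = 0.9)
  ga$edges <- data.frame(state_a = "st1", state_b = "st2", score = 1)
  gb <- niche_graph(codetection_matrix(maps[1:2]), threshold = 0.9)
  gb$edges <- data.frame(state_a = "st3", state_b = "st4", score = 1)
  expect_equal(cardioniche:::edge_jaccard(ga, gb), 0)
  # a group with no sections errors by name
  part2 <- assign_age_groups(c(6, 6, 9), c("s1", "s2", "sX"))
  expect_error(group_stability(maps[1:2], part2), "no sections")
})

test_that("groups simulated from one truth give highly concordant matrices", {
  cfg <- tiny_config(n_states = 6L, n_niches = 3L, n_sections = 4L,
                     spots_per_section = 200L, grid_side = 15L,
                     pcw_per_section = c(6, 6, 10, 10),
                     count_noise = "poisson", seed = 23L)
  ref <- generate_reference(cfg)
  secs <- generate_sections(cfg, ref$truth$state_profiles)
  prof <- build_profiles(ref$counts, ref$cell_meta$state)
  maps <- lapply(secs$sections, fit_proportions, profiles = prof)
  part <- assign_age_groups(c(6, 6, 10, 10), names(secs$sections),
                            bounds = list(`5.5-6` = c(5.5, 6),
                                          `9-14` = c(9, 14)))
  st <- group_stability(maps, part)
  off <- st$stability[st$stability$group_a != st$stability$group_b, ]
  expect_gte(off$score_correlation, 0.9)
  expect_gte(off$edge_jaccard, 0.8)
})
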