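test_that("codebook construction and CSV loading validate codes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,round_1,round_2", "GA,0,1", "GB,1,0"), path)
  cb <- load_codebook(path, n_channels = 2)
  expect_equal(length(cb$genes), 2)
  expect_equal(unname(cb$code["GA", ]), c(1L, 2L))
  writeLines(c("gene,round_1,round_2", "GA,0,1", "GB,0,1"), path)
  expect_error(load_codebook(path, n_channels = 2), "duplicate barcode")
  writeLines(c("gene,round_1,round_2", "GA,0,1", "GA,1,0"), path)
  expect_error(load_codebook(path, n_channels = 2), "duplicate gene")
  writeLines(c("gene,round_1,round_2", "GA,0,5", "GB,1,0"), path)
  expect_error(load_codebook(path, n_channels = 2), "out of range")
  # a 150-gene 5x5 panel draws without collision and round-trips
  cb150 <- make_codebook(150, 5, 5, seed = 3)
  keys <- apply(cb150$code, 1, paste, collapse = "-")
  expect_equal(anyDuplicated(keys), 0L)
  write_codebook(cb150, path)
  back <- load_codebook(path, n_channels = 5)
  expect_equal(back$code, cb150$code)
  expect_error(make_codebook(30, 2, 5), "unique codes")
})

test_that("noise-free one-hot tensors decode to the planted gene with quality 1", {
  cb <- make_codebook(20, 5, 5, seed = 6)
  sim <- generate_iss(cb, 100, background = 0, signal = 3, seed = 8)
  calls <- decode_spots(sim$tensor, cb)
  expect_equal(calls$called_gene,
               unname(sim$truth$iss_gene_of_spot[calls$spot_id]))
  expect_true(all(calls$mean_quality == 1))
  expect_true(all(calls$min_quality == 1))
  expect_false(any(calls$flagged))
})

test_that("per-round quality follows the L1 rule, with hand-checked mean and min", {
  cb <- codebook(c("GA", "GB"), rbind(c(1, 1, 1, 1, 1), c(2, 2, 2, 2, 2)), 5)
  # round intensities (0.6, 0.1, 0.1, 0.1, 0.1) -> q_r = 0.6; vary one round
  intens <- array(0.1, dim = c(1, 5, 5))
  intens[1, , 1] <- 0.6
  intens[1, 3, 1] <- 0.3   # round 3: (0.3,.1,.1,.1,.1) -> q = 0.3/0.7
  calls <- decode_spots(intens, cb)
  q <- unlist(calls[1, paste0("quality_r", 1:5)], use.names = FALSE)
  expect_equal(q, c(0.6, 0.6, 0.3 / 0.7, 0.6, 0.6))
  expect_equal(calls$mean_quality, mean(c(0.6, 0.6, 0.3 / 0.7, 0.6, 0.6)))
  expect_equal(calls$min_quality, 0.3 / 0.7)
  expect_equal(calls$called_gene, "GA")
  # background equal to signal everywhere: q = 2b / 6b = 1/3 each round
  intens2 <- array(1, dim = c(1, 5, 5))
  intens2[1, , 2] <- 2
  calls2 <- decode_spots(intens2, cb)
  expect_equal(unlist(calls2[1, paste0("quality_r", 1:5)],
                      use.names = FALSE), rep(1 / 3, 5))
  expect_equal(calls2$called_gene, "GB")
})

test_that("uniform and all-zero rounds hit the 1/C floor, tie-break to channel 1, and get flagged", {
  cb <- codebook(c("GA"), rbind(rep(1, 5)), 5)
  uni <- array(1, dim = c(1, 5, 5))
  calls <- decode_spots(uni, cb)
  expect_equal(calls$mean_quality, 0.2)
  expect_equal(calls$barcode, "1-1-1-1-1")
  expect_true(calls$flagged)
  zero <- array(0, dim = c(1, 5, 5))
  callz <- decode_spots(zero, cb)
  expect_equal(callz$min_quality, 0.2)
  expect_true(callz$flagged)
  expect_error(decode_spots(array(-1, dim = c(1, 5, 5)), cb),
               "non-negative")
  expect_error(decode_spots(array(NaN, dim = c(1, 5, 5)), cb), "finite")
})

test_that("quality is bounded in [1/C, 1] and strictly decreases with uniform background", {
  cb <- codebook(c("GA"), rbind(rep(1, 5)), 5)
  s <- 10
  qs <- vapply(c(0, 1, 2, 5, 10, 50), function(b) {
    intens <- array(b, dim = c(1, 5, 5))
    intens[1, , 1] <- s + b
    decode_spots(intens, cb)$mean_quality
  }, 1)
  expect_true(all(diff(qs) < 0))
  # analytic form q = (s+b)/(s+Cb)
  expect_equal(qs, (s + c(0, 1, 2, 5, 10, 50)) /
                 (s + 5 * c(0, 1, 2, 5, 10, 50)))
  # random tensors stay within bounds
  set.seed(5)
  intens <- array(runif(40 * 5 * 5), dim = c(40, 5, 5))
  calls <- decode_spots(intens, cb)
  qmat <- as.matrix(calls[paste0("quality_r", 1:5)])
  expect_true(all(qmat >= 1 / 5 - 1e-12 & qmat <= 1))
  expect_true(all(calls$min_quality <= calls$mean_quality))
})

test_that("the L2 option uses the channel norm and its floor sits at 1/sqrt(C)", {
  cb <- codebook(c("GA"), rbind(rep(1, 3)), 3)
  intens <- array(1, dim = c(1, 3, 3))
  calls <- decode_spots(intens, cb, quality_norm = "l2")
  expect_equal(unname(unlist(calls[paste0("quality_r", 1:3)])),
               rep(1 / sqrt(3), 3))
})

test_that("the minimum-quality filter is strict and matches a brute-force filter", {
  cb <- make_codebook(50, 5, 5, seed = 10)
  sim <- generate_iss(cb, 1000, background = 3, signal = 6, noise_sd = 2,
                      seed = 12)
  calls <- decode_spots(sim$tensor, cb)
  kept <- suppressMessages(filter_calls(calls, 0.4))
  brute <- calls[!is.na(calls$called_gene) & calls$min_quality > 0.4, ]
  expect_equal(nrow(kept), nrow(brute))
  expect_equal(kept$spot_id, brute$spot_id)
  # a row at exactly the threshold is removed
  calls2 <- calls[1:2, ]
  calls2$min_quality <- c(0.4, 0.400001)
  calls2$called_gene <- cb$genes[1:2]
  kept2 <- suppressMessages(filter_calls(calls2, 0.4))
  expect_equal(nrow(kept2), 1)
  expect_equal(kept2$min_quality, 0.400001)
  # empty in, empty out
  empty <- suppressMessages(filter_calls(calls[0, ], 0.4))
  expect_equal(nrow(empty), 0)
})

test_that("filtering improves call precision under background noise", {
  cb <- make_codebook(50, 5, 5, seed = 14)
  sim <- generate_iss(cb, 2000, background = 2, signal = 8, noise_sd = 3,
                      seed = 16)
  calls <- decode_spots(sim$tensor, cb)
  truth <- unname(sim$truth$iss_gene_of_spot[calls$spot_id])
  precision <- function(tab, tr) {
    dec <- !is.na(tab$called_gene)
    if (!sum(dec)) return(NA_real_)
    mean(tab$called_gene[dec] == tr[dec])
  }
  kept <- suppressMessages(filter_calls(calls, 0.4))
  expect_gte(precision(kept, truth[match(kept$spot_id, calls$spot_id)]),
             precision(calls, truth))
})

test_that("expression maps group filtered calls by gene with exact counts", {
  cb <- make_codebook(30, 5, 5, seed = 18)
  sim <- generate_iss(cb, 500, background = 0, signal = 5, seed = 20)
  calls <- decode_spots(sim$tensor, cb)
  kept <- suppressMessages(filter_calls(calls, 0.4))
  em <- expression_map(kept)
  planted <- table(sim$truth$iss_gene_of_spot)
  expect_equal(em$counts[sort(names(em$counts))],
               c(planted)[sort(names(em$counts))])
  expect_equal(sum(em$counts), nrow(kept))
  # a gene with 3 calls yields one entry with 3 coordinate rows
  g3 <- names(em$counts)[em$counts == em$counts[1]][1]
  expect_equal(nrow(em$positions[[g3]]), unname(em$counts[g3]))
})

test_that("tensor CSV round-trips exactly", {
  cb <- make_codebook(10, 3, 4, seed = 22)
  sim <- generate_iss(cb, 30, background = 1, signal = 4, noise_sd = 0.5,
                      seed = 24)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_tensor(sim$tensor, path)
  back <- read_signal_tensor(path)
  expect_equal(back$intensities, sim$tensor$intensities, tolerance = 1e-9)
  expect_equal(back$coords$x, sim$tensor$coords$x, tolerance = 1e-9)
})
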