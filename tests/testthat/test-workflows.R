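test_that("sliding profile window count and placement follow the step formula", {
  x <- random_signal(3970, seed = 41)
  prof <- sliding_profile(x, "pe", window_length = 1000, step = 30, d = 3)
  expect_equal(length(prof$values), 100L) # floor((3970-1000)/30)+1
  expect_equal(prof$offsets[1], 1L)
  expect_equal(prof$offsets[100], 2971L)
  expect_lte(prof$offsets[100] + prof$window_length - 1L, length(x))

  # Bonn-style segment length: trailing samples that fill no window are unused
  x2 <- random_signal(4097, seed = 42)
  prof2 <- sliding_profile(x2, "pe", 1000, 30, d = 3)
  expect_equal(length(prof2$values), (4097 - 1000) %/% 30 + 1)

  # single window equals the whole-signal entropy
  x3 <- random_signal(1000, seed = 43)
  prof3 <- sliding_profile(x3, "npe", 1000, 30, d = 3, error = 0.005)
  expect_equal(length(prof3$values), 1L)
  expect_equal(prof3$values, npe(x3, 3, 0.005)$value)

  expect_error(sliding_profile(runif(100), "pe", 1000, 30), "too short")
})

test_that("sliding profile of a stationary periodic signal is flat", {
  x <- periodic_signal(1:5, 4000)
  prof <- sliding_profile(x, "npe", window_length = 1000, step = 500,
                          d = 3, error = 0.0005)
  expect_equal(length(prof$values), 7L)
  expect_true(all(abs(prof$values - prof$values[1]) < 1e-12))
})

test_that("1D sweeps have inclusive endpoints and the printed grid sizes", {
  expect_equal(length(npentropy:::axis_values(3.4, 4, 0.0024)), 251L)
  expect_equal(length(npentropy:::axis_values(-2, 8, 0.04)), 251L)
  expect_equal(length(npentropy:::axis_values(0, 1, n_points = 101)), 101L)

  sw <- sweep_1d("logistic", "mu", 3.5, 3.7, step = 0.1, method = "pe",
                 d = 3, n = 300)
  expect_equal(sw$grid, c(3.5, 3.6, 3.7))
  expect_true(all(sw$values >= 0 & sw$values <= 1))

  # degenerate one-point sweep equals a direct call
  one <- sweep_1d("logistic", "mu", 3.6, 3.6, n_points = 1, method = "pe",
                  d = 3, n = 300)
  expect_equal(one$values, pe(logistic_series(3.6, 300), 3))

  expect_error(sweep_1d("nosuch", "mu", 0, 1, 0.1), "unknown generator")
  expect_error(sweep_1d("logistic", "bogus", 0, 1, 0.1), "unknown parameter")
})

test_that("2D sweeps fill the grid, flag diverged cells, and match direct calls", {
  sw <- sweep_2d("fractional_henon", "a", 1.0, 1.2, x_step = 0.1,
                 "nu", 0.9, 1.0, y_step = 0.1,
                 method = "pe", d = 3, n = 200, b = 0.2)
  expect_equal(dim(sw$values), c(2L, 3L))
  # single cell equals the direct computation
  cell <- sweep_2d("fractional_henon", "a", 1.1, 1.1, x_n = 1,
                   "nu", 1, 1, y_n = 1, method = "pe", d = 3, n = 200, b = 0.2)
  expect_equal(dim(cell$values), c(1L, 1L))
  expect_equal(cell$values[1, 1],
               pe(fractional_henon_series(a = 1.1, b = 0.2, nu = 1, n = 200), 3))

  # a diverging parameter produces an NA cell, not an error
  div <- sweep_2d("fractional_henon", "a", 1.1, 8, x_n = 2,
                  "nu", 1, 1, y_n = 1, method = "pe", d = 3, n = 200, b = 0.2)
  expect_true(is.na(div$values[1, 2]))
  expect_false(is.na(div$values[1, 1]))
})

test_that("signals round-trip through ASCII and CSV readers", {
  p <- tempfile(fileext = ".txt")
  writeLines(c("# generator: toy", "1", "3", "4"), p)
  expect_equal(read_signal(p), c(1, 3, 4))

  write_signal(periodic_signal(1:5, 100), p,
               header = list(generator = "periodic", n = 100))
  expect_equal(read_signal(p), periodic_signal(1:5, 100))

  pc <- tempfile(fileext = ".csv")
  writeLines(c("1,10.5", "2,11.5", "3,12.5"), pc)
  expect_equal(read_signal(pc, "csv", column = 2), c(10.5, 11.5, 12.5))

  writeLines(c("1", "oops", "3"), p)
  expect_error(read_signal(p), "line 2")
  writeLines(character(0), p)
  expect_error(read_signal(p), "empty")
  unlink(c(p, pc))
})

test_that("results round-trip losslessly through JSON and carry config in TSV", {
  toy <- c(1, 3, 4, 5, 4, 5, 3, 1, 2, 4, 5, 3)
  res <- npe(toy, 3, 0.5)
  pj <- tempfile(fileext = ".json")
  write_results(res, pj, "json")
  back <- read_results(pj)
  expect_equal(back$value, res$value, tolerance = 1e-12)
  expect_equal(back$probabilities, res$probabilities, tolerance = 1e-12)
  expect_equal(back$d, 3)

  pt <- tempfile(fileext = ".tsv")
  write_results(res, pt, "tsv")
  head <- readLines(pt, n = 1)
  expect_match(head, "error=0.5")
  tab <- utils::read.delim(pt, comment.char = "#")
  expect_equal(nrow(tab), 10L)

  prof <- sliding_profile(periodic_signal(1:4, 300), "pe",
                          window_length = 100, step = 50, d = 3)
  write_results(prof, pj, "json")
  back2 <- read_results(pj)
  expect_equal(back2$values, prof$values, tolerance = 1e-12)
  expect_equal(back2$offsets, prof$offsets)

  sw <- sweep_1d("logistic", "mu", 3.5, 3.7, step = 0.1, method = "pe",
                 d = 3, n = 200)
  write_results(sw, pj, "json")
  back3 <- read_results(pj)
  expect_equal(back3$values, sw$values, tolerance = 1e-12)
  expect_equal(back3$grid, sw$grid)
  write_results(sw, pt, "tsv")
  tab3 <- utils::read.delim(pt, comment.char = "#")
  expect_equal(tab3$value, unname(sw$values), tolerance = 1e-10)
  unlink(c(pj, pt))
})

test_that("entropy_of dispatches to every method consistently", {
  x <- random_signal(400, seed = 44)
  expect_equal(entropy_of(x, "pe", d = 3), pe(x, 3))
  expect_equal(entropy_of(x, "wpe", d = 3), wpe(x, 3))
  expect_equal(entropy_of(x, "ipe", d = 3, L = 4), ipe(x, 3, 4))
  expect_equal(entropy_of(x, "npe", d = 3, error = 0.005),
               npe(x, 3, 0.005)$value)
})
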