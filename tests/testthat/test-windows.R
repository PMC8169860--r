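test_that("window construction matches the scheme for Y = 34, n = 5", {
  ws <- build_windows(windowing_config(34, 5))
  w <- ws$windows
  main <- w[w$kind == "main", ]
  expect_equal(nrow(main), 30L)
  expect_equal(main$start_year, 1:30)
  expect_equal(main$end_year, 5:34)
  expect_true(all(main$length == 5L))

  aux <- w[w$kind != "main", ]
  expect_equal(nrow(aux), 8L)
  head <- aux[aux$kind == "aux_head", ]
  expect_equal(head$index, 2:5)
  expect_equal(unname(cbind(head$start_year, head$end_year)),
               cbind(rep(1L, 4), 1:4))
  tail <- aux[aux$kind == "aux_tail", ]
  expect_equal(tail$index, 26:29)
  expect_equal(unname(cbind(tail$start_year, tail$end_year)),
               cbind(31:34, rep(34L, 4)))
})

test_that("every year is covered by exactly n windows and counts add up", {
  for (cfg in list(c(10, 5), c(12, 3), c(34, 5), c(20, 4))) {
    wc <- windowing_config(cfg[1], cfg[2])
    ws <- build_windows(wc)
    expect_equal(nrow(ws$windows), (cfg[1] - cfg[2] + 1) + 2 * (cfg[2] - 1))
    for (y in seq_len(cfg[1])) {
      expect_equal(nrow(covering_windows(ws, y)), cfg[2])
    }
    # successive main windows overlap by n - 1 years
    main <- ws$windows[ws$windows$kind == "main", ]
    expect_true(all(diff(main$start_year) == 1L))
  }
})

test_that("invalid windowing configurations are rejected with clear errors", {
  expect_error(windowing_config(9, 5), "Y >= 2n")
  expect_error(windowing_config(10, 1), "n must be >= 2")
  ws <- build_windows(windowing_config(12, 3))
  expect_error(covering_windows(ws, 0), "outside")
  expect_error(covering_windows(ws, 13), "outside")
})

test_that("covering windows match the enumerated cases for Y = 34, n = 5", {
  ws <- build_windows(windowing_config(34, 5))
  key <- function(d) sort(paste(d$kind, d$index, sep = ":"))
  expect_equal(key(covering_windows(ws, 1)),
               sort(c("main:1", paste0("aux_head:", 2:5))))
  expect_equal(key(covering_windows(ws, 10)), sort(paste0("main:", 6:10)))
  expect_equal(key(covering_windows(ws, 34)),
               sort(c("main:30", paste0("aux_tail:", 26:29))))
})

test_that("year weights are normalized, symmetric, and match year-1 pattern", {
  for (cfg in list(c(10, 5), c(12, 3), c(34, 5))) {
    wc <- windowing_config(cfg[1], cfg[2])
    for (y in seq_len(cfg[1])) {
      w <- year_weights(wc, y)
      expect_equal(sum(w$weight), 1, tolerance = 1e-12)
      expect_true(all(w$weight >= 0))
      # weight multiset at year y mirrors year Y - y + 1
      w2 <- year_weights(wc, cfg[1] - y + 1)
      expect_equal(sort(w$weight), sort(w2$weight), tolerance = 1e-12)
    }
  }
  w1 <- year_weights(windowing_config(34, 5), 1)
  expect_equal(w1$weight[order(w1$kind, w1$index)],
               c(1, 2, 3, 4, 5) / 15)
})

test_that("three-branch combination equals the brute-force length-weighted oracle", {
  for (cfg in list(c(10, 5), c(12, 3), c(34, 5))) {
    wc <- windowing_config(cfg[1], cfg[2])
    ws <- build_windows(wc)
    est <- random_estimates(ws, d = 3, seed = 100 + cfg[1])
    for (y in seq_len(cfg[1])) {
      expect_equal(yearly_weighted_average(est, y, wc),
                   brute_force_yearly_average(est, y, ws),
                   tolerance = 1e-12)
    }
  }
})

test_that("central years are plain means of main windows; constants are fixed points", {
  wc <- windowing_config(34, 5)
  ws <- build_windows(wc)
  est <- random_estimates(ws, d = 2, seed = 7)
  keys <- vapply(est, function(e)
    paste(e$window$kind, e$window$index, sep = ":"), "")
  mains <- sapply(paste0("main:", 6:10), function(k) est[[match(k, keys)]]$values)
  expect_equal(yearly_weighted_average(est, 10, wc), rowMeans(mains),
               tolerance = 1e-12)

  cst <- lapply(seq_len(nrow(ws$windows)), function(i)
    window_estimate(ws$windows[i, ], c(a = 1.5, b = -2), objective = 0))
  for (y in c(1, 3, 17, 33, 34)) {
    expect_equal(yearly_weighted_average(cst, y, wc), c(a = 1.5, b = -2))
  }
})

test_that("missing window estimates are reported by identity", {
  wc <- windowing_config(12, 3)
  ws <- build_windows(wc)
  est <- random_estimates(ws, d = 1, seed = 3)
  expect_error(yearly_weighted_average(est[-1], 1, wc), "main:1")
})

test_that("window sets serialize to CSV with calendar years", {
  wc <- windowing_config(12, 3, first_year = 1990)
  f <- withr::local_tempfile(fileext = ".csv")
  write_windows_csv(build_windows(wc), f)
  d <- read.csv(f)
  expect_named(d, c("window_index", "kind", "start_year", "end_year", "length"))
  expect_equal(min(d$start_year), 1990)
  expect_equal(max(d$end_year), 2001)
  expect_equal(sum(d$kind == "main"), 10)
})
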