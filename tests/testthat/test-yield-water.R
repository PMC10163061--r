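test_that("the yield response evaluates and peaks where published", {
  expect_equal(yield_from_laimax(0), 5824)
  expect_equal(round(yield_from_laimax(6.043), 1), 7171.7)
  v <- response_vertex(yield_response())
  expect_equal(round(v[["x"]], 3), 6.043)
  expect_equal(round(v[["y"]], 1), 7171.7)

  # dense-grid argmax oracle
  grid <- seq(0, 12, length.out = 1e6)
  yy <- yield_from_laimax(grid)
  expect_equal(v[["x"]], grid[which.max(yy)], tolerance = 2 * 12 / 1e6)
  expect_equal(v[["y"]], max(yy), tolerance = 1e-6)
})

test_that("the leaf-area response evaluates, peaks, and is symmetric about its vertex", {
  v <- response_vertex(laimax_response())
  expect_equal(round(v[["x"]], 3), 573.541)
  # the vertex *value* from the printed coefficients (~6.438)
  expect_equal(round(v[["y"]], 3), 6.438)
  expect_equal(laimax_from_irrigation(v[["x"]]), v[["y"]])
  expect_equal(laimax_from_irrigation(v[["x"]] - 30),
               laimax_from_irrigation(v[["x"]] + 30))
  expect_equal(response_vertex(quad_response(-1, 2, 0)), c(x = 1, y = 1))
})

test_that("root solving for a target leaf area picks the requested branch", {
  w <- irrigation_for_laimax(6.043, branch = "ascending")
  expect_equal(round(w, 3), 518.793)
  expect_equal(laimax_from_irrigation(w), 6.043, tolerance = 1e-9)
  expect_gt(irrigation_for_laimax(6.043, branch = "descending"), w)

  v <- response_vertex(laimax_response())
  expect_equal(irrigation_for_laimax(v[["y"]]), v[["x"]], tolerance = 1e-3)
  expect_error(irrigation_for_laimax(7), "no real root")

  # ascending-branch round trip below the vertex
  for (w0 in c(450, 500, 550)) {
    expect_equal(irrigation_for_laimax(laimax_from_irrigation(w0)), w0,
                 tolerance = 1e-9)
  }
})

test_that("the two IWUE modes behave as documented", {
  w <- irrigation_for_laimax(6.043)
  expect_equal(round(iwue(w, "as_printed"), 3), 21.153)
  expect_equal(iwue(w, "composed"), yield_from_laimax(6.043) / w,
               tolerance = 1e-12)
  expect_equal(round(iwue(518.793, "composed"), 3), 13.824)

  # composed mode at the exact ascending optimum equals vertex yield / W
  v <- response_vertex(yield_response())
  w_exact <- irrigation_for_laimax(v[["x"]])
  expect_equal(iwue(w_exact, "composed"), v[["y"]] / w_exact, tolerance = 1e-9)

  # both modes agree when the exact composition is rounded to print precision
  cf <- compose_yield_irrigation()
  rounded <- c(signif(cf[1], 5), signif(cf[2], 2), round(cf[3], 4),
               round(cf[4], 3), round(cf[5], 3))
  num <- sum(rounded * w^(4:0))
  expect_equal(num / w, iwue(w, "as_printed"), tolerance = 0.01 * iwue(w, "as_printed"))
  expect_error(iwue(-5), "positive")
})

test_that("composing the two responses reproduces the printed quartic coefficients", {
  cf <- compose_yield_irrigation()
  expect_equal(cf[["w4"]], -6.4197e-7, tolerance = 5e-5)   # relative
  expect_equal(cf[["w3"]], 0.0015, tolerance = 5e-5 / 0.0015)
  expect_equal(cf[["w2"]], -1.2632, tolerance = 5e-5 / 1.2632)
  expect_equal(cf[["w1"]], 480.061, tolerance = 5e-4 / 480.061)
  expect_equal(cf[["w0"]], -61035.362, tolerance = 5e-4 / 61035.362)
  # hand expansions of the extreme coefficients
  expect_equal(cf[["w4"]], -36.9 * (1.319e-4)^2)
  expect_equal(cf[["w0"]], -36.9 * 36.95^2 + 446 * -36.95 + 5824)
})

test_that("bin_average computes category means over half-open bins", {
  d <- tibble::tibble(x = c(2.5, 2.7), y = c(10, 20))
  b <- bin_average(d, edges = c(2, 3))
  expect_equal(b$x_mean, 2.6)
  expect_equal(b$y_mean, 15)
  expect_equal(b$n, 2L)

  # boundary value joins the upper bin under [lo, hi)
  d2 <- tibble::tibble(x = c(440, 450, 460), y = 1:3)
  b2 <- bin_average(d2, edges = c(400, 450, 500))
  expect_equal(b2$n, c(1L, 2L))
  expect_equal(b2$x_mean[2], 455)
  # ...except the final edge, which closes the last bin
  b3 <- bin_average(tibble::tibble(x = 500, y = 1), edges = c(400, 450, 500))
  expect_equal(b3$bin_lo, 450)

  # brute-force oracle on random data over the published irrigation bins
  set.seed(99)
  d4 <- tibble::tibble(x = runif(200, 390, 710), y = rnorm(200))
  edges <- seq(400, 700, by = 50)
  b4 <- bin_average(d4, edges)
  for (i in seq_len(nrow(b4))) {
    lo <- b4$bin_lo[i]; hi <- b4$bin_hi[i]
    inb <- if (hi == 700) d4$x >= lo & d4$x <= hi else d4$x >= lo & d4$x < hi
    expect_equal(b4$n[i], sum(inb))
    expect_equal(b4$x_mean[i], mean(d4$x[inb]))
    expect_equal(b4$y_mean[i], mean(d4$y[inb]))
    expect_true(b4$x_mean[i] >= lo && b4$x_mean[i] <= hi)
  }
  expect_equal(attr(b4, "dropped"), sum(d4$x < 400 | d4$x > 700))
  expect_error(bin_average(tibble::tibble(x = 1, y = 1), edges = c(5, 6)),
               "inside the bin range")
})

test_that("yield_summary chains the published optimisation end to end", {
  s <- yield_summary()
  expect_equal(s$laimax_opt, 6.043)
  expect_equal(round(s$yield_max_kg_ha, 1), 7171.7)
  expect_equal(round(s$w_required_mm, 3), 518.793)
  expect_equal(round(s$iwue_as_printed, 3), 21.153)
  expect_lt(s$iwue_composed, s$iwue_as_printed)
})
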