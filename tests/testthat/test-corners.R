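# Independent Harris oracle: explicit nested-loop Sobel derivatives,
# Gaussian windowing and response evaluation, sharing no code with the
# package's filtering path.
oracle_harris <- function(px, k = 0.05, form = c("squared_trace", "printed")) {
  form <- match.arg(form)
  h <- nrow(px); w <- ncol(px)
  cl <- function(i, n) min(max(i, 1), n)
  at <- function(r, c) px[cl(r, h), cl(c, w)]
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    gx[r, c] <- (at(r - 1, c + 1) + 2 * at(r, c + 1) + at(r + 1, c + 1)) -
      (at(r - 1, c - 1) + 2 * at(r, c - 1) + at(r + 1, c - 1))
    gy[r, c] <- (at(r + 1, c - 1) + 2 * at(r + 1, c) + at(r + 1, c + 1)) -
      (at(r - 1, c - 1) + 2 * at(r - 1, c) + at(r - 1, c + 1))
  }
  g1 <- dnorm(-3:3, sd = 1.5); g1 <- g1 / sum(g1)
  wgt <- outer(g1, g1)
  R <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    sxx <- 0; syy <- 0; sxy <- 0
    for (dr in -3:3) for (dc in -3:3) {
      rr <- cl(r + dr, h); cc <- cl(c + dc, w)
      wv <- wgt[dr + 4, dc + 4]
      sxx <- sxx + wv * gx[rr, cc]^2
      syy <- syy + wv * gy[rr, cc]^2
      sxy <- sxy + wv * gx[rr, cc] * gy[rr, cc]
    }
    det_m <- sxx * syy - sxy^2
    tr_m <- sxx + syy
    R[r, c] <- if (form == "squared_trace") det_m - k * tr_m^2
               else det_m - k * tr_m
  }
  R
}

test_that("constant and empty-ish images yield zero corners", {
  expect_equal(nrow(detect_corners(image_grid(matrix(5, 32, 32)))), 0L)
  expect_equal(nrow(detect_corners(image_grid(matrix(0, 20, 20)))), 0L)
})

test_that("a white square yields four corners at its vertices", {
  img <- square_image(64, lo = 21, hi = 45, value = 200)  # 0-based 20..44
  cs <- detect_corners(img, k = 0.05, threshold = 1500)
  expect_equal(nrow(cs), 4L)
  vertices <- expand.grid(x = c(20, 44), y = c(20, 44))
  for (i in seq_len(4)) {
    d <- sqrt((cs$x - vertices$x[i])^2 + (cs$y - vertices$y[i])^2)
    expect_lte(min(d), sqrt(2))  # within 1 px per axis
  }
})

test_that("the response map matches the brute-force Harris oracle", {
  set.seed(21)
  px <- square_image(40, lo = 12, hi = 28, value = 150)$pixels +
    matrix(rnorm(1600, sd = 2), 40, 40)
  for (form in c("squared_trace", "printed")) {
    Rpkg <- hogreg:::harris_response(px, k = 0.05, response_form = form)
    Rorc <- oracle_harris(px, k = 0.05, form = form)
    expect_equal(Rpkg, Rorc, tolerance = 1e-9)
  }
})

test_that("detected corners equal the oracle's thresholded local maxima", {
  img <- square_image(48, lo = 14, hi = 34, value = 180)
  cs <- detect_corners(img, k = 0.05, threshold = 1500)
  R <- oracle_harris(img$pixels)
  # oracle-side 5x5 NMS with the same 4 px margin
  hits <- NULL
  for (r in 5:(48 - 4)) for (c in 5:(48 - 4)) {
    nb <- R[max(1, r - 2):min(48, r + 2), max(1, c - 2):min(48, c + 2)]
    if (R[r, c] >= max(nb) && R[r, c] >= 1500 && R[r, c] > 0) {
      hits <- rbind(hits, c(x = c - 1, y = r - 1, resp = R[r, c]))
    }
  }
  # compare as sets: equal responses make the strongest-first order
  # ambiguous, so sort both sides by position
  expect_equal(nrow(cs), nrow(hits))
  ord_pkg <- order(cs$x, cs$y)
  ord_orc <- order(hits[, "x"], hits[, "y"])
  expect_equal(cs$x[ord_pkg], unname(hits[ord_orc, "x"]))
  expect_equal(cs$y[ord_pkg], unname(hits[ord_orc, "y"]))
  expect_equal(cs$response[ord_pkg], unname(hits[ord_orc, "resp"]),
               tolerance = 1e-9)
  expect_true(all(diff(cs$response) <= 1e-9))  # strongest first
})

test_that("the Harris response ignores a constant intensity offset", {
  img <- square_image(48)
  c1 <- detect_corners(img)
  c2 <- detect_corners(image_grid(img$pixels + 57))
  expect_equal(c1$x, c2$x)
  expect_equal(c1$y, c2$y)
  expect_equal(c1$response, c2$response, tolerance = 1e-6)
})

test_that("corner count is non-increasing in the threshold", {
  ph <- generate_phantom_pair(size = 128, seed = 5)
  base <- detect_corners(ph$fixed, threshold = 0)
  thrs <- seq(0, max(base$response) * 1.1, length.out = 10)
  counts <- vapply(thrs, function(thr) {
    nrow(detect_corners(ph$fixed, threshold = thr))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[10])  # the sweep actually bites
})

test_that("corner matching pairs identical sets at distance zero", {
  cs <- detect_corners(square_image(64))
  pr <- match_corners(cs, cs)
  expect_equal(nrow(pr), nrow(cs))
  expect_true(all(pr$distance == 0))
  expect_equal(mean_pair_distance(pr), 0)
})

test_that("corner matching recovers a rigid shift and drops outliers", {
  set.seed(7)
  src <- detect_corners(square_image(64))
  shifted <- src
  shifted$x <- shifted$x + 2
  pr <- match_corners(src, shifted)
  expect_equal(nrow(pr), nrow(src))
  expect_true(all(pr$tgt_x - pr$src_x == 2))
  expect_true(all(pr$tgt_y - pr$src_y == 0))

  # an isolated far-away point has no mutual partner within the gate
  outlier <- tibble::tibble(x = c(src$x, 500), y = c(src$y, 500),
                            response = c(src$response, 1))
  class(outlier) <- class(src)
  pr2 <- match_corners(src, outlier, gate_px = 20)
  expect_equal(nrow(pr2), nrow(src))
  expect_false(500 %in% pr2$tgt_x)
})

test_that("matching is symmetric under swapping source and target", {
  set.seed(12)
  a <- tibble::tibble(x = runif(30, 0, 100), y = runif(30, 0, 100),
                      response = runif(30))
  b <- tibble::tibble(x = runif(25, 0, 100), y = runif(25, 0, 100),
                      response = runif(25))
  class(a) <- c("corner_set", class(a)); class(b) <- c("corner_set", class(b))
  ab <- match_corners(a, b, max_pairs = 100L)
  ba <- match_corners(b, a, max_pairs = 100L)
  expect_equal(nrow(ab), nrow(ba))
  key_ab <- paste(ab$src_x, ab$src_y, ab$tgt_x, ab$tgt_y)
  key_ba <- paste(ba$tgt_x, ba$tgt_y, ba$src_x, ba$src_y)
  expect_setequal(key_ab, key_ba)
})

test_that("mean pair distance matches hand arithmetic and rejects empties", {
  pr <- make_pairing(cbind(0, 0), cbind(3, 4))
  expect_equal(mean_pair_distance(pr), 5)
  set.seed(3)
  src <- cbind(runif(30, 0, 50), runif(30, 0, 50))
  tgt <- src + matrix(rnorm(60), 30, 2)
  pr30 <- make_pairing(src, tgt)
  manual <- sum(sqrt(rowSums((src - tgt)^2))) / 30
  expect_equal(mean_pair_distance(pr30), manual, tolerance = 1e-12)
  empty <- make_pairing(cbind(numeric(0), numeric(0)),
                        cbind(numeric(0), numeric(0)))
  expect_error(mean_pair_distance(empty), "empty")
})

test_that("corner sets and pairings export to CSV", {
  cs <- detect_corners(square_image(64))
  path <- withr::local_tempfile(fileext = ".csv")
  write_corners_csv(cs, path)
  got <- utils::read.csv(path)
  expect_equal(got$x, cs$x)
  expect_equal(got$response, cs$response)
})
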