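test_that("BD is zero for identical distributions, both estimators", {
  set.seed(11)
  px <- ab_pixels(500, c(5, -3), diag(2) * 4)
  for (m in c("histogram", "gaussian")) {
    p <- lab_distribution(px, method = m)
    rec <- bhattacharyya(p, p)
    expect_equal(rec$bd, 0, tolerance = 1e-9)
    expect_equal(rec$bc, 1, tolerance = 1e-9)
  }
})

test_that("BD is symmetric, non-negative, with BC in [0,1]", {
  set.seed(12)
  for (i in 1:25) {
    mu1 <- runif(2, -20, 20)
    mu2 <- runif(2, -20, 20)
    p <- lab_distribution(ab_pixels(300, mu1, diag(2) * runif(1, 1, 9)))
    q <- lab_distribution(ab_pixels(300, mu2, diag(2) * runif(1, 1, 9)))
    ab <- bhattacharyya(p, q)
    ba <- bhattacharyya(q, p)
    expect_identical(ab$bd, ba$bd)
    expect_gte(ab$bd, 0)
    expect_true(ab$bc >= 0 && ab$bc <= 1)
    if (ab$capped) {
      expect_equal(ab$bc, 0) # sentinel stands in for -ln(0)
    } else {
      expect_equal(ab$bd, -log(ab$bc), tolerance = 1e-9)
    }
  }
})

test_that("a point mass lands in a single histogram bin", {
  px <- data.frame(L = 65, a = rep(10.5, 100), b = rep(-3.2, 100))
  p <- lab_distribution(px)
  expect_equal(sum(p$prob > 0), 1)
  expect_equal(sum(p$prob), 1)
})

test_that("disjoint supports report BC = 0 with the capped sentinel", {
  p <- lab_distribution(data.frame(L = 65, a = rep(-50, 100), b = rep(-50, 100)))
  q <- lab_distribution(data.frame(L = 65, a = rep(50, 100), b = rep(50, 100)))
  rec <- bhattacharyya(p, q)
  expect_equal(rec$bc, 0)
  expect_equal(rec$bd, 50)
  expect_true(rec$capped)
})

test_that("distributions are permutation-invariant", {
  set.seed(13)
  px <- ab_pixels(400, c(2, 2), diag(2) * 4)
  p1 <- lab_distribution(px)
  p2 <- lab_distribution(px[sample(nrow(px)), ])
  expect_identical(p1$prob, p2$prob)
  g1 <- lab_distribution(px, method = "gaussian")
  g2 <- lab_distribution(px[rev(seq_len(nrow(px))), ], method = "gaussian")
  expect_equal(g1$mean, g2$mean)
  expect_equal(g1$cov, g2$cov)
})

test_that("Gaussian fit recovers the mean within 3 sd / sqrt(n)", {
  set.seed(14)
  n <- 2000
  mu <- c(4, -7)
  p <- lab_distribution(ab_pixels(n, mu, diag(2) * 9), method = "gaussian")
  expect_true(all(abs(p$mean - mu) < 3 * 3 / sqrt(n)))
})

test_that("histogram BD approaches the Gaussian closed form", {
  set.seed(15)
  n <- 1e5
  # bin width ~ sd/2: coarser bins bias the discretised BD low
  br <- list(a = seq(-60, 60, 0.5), b = seq(-60, 60, 0.5))
  p <- lab_distribution(ab_pixels(n, c(0, 0)), breaks = br)
  q <- lab_distribution(ab_pixels(n, c(5, 0)), breaks = br)
  closed <- 25 / 8 # (1/8) d' S^-1 d with identity covariances, d = (5,0)
  expect_equal(bhattacharyya(p, q)$bd, closed, tolerance = 0.05)
  pg <- lab_distribution(ab_pixels(n, c(0, 0)), method = "gaussian")
  qg <- lab_distribution(ab_pixels(n, c(5, 0)), method = "gaussian")
  expect_equal(bhattacharyya(pg, qg)$bd, closed, tolerance = 0.02)
})

test_that("BD increases strictly with mean separation at fixed covariance", {
  set.seed(16)
  n <- 20000
  bds <- vapply(seq(1, 8, by = 1), function(d) {
    p <- lab_distribution(ab_pixels(n, c(0, 0), diag(2) * 4))
    q <- lab_distribution(ab_pixels(n, c(d, 0), diag(2) * 4))
    bhattacharyya(p, q)$bd
  }, numeric(1))
  expect_true(all(diff(bds) > 0))
})

test_that("mismatched estimators or binning are a hard error", {
  px <- ab_pixels(100, c(0, 0))
  p <- lab_distribution(px)
  g <- lab_distribution(px, method = "gaussian")
  expect_error(bhattacharyya(p, g), "estimator")
  q <- lab_distribution(px, breaks = list(a = seq(-50, 50, 2), b = seq(-50, 50, 2)))
  expect_error(bhattacharyya(p, q), "bin edges")
})

test_that("hue-plane BD is robust to a pure lightness shift", {
  # scaling the luminance moves L* only: (a*, b*) BD barely moves while
  # the full three-channel BD responds strongly
  set.seed(17)
  base <- ab_pixels(5000, c(5, 5), diag(2) * 4)
  lifted <- base
  lifted$L <- base$L + 15
  ab_ref <- lab_distribution(ab_pixels(5000, c(7, 5), diag(2) * 4))
  bd_ab_base <- bhattacharyya(lab_distribution(base), ab_ref)$bd
  bd_ab_lift <- bhattacharyya(lab_distribution(lifted), ab_ref)$bd
  expect_lt(abs(bd_ab_lift - bd_ab_base) / bd_ab_base, 0.1)
  ch3 <- c("L", "a", "b")
  b3 <- bd_breaks(ch3)
  bd_lab_base <- bhattacharyya(
    lab_distribution(base, channels = ch3, breaks = b3),
    lab_distribution(base, channels = ch3, breaks = b3)
  )$bd
  bd_lab_lift <- bhattacharyya(
    lab_distribution(lifted, channels = ch3, breaks = b3),
    lab_distribution(base, channels = ch3, breaks = b3)
  )$bd
  expect_gt(bd_lab_lift, bd_lab_base + 1)
})

test_that("image mean BD follows the missing-data rules", {
  recs <- tibble::tibble(
    image = "a", bd = rep(2, 24), degenerate = FALSE
  )
  expect_equal(image_mean_bd(recs, by = "image")$mean_bd, 2)
  recs2 <- tibble::tibble(
    image = "a", bd = c(rep(0, 23), 50), degenerate = c(rep(FALSE, 23), TRUE)
  )
  out <- image_mean_bd(recs2, by = "image")
  expect_equal(out$mean_bd, 0)
  expect_equal(out$n_rois, 23L)
  recs3 <- tibble::tibble(image = "a", bd = 1, degenerate = TRUE)
  expect_warning(out3 <- image_mean_bd(recs3, by = "image"), "no usable ROI")
  expect_equal(nrow(out3), 0)
})
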