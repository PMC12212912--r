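test_that("perfectly correlated data give r = 1 with a vanishing p", {
  d <- data.frame(x = 1:10, y = 1:10)
  res <- pearson_with_ci(d, "x", "y")
  expect_equal(res$r, 1)
  expect_lt(res$p_value, 1e-12)
})

test_that("correlation matches the brute-force formulas on random draws", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    d <- data.frame(x = rnorm(n), y = rnorm(n))
    got <- pearson_with_ci(d, "x", "y")
    ref <- pearson_bruteforce(d$x, d$y)
    expect_equal(got$r, ref$r, tolerance = 1e-12)
    expect_equal(c(got$ci_low, got$ci_high), ref$ci, tolerance = 1e-12)
    expect_equal(got$p_value, ref$p, tolerance = 1e-12)
    expect_true(got$ci_low <= got$r && got$r <= got$ci_high)
  }
})

test_that("under independence r is centred and the CI covers zero ~95%", {
  set.seed(32)
  n_rep <- 400
  rs <- numeric(n_rep)
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- data.frame(x = rnorm(25), y = rnorm(25))
    res <- pearson_with_ci(d, "x", "y")
    rs[i] <- res$r
    covered[i] <- res$ci_low <= 0 && 0 <= res$ci_high
  }
  expect_lt(abs(mean(rs)), 0.05)
  expect_gt(mean(covered), 0.91)
  expect_lt(mean(covered), 0.985)
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(pearson_with_ci(data.frame(x = 1:3, y = 1:3), "x", "y"),
               "at least 4")
  expect_error(pearson_with_ci(data.frame(x = rep(1, 8), y = 1:8), "x", "y"),
               "zero variance")
})

test_that("single-patient ANOVA matches brute-force sums of squares", {
  # 12 observations, 3 severity levels: classic one-way table
  d <- tibble::tibble(
    patient_id = "P01",
    severity = rep(c(2, 5, 8), each = 4),
    mean_bd = c(1.1, 0.9, 1.3, 1.0, 2.2, 2.4, 1.9, 2.1, 3.6, 3.2, 3.9, 3.5)
  )
  fit <- bd_anova(d)
  # brute force
  g <- split(d$mean_bd, d$severity)
  grand <- mean(d$mean_bd)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, numeric(1)))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  f_ref <- (ssb / 2) / (ssw / 9)
  td <- tidy(fit)
  expect_equal(td$statistic[td$term == "severity"], f_ref, tolerance = 1e-10)
  expect_equal(glance(fit)$severity_f, f_ref, tolerance = 1e-10)
})

test_that("balanced two-factor sums of squares decompose exactly", {
  set.seed(33)
  pats <- rep(sprintf("P%02d", 1:4), each = 6)
  sev <- rep(rep(c(1, 4, 7), each = 2), times = 4)
  d <- tibble::tibble(
    patient_id = pats, severity = sev,
    mean_bd = rnorm(24, 2 + 0.2 * sev + as.integer(factor(pats)) * 0.3)
  )
  fit <- bd_anova(d)
  td <- tidy(fit)
  ss_model <- sum(td$sumsq[td$term %in% c("patient", "severity")])
  ss_resid <- td$sumsq[td$term == "Residuals"]
  ss_total <- sum((d$mean_bd - mean(d$mean_bd))^2)
  expect_equal(ss_model + ss_resid, ss_total, tolerance = 1e-9)
  expect_true(all(td$statistic[!is.na(td$statistic)] >= 0))
})

test_that("severity confounded with patient is refused by name", {
  d <- tibble::tibble(
    patient_id = rep(c("P01", "P02"), each = 5),
    severity = rep(c(3, 8), each = 5),
    mean_bd = rnorm(10)
  )
  expect_error(bd_anova(d), "confounded")
})

test_that("a strong built-in severity effect is detected", {
  tbl <- simulate_episode_bd(n_patients = 8, episodes_per_patient = 10,
                             effect = 0.4, seed = 34)
  fit <- bd_anova(tbl)
  expect_lt(glance(fit)$severity_p, 0.001)
})

test_that("Tukey finds no pairs when level means are equal", {
  set.seed(35)
  d <- tibble::tibble(
    patient_id = rep("P01", 30),
    severity = rep(c(2, 5, 8), each = 10),
    mean_bd = rnorm(30, mean = 3, sd = 0.5)
  )
  tk <- tukey_hsd(bd_anova(d))
  expect_false(any(tk$pairs$significant))
})

test_that("well-separated levels with tiny residual variance are significant", {
  set.seed(36)
  d <- tibble::tibble(
    patient_id = rep("P01", 20),
    severity = rep(c(2, 8), each = 10),
    mean_bd = rep(c(1, 5), each = 10) + rnorm(20, sd = 0.01)
  )
  tk <- tukey_hsd(bd_anova(d))
  expect_true(all(tk$pairs$significant))
  # the display contract: non-overlapping comparison intervals
  m <- tk$means
  expect_lt(m$comparison_high[1], m$comparison_low[2])
})

test_that("Tukey intervals match the brute-force studentised range", {
  set.seed(37)
  k <- 3; n <- 10
  d <- tibble::tibble(
    patient_id = "P01",
    severity = rep(c(1, 5, 9), each = n),
    mean_bd = rnorm(k * n, mean = rep(c(1, 2, 4), each = n))
  )
  fit <- bd_anova(d)
  tk <- tukey_hsd(fit)
  g <- split(d$mean_bd, d$severity)
  mse <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1))) / (k * n - k)
  qc <- stats::qtukey(0.95, k, k * n - k)
  means <- vapply(g, mean, numeric(1))
  combs <- utils::combn(names(g), 2)
  for (j in seq_len(ncol(combs))) {
    est <- means[combs[1, j]] - means[combs[2, j]]
    hw <- qc * sqrt(mse / n)
    row <- tk$pairs[tk$pairs$level_1 == combs[1, j] &
                      tk$pairs$level_2 == combs[2, j], ]
    expect_equal(row$estimate, unname(est), tolerance = 1e-9)
    expect_equal(row$ci_high - row$ci_low, 2 * hw, tolerance = 1e-9)
  }
})

test_that("adjusted level means recover a monotone severity effect", {
  tbl <- simulate_episode_bd(n_patients = 10, episodes_per_patient = 12,
                             effect = 0.5, bd_noise_sd = 0.5, seed = 38)
  tk <- tukey_hsd(bd_anova(tbl))
  m <- tk$means[order(as.integer(tk$means$severity)), ]
  keep <- m$n >= 3 # thin extreme levels carry little information
  expect_equal(
    stats::cor(as.integer(m$severity[keep]), m$emmean[keep], method = "spearman"),
    1
  )
})

test_that("summary report computes the order statistics", {
  eps <- tibble::tibble(
    patient_id = "P01",
    episode_id = sprintf("P01-e%02d", 1:3),
    n_images = c(1, 2, 41),
    mean_bd = c(1, 2, 3)
  )
  rep <- summary_report(eps)
  expect_equal(rep$overall$median_images_per_episode, 2)
  expect_equal(rep$overall$min_images_per_episode, 1)
  expect_equal(rep$overall$max_images_per_episode, 41)
  five <- tibble::tibble(
    patient_id = "P01", episode_id = sprintf("e%d", 1:5),
    n_images = 2, mean_bd = 1
  )
  r5 <- summary_report(five)
  expect_equal(r5$overall$median_episodes_per_patient, 5)
  expect_equal(r5$overall$min_episodes_per_patient, 5)
  empty <- summary_report(tibble::tibble())
  expect_s3_class(empty, "rp_summary")
})
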