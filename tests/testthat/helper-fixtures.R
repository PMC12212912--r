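# Shared fixture helpers: small, fast variants of the study conditions.

tiny_image_size <- c(240, 160)

# A rendered hand with a uniform per-digit shift magnitude.
render_tiny <- function(mag = 0, noise_sd = 3, seed = 1, ...) {
  shift <- matrix(rep(mag * c(-0.8, -0.6), each = 8), 8, 2)
  render_hand_image(hand_spec(per_digit_shift = shift, noise_sd = noise_sd,
                              image_size = tiny_image_size, seed = seed, ...))
}

# A small on-disk dataset for ingest/pipeline tests.
tiny_dataset <- function(root, n_patients = 1, episodes_per_patient = 2,
                         seed = 42, ...) {
  generate_dataset(root, n_patients = n_patients,
                   episodes_per_patient = episodes_per_patient,
                   image_size = tiny_image_size, seed = seed, ...)
}

# Union-find over all image pairs closer than the window: an independent
# route to the transitive chaining the window grouper implements.
chain_components_bruteforce <- function(times, window_minutes = 30) {
  n <- length(times)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(as.numeric(times[i]) - as.numeric(times[j])) <= window_minutes * 60) {
        parent[find(i)] <- find(j)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Direct evaluation of the product-moment and Fisher-z formulas.
pearson_bruteforce <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- atanh(r)
  hw <- stats::qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 3)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, ci = tanh(c(z - hw, z + hw)),
       p = 2 * stats::pt(-abs(tstat), n - 2))
}

# Frozen reference L*a*b* values for spot colours, computed with an
# independent implementation of the CIE formulas (scikit-image rgb2lab,
# sRGB/D65/2 degrees).
spot_colours <- rbind(
  c(188, 143, 143), c(255, 0, 0), c(0, 255, 0), c(0, 0, 255),
  c(128, 128, 128), c(200, 160, 140), c(70, 110, 150),
  c(255, 200, 180), c(30, 60, 90), c(210, 180, 160)
)
spot_lab_reference <- rbind(
  c(63.6074, 17.0113, 6.6126),
  c(53.2406, 80.0923, 67.2028),
  c(87.7351, -86.1830, 83.1797),
  c(32.2957, 79.1856, -107.8573),
  c(53.5850, -0.0015, 0.0028),
  c(68.9798, 11.8801, 16.0483),
  c(45.1578, -2.0636, -26.0678),
  c(84.9286, 16.7822, 17.4968),
  c(24.4670, -0.5681, -21.2960),
  c(75.3790, 7.7091, 14.2034)
)

# Gaussian samples wrapped as L*a*b* pixel frames in the (a, b) plane.
ab_pixels <- function(n, mean, sigma = diag(2)) {
  ch <- chol(sigma)
  z <- matrix(stats::rnorm(2 * n), n, 2) %*% ch
  data.frame(L = 65, a = mean[1] + z[, 1], b = mean[2] + z[, 2])
}
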