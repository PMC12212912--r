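mk_images <- function(times, pid = "P01") {
  tibble::tibble(
    patient_id = pid,
    path = sprintf("%s/img%03d.jpg", pid, seq_along(times)),
    timestamp = as.POSIXct(times, tz = "UTC")
  )
}

test_that("images within the window chain into one episode", {
  img <- mk_images(c("2024-01-05 09:00:00", "2024-01-05 09:10:00",
                     "2024-01-05 09:25:00"))
  out <- group_by_window(img)
  expect_equal(unique(out$episode_id), "P01-e01")
  expect_true(all(out$episode_status == "episode"))
})

test_that("singletons and over-window gaps do not form episodes", {
  img <- mk_images(c("2024-01-05 09:00:00", "2024-01-05 09:45:00"))
  out <- group_by_window(img)
  expect_true(all(is.na(out$episode_id)))
  expect_true(all(out$episode_status == "unattached"))
})

test_that("chains split at gaps above the window, including two-by-two", {
  img <- mk_images(c("2024-01-05 09:00:00", "2024-01-05 09:29:00",
                     "2024-01-05 10:10:00", "2024-01-05 10:20:00"))
  out <- group_by_window(img)
  expect_equal(as.vector(table(out$episode_id)), c(2, 2))
})

test_that("a gap of exactly the window joins", {
  img <- mk_images(c("2024-01-05 09:00:00", "2024-01-05 09:30:00"))
  out <- group_by_window(img)
  expect_equal(unique(out$episode_id), "P01-e01")
})

test_that("window grouping is order-invariant and idempotent", {
  set.seed(21)
  t0 <- as.POSIXct("2024-01-05 08:00:00", tz = "UTC")
  img <- tibble::tibble(
    patient_id = "P01",
    path = sprintf("img%03d.jpg", 1:12),
    timestamp = t0 + sort(sample.int(6 * 3600, 12))
  )
  a <- group_by_window(img)
  b <- group_by_window(img[sample(12), ])
  b <- b[order(b$path), ]
  a <- a[order(a$path), ]
  expect_equal(a$episode_id, b$episode_id)
  again <- group_by_window(a[, names(img)])
  expect_equal(again$episode_id[order(again$path)], a$episode_id)
})

test_that("window grouping matches brute-force chain components", {
  set.seed(22)
  t0 <- as.POSIXct("2024-01-05 00:00:00", tz = "UTC")
  for (rep in 1:50) {
    n <- sample(2:12, 1)
    # minute-resolution stamps so exact-30-min boundaries occur often
    times <- t0 + sort(sample.int(300, n)) * 60
    img <- tibble::tibble(patient_id = "P01",
                          path = sprintf("i%02d", 1:n), timestamp = times)
    got <- group_by_window(img)
    comp <- chain_components_bruteforce(times)
    sizes <- table(comp)
    expected_status <- ifelse(sizes[as.character(comp)] >= 2,
                              "episode", "unattached")
    expect_equal(got$episode_status, as.vector(expected_status))
    # same partition: episode ids constant exactly within brute components
    for (cc in unique(comp[got$episode_status == "episode"])) {
      expect_equal(length(unique(got$episode_id[comp == cc])), 1)
    }
    expect_equal(length(unique(stats::na.omit(got$episode_id))),
                 sum(sizes >= 2))
  }
})

test_that("every image lands in exactly one of episode/unattached/no-timestamp", {
  img <- mk_images(c("2024-01-05 09:00:00", "2024-01-05 09:10:00",
                     "2024-01-05 12:00:00"))
  img$timestamp[3] <- NA
  expect_warning(out <- group_by_window(img), "without timestamp")
  expect_equal(sort(out$episode_status), c("episode", "episode", "no_timestamp"))
})

test_that("app-delimited grouping assigns images to their attack record", {
  img <- mk_images(c("2024-01-05 09:00:00", "2024-01-05 09:05:00",
                     "2024-01-05 09:10:00"))
  atk <- tibble::tibble(patient_id = "P01",
                        end_time = as.POSIXct("2024-01-05 09:12:00", tz = "UTC"),
                        severity = 7L)
  out <- group_by_app(img, atk)
  expect_true(all(out$episode_status == "episode"))
  expect_true(all(out$severity == 7L))
  expect_equal(length(unique(out$episode_id)), 1)
})

test_that("images far after the only attack end stay unassigned", {
  img <- mk_images("2024-01-05 11:12:00")
  atk <- tibble::tibble(patient_id = "P01",
                        end_time = as.POSIXct("2024-01-05 09:12:00", tz = "UTC"),
                        severity = 3L)
  out <- group_by_app(img, atk)
  expect_equal(out$episode_status, "unassigned")
  expect_true(is.na(out$severity))
})

test_that("interleaved attacks partition images by record span", {
  img <- mk_images(c("2024-01-05 09:00:00", "2024-01-05 09:05:00",
                     "2024-01-05 10:00:00", "2024-01-05 10:06:00"))
  atk <- tibble::tibble(
    patient_id = "P01",
    end_time = as.POSIXct(c("2024-01-05 09:08:00", "2024-01-05 10:07:00"),
                          tz = "UTC"),
    severity = c(2L, 8L)
  )
  out <- group_by_app(img, atk)
  # brute-force assignment: earliest record whose window contains the image
  expect_equal(out$severity, c(2L, 2L, 8L, 8L))
  expect_equal(length(unique(out$episode_id)), 2)
})

test_that("episode mean BD averages usable images only", {
  base <- tibble::tibble(
    patient_id = "P01", episode_id = "P01-e01",
    timestamp = as.POSIXct("2024-01-05 09:00:00", tz = "UTC") + (0:2) * 300,
    mean_bd = c(1, 2, 3)
  )
  expect_equal(episode_mean_bd(base)$mean_bd, 2)
  two <- base[1:2, ]
  two$mean_bd <- c(4, NA)
  expect_warning(out <- episode_mean_bd(two), "without usable")
  expect_equal(out$mean_bd, 4)
  expect_equal(out$n_images, 1L)
})

test_that("episode mean lies between the per-image extremes", {
  set.seed(23)
  vals <- runif(5, 0, 6)
  tbl <- tibble::tibble(
    patient_id = "P01", episode_id = "P01-e01",
    timestamp = as.POSIXct("2024-01-05 09:00:00", tz = "UTC") + (0:4) * 240,
    mean_bd = vals
  )
  m <- episode_mean_bd(tbl)$mean_bd
  expect_gte(m, min(vals))
  expect_lte(m, max(vals))
})
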