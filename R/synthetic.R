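# Synthetic fixture generation.
#
# No patient photographs are distributed with the package, so every
# downstream stage is exercised on rendered stand-ins: stylised two-hand
# images (rectangular digits with rounded tips on a flat background) whose
# per-digit colour shifts, masks, timestamps and questionnaire records are
# all known ground truth. Geometry is deliberately schematic — the
# pipeline's contract is colour statistics over masks, not shape realism.

#' Specification of a synthetic hand image
#'
#' @param n_digits Number of digits, split across two stylised hands
#'   (default 8 = 4 non-thumb digits per hand; must be even).
#' @param base_skin_colour sRGB triple for unshifted skin (default a light
#'   skin tone, matching the study population).
#' @param per_digit_shift n_digits x 2 matrix of (delta-a*, delta-b*)
#'   colour offsets applied to each digit in the CIELAB hue plane; a
#'   vasospastic digit drifts towards less red / more blue, i.e. negative
#'   a* and b*.
#' @param noise_sd Per-channel Gaussian pixel noise, in L*a*b* units,
#'   added before conversion back to sRGB (default 3, a plausible
#'   smartphone-JPEG chroma noise level).
#' @param image_size (width, height) in pixels (default 480 x 320).
#' @param background_colour sRGB triple for the flat background.
#' @param seed Optional integer seed for the pixel noise.
#' @return A `hand_spec` list.
#' @export
hand_spec <- function(n_digits = 8,
                      base_skin_colour = c(200, 160, 140),
                      per_digit_shift = matrix(0, n_digits, 2),
                      noise_sd = 3,
                      image_size = c(480, 320),
                      background_colour = c(70, 110, 150),
                      seed = NULL) {
  per_digit_shift <- rbind(per_digit_shift)
  if (is.vector(per_digit_shift)) per_digit_shift <- matrix(per_digit_shift, ncol = 2)
  stopifnot(
    n_digits >= 2, n_digits %% 2 == 0,
    nrow(per_digit_shift) == n_digits, ncol(per_digit_shift) == 2,
    noise_sd >= 0, all(image_size > 0),
    length(base_skin_colour) == 3, length(background_colour) == 3
  )
  structure(
    list(
      n_digits = n_digits, base_skin_colour = base_skin_colour,
      per_digit_shift = per_digit_shift, noise_sd = noise_sd,
      image_size = as.integer(image_size),
      background_colour = background_colour, seed = seed
    ),
    class = "hand_spec"
  )
}

# Geometric layout of the two stylised hands. The left hand is rendered
# slightly larger so that "the hand with the larger area" (which hosts the
# dorsal reference) is deterministic. Returns integer masks:
#   hand  - 0 background, 1/2 hand id (palm + digits)
#   digit - 0 or digit index 1..n_digits, left to right
# plus palm row/column extents per hand.
.hand_layout <- function(w, h, n_digits) {
  dph <- n_digits / 2
  hand <- matrix(0L, h, w)
  digit <- matrix(0L, h, w)
  palms <- vector("list", 2)
  digit_idx <- 0L
  for (k in 1:2) {
    scale <- if (k == 1) 1 else 0.92
    bx0 <- (k - 1) * w / 2
    bw <- w / 2
    pw <- 0.76 * bw * scale
    pcx <- bx0 + bw / 2
    px0 <- max(1L, round(pcx - pw / 2))
    px1 <- min(w, round(pcx + pw / 2))
    py0 <- round(0.58 * h)
    py1 <- min(h - 2L, round((0.58 + 0.35 * scale) * h))
    hand[py0:py1, px0:px1] <- k
    palms[[k]] <- list(x = c(px0, px1), y = c(py0, py1))
    wd <- (px1 - px0 + 1) / (2 * dph - 1)
    y_top <- round(0.20 * h)
    for (i in seq_len(dph)) {
      digit_idx <- digit_idx + 1L
      dx0 <- round(px0 + 2 * (i - 1) * wd)
      dx1 <- min(px1, round(dx0 + wd - 1))
      r <- floor((dx1 - dx0 + 1) / 2)
      cx <- (dx0 + dx1) / 2
      cy <- y_top + r
      # shaft
      hand[(y_top + r):(py0 - 1), dx0:dx1] <- k
      digit[(y_top + r):(py0 - 1), dx0:dx1] <- digit_idx
      # rounded tip
      for (yy in y_top:(y_top + r)) {
        dxr <- sqrt(max(r^2 - (yy - cy)^2, 0))
        xs <- max(dx0, ceiling(cx - dxr)):min(dx1, floor(cx + dxr))
        hand[yy, xs] <- k
        digit[yy, xs] <- digit_idx
      }
    }
  }
  list(hand = hand, digit = digit, palms = palms,
       digit_rows = c(round(0.20 * h), round(0.58 * h) - 1))
}

# Ground-truth ROI label matrix from the layout masks: each digit split
# into distal/middle/proximal thirds along its vertical extent, inset from
# the digit border; reference ROI centred on the larger hand's palm.
.layout_rois <- function(layout, n_digits, inset_frac = 0.2) {
  labels <- matrix(0L, nrow(layout$digit), ncol(layout$digit))
  parts <- c("distal", "middle", "proximal")
  map <- list()
  for (d in seq_len(n_digits)) {
    px <- which(layout$digit == d, arr.ind = TRUE)
    rows <- range(px[, 1])
    cuts <- round(seq(rows[1], rows[2] + 1, length.out = 4))
    width <- diff(range(px[, 2])) + 1
    margin <- max(1L, round(inset_frac * width))
    for (p in 1:3) {
      roi_id <- (d - 1L) * 3L + p
      lo <- cuts[p] + 2L
      hi <- cuts[p + 1] - 3L
      sel <- px[px[, 1] >= lo & px[, 1] <= hi, , drop = FALSE]
      if (nrow(sel)) {
        for (rr in unique(sel[, 1])) {
          xs <- sel[sel[, 1] == rr, 2]
          keep <- xs[xs >= min(xs) + margin & xs <= max(xs) - margin]
          labels[rr, keep] <- roi_id
        }
      }
      map[[roi_id]] <- tibble::tibble(roi_id = roi_id, digit = d, part = parts[p])
    }
  }
  palm <- layout$palms[[1]]
  cx <- mean(palm$x); cy <- mean(palm$y)
  hx <- 0.25 * diff(palm$x); hy <- 0.25 * diff(palm$y)
  labels[round(cy - hy):round(cy + hy), round(cx - hx):round(cx + hx)] <- 25L
  map[[25]] <- tibble::tibble(roi_id = 25L, digit = NA_integer_, part = "reference")
  list(labels = labels, digit_of_roi = dplyr::bind_rows(map))
}

#' Render a synthetic hand image with ground-truth ROIs
#'
#' Draws a flat background, two palm/dorsum blocks at the base skin
#' colour, and rounded-tip digits whose colour is the base colour shifted
#' by `per_digit_shift` in the (a*, b*) hue plane. Gaussian pixel noise is
#' added in L*a*b* before conversion back to sRGB. Shifts that leave the
#' sRGB gamut are clipped and flagged.
#'
#' @param spec A [hand_spec()].
#' @return List with elements `image` (a [hand_image()]), `rois` (the
#'   ground-truth [roi_set()]), `layout` (internal masks, used for
#'   ground-truth landmarks) and `gamut_clipped` (logical flag).
#' @export
render_hand_image <- function(spec) {
  stopifnot(inherits(spec, "hand_spec"))
  w <- spec$image_size[1]; h <- spec$image_size[2]
  layout <- .hand_layout(w, h, spec$n_digits)
  base_lab <- as.matrix(srgb_to_lab(spec$base_skin_colour))
  bg_lab <- as.matrix(srgb_to_lab(spec$background_colour))
  n <- w * h
  lab <- matrix(bg_lab, n, 3, byrow = TRUE)
  on_hand <- layout$hand > 0L
  lab[on_hand, ] <- matrix(base_lab, sum(on_hand), 3, byrow = TRUE)
  for (d in seq_len(spec$n_digits)) {
    sel <- layout$digit == d
    lab[sel, 2] <- lab[sel, 2] + spec$per_digit_shift[d, 1]
    lab[sel, 3] <- lab[sel, 3] + spec$per_digit_shift[d, 2]
  }
  .with_seed(spec$seed, {
    if (spec$noise_sd > 0) {
      # L* noise per pixel; a*/b* noise at 2x2-pixel blocks, the chroma
      # resolution of a 4:2:0 smartphone JPEG — finer chroma variation
      # would not survive the camera's own encoder.
      lab[, 1] <- lab[, 1] + stats::rnorm(n, sd = spec$noise_sd)
      hb <- ceiling(h / 2); wb <- ceiling(w / 2)
      row_block <- (seq_len(h) + 1L) %/% 2L
      col_block <- (seq_len(w) + 1L) %/% 2L
      block_of <- as.vector(outer(row_block, (col_block - 1L) * hb, "+"))
      for (ch in 2:3) {
        lab[, ch] <- lab[, ch] +
          stats::rnorm(hb * wb, sd = spec$noise_sd)[block_of]
      }
    }
  })
  rgb <- lab_to_srgb(lab)
  clipped <- any(attr(rgb, "gamut_clipped") & c(on_hand))
  pixels <- array(0, dim = c(h, w, 3))
  pixels[, , 1] <- rgb$R
  pixels[, , 2] <- rgb$G
  pixels[, , 3] <- rgb$B
  gt <- .layout_rois(layout, spec$n_digits)
  list(
    image = hand_image(pixels, aspect = "dorsal", timestamp_source = "synthetic"),
    rois = roi_set(gt$labels, gt$digit_of_roi),
    layout = layout,
    gamut_clipped = clipped
  )
}

#' Simulate an episode-level BD table (no images)
#'
#' The statistical layer of the generator: draws per-episode mean
#' Bhattacharyya distances and patient-reported severities directly,
#' without rendering photographs. Used to study the calibration and power
#' of the ANOVA stage at scale. Severity follows the package's reporting
#' model: `clip(round(k * shift + patient_offset + noise), 0, 10)`, where
#' the per-patient offset captures each patient's subjective use of the
#' 0-10 scale (some always score high, others minimise).
#'
#' @param n_patients,episodes_per_patient Design size.
#' @param effect Slope of mean BD on the true shift magnitude; 0 gives the
#'   null model in which colour change is unrelated to severity.
#' @param shift_range Range of true shift magnitudes (L*a*b* units).
#' @param severity_k Slope of reported severity on true shift.
#' @param offset_range Patient offsets are drawn uniformly from
#'   `-offset_range:offset_range`.
#' @param severity_noise_sd,bd_noise_sd Reporting and measurement noise.
#' @param bd_baseline Mean BD at zero shift.
#' @param seed Optional integer seed.
#' @return Tibble: `patient_id`, `episode`, `true_shift`, `severity`,
#'   `mean_bd`.
#' @export
simulate_episode_bd <- function(n_patients = 10, episodes_per_patient = 12,
                                effect = 0.4, shift_range = c(2, 10),
                                severity_k = 0.65, offset_range = 2,
                                severity_noise_sd = 0.5, bd_noise_sd = 1,
                                bd_baseline = 3, seed = NULL) {
  stopifnot(n_patients >= 1, episodes_per_patient >= 1)
  .with_seed(seed, {
    offsets <- sample(-offset_range:offset_range, n_patients, replace = TRUE)
    patient_bd <- stats::rnorm(n_patients, 0, 0.5)
    out <- purrr::map_dfr(seq_len(n_patients), function(i) {
      shift <- stats::runif(episodes_per_patient, shift_range[1], shift_range[2])
      sev <- .clamp(
        round(severity_k * shift + offsets[i] +
                stats::rnorm(episodes_per_patient, 0, severity_noise_sd)),
        0, 10
      )
      tibble::tibble(
        patient_id = sprintf("P%02d", i),
        episode = seq_len(episodes_per_patient),
        true_shift = shift,
        severity = as.integer(sev),
        mean_bd = bd_baseline + patient_bd[i] + effect * shift +
          stats::rnorm(episodes_per_patient, 0, bd_noise_sd)
      )
    })
    out
  })
}

#' Generate an app-style synthetic dataset on disk
#'
#' Writes the folder tree the mobile app would produce — per-patient
#' directories of date-stamped subfolders holding JPEG images (quality 95,
#' EXIF `DateTimeOriginal` set) plus plain-text questionnaire records —
#' together with a ground-truth table of the true colour shift, reported
#' severity and timing of every episode.
#'
#' All randomness is drawn from a single stream seeded once with `seed`;
#' per-image render seeds are drawn from that stream, so the whole dataset
#' is reproducible from one integer.
#'
#' @param root Destination directory (created; must be writable).
#' @param n_patients,episodes_per_patient Design size (defaults 5 and 10).
#' @param images_per_episode Inclusive range; each episode's image count
#'   is drawn uniformly from it (default 3-5: the app's one-minute
#'   reminder cadence makes several photographs per attack typical, and
#'   averaging at least three stabilises the episode mean).
#' @param gap_minutes Range of within-episode gaps between consecutive
#'   images, in minutes (default 2-8; well inside the 30-min episode
#'   window).
#' @param episodes_per_day Episodes started per study day (default 2,
#'   spaced 4 h apart, so between-episode gaps far exceed the window).
#' @param shift_range Span of the true per-episode shift magnitudes
#'   (L*a*b* units, default 2-10). Each patient's episodes sweep a
#'   deterministic evenly spaced ladder across this range — a designed
#'   severity sweep, so parameter-recovery checks are well posed.
#' @param severity_k,offset_range,severity_noise_sd Reporting model, as in
#'   [simulate_episode_bd()].
#' @param noise_sd Pixel noise passed to the renderer (default 2).
#' @param image_size,base_skin_colour,background_colour Renderer options.
#' @param start_date First study day (`"YYYY-MM-DD"`).
#' @param quality JPEG quality (fixed default 95 so compression-induced
#'   colour error stays small and bounded).
#' @param write_masks Also write ground-truth label masks as PNG.
#' @param write_landmarks Also write per-image hand-outline landmark
#'   sidecar CSVs derived from the ground-truth masks.
#' @param seed Integer seed (required for a reproducible dataset).
#' @return Invisibly, a list with `root`, the `ground_truth` tibble (also
#'   written to `<root>/ground_truth.csv`) and the manifest.
#' @export
generate_dataset <- function(root,
                             n_patients = 5, episodes_per_patient = 10,
                             images_per_episode = c(3, 5),
                             gap_minutes = c(2, 8),
                             episodes_per_day = 2,
                             shift_range = c(2, 10),
                             severity_k = 0.65, offset_range = 2,
                             severity_noise_sd = 0.5,
                             noise_sd = 3,
                             image_size = c(480, 320),
                             base_skin_colour = c(200, 160, 140),
                             background_colour = c(70, 110, 150),
                             start_date = "2024-01-05",
                             quality = 95,
                             write_masks = FALSE,
                             write_landmarks = FALSE,
                             seed = 1) {
  stopifnot(n_patients >= 1, episodes_per_patient >= 1)
  ok <- dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) stop("cannot create dataset root: ", root)
  day0 <- as.Date(start_date)
  gt <- list()
  .with_seed(seed, {
    mag_ladder <- if (episodes_per_patient == 1) mean(shift_range) else
      seq(shift_range[1], shift_range[2], length.out = episodes_per_patient)
    for (i in seq_len(n_patients)) {
      pid <- sprintf("P%02d", i)
      offset <- sample(-offset_range:offset_range, 1)
      for (e in seq_len(episodes_per_patient)) {
        day <- day0 + (e - 1) %/% episodes_per_day
        slot <- (e - 1) %% episodes_per_day
        t0 <- as.POSIXct(paste(day, "09:00:00"), tz = "UTC") +
          slot * 4 * 3600 + round(stats::runif(1, 0, 30)) * 60
        n_img <- sample(images_per_episode[1]:images_per_episode[2], 1)
        gaps <- stats::runif(max(n_img - 1, 0), gap_minutes[1], gap_minutes[2])
        times <- t0 + c(0, cumsum(round(gaps * 60)))
        mag <- mag_ladder[e]
        dir_ab <- c(-0.8, -0.6) # pallor/cyanosis: less red, more blue
        severity <- as.integer(.clamp(
          round(severity_k * mag + offset + stats::rnorm(1, 0, severity_noise_sd)),
          0, 10
        ))
        date_dir <- file.path(root, pid, format(day, "%Y-%m-%d"))
        dir.create(date_dir, recursive = TRUE, showWarnings = FALSE)
        for (k in seq_len(n_img)) {
          img_seed <- sample.int(.Machine$integer.max, 1)
          spec <- hand_spec(
            base_skin_colour = base_skin_colour,
            per_digit_shift = matrix(rep(mag * dir_ab, each = 8), 8, 2),
            noise_sd = noise_sd, image_size = image_size,
            background_colour = background_colour, seed = img_seed
          )
          rendered <- render_hand_image(spec)
          fname <- sprintf("img_%s_%02d.jpg", format(times[k], "%H%M%S", tz = "UTC"), k)
          path <- file.path(date_dir, fname)
          .write_jpeg_with_exif(rendered$image$pixels, path,
                                timestamp = times[k], quality = quality)
          if (write_masks) {
            EBImage::writeImage(
              EBImage::Image(t(rendered$rois$labels) / 255),
              file.path(date_dir, sub("\\.jpg$", "_mask.png", fname))
            )
          }
          if (write_landmarks) {
            lm <- .mask_landmarks(rendered$layout$hand)
            readr::write_csv(
              lm, file.path(date_dir, sub("\\.jpg$", "_landmarks.csv", fname))
            )
          }
        }
        end_time <- times[n_img] + 60
        .append_attack_record(date_dir, pid, end_time, severity, trigger = "cold")
        .append_aspect(date_dir, sprintf("img_%s_%02d.jpg",
                                         format(times, "%H%M%S", tz = "UTC"),
                                         seq_len(n_img)))
        gt[[length(gt) + 1]] <- tibble::tibble(
          patient_id = pid, episode = e, date = format(day, "%Y-%m-%d"),
          start_time = .format_exif_time(times[1]),
          end_time = .format_exif_time(end_time),
          n_images = n_img, shift_mag = mag,
          shift_a = mag * dir_ab[1], shift_b = mag * dir_ab[2],
          severity = severity, patient_offset = offset
        )
      }
    }
    gt <- dplyr::bind_rows(gt)
    # daily records: RCS loosely tracks the day's attack severities
    daily <- gt |>
      dplyr::group_by(.data$patient_id, .data$date) |>
      dplyr::summarise(
        n_attacks = dplyr::n(),
        rcs = as.integer(.clamp(round(mean(.data$severity) +
                                        stats::rnorm(1, 0, 1)), 0, 10)),
        .groups = "drop"
      )
    purrr::pwalk(daily, function(patient_id, date, n_attacks, rcs) {
      .append_daily_record(file.path(root, patient_id, date),
                           patient_id, date, rcs, n_attacks)
    })
    readr::write_csv(gt, file.path(root, "ground_truth.csv"))
    manifest <- list(
      package = "raynaudbd",
      version = as.character(utils::packageVersion("raynaudbd")),
      seed = seed, n_patients = n_patients,
      episodes_per_patient = episodes_per_patient,
      images_per_episode = images_per_episode, gap_minutes = gap_minutes,
      shift_range = shift_range, severity_k = severity_k,
      offset_range = offset_range, noise_sd = noise_sd,
      image_size = image_size, quality = quality, start_date = start_date
    )
    jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(root = root, ground_truth = gt, manifest = manifest))
  })
}

# Questionnaire files: UTF-8 key=value blocks with a versioned header.
.ensure_header <- function(path) {
  if (!file.exists(path)) writeLines("# rpdiary v1", path, useBytes = TRUE)
}

.append_attack_record <- function(dir, patient_id, end_time, severity,
                                  trigger = "") {
  path <- file.path(dir, "attacks.txt")
  .ensure_header(path)
  cat(
    sprintf("[attack]\npatient=%s\nend=%s\nseverity=%d\ntrigger=%s\n",
            patient_id, .format_exif_time(end_time), severity, trigger),
    file = path, append = TRUE
  )
}

.append_daily_record <- function(dir, patient_id, date, rcs, n_attacks) {
  path <- file.path(dir, "daily.txt")
  .ensure_header(path)
  cat(
    sprintf("[daily]\npatient=%s\ndate=%s\nrcs=%d\nn_attacks=%d\n",
            patient_id, date, rcs, n_attacks),
    file = path, append = TRUE
  )
}

.append_aspect <- function(dir, filenames, aspect = "dorsal") {
  path <- file.path(dir, "aspect.txt")
  cat(sprintf("%s=%s\n", filenames, aspect),
      file = path, append = TRUE, sep = "")
}

# Ordered hand-border landmarks from a hand-id mask, one polygon per hand.
.mask_landmarks <- function(hand_mask, every = 3L) {
  out <- list()
  for (k in sort(unique(hand_mask[hand_mask > 0]))) {
    cont <- EBImage::ocontour(EBImage::Image(t(hand_mask == k)))[[1]]
    keep <- seq(1, nrow(cont), by = every)
    out[[k]] <- tibble::tibble(
      point_index = seq_along(keep),
      x = cont[keep, 1] + 1, # ocontour is 0-based; pixels here are 1-based
      y = cont[keep, 2] + 1,
      label = paste0("hand", k)
    )
  }
  dplyr::bind_rows(out)
}
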