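# Episode grouping: turning timestamped images into discrete attacks.

#' Group images into episodes by a sliding time window
#'
#' Transitive chaining: consecutive images (within a patient, in time
#' order) whose gap is at most `window_minutes` belong to one episode; a
#' gap of exactly the window still joins. Chains of a single image do not
#' qualify as episodes and are returned as unattached. Grouping is
#' deterministic — ties in timestamp are broken path-lexicographically —
#' and invariant to input order.
#'
#' @param images Image metadata tibble with `patient_id`, `path`,
#'   `timestamp` columns (e.g. [scan_app_folder()]'s `images`).
#' @param window_minutes Maximum within-episode gap (default 30).
#' @return The input with added columns `episode_id` (e.g. `"P01-e03"`,
#'   `NA` for unattached images) and `episode_status`
#'   (`"episode"`, `"unattached"`, or `"no_timestamp"`).
#' @export
group_by_window <- function(images, window_minutes = 30) {
  stopifnot(all(c("patient_id", "path", "timestamp") %in% names(images)))
  no_ts <- is.na(images$timestamp)
  if (any(no_ts)) warning(sum(no_ts), " image(s) without timestamp set aside")
  out <- images
  out$episode_id <- NA_character_
  out$episode_status <- ifelse(no_ts, "no_timestamp", "unattached")
  ord <- order(images$patient_id, images$timestamp, images$path)
  for (pid in unique(images$patient_id[!no_ts])) {
    idx <- ord[images$patient_id[ord] == pid & !no_ts[ord]]
    if (!length(idx)) next
    ts <- as.numeric(images$timestamp[idx])
    gaps <- diff(ts)
    new_chain <- c(TRUE, gaps > window_minutes * 60)
    chain <- cumsum(new_chain)
    sizes <- table(chain)
    is_ep <- chain %in% as.integer(names(sizes)[sizes >= 2])
    ep_ids <- match(chain, unique(chain[is_ep]))
    out$episode_id[idx[is_ep]] <- sprintf("%s-e%02d", pid, ep_ids[is_ep])
    out$episode_status[idx[is_ep]] <- "episode"
  }
  out
}

#' Assign images to app-recorded attacks
#'
#' App-delimited mode: each attack record carries the time the patient
#' declared the attack over. An image belongs to the earliest attack
#' whose end time is at or after the image (allowing `tolerance_minutes`
#' after the recorded end for the closing photograph) and within the same
#' patient. One image suffices for an app-delimited episode. Unassigned
#' images are flagged. Overlapping records are resolved in favour of the
#' earlier end time (images are taken by the first attack that can claim
#' them); duplicate end times are collapsed with a warning.
#'
#' @param images Image metadata tibble (`patient_id`, `path`,
#'   `timestamp`).
#' @param attacks Attack record tibble (`patient_id`, `end_time`,
#'   `severity`).
#' @param tolerance_minutes Grace period after the recorded end
#'   (default 5).
#' @param max_lookback_minutes Images more than this far before the end
#'   time are not claimed (default 120).
#' @return The input images with `episode_id` (`"<patient>-a<k>"`),
#'   `severity`, and `episode_status` (`"episode"` or `"unassigned"`).
#' @export
group_by_app <- function(images, attacks, tolerance_minutes = 5,
                         max_lookback_minutes = 120) {
  stopifnot(all(c("patient_id", "path", "timestamp") %in% names(images)))
  stopifnot(all(c("patient_id", "end_time", "severity") %in% names(attacks)))
  out <- images
  out$episode_id <- NA_character_
  out$severity <- NA_integer_
  out$episode_status <- "unassigned"
  atk <- dplyr::arrange(attacks, .data$patient_id, .data$end_time)
  dup <- duplicated(atk[, c("patient_id", "end_time")])
  if (any(dup)) {
    warning(sum(dup), " attack record(s) with duplicate end times dropped (later record wins not applicable: identical span)")
    atk <- atk[!dup, , drop = FALSE]
  }
  for (pid in unique(out$patient_id)) {
    a <- atk[atk$patient_id == pid, , drop = FALSE]
    if (!nrow(a)) next
    rows <- which(out$patient_id == pid & !is.na(out$timestamp))
    for (r in rows) {
      ts <- out$timestamp[r]
      ok <- which(
        as.numeric(a$end_time) + tolerance_minutes * 60 >= as.numeric(ts) &
          as.numeric(a$end_time) - max_lookback_minutes * 60 <= as.numeric(ts)
      )
      if (length(ok)) {
        k <- ok[1] # earliest qualifying attack claims the image
        out$episode_id[r] <- sprintf("%s-a%02d", pid, k)
        out$severity[r] <- a$severity[k]
        out$episode_status[r] <- "episode"
      }
    }
  }
  out
}

#' Per-episode mean Bhattacharyya distance
#'
#' The attack-level severity summary: the arithmetic mean of the
#' per-image mean BDs over all usable images of the episode ("BD of all
#' ROIs on the digits averaged across each image and for all images in an
#' episode"). Episodes with no usable image are dropped with a warning.
#'
#' @param image_bd Tibble with one row per image carrying `episode_id`
#'   and `mean_bd` (join of [group_by_window()]/[group_by_app()] output
#'   with [image_mean_bd()]).
#' @return Tibble: one row per episode with `patient_id`, `episode_id`,
#'   `start`, `end`, `n_images`, `mean_bd`, plus `severity` carried
#'   through when present.
#' @export
episode_mean_bd <- function(image_bd) {
  stopifnot(all(c("episode_id", "mean_bd") %in% names(image_bd)))
  dat <- image_bd[!is.na(image_bd$episode_id), , drop = FALSE]
  dropped <- sum(is.na(dat$mean_bd))
  if (dropped) warning(dropped, " image(s) without usable mean BD excluded")
  grouping <- intersect(c("patient_id", "episode_id"), names(dat))
  out <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      start = min(.data$timestamp),
      end = max(.data$timestamp),
      n_images = sum(!is.na(.data$mean_bd)),
      mean_bd = mean(.data$mean_bd, na.rm = TRUE),
      severity = if ("severity" %in% names(dat)) .data$severity[1] else NA_integer_,
      .groups = "drop"
    )
  bad <- out$n_images == 0
  if (any(bad)) {
    warning(sum(bad), " episode(s) with no usable image excluded")
    out <- out[!bad, , drop = FALSE]
  }
  out
}
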