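# Ingest: images "as taken", app-folder questionnaire text, landmark
# sidecars and exclusion lists.

#' Read a photograph into a hand image
#'
#' Decodes a JPEG or PNG without any colour transformation. The capture
#' time is taken from EXIF `DateTimeOriginal`; if absent (PNGs, stripped
#' JPEGs) the file modification time is used and the provenance flag
#' records the fallback.
#'
#' @param path Image file path.
#' @param patient_id Patient identifier to attach.
#' @param aspect `"dorsal"`, `"palmar"` or `"unknown"` (metadata; never
#'   inferred from the image).
#' @return A [hand_image()].
#' @export
read_hand_image <- function(path, patient_id = NA_character_,
                            aspect = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode ", path, ": ",
                                           conditionMessage(e)))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2) dat <- array(rep(dat, 3), dim = c(dim(dat), 3))
  if (dim(dat)[3] > 3) dat <- dat[, , 1:3] # drop alpha
  pixels <- aperm(dat, c(2, 1, 3)) * 255
  ts_string <- if (grepl("\\.jpe?g$", path, ignore.case = TRUE)) {
    read_exif_datetime(path)
  } else {
    NA_character_
  }
  if (!is.na(ts_string)) {
    timestamp <- .parse_exif_time(ts_string)
    source <- "exif"
  } else {
    timestamp <- as.POSIXct(file.info(path)$mtime, tz = "UTC")
    source <- "mtime"
  }
  hand_image(pixels, timestamp = timestamp, patient_id = patient_id,
             source_path = path, aspect = aspect, timestamp_source = source)
}

#' Scan an app-style data folder
#'
#' Walks the folder tree the app produces — `<root>/<patient>/<date>/`
#' with images, `attacks.txt`, `daily.txt` and optional `aspect.txt` in
#' each dated subfolder — and returns tidy metadata tables. Pixels are not
#' loaded here (use [read_hand_image()] per image); the tables carry paths
#' and are sorted deterministically by (patient, timestamp, path) so
#' ingestion order can never affect downstream results.
#'
#' @param root Dataset root directory.
#' @return List of class `rp_app_data`: `images` (patient_id, path,
#'   timestamp, timestamp_source, aspect, date, orphan), `attacks`
#'   (patient_id, end_time, severity, plus free-text fields carried
#'   opaquely) and `daily` (patient_id, date, rcs, n_attacks). Attack and
#'   daily records whose date has no image subfolder are kept and flagged
#'   `orphan_record`.
#' @export
scan_app_folder <- function(root) {
  if (!dir.exists(root)) stop("not a directory: ", root)
  patients <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  images <- list(); attacks <- list(); daily <- list()
  for (pid in patients) {
    pdir <- file.path(root, pid)
    dates <- sort(list.dirs(pdir, recursive = FALSE, full.names = FALSE))
    dates <- dates[grepl("^\\d{4}-\\d{2}-\\d{2}$", dates)]
    for (d in dates) {
      ddir <- file.path(pdir, d)
      aspect_map <- .read_aspect_file(file.path(ddir, "aspect.txt"))
      files <- sort(list.files(ddir, pattern = "\\.(jpe?g|png)$",
                               ignore.case = TRUE))
      for (f in files) {
        if (grepl("_mask\\.png$", f)) next
        path <- file.path(ddir, f)
        ts_string <- if (grepl("\\.jpe?g$", f, ignore.case = TRUE)) {
          read_exif_datetime(path)
        } else {
          NA_character_
        }
        if (!is.na(ts_string)) {
          ts <- .parse_exif_time(ts_string)
          src <- "exif"
        } else {
          ts <- as.POSIXct(file.info(path)$mtime, tz = "UTC")
          src <- "mtime"
        }
        images[[length(images) + 1]] <- tibble::tibble(
          patient_id = pid, path = path, timestamp = ts,
          timestamp_source = src,
          aspect = if (f %in% names(aspect_map)) aspect_map[[f]] else "unknown",
          date = d
        )
      }
      attacks[[length(attacks) + 1]] <-
        .parse_diary_file(file.path(ddir, "attacks.txt"), "attack", pid)
      daily[[length(daily) + 1]] <-
        .parse_diary_file(file.path(ddir, "daily.txt"), "daily", pid)
    }
  }
  images <- dplyr::bind_rows(images)
  attacks <- dplyr::bind_rows(attacks)
  daily <- dplyr::bind_rows(daily)
  if (nrow(images)) {
    images <- dplyr::arrange(images, .data$patient_id, .data$timestamp, .data$path)
  }
  image_dates <- if (nrow(images)) unique(images[, c("patient_id", "date")]) else
    tibble::tibble(patient_id = character(), date = character())
  flag_orphan <- function(tbl, date_col) {
    if (!nrow(tbl)) return(tbl)
    tbl$orphan_record <- !paste(tbl$patient_id, tbl[[date_col]]) %in%
      paste(image_dates$patient_id, image_dates$date)
    tbl
  }
  if (nrow(attacks)) {
    attacks$end_time <- .parse_exif_time(attacks$end)
    attacks$severity <- as.integer(attacks$severity)
    attacks$date <- format(attacks$end_time, "%Y-%m-%d", tz = "UTC")
    bad <- is.na(attacks$severity) | attacks$severity < 0 | attacks$severity > 10
    if (any(bad)) {
      warning(sum(bad), " attack record(s) with invalid severity dropped")
      attacks <- attacks[!bad, , drop = FALSE]
    }
  }
  attacks <- flag_orphan(attacks, "date")
  if (nrow(daily)) {
    daily$rcs <- as.integer(daily$rcs)
    daily$n_attacks <- as.integer(daily$n_attacks)
  }
  daily <- flag_orphan(daily, "date")
  structure(list(images = images, attacks = attacks, daily = daily,
                 root = root),
            class = "rp_app_data")
}

#' @export
print.rp_app_data <- function(x, ...) {
  cat(sprintf(
    "<rp_app_data: %d images, %d attack records, %d daily records, %d patient(s)>\n",
    nrow(x$images), nrow(x$attacks), nrow(x$daily),
    length(unique(x$images$patient_id))
  ))
  invisible(x)
}

# Parse a key=value block file ("# rpdiary v1" header, [attack]/[daily]
# blocks). Malformed lines invalidate only their own record.
.parse_diary_file <- function(path, kind, patient_id) {
  if (!file.exists(path)) return(tibble::tibble())
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  records <- list()
  current <- NULL
  flush <- function() {
    if (!is.null(current) && length(current)) {
      records[[length(records) + 1]] <<- tibble::as_tibble(as.list(current))
    }
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    if (line == sprintf("[%s]", kind)) {
      flush()
      current <- character()
      next
    }
    if (grepl("^\\[", line)) { # foreign block type: skip it wholesale
      flush()
      current <- NULL
      next
    }
    if (is.null(current)) next
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*=", line)) {
      warning(sprintf("%s:%d: malformed line, record skipped", path, i))
      current <- NULL
      next
    }
    key <- sub("=.*$", "", line)
    current[key] <- sub("^[^=]*=", "", line)
  }
  flush()
  if (!length(records)) return(tibble::tibble())
  out <- dplyr::bind_rows(records)
  out$patient_id <- patient_id
  out
}

.read_aspect_file <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  vals <- sub("^[^=]*=", "", lines)
  names(vals) <- sub("=.*$", "", lines)
  as.list(vals)
}

#' Remove images named on an exclusion list
#'
#' Replaces the study's manual poor-quality review with an explicit,
#' auditable list: a plain-text file of image paths (one per line; either
#' full paths or basenames). Listed paths that match no image produce a
#' warning, not an error.
#'
#' @param images Image metadata tibble (from [scan_app_folder()]'s
#'   `images` element).
#' @param exclusion_file Path to the list, or `NULL`/missing file for the
#'   identity.
#' @return The filtered tibble, with attribute `n_excluded`.
#' @export
apply_exclusion_list <- function(images, exclusion_file = NULL) {
  if (is.null(exclusion_file) || !file.exists(exclusion_file)) {
    attr(images, "n_excluded") <- 0L
    return(images)
  }
  listed <- trimws(readLines(exclusion_file, warn = FALSE))
  listed <- listed[listed != "" & !startsWith(listed, "#")]
  hit <- images$path %in% listed | basename(images$path) %in% basename(listed)
  unmatched <- !(listed %in% images$path | basename(listed) %in% basename(images$path))
  if (any(unmatched)) {
    warning("exclusion list entries not found among images: ",
            paste(listed[unmatched], collapse = ", "))
  }
  out <- images[!hit, , drop = FALSE]
  if (!nrow(out) && nrow(images)) warning("exclusion list removed every image")
  attr(out, "n_excluded") <- sum(hit)
  out
}

#' Read a landmark sidecar file
#'
#' Landmarks delineate the hand border as ordered 2-D points (pixel
#' units, origin top-left, x rightwards, y downwards) with a `label`
#' column naming the hand (`"hand1"`, `"hand2"`). This is the faithful
#' ingestion path for externally fitted hand outlines; the built-in
#' [segment_hand()] fallback covers fixture-style images only.
#'
#' @param path CSV with columns `point_index`, `x`, `y`, `label`.
#' @param image_size Optional (width, height); points outside bounds are
#'   an error.
#' @return Tibble of landmarks.
#' @export
read_landmarks <- function(path, image_size = NULL) {
  lm <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("point_index", "x", "y", "label")
  if (!all(need %in% names(lm))) {
    stop("landmark file lacks columns: ",
         paste(setdiff(need, names(lm)), collapse = ", "))
  }
  if (nrow(lm) < 3) stop("landmark set needs at least 3 points")
  if (!is.null(image_size)) {
    if (any(lm$x < 1 | lm$x > image_size[1] | lm$y < 1 | lm$y > image_size[2])) {
      stop("landmarks outside image bounds")
    }
  }
  lm
}

# Sidecar path convention: <image>_landmarks.csv next to the image.
.landmark_sidecar <- function(image_path) {
  sub("\\.(jpe?g|png)$", "_landmarks.csv", image_path, ignore.case = TRUE)
}
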