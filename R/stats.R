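# Statistical comparisons of BD against patient-reported severity:
# Pearson correlation (Fisher-z interval), additive two-factor ANOVA of
# mean BD on patient and severity (Type II sums of squares), and Tukey
# HSD multiple comparisons of the severity levels.

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation between two columns, with the 95% Fisher-z
#' confidence interval and a two-sided p value from the t distribution on
#' n - 2 degrees of freedom.
#'
#' @param data Data frame.
#' @param x,y Column names (strings) of the paired values.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `r`, `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
pearson_with_ci <- function(data, x, y, conf_level = 0.95) {
  xv <- data[[x]]
  yv <- data[[y]]
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("correlation undefined: zero variance in '",
         if (stats::sd(xv) == 0) x else y, "'")
  }
  ct <- stats::cor.test(xv, yv, method = "pearson", conf.level = conf_level)
  tibble::tibble(
    r = unname(ct$estimate),
    ci_low = ct$conf.int[1],
    ci_high = ct$conf.int[2],
    p_value = ct$p.value,
    n = length(xv)
  )
}

#' Two-factor ANOVA of mean BD on patient and severity
#'
#' Fits the additive fixed-effects model `mean_bd ~ patient + severity`
#' (no interaction; both factors categorical) and tests each factor with
#' Type II sums of squares — appropriate because severity counts are
#' naturally unbalanced across patients. Including patient as a factor
#' absorbs each patient's subjective use of the 0-10 scale, so the
#' severity test asks whether, within patients, attacks rated more severe
#' show larger colour change.
#'
#' @param data Data frame of episodes.
#' @param response,patient,severity Column names.
#' @return An object of class `bd_anova`: the `lm` fit, the Type II
#'   ANOVA table, and metadata. Use [tidy()] / [glance()] to extract
#'   tables, [tukey_hsd()] for level comparisons.
#' @export
bd_anova <- function(data, response = "mean_bd", patient = "patient_id",
                     severity = "severity") {
  stopifnot(all(c(response, patient, severity) %in% names(data)))
  df <- data.frame(
    y = data[[response]],
    patient = factor(data[[patient]]),
    severity = factor(data[[severity]])
  )
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nlevels(droplevels(df$patient)) < 1 || nlevels(droplevels(df$severity)) < 2) {
    stop("need at least 2 severity levels")
  }
  df$patient <- droplevels(df$patient)
  df$severity <- droplevels(df$severity)
  # confounding check: severity constant within every patient means the
  # severity effect is inseparable from the patient effect
  if (nlevels(df$patient) > 1) {
    within_var <- tapply(as.integer(df$severity), df$patient,
                         function(s) length(unique(s)))
    if (all(within_var == 1)) {
      stop("severity is confounded with patient: severity is constant ",
           "within every patient")
    }
  }
  fit <- if (nlevels(df$patient) > 1) {
    stats::lm(y ~ patient + severity, data = df)
  } else {
    stats::lm(y ~ severity, data = df) # one patient: one-way ANOVA
  }
  if (fit$df.residual < 1) stop("no residual degrees of freedom")
  tab <- car::Anova(fit, type = 2)
  structure(
    list(
      fit = fit, table = tab, data = df,
      response = response,
      factors = if (nlevels(df$patient) > 1) c("patient", "severity") else "severity",
      ss_type = "II"
    ),
    class = "bd_anova"
  )
}

#' @export
print.bd_anova <- function(x, ...) {
  cat("Two-factor ANOVA of", x$response,
      "(Type", x$ss_type, "sums of squares)\n")
  print(x$table)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-factor ANOVA table
#'
#' @param x A [bd_anova()] fit.
#' @param ... Unused.
#' @return Tibble: `term`, `sumsq`, `df`, `statistic` (F), `p_value`.
#' @method tidy bd_anova
#' @export
tidy.bd_anova <- function(x, ...) {
  tab <- as.data.frame(x$table)
  tibble::tibble(
    term = rownames(tab),
    sumsq = tab[["Sum Sq"]],
    df = tab[["Df"]],
    statistic = tab[["F value"]],
    p_value = tab[["Pr(>F)"]]
  )
}

#' One-row model summary of a BD ANOVA
#'
#' @param x A [bd_anova()] fit.
#' @param ... Unused.
#' @return Tibble: `n`, `df_residual`, `sigma`, `r_squared`,
#'   `severity_f`, `severity_p`.
#' @method glance bd_anova
#' @export
glance.bd_anova <- function(x, ...) {
  td <- tidy(x)
  sev <- td[td$term == "severity", ]
  tibble::tibble(
    n = nrow(x$data),
    df_residual = x$fit$df.residual,
    sigma = stats::sigma(x$fit),
    r_squared = summary(x$fit)$r.squared,
    severity_f = sev$statistic,
    severity_p = sev$p_value
  )
}

#' Tukey HSD comparisons of severity levels
#'
#' All pairwise comparisons of the model-adjusted severity-level means
#' with studentised-range (Tukey HSD) adjustment, plus per-level adjusted
#' means with comparison half-widths chosen so that two levels differ
#' significantly (approximately, exactly under equal standard errors)
#' when their comparison intervals do not overlap — the standard
#' error-bar display for multiple comparisons.
#'
#' @param x A [bd_anova()] fit.
#' @param conf_level Family-wise confidence level (default 0.95).
#' @return List of class `bd_tukey`: `pairs` (tibble: `level_1`,
#'   `level_2`, `estimate`, `ci_low`, `ci_high`, `p_value`,
#'   `significant`) and `means` (tibble: `severity`, `emmean`, `se`,
#'   `df`, `comparison_low`, `comparison_high`, `n`, `single_obs`).
#' @export
tukey_hsd <- function(x, conf_level = 0.95) {
  stopifnot(inherits(x, "bd_anova"))
  emm <- emmeans::emmeans(x$fit, "severity")
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"),
                 infer = c(TRUE, TRUE), level = conf_level)
  lvl <- do.call(rbind, strsplit(as.character(prs$contrast), " - "))
  strip <- function(s) sub("^severity", "", s)
  pairs_tbl <- tibble::tibble(
    level_1 = strip(lvl[, 1]),
    level_2 = strip(lvl[, 2]),
    estimate = prs$estimate,
    ci_low = prs$lower.CL,
    ci_high = prs$upper.CL,
    p_value = prs$p.value,
    significant = prs$lower.CL > 0 | prs$upper.CL < 0
  )
  ms <- summary(emm)
  k <- nrow(ms)
  df <- ms$df[1]
  qcrit <- stats::qtukey(conf_level, k, df) / sqrt(2)
  counts <- table(x$data$severity)
  n_per <- as.integer(counts[as.character(ms$severity)])
  # comparison half-width: Tukey declares |diff| significant when it
  # exceeds qcrit * sqrt(se_i^2 + se_j^2); hw_i = qcrit * se_i / sqrt(2)
  # makes interval non-overlap equivalent under equal standard errors and
  # a close approximation otherwise (the multcompare-style display).
  hw <- qcrit * ms$SE / sqrt(2)
  means_tbl <- tibble::tibble(
    severity = as.character(ms$severity),
    emmean = ms$emmean,
    se = ms$SE,
    df = ms$df,
    comparison_low = ms$emmean - hw,
    comparison_high = ms$emmean + hw,
    n = n_per,
    single_obs = n_per == 1
  )
  if (any(means_tbl$single_obs)) {
    warning(sum(means_tbl$single_obs),
            " severity level(s) with a single observation: intervals are wide")
  }
  structure(list(pairs = pairs_tbl, means = means_tbl,
                 conf_level = conf_level),
            class = "bd_tukey")
}

#' @export
print.bd_tukey <- function(x, ...) {
  cat(sprintf("Tukey HSD severity comparisons (%d pairs, %.0f%% family-wise)\n",
              nrow(x$pairs), 100 * x$conf_level))
  print(x$pairs, n = 10)
  invisible(x)
}

#' Study-style summary of an analysed dataset
#'
#' Per-patient and overall medians and ranges of episode counts, images
#' per episode and BD summaries, in the style in which cohort papers
#' report them.
#'
#' @param episodes Episode table (from [episode_mean_bd()]).
#' @param images Optional image table for usable-image counts.
#' @return List of class `rp_summary`: `per_patient` tibble and
#'   `overall` one-row tibble.
#' @export
summary_report <- function(episodes, images = NULL) {
  if (!nrow(episodes)) {
    return(structure(list(
      per_patient = tibble::tibble(),
      overall = tibble::tibble(note = "no episodes")
    ), class = "rp_summary"))
  }
  per_patient <- episodes |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_episodes = dplyr::n(),
      n_images = sum(.data$n_images),
      median_images_per_episode = stats::median(.data$n_images),
      mean_bd = mean(.data$mean_bd),
      sd_bd = stats::sd(.data$mean_bd),
      .groups = "drop"
    )
  overall <- tibble::tibble(
    n_patients = nrow(per_patient),
    n_episodes = nrow(episodes),
    n_images = sum(episodes$n_images),
    median_episodes_per_patient = stats::median(per_patient$n_episodes),
    min_episodes_per_patient = min(per_patient$n_episodes),
    max_episodes_per_patient = max(per_patient$n_episodes),
    median_images_per_episode = stats::median(episodes$n_images),
    min_images_per_episode = min(episodes$n_images),
    max_images_per_episode = max(episodes$n_images),
    mean_bd = mean(episodes$mean_bd),
    sd_bd = stats::sd(episodes$mean_bd)
  )
  if (!is.null(images)) overall$n_images_scanned <- nrow(images)
  structure(list(per_patient = per_patient, overall = overall),
            class = "rp_summary")
}

#' @export
print.rp_summary <- function(x, ...) {
  if (!nrow(x$per_patient)) {
    cat("Empty dataset: no episodes.\n")
    return(invisible(x))
  }
  o <- x$overall
  cat(sprintf(
    paste0("%d patients, %d episodes, %d images in episodes\n",
           "episodes/patient: median %s (range %d-%d)\n",
           "images/episode:   median %s (range %d-%d)\n",
           "mean BD %.2f (s.d. %.2f)\n"),
    o$n_patients, o$n_episodes, o$n_images,
    format(o$median_episodes_per_patient), o$min_episodes_per_patient,
    o$max_episodes_per_patient,
    format(o$median_images_per_episode), o$min_images_per_episode,
    o$max_images_per_episode, o$mean_bd, o$sd_bd
  ))
  invisible(x)
}
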