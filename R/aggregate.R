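#' Aggregate per-image records into a study report
#'
#' The study-level summary: per-modality means and standard deviations of
#' the Mahalanobis distance and of F1 (unweighted across lesions), plus
#' paired cross-modality comparisons (WL-Indigo, WL-AIM, Indigo-AIM) on the
#' per-lesion values of each metric. The primary test is the two-sided
#' paired Wilcoxon signed-rank test; a paired t-test is reported alongside,
#' both labeled. P-values are uncorrected by default, with a Holm-corrected
#' column (within each metric x test family of three comparisons) emitted
#' for transparency.
#'
#' The reported `statistic` is a signed location statistic: the centered
#' signed-rank statistic `V - m(m+1)/4` (m = nonzero differences) for the
#' Wilcoxon test and the t statistic for the t-test, so swapping a pair's
#' order flips its sign while leaving the p-value unchanged. If all paired
#' differences are exactly zero, the test is degenerate: statistic 0,
#' p-value 1, flagged in the `degenerate` column.
#'
#' @param records Per-image tibble from [run_study()]: one row per
#'   (lesion, modality) with `mahalanobis_distance` and `f1`; all three
#'   modalities must be present for every lesion.
#' @return An object of class `study_report` with elements
#'   `modality_summary`, `comparisons`, `n_lesions`, `records`.
#' @export
aggregate_study <- function(records) {
  required <- c("lesion_id", "modality", "mahalanobis_distance", "f1")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("`records` is missing columns: %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "chromsep_format_error")
  }
  gaps <- records |>
    dplyr::count(.data$lesion_id, .data$modality) |>
    tidyr::complete(lesion_id = unique(records$lesion_id),
                    modality = MODALITIES, fill = list(n = 0L)) |>
    dplyr::filter(.data$n != 1L)
  if (nrow(gaps) > 0) {
    abort(paste0(
      "Records must hold exactly one row per (lesion, modality); problems: ",
      paste(sprintf("%s/%s (%d rows)", gaps$lesion_id, gaps$modality, gaps$n),
            collapse = ", "), "."),
      class = "chromsep_completeness_error")
  }

  records <- dplyr::arrange(records, .data$lesion_id,
                            match(.data$modality, MODALITIES))
  n_lesions <- dplyr::n_distinct(records$lesion_id)

  modality_summary <- records |>
    tidyr::pivot_longer(c("mahalanobis_distance", "f1"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$modality, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop") |>
    dplyr::arrange(match(.data$modality, MODALITIES), .data$metric)

  comparisons <- if (n_lesions < 2) {
    warn("Fewer than 2 lesions: means reported, paired tests skipped.")
    tibble(metric = character(), pair = character(), test = character(),
           mean_difference = numeric(), statistic = numeric(),
           p_value = numeric(), p_holm = numeric(), degenerate = logical())
  } else {
    pairs <- list(c("WL", "Indigo"), c("WL", "AIM"), c("Indigo", "AIM"))
    by_lesion <- records |>
      tidyr::pivot_wider(id_cols = "lesion_id", names_from = "modality",
                         values_from = c("mahalanobis_distance", "f1"))
    res <- purrr::map(c("mahalanobis_distance", "f1"), function(metric) {
      purrr::map(pairs, function(p) {
        x <- by_lesion[[paste0(metric, "_", p[1])]]
        y <- by_lesion[[paste0(metric, "_", p[2])]]
        dplyr::bind_rows(
          paired_wilcoxon(x, y, metric, paste(p, collapse = "-")),
          paired_ttest(x, y, metric, paste(p, collapse = "-"))
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    res |>
      dplyr::group_by(.data$metric, .data$test) |>
      dplyr::mutate(p_holm = stats::p.adjust(.data$p_value, "holm")) |>
      dplyr::ungroup() |>
      dplyr::relocate("p_holm", .after = "p_value")
  }

  structure(
    list(modality_summary = modality_summary, comparisons = comparisons,
         n_lesions = n_lesions, records = records),
    class = "study_report"
  )
}

paired_wilcoxon <- function(x, y, metric, pair) {
  d <- x - y
  m <- sum(d != 0)
  if (m == 0) {
    return(tibble(metric = metric, pair = pair, test = "wilcoxon_signed_rank",
                  mean_difference = 0, statistic = 0, p_value = 1,
                  degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            alternative = "two.sided"))
  tibble(metric = metric, pair = pair, test = "wilcoxon_signed_rank",
         mean_difference = mean(d),
         statistic = unname(wt$statistic) - m * (m + 1) / 4,
         p_value = wt$p.value, degenerate = FALSE)
}

paired_ttest <- function(x, y, metric, pair) {
  d <- x - y
  if (all(d == 0)) {
    return(tibble(metric = metric, pair = pair, test = "paired_t",
                  mean_difference = 0, statistic = 0, p_value = 1,
                  degenerate = TRUE))
  }
  tt <- tryCatch(stats::t.test(x, y, paired = TRUE),
                 error = function(e) NULL)
  if (is.null(tt)) { # constant nonzero differences: t statistic undefined
    return(tibble(metric = metric, pair = pair, test = "paired_t",
                  mean_difference = mean(d), statistic = NA_real_,
                  p_value = 0, degenerate = TRUE))
  }
  tibble(metric = metric, pair = pair, test = "paired_t",
         mean_difference = mean(d), statistic = unname(tt$statistic),
         p_value = tt$p.value, degenerate = FALSE)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d lesions x 3 modalities\n", x$n_lesions))
  wide <- tidyr::pivot_wider(x$modality_summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  cat("\nPer-modality means (SD):\n")
  for (i in seq_len(nrow(wide))) {
    cat(sprintf("  %-6s distance %s (%s)   F1 %s (%s)\n",
                wide$modality[i],
                fmt3(wide$mean_mahalanobis_distance[i]),
                fmt3(wide$sd_mahalanobis_distance[i]),
                fmt3(wide$mean_f1[i]), fmt3(wide$sd_f1[i])))
  }
  if (nrow(x$comparisons) > 0) {
    w <- x$comparisons[x$comparisons$test == "wilcoxon_signed_rank", ]
    cat("\nPaired Wilcoxon signed-rank (two-sided, uncorrected):\n")
    for (i in seq_len(nrow(w))) {
      cat(sprintf("  %-22s %-12s p = %s\n", w$metric[i], w$pair[i],
                  fmt3(w$p_value[i])))
    }
  }
  invisible(x)
}

# Human-readable rounding used only in printed summaries.
fmt3 <- function(x) sprintf("%.3f", x)

#' @export
tidy.study_report <- function(x, ...) x$comparisons

#' @export
glance.study_report <- function(x, ...) {
  wide <- x$modality_summary |>
    dplyr::mutate(modality = tolower(.data$modality),
                  metric = ifelse(.data$metric == "mahalanobis_distance",
                                  "distance", .data$metric)) |>
    tidyr::pivot_wider(names_from = c("metric", "modality"),
                       values_from = c("mean", "sd"),
                       names_glue = "{.value}_{metric}_{modality}")
  dplyr::bind_cols(tibble(n_lesions = x$n_lesions), wide)
}

#' Bar chart of per-modality means
#'
#' Mean Mahalanobis distance or mean F1 by modality with standard-deviation
#' error bars — the study's headline comparison figure.
#'
#' @param object A `study_report`.
#' @param metric `"mahalanobis_distance"` or `"f1"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.study_report <- function(object, metric = c("mahalanobis_distance",
                                                     "f1"), ...) {
  metric <- match.arg(metric)
  df <- object$modality_summary |>
    dplyr::filter(.data$metric == !!metric) |>
    dplyr::mutate(modality = factor(.data$modality, levels = MODALITIES))
  ylab <- if (metric == "f1") "Mean F1 measure" else
    "Mean Mahalanobis distance"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$modality, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey40", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}

#' Write a study report to disk
#'
#' Emits a machine-readable JSON report (modality summary, comparisons,
#' lesion count) and the per-image records CSV at full numeric precision;
#' rounding happens only in the printed human-readable summary.
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written (`json`, `csv`).
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(out_dir, "report.json")
  csv_path <- file.path(out_dir, "records.csv")
  jsonlite::write_json(
    list(n_lesions = report$n_lesions,
         modality_summary = report$modality_summary,
         comparisons = report$comparisons),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(report$records, csv_path)
  invisible(list(json = json_path, csv = csv_path))
}

#' Reload a written study report
#'
#' @param out_dir Directory written by [write_report()].
#' @return A `study_report` equal in content to the one written.
#' @export
read_report <- function(out_dir) {
  raw <- jsonlite::fromJSON(file.path(out_dir, "report.json"))
  records <- readr::read_csv(file.path(out_dir, "records.csv"),
                             show_col_types = FALSE)
  structure(
    list(modality_summary = as_tibble(raw$modality_summary),
         comparisons = as_tibble(raw$comparisons),
         n_lesions = raw$n_lesions,
         records = records),
    class = "study_report"
  )
}

#' Re-aggregate existing per-image results
#'
#' Reads a per-image records CSV (the format written by [write_report()])
#' and rebuilds the study report without re-running the pipeline.
#'
#' @param results_path Per-image records CSV.
#' @return A `study_report`.
#' @export
reaggregate_results <- function(results_path) {
  aggregate_study(readr::read_csv(results_path, show_col_types = FALSE))
}
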