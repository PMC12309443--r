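#' Run the full song analysis
#'
#' Executes the analysis stages in their methodological order: dataset
#' summary; the C-syllable stream-membership comparison (whose verdict
#' decides, under `include_c = "auto"`, whether C onsets enter the IOI
#' arithmetic downstream — they are omitted unless the comparison
#' significantly favors inclusion); then the accelerando, acceleration-
#' constancy, component-duration, CV-trend, first-IOI-plasticity and
#' crescendo mixed models, per-penguin regressions, and the per-penguin
#' first-versus-last IOI CV-equality tests. A stage that fails (e.g. the
#' crescendo model on a dataset without intensities) is recorded as failed
#' and the remaining stages continue.
#'
#' @param dataset a `song_dataset` (from [read_csv_table()],
#'   [generate_dataset()], or TextGrids via [read_textgrid()] +
#'   [as_song_dataset()]).
#' @param include_c `"auto"` (follow the C-analysis verdict),
#'   `"always_omit"`, or `"always_include"`.
#' @param alpha significance level used in verdicts and counts.
#' @param kde_bandwidth optional KDE bandwidth for the C analysis.
#' @param output_dir if non-`NULL`, intermediate tables and a model summary
#'   are written there as CSV.
#' @param seed seed for the Monte-Carlo correction inside the CV-equality
#'   tests (the only stochastic stage).
#' @return list of class `"song_analysis_report"`.
#' @export
run_pipeline <- function(dataset, include_c = c("auto", "always_omit",
                                                "always_include"),
                         alpha = 0.05, kde_bandwidth = NULL,
                         output_dir = NULL, seed = 1L) {
  include_c <- match.arg(include_c)
  report <- list(summary = summarize_dataset(dataset), failed = character(0))

  c_analysis <- NULL
  if (include_c == "auto") {
    c_analysis <- tryCatch(
      likelihood_comparison(partition_ratios(dataset),
                            bandwidth = kde_bandwidth, alpha = alpha),
      eligibility_error = function(e) {
        message("C analysis not applicable: ", conditionMessage(e))
        NULL
      })
    use_c <- !is.null(c_analysis) && c_analysis$verdict == "include"
  } else {
    use_c <- include_c == "always_include"
  }
  report$c_analysis <- c_analysis
  report$include_c <- use_c
  message("C syllables ", if (use_c) "included" else "omitted",
          " in interval calculations")

  intervals <- dataset_intervals(dataset, include_c = use_c)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      message("stage '", name, "' failed: ", conditionMessage(e))
      report$failed <<- c(report$failed, name)
      NULL
    })
  }
  report$accelerando <- stage("accelerando", model_accelerando(intervals))
  report$acceleration_constancy <- stage("acceleration_constancy",
    model_acceleration_constancy(dataset, include_c = use_c))
  report$components <- stage("components",
                             model_component_durations(intervals))
  report$binned_cv <- stage("binned_cv", bin_iois(intervals))
  report$cv_trend <- stage("cv_trend", model_cv_trend(report$binned_cv))
  report$ioi1_plasticity <- stage("ioi1_plasticity",
    model_ioi1_plasticity(dataset, include_c = use_c))
  report$crescendo <- stage("crescendo", model_crescendo(dataset))
  report$per_penguin <- list(
    accelerando = stage("per_penguin_accelerando",
      per_penguin_regressions(dataset, "accelerando", alpha = alpha,
                              include_c = use_c)),
    ioi1 = stage("per_penguin_ioi1",
      per_penguin_regressions(dataset, "ioi1", alpha = alpha,
                              include_c = use_c)),
    crescendo = stage("per_penguin_crescendo",
      per_penguin_regressions(dataset, "crescendo", alpha = alpha)))
  set.seed(seed)
  report$cv_equality <- stage("cv_equality",
    cv_equality_by_penguin(dataset, alpha = alpha, include_c = use_c))
  report$alpha <- alpha
  class(report) <- "song_analysis_report"
  if (!is.null(output_dir)) write_report_tables(report, intervals, output_dir)
  report
}

write_report_tables <- function(report, intervals, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(intervals, file.path(output_dir, "intervals.csv"),
                   row.names = FALSE)
  if (!is.null(report$binned_cv)) {
    utils::write.csv(report$binned_cv, file.path(output_dir, "binned_cv.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(model_fit_table(report),
                   file.path(output_dir, "model_fits.csv"), row.names = FALSE)
  if (!is.null(report$cv_equality)) {
    utils::write.csv(report$cv_equality,
                     file.path(output_dir, "cv_equality.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$c_analysis)) {
    utils::write.csv(report$c_analysis$per_penguin,
                     file.path(output_dir, "c_likelihoods.csv"),
                     row.names = FALSE)
  }
  invisible(output_dir)
}

#' Collect every fitted model of a report into one table
#'
#' @param report a `"song_analysis_report"`.
#' @return data frame with one row per mixed model: name, estimate, SE,
#'   chi-square, df, p, n, convergence.
#' @export
model_fit_table <- function(report) {
  fits <- list(report$accelerando, report$acceleration_constancy,
               report$components$syllable, report$components$silence,
               report$cv_trend, report$ioi1_plasticity, report$crescendo)
  fits <- fits[!vapply(fits, is.null, logical(1))]
  do.call(rbind, lapply(fits, function(f) {
    data.frame(name = f$name, estimate = f$estimate, se = f$se,
               chi_square = f$chi_square, df = f$df, p_value = f$p_value,
               n = f$n, converged = f$converged, singular = f$singular,
               percent_change = if (is.null(f$percent_change)) NA_real_
                                else f$percent_change,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.song_analysis_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Song dataset: %d colonies, %d penguins, %d songs\n",
              s$n_colonies, s$n_penguins, s$n_songs))
  cat("  syllables:", paste(names(s$syllable_counts), s$syllable_counts,
                            sep = "=", collapse = " "), "\n")
  if (!is.null(x$c_analysis)) {
    cat(sprintf("C-syllable analysis: verdict '%s' (Wilcoxon T = %.1f, p = %.2g, n = %d penguins)\n",
                x$c_analysis$verdict, x$c_analysis$wilcoxon_T,
                x$c_analysis$p_value, x$c_analysis$n_penguins))
  } else {
    cat("C-syllable analysis: not applicable\n")
  }
  cat("Mixed-model suite:\n")
  tab <- model_fit_table(x)
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-55s est %8.4f  chi2(1) %9.3f  p %s  n %d\n",
                tab$name[i], tab$estimate[i], tab$chi_square[i],
                format.pval(tab$p_value[i], digits = 3), tab$n[i]))
  }
  if (!is.null(x$per_penguin$accelerando)) {
    cat(sprintf("Per-penguin accelerando: %d/%d penguins with significant negative slope\n",
                attr(x$per_penguin$accelerando, "n_significant"),
                nrow(x$per_penguin$accelerando)))
  }
  if (!is.null(x$cv_equality)) {
    cat(sprintf("CV equality (first vs last IOI): %d/%d penguins with significant decrease\n",
                attr(x$cv_equality, "n_significant_decrease"),
                nrow(x$cv_equality)))
  }
  if (length(x$failed)) cat("Failed stages:", paste(x$failed, collapse = ", "),
                            "\n")
  invisible(x)
}
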