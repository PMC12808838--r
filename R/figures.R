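# Report figures
#
# Three figures mirror the benchmark report: the distribution of clinical
# staff hours by staff category and shift type (boxplots; the default
# boxplot marks points beyond Q3 + 1.5 IQR / below Q1 - 1.5 IQR as
# outliers), the daily census of admitted infants per acuity category, and
# the histogram of the RN provision ratio with a reference line at 1.0.

#' Render the three report figures
#'
#' @param benchmark Benchmark table from [benchmark_table()].
#' @param ledgers Ledger table from [build_ledgers()].
#' @param acuity Acuity table from [classify_cohort()].
#' @param out_dir Output directory (must exist).
#' @param format `"png"` or `"pdf"`.
#' @return Character vector of the files written.
#' @export
render_figures <- function(benchmark, ledgers, acuity, out_dir,
                           format = c("png", "pdf")) {
  format <- match.arg(format)
  if (nrow(benchmark) == 0 || nrow(ledgers) == 0) {
    warning("empty input; figures skipped")
    return(character())
  }
  dev <- if (format == "png") {
    function(file) grDevices::png(file, width = 1600, height = 1000, res = 200)
  } else {
    function(file) grDevices::pdf(file, width = 8, height = 5)
  }
  save_plot <- function(plot, name) {
    file <- file.path(out_dir, paste0(name, ".", format))
    dev(file)
    on.exit(grDevices::dev.off(), add = TRUE)
    print(plot)
    file
  }

  staff_long <- tidyr::pivot_longer(
    ledgers[c("shift_type", "rn_hours", "rn_spec_hours", "na_hours")],
    cols = c("rn_hours", "rn_spec_hours", "na_hours"),
    names_to = "staff_category", values_to = "hours"
  )
  staff_long$staff_category <- factor(
    staff_long$staff_category,
    levels = c("rn_hours", "rn_spec_hours", "na_hours"),
    labels = c("RN", "RN specialist", "Nursing assistant")
  )
  p1 <- ggplot2::ggplot(staff_long,
                        ggplot2::aes(x = .data$shift_type, y = .data$hours,
                                     fill = .data$staff_category)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = "Shift type", y = "Clinical hours per shift",
                  fill = "Staff category",
                  title = "Staff hours by category and shift type") +
    ggplot2::theme_minimal()

  census <- dplyr::count(tibble::as_tibble(acuity), .data$care_day,
                         .data$category, name = "n_infants")
  p2 <- ggplot2::ggplot(census,
                        ggplot2::aes(x = .data$care_day, y = .data$n_infants,
                                     colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Care-day", y = "Admitted infants", colour = "Acuity",
                  title = "Daily census per acuity category") +
    ggplot2::theme_minimal()

  ratios <- benchmark[benchmark$ratio_defined, ]
  p3 <- ggplot2::ggplot(ratios, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(binwidth = 0.05, fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = 1.0, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "RN provision ratio", y = "Shifts",
                  title = "RN provision ratio (reference 1.0)") +
    ggplot2::theme_minimal()

  c(save_plot(p1, "fig_staff_hours"),
    save_plot(p2, "fig_acuity_census"),
    save_plot(p3, "fig_provision_ratio"))
}
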