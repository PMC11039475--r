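#' Two-branch group comparison (normality-gated)
#'
#' Reproduces the comparison scheme used for the day-group statistics:
#' normality of each sample is assessed with the Shapiro-Wilk test; when
#' both samples pass (p > alpha) the groups are compared with an
#' independent-samples t test (Welch form) and described as mean +/- SD,
#' otherwise with the Mann-Whitney U test and described as median (IQR).
#'
#' @param sample_a,sample_b numeric vectors (n >= 3 each).
#' @param alpha significance level for both the normality gate and the
#'   comparison.
#' @param labels length-2 character vector of group names.
#' @param variable name of the compared quantity.
#' @return A `group_comparison` list: descriptives per group, per-group
#'   Shapiro-Wilk p, `test_used` (`"t"` or `"mann-whitney"`), `p_value`,
#'   `significant`.
#' @export
compare_groups <- function(sample_a, sample_b, alpha = 0.05,
                           labels = c("A", "B"), variable = "value") {
  if (length(sample_a) < 3L || length(sample_b) < 3L)
    stop("insufficient sample: each group needs n >= 3")
  sw_a <- stats::shapiro.test(sample_a)$p.value
  sw_b <- stats::shapiro.test(sample_b)$p.value
  normal <- sw_a > alpha && sw_b > alpha
  if (normal) {
    ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
    test_used <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(sample_a, sample_b))
    test_used <- "mann-whitney"
  }
  desc <- function(x) {
    c(n = length(x), mean = mean(x), sd = stats::sd(x),
      median = stats::median(x), iqr = stats::IQR(x))
  }
  structure(list(
    variable = variable, labels = labels,
    descriptives = rbind(desc(sample_a), desc(sample_b)),
    normality_p = c(sw_a, sw_b), normal = normal,
    test_used = test_used, p_value = ht$p.value,
    significant = ht$p.value < alpha, alpha = alpha),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s vs %s\n", x$variable,
              x$labels[1], x$labels[2]))
  d <- x$descriptives
  for (i in 1:2) {
    if (x$normal)
      cat(sprintf("  %s: %.4g +/- %.4g (n = %d)\n", x$labels[i],
                  d[i, "mean"], d[i, "sd"], d[i, "n"]))
    else
      cat(sprintf("  %s: %.4g (IQR %.4g) (n = %d)\n", x$labels[i],
                  d[i, "median"], d[i, "iqr"], d[i, "n"]))
  }
  cat(sprintf("  %s test, p = %.4g%s\n",
              if (x$test_used == "t") "Welch t" else "Mann-Whitney U",
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Assemble day-group summary tables and plots
#'
#' Renders per-day lobe summaries (and optional group comparisons) into
#' CSV tables plus simple bar/box figures, the shape of the published
#' per-day quantitative panels.
#'
#' @param summaries named list of `lobe_summary` objects, one per day
#'   group (names are the group labels, e.g. `"1"`, `"3"`, ...).
#' @param comparisons optional list of `group_comparison` objects.
#' @param out_dir output directory.
#' @param plots write PNG figures.
#' @param bh_adjust apply a Benjamini-Hochberg correction column to the
#'   comparison table (off by default, matching uncorrected per-pair
#'   reporting).
#' @return Invisible character vector of the files written.
#' @export
build_report <- function(summaries, comparisons = NULL, out_dir,
                         plots = TRUE, bh_adjust = FALSE) {
  if (length(summaries) < 1L) stop("at least one summary is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  tab <- do.call(rbind, lapply(names(summaries), function(day) {
    s <- summaries[[day]]
    data.frame(day = day, n_infarcts = s$n_infarcts,
               total_volume_um3 = s$total_volume_um3,
               lobe_volume_um3 = s$lobe_volume_um3,
               volume_ratio = s$volume_ratio,
               confluent_fraction = s$confluent_fraction)
  }))
  f <- file.path(out_dir, "lobe_summary.csv")
  utils::write.csv(tab, f, row.names = FALSE)
  files <- c(files, f)

  zone_tab <- do.call(rbind, lapply(names(summaries), function(day) {
    z <- summaries[[day]]$per_zone
    cbind(day = day, z)
  }))
  f <- file.path(out_dir, "zone_summary.csv")
  utils::write.csv(zone_tab, f, row.names = FALSE)
  files <- c(files, f)

  if (length(comparisons)) {
    ct <- do.call(rbind, lapply(comparisons, function(cc)
      data.frame(variable = cc$variable,
                 group_a = cc$labels[1], group_b = cc$labels[2],
                 test_used = cc$test_used, p_value = cc$p_value,
                 significant = cc$significant)))
    if (bh_adjust)
      ct$p_adj_bh <- stats::p.adjust(ct$p_value, method = "BH")
    f <- file.path(out_dir, "comparisons.csv")
    utils::write.csv(ct, f, row.names = FALSE)
    files <- c(files, f)
  }

  if (plots) {
    f <- file.path(out_dir, "summary_plots.png")
    grDevices::png(f, width = 1200, height = 400)
    op <- graphics::par(mfrow = c(1, 3))
    graphics::barplot(tab$n_infarcts, names.arg = tab$day,
                      xlab = "day", ylab = "number of infarcts")
    graphics::barplot(tab$total_volume_um3, names.arg = tab$day,
                      xlab = "day", ylab = "total infarct volume (um^3)")
    graphics::barplot(100 * tab$volume_ratio, names.arg = tab$day,
                      xlab = "day", ylab = "volume ratio (%)")
    graphics::par(op)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}
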