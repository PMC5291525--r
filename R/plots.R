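#' Data behind a disparity-curve plot
#'
#' Returns the exact arrays a disparity plot draws, so figures can be
#' checked on their data rather than on rendered pixels.
#'
#' @param curves `disparity_curves` (or anything coercible).
#' @param thin Keep roughly this many points per track (even subsampling;
#'   `Inf` keeps all). The endpoints are always retained.
#' @return Data frame `n`, `at`, `gc`.
#' @export
disparity_plot_data <- function(curves, thin = 2000L) {
  if (!inherits(curves, "disparity_curves")) curves <- disparity_curves(curves)
  idx <- if (is.finite(thin) && curves$N + 1L > thin) {
    unique(c(as.integer(round(seq(1L, curves$N + 1L, length.out = thin))),
             curves$N + 1L))
  } else seq_len(curves$N + 1L)
  data.frame(n = idx - 1L, at = curves$at[idx], gc = curves$gc[idx])
}

#' Plot AT and GC disparity curves
#'
#' Base-graphics plot of both cumulative disparity tracks against position,
#' with ori/ter markers when a replichore model is supplied. Rotated to the
#' origin, a genome with strong skew shows the canonical inverted-V GC
#' track; the AT track mirrors it (negative ZCC) or follows it (positive
#' ZCC).
#'
#' @param x `disparity_curves`.
#' @param model Optional `replichore_model` for ori/ter markers.
#' @param thin See [disparity_plot_data()].
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the plotted data frame.
#' @export
plot.disparity_curves <- function(x, model = NULL, thin = 2000L, ...) {
  d <- disparity_plot_data(x, thin = thin)
  graphics::matplot(d$n, cbind(d$at, d$gc), type = "l", lty = 1,
                    col = c("#D55E00", "#0072B2"),
                    xlab = "position (bp)", ylab = "cumulative disparity",
                    main = x$genome_id, ...)
  graphics::legend("topright", legend = c("AT (A - T)", "GC (G - C)"),
                   col = c("#D55E00", "#0072B2"), lty = 1, bty = "n")
  if (!is.null(model)) {
    graphics::abline(v = c(model$ori, model$ter), lty = 2,
                     col = "grey40")
    graphics::mtext(c("ori", "ter"), side = 3,
                    at = c(model$ori, model$ter), cex = 0.8)
  }
  invisible(d)
}

#' @export
plot.zcc_genome <- function(x, ...) {
  plot(x$curves, model = x$model, ...)
}

#' Data behind the per-phylum ZCC boxplot
#'
#' Boxplot statistics with Tukey-fence whiskers: for each phylum the
#' quartiles, the fences, and the flagged outliers, computed with
#' [tukey_outliers()] so the figure and the outlier tables always agree.
#'
#' @param records Results data frame with `phylum` and `zcc`.
#' @return A list per phylum: `values`, `fences` (a `tukey_fences`),
#'   `median`.
#' @export
cohort_boxplot_data <- function(records) {
  ok <- !is.na(records$zcc)
  lapply(split(records[ok, , drop = FALSE], records$phylum[ok]), function(g) {
    list(values = g$zcc,
         fences = if (nrow(g) >= 4L)
           tukey_outliers(g$zcc, g$genome_id) else NULL,
         median = stats::median(g$zcc))
  })
}

#' Boxplot of ZCC indexes by phylum
#'
#' @param records Results data frame with `phylum` and `zcc`.
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, [cohort_boxplot_data()] for the same records.
#' @export
plot_zcc_boxplot <- function(records, ...) {
  ok <- !is.na(records$zcc)
  graphics::boxplot(zcc ~ phylum, data = records[ok, , drop = FALSE],
                    range = 1.5, ylab = "ZCC index", xlab = "",
                    las = 2, ...)
  graphics::abline(h = 0, lty = 3, col = "grey50")
  invisible(cohort_boxplot_data(records))
}

#' Sign-percentage data and bar chart
#'
#' Percentages of genomes with negative and positive ZCC indexes per
#' phylum, from a [summarize_phylum()] table.
#'
#' @param summaries A `phylum_summary` data frame.
#' @return Matrix with rows `negative`, `positive` and one column per
#'   phylum (percent of total).
#' @export
sign_percentage_data <- function(summaries) {
  m <- rbind(negative = summaries$pct_negative,
             positive = summaries$pct_positive)
  colnames(m) <- summaries$phylum
  m
}

#' @rdname sign_percentage_data
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_sign_percentages <- function(summaries, ...) {
  m <- sign_percentage_data(summaries)
  graphics::barplot(m, beside = TRUE, col = c("#0072B2", "#D55E00"),
                    ylab = "% of genomes", las = 2,
                    legend.text = c("negative ZCC", "positive ZCC"),
                    args.legend = list(bty = "n"), ...)
  invisible(m)
}
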