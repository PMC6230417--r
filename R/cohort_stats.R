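#' Pearson correlation with a two-sided t test
#'
#' Product-moment correlation between two numeric vectors; the p-value uses
#' the exact t transform `t = r sqrt((n-2)/(1-r^2))` with `n - 2` degrees
#' of freedom (via [stats::cor.test()]). No multiple-testing correction is
#' applied.
#'
#' @param x,y numeric vectors of equal length, at least 3 pairs, each with
#'   non-zero variance.
#' @return List of class `correlation_result`: `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) {
    stop_ctb("pearson: vectors must have equal length",
             class = "ctb_contract_error")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop_ctb("pearson: need at least 3 complete pairs",
             class = "ctb_contract_error")
  }
  if (var(x) == 0 || var(y) == 0) {
    stop_ctb("pearson: zero variance input",
             class = "ctb_degenerate_data_error")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f, P = %.4f (n = %d)\n", x$r, x$p_value, x$n))
  invisible(x)
}

#' Progression / nonprogression group summaries
#'
#' Arithmetic means of the percent changes in volume, density and size
#' within the progression group (RECIST PD) and the nonprogression group
#' (PR or SD).
#'
#' @param cohort a [read_cohort()] table.
#' @return data.frame with rows `progression` and `nonprogression` and
#'   columns `n`, `mean_volume_pct`, `mean_density_pct`, `mean_size_pct`.
#' @export
group_summaries <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (anyNA(cohort$recist)) {
    stop_ctb("group_summaries: every row needs a RECIST category",
             class = "ctb_validation_error")
  }
  grp <- ifelse(cohort$recist == "PD", "progression", "nonprogression")
  out <- do.call(rbind, lapply(c("progression", "nonprogression"),
    function(g) {
      rows <- cohort[grp == g, ]
      if (nrow(rows) == 0L) {
        warning("group_summaries: empty group ", g)
        return(data.frame(group = g, n = 0L, mean_volume_pct = NA_real_,
                          mean_density_pct = NA_real_,
                          mean_size_pct = NA_real_))
      }
      data.frame(group = g, n = nrow(rows),
                 mean_volume_pct = mean(rows$volume_pct),
                 mean_density_pct = mean(rows$density_pct),
                 mean_size_pct = mean(rows$size_pct))
    }))
  rownames(out) <- out$group
  out
}

#' Cohort correlation report against PFS
#'
#' Correlates delta(V+D), deltaV, deltaD and deltaS with progression-free
#' survival over the complete cases (rows with recorded PFS; missing PFS is
#' never imputed). Significance is flagged at P < 0.05.
#'
#' @param cohort a [read_cohort()] table with at least 3 rows with PFS.
#' @return data.frame with one row per metric (`combined`, `volume`,
#'   `density`, `size`) and columns `r`, `p_value`, `n`, `significant`;
#'   attribute `scatter` holds per-metric `(x, y)` data.frames for
#'   plotting, attribute `cases` the case numbers used.
#' @export
correlation_report <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  cc <- cohort[!is.na(cohort$pfs_months), ]
  if (nrow(cc) < 3L) {
    stop_ctb("correlation_report: fewer than 3 rows with recorded PFS",
             class = "ctb_contract_error")
  }
  metrics <- c(combined = "combined_pct", volume = "volume_pct",
               density = "density_pct", size = "size_pct")
  rows <- lapply(names(metrics), function(m) {
    cr <- pearson(cc[[metrics[[m]]]], cc$pfs_months)
    data.frame(metric = m, r = cr$r, p_value = cr$p_value, n = cr$n,
               significant = cr$p_value < 0.05)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$metric
  attr(out, "scatter") <- lapply(metrics, function(col) {
    data.frame(x = cc[[col]], y = cc$pfs_months)
  })
  attr(out, "cases") <- cc$case
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' Scatterplots of the correlation report
#'
#' One panel per metric: percent change against PFS (months), with the
#' fitted least-squares line and the `r` / `P` annotation.
#'
#' @param report a [correlation_report()].
#' @param path optional PNG path; when given, the figure is written there.
#' @return `report`, invisibly.
#' @export
plot_correlations <- function(report, path = NULL) {
  stopifnot(inherits(report, "correlation_report"))
  scatter <- attr(report, "scatter")
  labels <- c(combined = expression(Delta * "(V+D) (%)"),
              volume = expression(Delta * "V (%)"),
              density = expression(Delta * "D (%)"),
              size = expression(Delta * "S (%)"))
  draw <- function() {
    op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    for (m in report$metric) {
      s <- scatter[[m]]
      graphics::plot(s$x, s$y, pch = 19, xlab = labels[[m]],
                     ylab = "PFS (months)",
                     main = sprintf("r = %.3f, P = %.3f",
                                    report[m, "r"], report[m, "p_value"]))
      graphics::abline(stats::lm(y ~ x, data = s), lty = 2)
    }
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 1200, height = 1000, res = 150)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  } else {
    draw()
  }
  invisible(report)
}
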