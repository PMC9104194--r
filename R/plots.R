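# Publication-style base-graphics views of a cohort analysis: fingerprint
# scatter with LDA boundary and class ellipses, per-class boxplots, and the
# p-value heatmap.

#' Scatterplot of a cohort with LDA boundary and confidence ellipses
#'
#' @param x A [maglev_cohort()].
#' @param model Optional [lda_fit()] model whose decision line is drawn.
#' @param level Ellipse coverage level (`NA` to omit ellipses).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.maglev_cohort <- function(x, model = NULL, level = 0.95, ...) {
  classes <- unique(x$labels)
  cols <- stats::setNames(grDevices::hcl.colors(max(length(classes), 3),
                                                "Dark 3")[seq_along(classes)],
                          classes)
  graphics::plot(x$points, col = cols[x$labels], pch = 19,
                 xlab = "starting position (mm)",
                 ylab = "levitating fraction area", ...)
  if (!is.na(level)) {
    for (cl in classes) {
      pts <- x$points[x$labels == cl, , drop = FALSE]
      if (nrow(pts) >= 3)
        graphics::lines(ellipse_boundary(confidence_ellipse(pts, level)),
                        col = cols[cl])
      graphics::points(t(colMeans(pts)), col = cols[cl], pch = 3, cex = 2)
    }
  }
  if (!is.null(model)) {
    w <- model$weights; c0 <- model$threshold
    usr <- graphics::par("usr")
    if (abs(w[2]) > abs(w[1]) * 1e-9) {
      xx <- seq(usr[1], usr[2], length.out = 2)
      graphics::lines(xx, (c0 - w[1] * xx) / w[2], lwd = 2)
    } else {
      graphics::abline(v = c0 / w[1], lwd = 2)
    }
  }
  graphics::legend("topright", legend = classes, col = cols[classes],
                   pch = 19, bty = "n")
  invisible(x)
}

#' Boxplots of one fingerprint feature by class
#'
#' @param cohort A [maglev_cohort()].
#' @param feature `"starting_position_mm"` or `"levitating_area"`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
boxplot_fingerprints <- function(cohort, feature = "starting_position_mm",
                                 ...) {
  graphics::boxplot(cohort$points[, feature] ~ factor(cohort$labels),
                    xlab = "class", ylab = feature, ...)
  invisible(cohort)
}

#' Heatmap of the pairwise p-value matrix
#'
#' @param pvals Matrix from [pairwise_pvalue_matrix()].
#' @param ... Passed to [graphics::image()].
#' @export
plot_pvalue_heatmap <- function(pvals, ...) {
  n <- nrow(pvals)
  graphics::image(seq_len(n), seq_len(n), log10(t(pvals[n:1, ])),
                  axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(pvals), las = 2)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(pvals)), las = 2)
  for (i in seq_len(n)) for (j in seq_len(n))
    graphics::text(j, n + 1 - i, signif(pvals[i, j], 2), cex = 0.7)
  invisible(pvals)
}
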