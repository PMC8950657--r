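## Report graphics: ROC curves, the cross-species accuracy heat map, and the
## leave-one-species-out radar chart. Base graphics, so the plots render on
## any device.

#' Plot one or more ROC curves
#'
#' @param rocs a `dsite_roc` or a named list of them (names become legend
#'   labels, annotated with AUC).
#' @param main plot title.
#' @return Invisibly, the AUCs plotted.
#' @export
plotRoc <- function(rocs, main = "ROC") {
  if (inherits(rocs, "dsite_roc")) rocs <- list(ROC = rocs)
  cols <- seq_along(rocs)
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate (1 - Sp)",
                 ylab = "True positive rate (Sn)", main = main)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  for (i in seq_along(rocs))
    graphics::lines(rocs[[i]]$curve$fpr, rocs[[i]]$curve$tpr,
                    col = cols[i], lwd = 2)
  aucs <- vapply(rocs, function(r) r$auc, 0)
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC = %.4f)", names(rocs), aucs),
                   col = cols, lwd = 2, bty = "n")
  invisible(aucs)
}

#' Heat map of a cross-species accuracy matrix
#'
#' @param m a `dsite_crossspecies` matrix from [experimentThree()].
#' @param main plot title.
#' @return Invisibly, `m`.
#' @export
plotCrossSpecies <- function(m, main = "Cross-species accuracy") {
  vals <- unclass(m)
  attr(vals, "config") <- NULL
  n <- nrow(vals)
  graphics::image(seq_len(n), seq_len(n), t(vals[n:1, , drop = FALSE]),
                  zlim = c(0, 1), axes = FALSE, xlab = "test species",
                  ylab = "training species", main = main,
                  col = grDevices::hcl.colors(50, "YlOrRd", rev = TRUE))
  graphics::axis(1, at = seq_len(n), labels = colnames(vals), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(vals)), las = 2,
                 cex.axis = 0.8)
  for (r in seq_len(n)) for (cc in seq_len(n))
    graphics::text(cc, n - r + 1L, sprintf("%.2f", vals[r, cc]),
                   cex = 0.8)
  invisible(m)
}

#' Radar chart of leave-one-species-out metrics
#'
#' One polygon per metric over the species corners (the conventional view
#' of the leave-one-species-out experiment).
#'
#' @param g the `dsite_grid` returned by [experimentTwo()].
#' @param metrics which metric columns to draw.
#' @param main plot title.
#' @return Invisibly, `g`.
#' @export
plotSpeciesRadar <- function(g, metrics = c("Acc", "MCC", "AUC"),
                             main = "Leave-one-species-out") {
  df <- as.data.frame(g)
  n <- nrow(df)
  ang <- pi / 2 - 2 * pi * (seq_len(n) - 1L) / n
  graphics::plot(NA, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  for (ring in c(0.25, 0.5, 0.75, 1))
    graphics::polygon(ring * cos(ang), ring * sin(ang), border = "grey80")
  graphics::text(1.2 * cos(ang), 1.2 * sin(ang), df$test_species, cex = 0.8)
  for (i in seq_along(metrics)) {
    v <- pmax(df[[metrics[i]]], 0)
    graphics::polygon(v * cos(ang), v * sin(ang), border = i, lwd = 2)
  }
  graphics::legend("topright", legend = metrics, col = seq_along(metrics),
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(g)
}
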