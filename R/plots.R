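# Figure helpers (base graphics). Plots are best-effort visual artifacts;
# the numeric CSV/JSON outputs are the pipeline's contract.

group_colours <- function() {
  c("0" = "black", "1" = "magenta", "2" = "green3", "3" = "blue")
}

save_plot <- function(path, draw, width = 900, height = 700) {
  opened <- tryCatch({
    grDevices::png(path, width = width, height = height)
    TRUE
  }, error = function(e) FALSE)
  if (!opened) grDevices::pdf(sub("\\.png$", ".pdf", path),
                              width = width / 100, height = height / 100)
  on.exit(grDevices::dev.off())
  draw()
  invisible(path)
}

#' Overlay plot of a cohort's root systems
#'
#' One panel per (line, nitrate) cell with all of that cell's root systems
#' overlaid, arranged in four rows: low-NUpE low-N, low-NUpE high-N,
#' high-NUpE low-N, high-NUpE high-N, the same line aligned by column
#' between the row pairs. Cells with no plants are left blank.
#'
#' @param cohort a `root_cohort`.
#' @return invisibly, the panel layout (data frame).
#' @export
overlay_plot <- function(cohort) {
  if (!length(cohort)) stop("empty cohort")
  meta <- cohort_meta(cohort)
  cols <- group_colours()
  lines_low <- unique(meta$line[meta$nupe_class == "low"])
  lines_high <- unique(meta$line[meta$nupe_class == "high"])
  ncols <- max(length(lines_low), length(lines_high), 1L)
  layout <- expand.grid(row = 1:4, col = seq_len(ncols))
  op <- par(mfrow = c(4L, ncols), mar = c(0.5, 0.5, 1.2, 0.5))
  on.exit(par(op))
  all_pts <- do.call(rbind, lapply(cohort, function(s)
    do.call(rbind, lapply(s$curves, function(cv) cv$points))))
  xlim <- range(all_pts[, 1]); ylim <- rev(range(all_pts[, 2]))
  for (row in 1:4) {
    nupe <- if (row <= 2L) "low" else "high"
    nitr <- if (row %% 2L == 1L) "low" else "high"
    lns <- if (nupe == "low") lines_low else lines_high
    for (ci in seq_len(ncols)) {
      if (ci > length(lns)) { plot.new(); next }
      sel <- which(meta$line == lns[ci] & meta$nupe_class == nupe &
                     meta$nitrate == nitr)
      if (!length(sel)) { plot.new(); next }
      code <- as.character(meta$group_code[sel[1L]])
      plot(NA, xlim = xlim, ylim = ylim, axes = FALSE, xlab = "", ylab = "",
           main = sprintf("%s %s", lns[ci],
                          if (nitr == "high") "N+" else "N-"),
           cex.main = 0.9, asp = 1)
      box(col = "grey80")
      for (k in sel) {
        for (cv in cohort[[k]]$curves)
          lines(cv$points[, 1], cv$points[, 2], col = cols[code],
                lwd = if (cv$order == "seminal") 0.8 else 0.4)
      }
    }
  }
  invisible(layout)
}

#' Heat map of a Mahalanobis group-distance map
#' @param map a [group_distance_map()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot_group_distance_map <- function(map, ...) {
  D <- map$distances
  G <- nrow(D)
  pal <- grDevices::colorRampPalette(c("black", "grey95"))(64L)
  op <- par(mar = c(6, 6, 2, 1))
  on.exit(par(op))
  image(seq_len(G), seq_len(G), t(D[G:1, ]), col = pal, axes = FALSE,
        xlab = "", ylab = "",
        main = sprintf("Mahalanobis distances (%s)", map$mode), ...)
  labs <- sprintf("%s %s", map$cells$line,
                  ifelse(map$cells$nitrate == "high", "N+", "N-"))
  axis(1, seq_len(G), labs, las = 2, cex.axis = 0.7)
  axis(2, seq_len(G), rev(labs), las = 2, cex.axis = 0.7)
  nupe_split <- sum(map$cells$nupe_class == "low")
  abline(v = nupe_split + 0.5, h = G - nupe_split + 0.5, lwd = 2)
  if (map$mode == "line-pairs") {
    pair_ends <- which(diff(match(map$cells$line, unique(map$cells$line))) != 0)
    abline(v = pair_ends + 0.5, h = G - pair_ends + 0.5, lty = 2,
           col = "grey40")
  }
  box()
  invisible(map)
}

#' Density plot of discriminant scores per group
#' @param model a [fit_lda()] result.
#' @param dim which discriminant.
#' @export
plot_score_densities <- function(model, dim = 1L) {
  g <- model$labels
  cols <- group_colours()
  dens <- lapply(levels(g), function(lv)
    density(model$scores[g == lv, dim]))
  xl <- range(unlist(lapply(dens, function(d) d$x)))
  yl <- c(0, max(unlist(lapply(dens, function(d) d$y))))
  plot(NA, xlim = xl, ylim = yl, xlab = colnames(model$scores)[dim],
       ylab = "density", main = "discriminant score densities")
  for (i in seq_along(dens)) {
    lv <- levels(g)[i]
    col <- if (lv %in% names(cols)) cols[lv] else i
    lines(dens[[i]], col = col, lwd = 2)
  }
  legend("topright", legend = levels(g),
         col = vapply(levels(g), function(lv)
           if (lv %in% names(cols)) cols[lv] else
             as.character(match(lv, levels(g))), character(1)),
         lwd = 2, bty = "n")
  invisible(model)
}

#' Loadings bar plot of a discriminant
#' @param model a [fit_lda()] result.
#' @param dim which discriminant.
#' @export
plot_loadings <- function(model, dim = 1L) {
  op <- par(mar = c(8, 4, 2, 1))
  on.exit(par(op))
  barplot(model$loadings[, dim], las = 2, cex.names = 0.75,
          main = colnames(model$loadings)[dim], ylab = "loading")
  invisible(model)
}

#' Mean confidence regions in a discriminant plane
#' @param regions a [mean_confidence_regions()] result.
#' @param xlab,ylab axis labels.
#' @export
plot_confidence_regions <- function(regions, xlab = "LD1", ylab = "LD2") {
  cols <- group_colours()
  allb <- do.call(rbind, lapply(regions, function(r) r$boundary))
  plot(NA, xlim = range(allb[, 1]), ylim = range(allb[, 2]), xlab = xlab,
       ylab = ylab, main = "group mean confidence regions")
  for (nm in names(regions)) {
    col <- if (nm %in% names(cols)) cols[nm] else match(nm, names(regions))
    r <- regions[[nm]]
    polygon(r$boundary, border = col, lwd = 2)
    points(r$centre[1], r$centre[2], pch = 19, col = col)
  }
  invisible(regions)
}

#' Null-distribution histograms for a set of permutation tests
#' @param results named list of [permutation_test()] results.
#' @export
plot_permutation_tests <- function(results) {
  n <- length(results)
  op <- par(mfrow = c(ceiling(n / 2), 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (nm in names(results)) {
    x <- results[[nm]]
    hist(x$null, breaks = 40L, main = sprintf("%s (p = %.4g)", nm,
                                              x$p_value),
         xlab = "zeta2 under permutation",
         xlim = range(c(x$null, x$observed)))
    abline(v = x$observed, col = "red", lwd = 2)
  }
  invisible(results)
}

#' Strip plot of LD1 percentile exemplar root systems
#'
#' Draws, for each percentile of the LD1 scores, the exemplar root systems
#' closest to that percentile, spread vertically for legibility.
#'
#' @param exemplars a [percentile_exemplars()] result.
#' @param cohort the `root_cohort` the scores came from.
#' @param scale drawing scale (mm of root per unit of LD1 axis).
#' @export
plot_exemplars <- function(exemplars, cohort, scale = NULL) {
  ids <- vapply(cohort, function(s) s$plant_id, character(1))
  qs <- unique(exemplars$percentile)
  xr <- range(exemplars$value)
  if (is.null(scale)) {
    depth <- max(vapply(cohort, function(s)
      max(vapply(s$curves, function(cv) max(cv$points[, 2]), numeric(1))),
      numeric(1)))
    scale <- diff(xr) / (8 * depth)
  }
  k <- max(exemplars$rank)
  plot(NA, xlim = xr + c(-0.05, 0.05) * diff(xr), ylim = c(-(k + 1.5), 0.5),
       xlab = "LD1 score percentile value", ylab = "",
       yaxt = "n", main = "root systems along LD1")
  lines(exemplars$value[exemplars$rank == 1L], rep(0, length(qs)),
        col = "red", lty = 2)
  cols <- group_colours()
  for (i in seq_len(nrow(exemplars))) {
    sys <- cohort[[match(exemplars$plant_id[i], ids)]]
    code <- as.character(sys$meta$group_code)
    x0 <- exemplars$value[i]
    y0 <- -exemplars$rank[i]
    for (cv in sys$curves)
      lines(x0 + cv$points[, 1] * scale, y0 - cv$points[, 2] * scale * 0.9,
            col = cols[code], lwd = 0.4)
  }
  invisible(exemplars)
}
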