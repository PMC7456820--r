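#' Plot an axial slice of a statistic or importance map
#'
#' Renders one z-slice of a per-voxel map as a tile plot, with non-mask
#' voxels blank. Works for an `eloquence_map` (t-scores), an
#' `importance_maps` object (one covariate's normalized importance), or a
#' bare numeric vector over the grid.
#'
#' @param x An `eloquence_map`, `importance_maps`, or numeric vector.
#' @param z Slice index along the third axis (default: middle slice).
#' @param covariate For `importance_maps`: which covariate to show
#'   (default: first).
#' @param grid Required when `x` is a bare vector.
#' @param surviving_only For an `eloquence_map` with a threshold applied:
#'   show only surviving voxels (default FALSE).
#' @return A ggplot object.
#' @export
plot_slice <- function(x, z = NULL, covariate = NULL, grid = NULL,
                       surviving_only = FALSE) {
  if (inherits(x, "eloquence_map")) {
    grid <- x$grid
    vals <- x$t
    if (surviving_only && !is.null(x$surviving)) vals[!x$surviving] <- NA
    legend <- "t"
  } else if (inherits(x, "importance_maps")) {
    grid <- x$grid
    covariate <- covariate %||% colnames(x$normalized)[1]
    vals <- rep(NA_real_, n_voxels(grid))
    vals[x$voxels] <- x$normalized[, covariate]
    legend <- paste0("importance\n(", covariate, ")")
  } else {
    if (is.null(grid)) abort("`grid` is required for a bare vector.")
    vals <- as.numeric(x)
    legend <- "value"
  }
  z <- z %||% ceiling(grid$shape[3] / 2)
  arr <- array(vals, dim = grid$shape)
  df <- expand.grid(x = seq_len(grid$shape[1]), y = seq_len(grid$shape[2]))
  df$value <- as.vector(arr[, , z])
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = legend) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("slice z = ", z),
                  x = "voxel x", y = "voxel y") +
    ggplot2::theme_minimal()
}

#' @describeIn check_collinearity Heatmap of the Spearman correlation
#'   matrix.
#' @param object A `collinearity_report`.
#' @export
autoplot.collinearity_report <- function(object, ...) {
  rs <- object$spearman
  df <- expand.grid(covariate_1 = rownames(rs), covariate_2 = colnames(rs))
  df$spearman <- as.vector(rs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$covariate_1,
                                   y = .data$covariate_2,
                                   fill = .data$spearman)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f", .data$spearman))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Covariate Spearman correlations") +
    ggplot2::theme_minimal()
}

#' @describeIn regional_means Heatmap of regional covariate importance
#'   (regions ordered by the clustering leaf order when one is supplied).
#' @param object A `regional_importance` tibble.
#' @param clustering Optional `region_clustering` supplying the row order.
#' @param ... Unused.
#' @export
autoplot.regional_importance <- function(object, clustering = NULL, ...) {
  covs <- setdiff(colnames(object),
                  c("label", "name", "n_voxels", "dominant", "tie"))
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("name", covs)],
    dplyr::all_of(covs),
    names_to = "covariate", values_to = "importance")
  lev <- if (!is.null(clustering)) {
    clustering$hclust$labels[clustering$hclust$order]
  } else {
    object$name
  }
  long$name <- factor(long$name, levels = lev)
  long$covariate <- factor(long$covariate, levels = covs)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$covariate, y = .data$name,
                                     fill = .data$importance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1),
                                  name = "mean\nimportance") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Regional covariate importance") +
    ggplot2::theme_minimal()
}

#' @describeIn cluster_regions Dendrogram of the region clustering.
#' @param object A `region_clustering`.
#' @export
autoplot.region_clustering <- function(object, ...) {
  seg <- dendrogram_segments(object$hclust)
  labs <- tibble(
    x = seq_along(object$hclust$order),
    label = object$hclust$labels[object$hclust$order]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = labs$x, labels = labs$label) +
    ggplot2::labs(x = NULL, y = paste0("height (", object$distance, ", ",
                                       object$linkage, " linkage)"),
                  title = "Region clustering") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

# Segment coordinates for a base-R hclust dendrogram: each merge draws an
# inverted U between its two children.
dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  pos <- numeric(n)                     # leaf x-positions
  pos[hc$order] <- seq_len(n)
  cx <- numeric(nrow(hc$merge))         # x-centre of each merged cluster
  ch <- numeric(nrow(hc$merge))         # height of each merged cluster
  segs <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    x <- numeric(2)
    y <- numeric(2)
    for (j in 1:2) {
      child <- hc$merge[m, j]
      if (child < 0) {
        x[j] <- pos[-child]
        y[j] <- 0
      } else {
        x[j] <- cx[child]
        y[j] <- ch[child]
      }
    }
    h <- hc$height[m]
    segs[[m]] <- tibble(
      x = c(x[1], x[2], x[1]),
      y = c(y[1], y[2], h),
      xend = c(x[1], x[2], x[2]),
      yend = c(h, h, h)
    )
    cx[m] <- mean(x)
    ch[m] <- h
  }
  dplyr::bind_rows(segs)
}
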