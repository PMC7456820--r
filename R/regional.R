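#' Mean covariate importance per atlas region
#'
#' Averages each covariate's normalized importance over the voxels where an
#' atlas region intersects the surviving mask. Regions with zero overlap are
#' omitted; the overlap voxel count per region is recorded, because small
#' isolated overlaps can bias the clustering and are filtered out later
#' (see [overlap_filter()]).
#'
#' @param maps An `importance_maps` object.
#' @param parc A `parcellation` on the same grid.
#' @return A `regional_importance` tibble: `label`, `name`, `n_voxels`
#'   (overlap with the surviving mask), one column per covariate (mean
#'   normalized importance in \[0, 1\]).
#' @export
regional_means <- function(maps, parc) {
  stopifnot(inherits(maps, "importance_maps"), inherits(parc, "parcellation"))
  if (!grids_equal(maps$grid, parc$grid)) {
    abort("Parcellation grid does not match the importance-map grid.")
  }
  labs <- parc$labels[maps$voxels]
  keep <- labs != 0L
  labs <- labs[keep]
  imp <- maps$normalized[keep, , drop = FALSE]
  covs <- colnames(imp)
  if (!length(labs)) {
    out <- tibble(label = integer(0), name = character(0),
                  n_voxels = integer(0))
    for (cv in covs) out[[cv]] <- numeric(0)
  } else {
    counts <- table(labs)
    means <- rowsum(imp, labs) / as.vector(counts)
    lab_ids <- as.integer(rownames(means))
    out <- tibble(
      label = lab_ids,
      name = parc$names$name[match(lab_ids, parc$names$label)],
      n_voxels = as.integer(counts)
    )
    for (j in seq_along(covs)) out[[covs[j]]] <- unname(means[, j])
  }
  class(out) <- c("regional_importance", class(tibble()))
  out
}

#' Filter regions by overlap with the surviving mask
#'
#' In absolute mode, keeps regions whose overlap voxel count is at least
#' `value`. In percentile mode (the default, mirroring the common
#' 50th-percentile convention), computes the given percentile of the overlap
#' distribution across regions (linear interpolation between order
#' statistics) and keeps regions at or above it. Absolute-mode filtering is
#' idempotent.
#'
#' @param table A `regional_importance` tibble.
#' @param mode `"percentile"` (default) or `"absolute"`.
#' @param value Percentile in \[0, 100\] (default 50) or absolute voxel
#'   count.
#' @return The filtered `regional_importance` tibble.
#' @export
overlap_filter <- function(table, mode = c("percentile", "absolute"),
                           value = 50) {
  mode <- match.arg(mode)
  if (!nrow(table)) abort("Cannot filter an empty regional table.")
  cutoff <- switch(mode,
    absolute = value,
    percentile = quantile(table$n_voxels, value / 100, type = 7,
                          names = FALSE)
  )
  out <- table[table$n_voxels >= cutoff, , drop = FALSE]
  if (!nrow(out)) {
    warn("Overlap filter removed every region; clustering will be skipped.")
  }
  attr(out, "overlap_cutoff") <- cutoff
  class(out) <- c("regional_importance", class(tibble()))
  out
}

#' Hierarchically cluster regions by their importance profiles
#'
#' Agglomerative clustering of the region rows (one covariate-importance
#' vector per region) with Euclidean distance and average linkage by
#' default. Unlike flat clustering, the dendrogram gives a structural
#' grouping of regions; regions dominated by the same covariate merge early.
#'
#' @param table A `regional_importance` tibble with >= 2 rows.
#' @param covariates Columns to cluster on; default: every column after
#'   `n_voxels`.
#' @param linkage `"average"` (default), `"complete"`, `"single"`, or
#'   `"ward.D2"`.
#' @param distance Distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @return A `region_clustering`: `hclust` (the [stats::hclust()] tree with
#'   region names as labels), `table`, `linkage`, `distance`.
#' @export
cluster_regions <- function(table, covariates = NULL, linkage = "average",
                            distance = "euclidean") {
  if (nrow(table) < 2L) {
    abort("At least 2 regions are required for clustering.")
  }
  if (is.null(covariates)) {
    covariates <- setdiff(colnames(table),
                          c("label", "name", "n_voxels", "dominant", "tie"))
  }
  X <- as.matrix(as.data.frame(table)[, covariates, drop = FALSE])
  rownames(X) <- table$name
  hc <- hclust(dist(X, method = distance), method = linkage)
  structure(list(hclust = hc, table = table, covariates = covariates,
                 linkage = linkage, distance = distance),
            class = "region_clustering")
}

#' @export
print.region_clustering <- function(x, ...) {
  cat("<region_clustering> ", nrow(x$table), " regions, ", x$distance,
      " distance, ", x$linkage, " linkage\n", sep = "")
  invisible(x)
}

#' @describeIn cluster_regions One row per merge: heights and cluster sizes.
#' @param x A `region_clustering`.
#' @param ... Unused.
#' @export
tidy.region_clustering <- function(x, ...) {
  hc <- x$hclust
  sizes <- integer(nrow(hc$merge))
  size_of <- function(v) {
    if (v < 0) 1L else sizes[v]
  }
  for (m in seq_len(nrow(hc$merge))) {
    sizes[m] <- size_of(hc$merge[m, 1]) + size_of(hc$merge[m, 2])
  }
  tibble(
    merge = seq_len(nrow(hc$merge)),
    child_1 = hc$merge[, 1], child_2 = hc$merge[, 2],
    height = hc$height, size = sizes
  )
}

#' Dominant covariate per region
#'
#' For each region, the covariate with the largest mean normalized
#' importance. Ties are broken by the fixed covariate column order (age
#' before volume before follow-up, under the default design) and flagged.
#'
#' @param table A `regional_importance` tibble.
#' @param covariates Columns to compare; default: every column after
#'   `n_voxels`.
#' @return The table with added columns `dominant` (covariate name) and
#'   `tie` (logical).
#' @export
dominant_covariate <- function(table, covariates = NULL) {
  if (!nrow(table)) abort("Empty regional table.")
  if (is.null(covariates)) {
    covariates <- setdiff(colnames(table),
                          c("label", "name", "n_voxels", "dominant", "tie"))
  }
  X <- as.matrix(as.data.frame(table)[, covariates, drop = FALSE])
  best <- apply(X, 1, which.max)          # first maximum wins ties
  is_tie <- apply(X, 1, function(v) sum(v == max(v)) > 1L)
  out <- table
  out$dominant <- covariates[best]
  out$tie <- as.logical(is_tie)
  class(out) <- c("regional_importance", class(tibble()))
  out
}

#' Write the regional importance table and linkage to disk
#'
#' @param table A `regional_importance` tibble (ideally after
#'   [dominant_covariate()]).
#' @param clustering Optional `region_clustering`.
#' @param dir Output directory.
#' @return Invisibly, the file paths written.
#' @export
write_regional_results <- function(table, clustering = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_table <- file.path(dir, "regional_importance.csv")
  readr::write_csv(as_tibble(table), p_table)
  paths <- p_table
  if (!is.null(clustering)) {
    p_link <- file.path(dir, "regional_linkage.csv")
    readr::write_csv(tidy(clustering), p_link)
    p_meta <- file.path(dir, "regional_clustering.json")
    jsonlite::write_json(list(
      linkage = clustering$linkage, distance = clustering$distance,
      covariates = clustering$covariates,
      leaf_order = clustering$hclust$labels[clustering$hclust$order]
    ), p_meta, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p_link, p_meta)
  }
  invisible(paths)
}
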