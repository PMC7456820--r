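#' Standardized-beta covariate importance maps
#'
#' Converts the fitted per-voxel covariate coefficients into importance
#' maps on the surviving (permutation-corrected) voxels. The default
#' standardization normalizes the raw coefficient by the covariate's sample
#' variance and the voxel's residual mean squared error,
#'
#'   bs_ij = b_ij * sqrt( var(x_j) / MSE_i ),
#'
#' so coefficients of covariates measured in different units become
#' comparable at each voxel. The fully classical alternative
#' bs_ij = b_ij * sd(x_j) / sd(S) is available via
#' `convention = "classical"`; the convention used is recorded in the
#' result. Each covariate's map is then linearly normalized to \[0, 1\]
#' (min-max over surviving voxels, on |bs| — importance is a magnitude
#' concept; the signed raw maps are kept alongside). Voxels with MSE = 0
#' (perfect fit, standardization undefined) are excluded with a logged
#' count.
#'
#' @param fit A `voxel_fit`.
#' @param surviving Logical vector over the grid (e.g. the `surviving` slot
#'   of a thresholded [lesion_t_map()]), a subset of the fit's testable
#'   mask. An `eloquence_map` with its threshold applied is also accepted.
#' @param convention `"covariate_variance"` (default) or `"classical"`.
#' @return An `importance_maps` object: `grid`, `surviving`, `voxels`,
#'   `raw` (Vs x k signed standardized betas), `normalized` (Vs x k in
#'   \[0, 1\]), `bounds` (tibble: covariate, min, max of |bs|),
#'   `convention`.
#' @export
standardized_betas <- function(fit, surviving,
                               convention = c("covariate_variance",
                                              "classical")) {
  stopifnot(inherits(fit, "voxel_fit"))
  convention <- match.arg(convention)
  if (inherits(surviving, "eloquence_map")) surviving <- surviving$surviving
  surviving <- as.logical(surviving)
  if (length(surviving) != n_voxels(fit$grid)) {
    abort("`surviving` must cover the whole grid.")
  }
  if (any(surviving & !fit$testable)) {
    abort("`surviving` must be a subset of the fit's testable mask.")
  }
  covs <- names(fit$covariate_variances)
  if (!length(covs)) abort("The fit has no covariates to standardize.")
  sel <- match(which(surviving), fit$voxels)
  mse <- fit$mse[sel]
  keep <- mse > 0
  if (any(!keep)) {
    inform(sprintf("Excluded %d voxel(s) with zero residual MSE.", sum(!keep)))
    surviving[which(surviving)[!keep]] <- FALSE
    sel <- sel[keep]
    mse <- mse[keep]
  }
  beta <- fit$coefficients[sel, covs, drop = FALSE]
  raw <- switch(convention,
    covariate_variance =
      beta * sqrt(outer(1 / mse, fit$covariate_variances)),
    classical =
      sweep(beta, 2, sqrt(fit$covariate_variances), `*`) /
        sqrt(fit$outcome_variance)
  )
  normalized <- raw
  bounds <- tibble(covariate = covs, min = NA_real_, max = NA_real_)
  for (j in seq_along(covs)) {
    if (nrow(raw)) {
      rng <- range(abs(raw[, j]))
      bounds$min[j] <- rng[1]
      bounds$max[j] <- rng[2]
      normalized[, j] <- normalize_map(raw[, j])
    }
  }
  structure(list(
    grid = fit$grid, surviving = surviving, voxels = which(surviving),
    raw = raw, normalized = normalized, bounds = bounds,
    convention = convention
  ), class = "importance_maps")
}

#' Min-max normalize a map to \[0, 1\]
#'
#' Takes |v| first (importance is a magnitude), then maps the observed range
#' linearly onto \[0, 1\]. A degenerate range (all values equal) yields all
#' zeros with a warning.
#'
#' @param values Finite numeric vector (the map restricted to its mask).
#' @param use_abs Take absolute values first (default TRUE).
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' normalize_map(c(2, 4, 6))    # 0, 0.5, 1
#' normalize_map(c(-6, 2, 4))   # 1, 0, 0.5
normalize_map <- function(values, use_abs = TRUE) {
  if (!length(values)) abort("Cannot normalize an empty map.")
  if (any(!is.finite(values))) abort("Map values must be finite.")
  v <- if (use_abs) abs(values) else values
  rng <- range(v)
  if (rng[2] - rng[1] <= 0) {
    warn("Degenerate map range (all values equal): normalized map is all zeros.")
    return(rep(0, length(v)))
  }
  (v - rng[1]) / (rng[2] - rng[1])
}

#' @export
print.importance_maps <- function(x, ...) {
  cat("<importance_maps> ", nrow(x$raw), " surviving voxels x ",
      ncol(x$raw), " covariates (", x$convention, " standardization)\n",
      sep = "")
  invisible(x)
}

#' @describeIn standardized_betas One row per surviving voxel and covariate,
#'   with raw and normalized importance.
#' @param x An `importance_maps` object.
#' @param ... Unused.
#' @export
tidy.importance_maps <- function(x, ...) {
  covs <- colnames(x$raw)
  purrr::map_dfr(seq_along(covs), function(j) {
    tibble(voxel = x$voxels, covariate = covs[j],
           standardized_beta = x$raw[, j], importance = x$normalized[, j])
  })
}

#' Write importance maps (raw + normalized) and metadata to disk
#'
#' One raw and one normalized NIfTI per covariate, the surviving mask, and a
#' JSON of the normalization bounds and standardization convention.
#'
#' @param maps An `importance_maps` object.
#' @param dir Output directory.
#' @return Invisibly, the vector of file paths written.
#' @export
write_importance_maps <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  covs <- colnames(maps$raw)
  safe <- gsub("[^A-Za-z0-9_]+", "_", covs)
  paths <- character(0)
  for (j in seq_along(covs)) {
    p_raw <- file.path(dir, paste0("importance_raw_", safe[j], ".nii.gz"))
    p_norm <- file.path(dir, paste0("importance_norm_", safe[j], ".nii.gz"))
    write_statistic_map(maps$raw[, j], maps$grid, p_raw,
                        mask = maps$surviving, mask_path = NULL)
    write_statistic_map(maps$normalized[, j], maps$grid, p_norm,
                        mask = maps$surviving, mask_path = NULL)
    paths <- c(paths, p_raw, p_norm)
  }
  p_mask <- file.path(dir, "surviving_mask.nii.gz")
  write_volume(array(as.integer(maps$surviving), dim = maps$grid$shape),
               maps$grid, p_mask, datatype = "uint8")
  p_meta <- file.path(dir, "importance_metadata.json")
  jsonlite::write_json(list(
    convention = maps$convention,
    bounds = maps$bounds,
    n_surviving = length(maps$voxels)
  ), p_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, p_mask, p_meta))
}
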