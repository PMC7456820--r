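#' Write a per-voxel statistic map as a NIfTI-1 volume
#'
#' Background voxels (outside `mask`) are filled with 0. Because 0 is a valid
#' statistic value, validity is defined by the mask, not the fill: the mask is
#' written alongside as a companion binary volume unless `mask_path = NULL`.
#' Values are stored as float32, so a round-trip read reproduces them to
#' float32 precision.
#'
#' @param values Numeric vector of statistic values. Either length
#'   `prod(grid$shape)` (a full map) or `sum(mask)` (values on the mask, in
#'   mask order).
#' @param grid A `voxel_grid`.
#' @param path Output path (.nii or .nii.gz).
#' @param mask Logical/0-1 vector of length `prod(grid$shape)` marking valid
#'   voxels; `NULL` (default) treats every voxel as valid.
#' @param mask_path Path for the companion mask volume; defaults to
#'   `<path>_mask.nii.gz` when a mask is given. `NULL` suppresses it.
#'
#' @return `path`, invisibly.
#' @export
write_statistic_map <- function(values, grid, path, mask = NULL,
                                mask_path = if (!is.null(mask))
                                  default_mask_path(path)) {
  V <- n_voxels(grid)
  if (is.null(mask)) {
    if (length(values) != V) {
      abort(sprintf("Expected %d values for a full map, got %d.",
                    V, length(values)))
    }
    full <- as.numeric(values)
  } else {
    mask <- as.logical(mask)
    if (length(mask) != V) {
      abort(sprintf("Mask length %d does not match grid voxel count %d.",
                    length(mask), V))
    }
    if (length(values) == V) {
      full <- as.numeric(values)
      full[!mask] <- 0
    } else if (length(values) == sum(mask)) {
      full <- numeric(V)
      full[mask] <- as.numeric(values)
    } else {
      abort(sprintf(
        "Expected %d (grid) or %d (mask) values, got %d.",
        V, sum(mask), length(values)))
    }
    if (sum(mask) == 0L) warn("Empty mask: writing an all-background volume.")
  }
  if (!all(is.finite(full))) abort("Statistic values must be finite.")
  write_volume(array(full, dim = grid$shape), grid, path)
  if (!is.null(mask) && !is.null(mask_path)) {
    write_volume(array(as.integer(mask), dim = grid$shape), grid, mask_path)
  }
  invisible(path)
}

default_mask_path <- function(path) {
  sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
}

# Low-level NIfTI writer: attaches the grid affine (qform and sform, code 2).
write_volume <- function(arr, grid, path, datatype = "float") {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$voxel_size
  aff <- structure(grid$affine, code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# Read a NIfTI volume and its grid.
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  grid <- voxel_grid(dim(img)[1:3], affine = unclass(RNifti::xform(img)))
  list(data = as.array(img), grid = grid)
}

#' Atlas parcellation container
#'
#' An integer-labelled volume assigning voxels to named regions; label 0 is
#' background and never named.
#'
#' @param grid A `voxel_grid`.
#' @param labels Integer vector/array of length `prod(grid$shape)`.
#' @param names Data frame with columns `label` (integer, nonzero) and `name`
#'   (character) covering every nonzero label present in `labels`.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(grid, labels, names) {
  stopifnot(inherits(grid, "voxel_grid"))
  labels <- as.integer(labels)
  if (length(labels) != n_voxels(grid)) {
    abort("Label volume does not match the grid voxel count.")
  }
  names <- as_tibble(names)
  if (!all(c("label", "name") %in% colnames(names))) {
    abort("`names` needs columns `label` and `name`.")
  }
  names$label <- as.integer(names$label)
  if (any(names$label == 0L)) abort("Label 0 is background and cannot be named.")
  present <- setdiff(unique(labels), 0L)
  unnamed <- setdiff(present, names$label)
  if (length(unnamed)) {
    abort(paste0("Unnamed parcellation label(s): ",
                 paste(sort(unnamed), collapse = ", ")))
  }
  structure(list(grid = grid, labels = labels,
                 names = names[names$label %in% present, ]),
            class = "parcellation")
}

#' Load a parcellation volume and its label lookup table
#'
#' @param path NIfTI path of the integer-labelled atlas volume.
#' @param lookup_path Two-column delimited file (label, name); a header line
#'   is detected automatically.
#' @param delim Delimiter for the lookup table; `NULL` auto-detects.
#' @return A `parcellation`.
#' @export
load_parcellation <- function(path, lookup_path, delim = NULL) {
  vol <- read_volume(path)
  if (is.null(delim)) {
    header <- readLines(lookup_path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  first <- strsplit(readLines(lookup_path, n = 1L), delim, fixed = TRUE)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[1])))
  lut <- readr::read_delim(lookup_path, delim = delim, col_names = has_header,
                           show_col_types = FALSE, progress = FALSE)
  if (!has_header) colnames(lut)[1:2] <- c("label", "name")
  colnames(lut)[1:2] <- c("label", "name")
  labs <- round(as.numeric(vol$data))
  if (max(abs(as.numeric(vol$data) - labs)) > 1e-6) {
    abort("Parcellation volume is not integer-labelled.")
  }
  parcellation(vol$grid, labs, lut[, c("label", "name")])
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation> ", nrow(x$names), " named regions on a ",
      paste(x$grid$shape, collapse = " x "), " grid\n", sep = "")
  invisible(x)
}
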