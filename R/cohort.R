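#' Lesion cohort container
#'
#' Stacks co-registered binary lesion masks into a voxels x subjects matrix
#' over a common [voxel_grid()]. Column n holds subject n's mask flattened in
#' array (column-major) order; entry 1 means the voxel is lesioned.
#'
#' @param grid A `voxel_grid`.
#' @param lesions Integer/numeric matrix, `prod(grid$shape)` rows by N
#'   subjects, entries in {0, 1}.
#' @param subject_ids Character vector of N unique subject identifiers.
#'
#' @return An object of class `lesion_cohort` with elements `grid`,
#'   `subject_ids` and `lesions` (integer matrix V x N).
#' @export
lesion_cohort <- function(grid, lesions, subject_ids) {
  stopifnot(inherits(grid, "voxel_grid"))
  lesions <- as.matrix(lesions)
  storage.mode(lesions) <- "integer"
  V <- n_voxels(grid)
  if (nrow(lesions) != V) {
    abort(sprintf("`lesions` has %d rows but the grid has %d voxels.",
                  nrow(lesions), V))
  }
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != ncol(lesions)) {
    abort("One subject ID per lesion column is required.")
  }
  if (anyDuplicated(subject_ids)) {
    abort("Subject IDs must be unique.")
  }
  if (!all(lesions %in% c(0L, 1L))) {
    abort("Lesion matrix entries must all be 0 or 1.")
  }
  cs <- colSums(lesions)
  if (any(cs == 0L)) {
    abort(paste0("Empty lesion mask (all zeros) for subject(s): ",
                 paste(subject_ids[cs == 0L], collapse = ", ")))
  }
  if (any(cs == V)) {
    abort(paste0("Lesion covers every voxel for subject(s): ",
                 paste(subject_ids[cs == V], collapse = ", ")))
  }
  colnames(lesions) <- subject_ids
  structure(
    list(grid = grid, subject_ids = subject_ids, lesions = lesions),
    class = "lesion_cohort"
  )
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat("<lesion_cohort> ", length(x$subject_ids), " subjects on a ",
      paste(x$grid$shape, collapse = " x "), " grid\n", sep = "")
  cs <- colSums(x$lesions)
  cat("  lesion voxels per subject: median ", stats::median(cs),
      " [", min(cs), ", ", max(cs), "]\n", sep = "")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A `lesion_cohort`.
#' @return Integer.
#' @export
n_subjects <- function(cohort) length(cohort$subject_ids)

#' Load binary lesion masks into a cohort
#'
#' Reads one NIfTI-1 volume per subject, checks that all volumes share the
#' first volume's grid (shape exactly; affine within `affine_tol`), binarizes
#' values (any nonzero voxel counts as lesioned — masks may arrive as
#' probabilistic or label volumes), and stacks them into a [lesion_cohort()].
#' Column order follows the order of `paths`.
#'
#' @param paths Character vector of NIfTI file paths (.nii or .nii.gz).
#' @param ids Character vector of subject IDs, same length as `paths`.
#' @param affine_tol Element-wise affine agreement tolerance (default 1e-4).
#' @param quiet Suppress the per-subject lesion-count log (default FALSE).
#'
#' @return A `lesion_cohort`.
#' @export
load_lesion_masks <- function(paths, ids, affine_tol = 1e-4, quiet = FALSE) {
  if (length(paths) != length(ids)) {
    abort("`paths` and `ids` must have the same length.")
  }
  if (length(paths) == 0L) abort("At least one mask path is required.")
  grid <- NULL
  cols <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    img <- RNifti::readNifti(paths[[k]])
    g <- voxel_grid(dim(img)[1:3], affine = unclass(RNifti::xform(img)))
    if (is.null(grid)) {
      grid <- g
    } else if (!grids_equal(grid, g, tol = affine_tol)) {
      abort(sprintf(
        "Grid mismatch: '%s' (subject %s) does not share the grid of '%s'.",
        paths[[k]], ids[[k]], paths[[1]]))
    }
    cols[[k]] <- as.integer(as.array(img) != 0)
  }
  lesions <- do.call(cbind, cols)
  cohort <- lesion_cohort(grid, lesions, ids)
  if (!quiet) {
    cs <- colSums(cohort$lesions)
    inform(paste0("Loaded ", length(ids), " lesion masks; voxel counts: ",
                  paste(paste0(ids, "=", cs), collapse = ", ")))
  }
  cohort
}

#' Per-subject lesion volume in cubic centimetres
#'
#' Volume is the set-voxel count times the voxel volume from the grid affine,
#' divided by 1000 (mm^3 to cm^3).
#'
#' @param cohort A `lesion_cohort`.
#' @return A tibble with columns `subject_id`, `n_voxels`, `volume_cm3`.
#' @export
compute_lesion_volume <- function(cohort) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  nv <- unname(colSums(cohort$lesions))
  tibble(
    subject_id = cohort$subject_ids,
    n_voxels = as.integer(nv),
    volume_cm3 = nv * voxel_volume_cm3(cohort$grid)
  )
}

#' Load the per-subject covariate/outcome table
#'
#' Reads a delimited table (delimiter auto-detected from the header line, or
#' set explicitly), maps its columns onto the four required fields, validates
#' them, and reorders rows to match the cohort's subject order. Subjects with
#' any missing field are rejected. Outcome values outside the NIHSS 0-42
#' integer range raise a warning, not an error: other outcome scales (e.g.
#' mRS) are legitimate.
#'
#' @param path Path to a CSV/TSV file.
#' @param subject_ids Character vector giving the required row order
#'   (typically `cohort$subject_ids`).
#' @param id_column Name of the subject-ID column (default "subject_id").
#' @param columns Named character vector mapping the canonical fields `age`,
#'   `lesion_volume`, `followup_time`, `outcome` to column names in the file.
#' @param delim Field delimiter; `NULL` (default) auto-detects comma vs tab.
#' @param check_nihss_range Warn when outcomes leave the 0-42 integer NIHSS
#'   range (default TRUE).
#'
#' @return A `covariate_table`: a tibble with columns `subject_id`, `age`,
#'   `lesion_volume`, `followup_time`, `outcome`, rows in `subject_ids` order.
#' @export
load_covariates <- function(path, subject_ids,
                            id_column = "subject_id",
                            columns = c(age = "age",
                                        lesion_volume = "lesion_volume",
                                        followup_time = "followup_time",
                                        outcome = "outcome"),
                            delim = NULL,
                            check_nihss_range = TRUE) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c(age = "age", lesion_volume = "lesion_volume",
                followup_time = "followup_time", outcome = "outcome")
  columns <- utils::modifyList(as.list(required), as.list(columns))
  need <- c(id_column, unlist(columns))
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Covariate table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab <- tibble(
    subject_id = as.character(raw[[id_column]]),
    age = raw[[columns$age]],
    lesion_volume = raw[[columns$lesion_volume]],
    followup_time = raw[[columns$followup_time]],
    outcome = raw[[columns$outcome]]
  )
  if (anyDuplicated(tab$subject_id)) {
    abort("Duplicate subject IDs in the covariate table.")
  }
  for (col in c("age", "lesion_volume", "followup_time", "outcome")) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      abort(sprintf("Non-numeric value in column '%s' (row %d).",
                    columns[[col]] %||% col, bad %||% 1L))
    }
    if (anyNA(v)) {
      abort(sprintf("Missing value(s) in column '%s' for subject(s): %s",
                    col, paste(tab$subject_id[is.na(v)], collapse = ", ")))
    }
  }
  covariate_table(tab, subject_ids = subject_ids,
                  check_nihss_range = check_nihss_range)
}

#' Construct/validate a covariate table
#'
#' @param data A data frame with columns `subject_id`, `age`,
#'   `lesion_volume`, `followup_time`, `outcome`.
#' @param subject_ids Optional required row order; rows are reordered to it
#'   and an error names any cohort subject missing from the table.
#' @param check_nihss_range Warn on outcomes outside integer 0-42.
#' @return A `covariate_table` tibble.
#' @export
covariate_table <- function(data, subject_ids = NULL,
                            check_nihss_range = TRUE) {
  data <- as_tibble(data)
  need <- c("subject_id", "age", "lesion_volume", "followup_time", "outcome")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  data$subject_id <- as.character(data$subject_id)
  if (!is.null(subject_ids)) {
    missing_ids <- setdiff(subject_ids, data$subject_id)
    if (length(missing_ids)) {
      abort(paste0("Covariate table is missing cohort subject(s): ",
                   paste(missing_ids, collapse = ", ")))
    }
    data <- data[match(subject_ids, data$subject_id), , drop = FALSE]
  }
  if (any(data$age <= 0)) {
    abort("`age` must be positive (years).")
  }
  if (any(data$lesion_volume < 0)) {
    abort("`lesion_volume` must be non-negative (cm^3).")
  }
  if (any(data$followup_time <= 0)) {
    abort("`followup_time` must be positive (hours).")
  }
  if (check_nihss_range) {
    off <- data$outcome < 0 | data$outcome > 42 |
      abs(data$outcome - round(data$outcome)) > 1e-8
    if (any(off)) {
      warn(sprintf(
        "%d outcome value(s) outside the integer NIHSS 0-42 range (kept; set check_nihss_range = FALSE if using another scale).",
        sum(off)))
    }
  }
  class(data) <- c("covariate_table", class(tibble()))
  data
}
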