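#' Specify a synthetic stroke cohort simulation
#'
#' Defines the generative model for a simulated cohort of middle-cerebral-
#' artery-like stroke patients with known ground truth. Lesions are grown as
#' single 6-connected blobs inside a vascular "territory" mask, with target
#' sizes drawn log-normally (heavy-tailed, like real infarct volumes).
#' Covariates are mutually independent: age ~ Normal(68.6, 12.6^2) years
#' truncated at 0 by resampling, follow-up imaging time ~ Uniform(18, 168)
#' hours (the 18 h - 7 d follow-up window typical of acute stroke imaging
#' studies), and lesion volume is computed from the realized mask. The
#' outcome (NIHSS-like score) is
#'
#'   S_n = sum_r frac_rn * (gamma_r + sum_j m_rj * z_jn)
#'         + b_age*age_n + b_vol*vol_n + b_fup*fup_n + eps_n
#'
#' where `frac_rn` is the fraction of eloquent region r's voxels lesioned in
#' subject n (partial hits yield partial deficits), `gamma_r` the region's
#' lesion effect, `m_rj` an optional per-region covariate modulation applied
#' to the spec-standardized covariate `z_jn`, and eps ~ Normal(0, noise_sd^2).
#'
#' @param grid A `voxel_grid` (default 24^3 voxels at 3 mm, so a median
#'   lesion of ~1500 voxels is ~40 cm^3, the scale seen in MCA stroke).
#' @param n_subjects Number of subjects (>= 2; default 222).
#' @param territory Logical/0-1 vector over the grid marking where lesions
#'   may occur; default: the interior box two voxels in from each face.
#' @param regions List of eloquent regions, each a list with elements
#'   `voxels` (integer indices into the flattened grid, inside the
#'   territory), `gamma` (lesion effect on the outcome for a full hit), and
#'   optionally `modulation` (named numeric over covariates `age`,
#'   `lesion_volume`, `followup_time`; default all 0) and `name`.
#' @param effects Named numeric: global covariate effects `age` (outcome
#'   points per year), `lesion_volume` (per cm^3), `followup_time` (per
#'   hour).
#' @param age_mean,age_sd Age distribution parameters (years).
#' @param followup_min,followup_max Follow-up window (hours).
#' @param size_meanlog,size_sdlog Log-normal target lesion size (voxels);
#'   draws are clamped to [1, 0.9 * territory size].
#' @param noise_sd Outcome noise standard deviation (NIHSS points).
#' @param seed Integer seed; mandatory, so every cohort is reproducible.
#'
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(grid = voxel_grid(c(24, 24, 24),
                                              voxel_size = c(3, 3, 3)),
                            n_subjects = 222,
                            territory = NULL,
                            regions = default_regions(grid, territory),
                            effects = c(age = 0.05, lesion_volume = 0.08,
                                        followup_time = 0.01),
                            age_mean = 68.6, age_sd = 12.6,
                            followup_min = 18, followup_max = 168,
                            size_meanlog = log(0.18 * sum(as.logical(
                              territory %||% default_territory(grid)))),
                            size_sdlog = 0.6,
                            noise_sd = 4,
                            seed) {
  if (missing(seed) || is.null(seed)) {
    abort("An explicit integer `seed` is required for reproducibility.")
  }
  if (is.null(territory)) territory <- default_territory(grid)
  territory <- as.logical(territory)
  if (length(territory) != n_voxels(grid)) {
    abort("`territory` must cover the whole grid.")
  }
  if (!any(territory)) abort("Territory mask is empty.")
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) abort("`n_subjects` must be at least 2.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (followup_max <= followup_min || followup_min <= 0) {
    abort("Follow-up window must satisfy 0 < min < max.")
  }
  covs <- c("age", "lesion_volume", "followup_time")
  eff <- setNames(numeric(3), covs)
  eff[names(effects)] <- effects
  regions <- lapply(seq_along(regions), function(r) {
    reg <- regions[[r]]
    reg$voxels <- as.integer(reg$voxels)
    if (!all(territory[reg$voxels])) {
      abort(sprintf("Region %d extends outside the territory mask.", r))
    }
    m <- setNames(numeric(3), covs)
    if (!is.null(reg$modulation)) m[names(reg$modulation)] <- reg$modulation
    reg$modulation <- m
    reg$gamma <- as.numeric(reg$gamma %||% 0)
    reg$name <- reg$name %||% paste0("region_", r)
    reg
  })
  if (exp(size_meanlog) > sum(territory)) {
    abort("Lesion-size distribution is incompatible with the territory size (median target exceeds the territory).")
  }
  structure(list(
    grid = grid, n_subjects = n_subjects, territory = territory,
    regions = regions, effects = eff,
    age_mean = age_mean, age_sd = age_sd,
    followup_min = followup_min, followup_max = followup_max,
    size_meanlog = size_meanlog, size_sdlog = size_sdlog,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "simulation_spec")
}

default_territory <- function(grid) {
  sh <- grid$shape
  margin <- pmin(2L, pmax(0L, (sh - 1L) %/% 3L))
  in_box <- function(i, n, m) i > m & i <= n - m
  idx <- arrayInd(seq_len(prod(sh)), sh)
  in_box(idx[, 1], sh[1], margin[1]) &
    in_box(idx[, 2], sh[2], margin[2]) &
    in_box(idx[, 3], sh[3], margin[3])
}

default_regions <- function(grid, territory = NULL) {
  if (is.null(territory)) territory <- default_territory(grid)
  inside <- which(as.logical(territory))
  k <- min(3L, length(inside))
  # three compact boxes spread along the first axis, each an eloquent region
  idx <- arrayInd(inside, grid$shape)
  thirds <- cut(rank(idx[, 1], ties.method = "first"), k, labels = FALSE)
  lapply(seq_len(k), function(r) {
    vox <- inside[thirds == r]
    list(voxels = head(vox[order(vox)], max(8L, length(vox) %/% 10L)),
         gamma = c(8, 6, 4)[r], name = paste0("eloquent_", r))
  })
}

# Deterministic per-subject sub-seed below 2^31.
subseed <- function(seed, k, salt = 0L) {
  as.integer((as.double(seed) * 48271 + k * 1009 + salt * 7919) %% 2147483629)
}

# Grow a single 6-connected lesion of ~target voxels inside the territory.
# Frontier-based random region growing: start at a uniform seed voxel, then
# repeatedly lesion a uniformly drawn frontier voxel.
grow_lesion <- function(grid, territory_idx, territory_flag, target, rng_seed) {
  set.seed(rng_seed)
  sh <- grid$shape
  V <- prod(sh)
  target <- max(1L, min(as.integer(target), length(territory_idx)))
  in_lesion <- logical(V)
  start <- territory_idx[sample.int(length(territory_idx), 1L)]
  in_lesion[start] <- TRUE
  frontier <- neighbours6(start, sh)
  frontier <- frontier[territory_flag[frontier]]
  size <- 1L
  while (size < target && length(frontier) > 0L) {
    pick <- sample.int(length(frontier), 1L)
    vox <- frontier[pick]
    frontier <- frontier[-pick]
    if (in_lesion[vox]) next
    in_lesion[vox] <- TRUE
    size <- size + 1L
    nb <- neighbours6(vox, sh)
    nb <- nb[territory_flag[nb] & !in_lesion[nb]]
    frontier <- c(frontier, nb)
  }
  which(in_lesion)
}

# 6-connected neighbours of a flat index on a 3D grid.
neighbours6 <- function(i, sh) {
  xyz <- arrayInd(i, sh)
  x <- xyz[1]; y <- xyz[2]; z <- xyz[3]
  out <- integer(0)
  if (x > 1L)     out <- c(out, i - 1L)
  if (x < sh[1])  out <- c(out, i + 1L)
  if (y > 1L)     out <- c(out, i - sh[1])
  if (y < sh[2])  out <- c(out, i + sh[1])
  sxy <- sh[1] * sh[2]
  if (z > 1L)     out <- c(out, i - sxy)
  if (z < sh[3])  out <- c(out, i + sxy)
  out
}

# Spec-level standardization used by regional covariate modulation: the
# covariates are centred/scaled by their *population* moments so modulation
# terms have mean ~0 and unit scale regardless of the realized sample.
spec_standardize <- function(spec, age, vol, fup) {
  vox_cm3 <- voxel_volume_cm3(spec$grid)
  mu_sz <- exp(spec$size_meanlog + spec$size_sdlog^2 / 2)
  sd_sz <- mu_sz * sqrt(exp(spec$size_sdlog^2) - 1)
  fup_mu <- (spec$followup_min + spec$followup_max) / 2
  fup_sd <- (spec$followup_max - spec$followup_min) / sqrt(12)
  cbind(
    age = (age - spec$age_mean) / spec$age_sd,
    lesion_volume = (vol - mu_sz * vox_cm3) / (sd_sz * vox_cm3),
    followup_time = (fup - fup_mu) / fup_sd
  )
}

#' Simulate a lesion cohort with known ground truth
#'
#' Draws covariates, grows one contiguous lesion per subject, and generates
#' outcomes from the generative model described in [simulation_spec()]. The
#' same spec (including seed) always yields bit-identical results; lesion
#' growth uses a deterministic per-subject sub-stream, so subject k's lesion
#' does not depend on how many subjects precede it.
#'
#' @param spec A `simulation_spec`.
#' @return A list of class `simulated_cohort` with elements `cohort`
#'   (a [lesion_cohort()]), `covariates` (a `covariate_table`), and
#'   `ground_truth` (gamma map, effects, modulations, per-subject region
#'   lesion fractions, standardized covariates, noise draws).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_subjects
  V <- n_voxels(spec$grid)
  territory_idx <- which(spec$territory)

  set.seed(subseed(spec$seed, 0L, salt = 1L))
  age <- rnorm(n, spec$age_mean, spec$age_sd)
  while (any(age <= 0)) {                 # truncate at 0 by resampling
    age[age <= 0] <- rnorm(sum(age <= 0), spec$age_mean, spec$age_sd)
  }
  fup <- runif(n, spec$followup_min, spec$followup_max)
  sizes <- rlnorm(n, spec$size_meanlog, spec$size_sdlog)
  sizes <- pmax(1, pmin(sizes, 0.9 * length(territory_idx)))
  eps <- rnorm(n, 0, spec$noise_sd)

  lesions <- matrix(0L, V, n)
  for (k in seq_len(n)) {
    vox <- grow_lesion(spec$grid, territory_idx, spec$territory,
                       round(sizes[k]), subseed(spec$seed, k, salt = 2L))
    lesions[vox, k] <- 1L
  }
  ids <- sprintf("sub-%03d", seq_len(n))
  cohort <- lesion_cohort(spec$grid, lesions, ids)
  vol <- colSums(lesions) * voxel_volume_cm3(spec$grid)

  nr <- length(spec$regions)
  frac <- matrix(0, n, max(nr, 1))
  z <- spec_standardize(spec, age, vol, fup)
  regional <- numeric(n)
  if (nr > 0) {
    for (r in seq_len(nr)) {
      reg <- spec$regions[[r]]
      frac[, r] <- colSums(lesions[reg$voxels, , drop = FALSE]) /
        length(reg$voxels)
      regional <- regional +
        frac[, r] * (reg$gamma + drop(z %*% reg$modulation))
    }
    colnames(frac) <- vapply(spec$regions, `[[`, "", "name")
  }
  outcome <- regional + spec$effects["age"] * age +
    spec$effects["lesion_volume"] * vol +
    spec$effects["followup_time"] * fup + eps

  gamma_map <- numeric(V)
  for (reg in spec$regions) gamma_map[reg$voxels] <- reg$gamma

  covariates <- covariate_table(
    tibble(subject_id = ids, age = age, lesion_volume = vol,
           followup_time = fup, outcome = as.numeric(outcome)),
    check_nihss_range = FALSE
  )
  structure(list(
    cohort = cohort,
    covariates = covariates,
    ground_truth = list(
      gamma_map = gamma_map,
      effects = spec$effects,
      regions = spec$regions,
      region_fractions = frac,
      standardized_covariates = z,
      noise = eps,
      spec = spec
    )
  ), class = "simulated_cohort")
}

#' Simulate a null cohort (outcome independent of lesions)
#'
#' Identical to [simulate_cohort()] except all regional lesion effects (and
#' modulations) are zeroed, so the outcome depends only on the covariates
#' (optionally also zeroed) and noise. Used to measure family-wise error.
#'
#' @param spec A `simulation_spec`.
#' @param keep_covariate_effects Retain the global covariate effects
#'   (default TRUE); `FALSE` zeroes them, making the outcome pure noise.
#' @return A `simulated_cohort` (see [simulate_cohort()]).
#' @export
null_cohort <- function(spec, keep_covariate_effects = TRUE) {
  stopifnot(inherits(spec, "simulation_spec"))
  spec$regions <- lapply(spec$regions, function(reg) {
    reg$gamma <- 0
    reg$modulation[] <- 0
    reg
  })
  if (!keep_covariate_effects) spec$effects[] <- 0
  simulate_cohort(spec)
}

#' Write a simulated cohort to disk
#'
#' Emits one NIfTI lesion mask per subject, the covariate table as CSV, the
#' ground-truth gamma map as NIfTI, and the ground-truth effects as JSON —
#' the same formats [load_lesion_masks()] and [load_covariates()] read back.
#'
#' @param sim A `simulated_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `mask_paths`, `covariate_path`,
#'   `gamma_path`, `truth_path`.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- sim$cohort$grid
  mask_paths <- file.path(dir, paste0(sim$cohort$subject_ids, "_lesion.nii.gz"))
  for (k in seq_along(mask_paths)) {
    write_volume(array(sim$cohort$lesions[, k], dim = grid$shape),
                 grid, mask_paths[k], datatype = "uint8")
  }
  covariate_path <- file.path(dir, "covariates.csv")
  readr::write_csv(as_tibble(sim$covariates), covariate_path)
  gamma_path <- file.path(dir, "ground_truth_gamma.nii.gz")
  write_volume(array(sim$ground_truth$gamma_map, dim = grid$shape),
               grid, gamma_path)
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    effects = as.list(sim$ground_truth$effects),
    regions = lapply(sim$ground_truth$regions, function(r)
      list(name = r$name, gamma = r$gamma, n_voxels = length(r$voxels),
           modulation = as.list(r$modulation))),
    seed = sim$ground_truth$spec$seed
  ), truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(mask_paths = mask_paths, covariate_path = covariate_path,
                 gamma_path = gamma_path, truth_path = truth_path))
}
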