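# Shared fixtures and independent oracles for the test suite.

# Random but valid lesion cohort on a small grid: every voxel's lesion count
# is left to chance, every subject's mask is nonempty and not full.
random_cohort <- function(n = 20, shape = c(5, 5, 4), p = 0.3, seed = 1,
                          voxel_size = c(1, 1, 1)) {
  set.seed(seed)
  grid <- voxel_grid(shape, voxel_size = voxel_size)
  V <- prod(shape)
  repeat {
    lesions <- matrix(rbinom(V * n, 1, p), V, n)
    cs <- colSums(lesions)
    if (all(cs > 0 & cs < V)) break
  }
  lesion_cohort(grid, lesions, sprintf("s%02d", seq_len(n)))
}

# Covariate table from bare vectors (valid ages/times by construction).
make_table <- function(ids, age = NULL, vol = NULL, fup = NULL,
                       outcome = NULL, seed = 1) {
  set.seed(seed)
  n <- length(ids)
  covariate_table(tibble::tibble(
    subject_id = ids,
    age = age %||% runif(n, 40, 90),
    lesion_volume = vol %||% runif(n, 1, 100),
    followup_time = fup %||% runif(n, 18, 168),
    outcome = outcome %||% rnorm(n, 10, 4)
  ), check_nihss_range = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent OLS oracle: explicit normal equations for one voxel's design
# [Z, l]; returns the lesion coefficient, all coefficients, MSE and the
# lesion t. Deliberately avoids the package's QR/residualization path.
oracle_ols <- function(y, l, Z) {
  X <- cbind(Z, lesion = l)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  mse <- sum(resid^2) / df
  se_l <- sqrt(mse * solve(XtX)[ncol(X), ncol(X)])
  list(beta = drop(beta), lesion_beta = beta[ncol(X)],
       mse = mse, t = beta[ncol(X)] / se_l, df = df)
}

# Pooled-variance two-sample t statistic (textbook formula), lesioned minus
# non-lesioned group mean.
pooled_t <- function(y, l) {
  y1 <- y[l == 1]; y0 <- y[l == 0]
  n1 <- length(y1); n0 <- length(y0)
  sp2 <- ((n1 - 1) * var(y1) + (n0 - 1) * var(y0)) / (n1 + n0 - 2)
  (mean(y1) - mean(y0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

# BFS connected-component check (6-connectivity), independent of the
# simulator's frontier-growing code.
is_single_component <- function(voxels, shape) {
  if (length(voxels) <= 1L) return(TRUE)
  inset <- logical(prod(shape))
  inset[voxels] <- TRUE
  seen <- logical(prod(shape))
  queue <- voxels[1]
  seen[queue] <- TRUE
  sxy <- shape[1] * shape[2]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    xyz <- arrayInd(v, shape)
    nb <- integer(0)
    if (xyz[1] > 1)        nb <- c(nb, v - 1L)
    if (xyz[1] < shape[1]) nb <- c(nb, v + 1L)
    if (xyz[2] > 1)        nb <- c(nb, v - shape[1])
    if (xyz[2] < shape[2]) nb <- c(nb, v + shape[1])
    if (xyz[3] > 1)        nb <- c(nb, v - sxy)
    if (xyz[3] < shape[3]) nb <- c(nb, v + sxy)
    nb <- nb[inset[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  sum(seen) == length(voxels)
}

# Parameter-recovery scenario: one compact eloquent region (8 voxels, at one
# of three slots along the x-axis) whose lesion effect is modulated by one
# covariate, all other covariate effects zero — so exactly that covariate
# drives outcome variance in the region. Lesion sizes are drawn with a
# narrow spread so lesion volume stays decoupled from the region hit
# fraction; otherwise volume proxies for lesion burden at every eloquent
# voxel and the importance maps cannot separate the covariates.
recovery_spec <- function(seed, covariate = "age", region_slot = 1,
                          n_subjects = 250, gamma = 15, modulation = 20,
                          noise_sd = 1) {
  grid <- voxel_grid(c(12, 12, 6))
  idx <- arrayInd(seq_len(prod(grid$shape)), grid$shape)
  territory <- idx[, 1] >= 2 & idx[, 1] <= 11 &
    idx[, 2] >= 2 & idx[, 2] <= 11 &
    idx[, 3] >= 2 & idx[, 3] <= 5
  box <- function(xr) {
    which(territory & idx[, 1] >= xr[1] & idx[, 1] <= xr[2] &
            idx[, 2] %in% 5:6 & idx[, 3] %in% 3:4)
  }
  slots <- list(box(c(2, 3)), box(c(6, 7)), box(c(10, 11)))
  m <- setNames(modulation, covariate)
  simulation_spec(
    grid = grid, n_subjects = n_subjects, territory = territory,
    regions = list(list(voxels = slots[[region_slot]], gamma = gamma,
                        modulation = m, name = "target")),
    effects = c(age = 0, lesion_volume = 0, followup_time = 0),
    size_meanlog = log(40), size_sdlog = 0.08, noise_sd = noise_sd,
    seed = seed
  )
}

# Parcellation splitting the territory into x-axis bands (named regions) —
# gives the regional stage several regions to aggregate and cluster.
territory_parcellation <- function(spec, n_bands = 3) {
  sh <- spec$grid$shape
  idx <- arrayInd(seq_len(prod(sh)), sh)
  labels <- integer(prod(sh))
  terr <- which(spec$territory)
  band <- cut(idx[terr, 1], n_bands, labels = FALSE)
  labels[terr] <- band
  parcellation(spec$grid, labels, tibble::tibble(
    label = seq_len(n_bands), name = paste0("band_", seq_len(n_bands))))
}

# Parcellation whose single named region is the spec's eloquent region.
recovery_parcellation <- function(spec) {
  labels <- integer(prod(spec$grid$shape))
  for (r in seq_along(spec$regions)) {
    labels[spec$regions[[r]]$voxels] <- r
  }
  parcellation(spec$grid, labels, tibble::tibble(
    label = seq_along(spec$regions),
    name = vapply(spec$regions, `[[`, "", "name")
  ))
}

# Null-cohort spec at the family-wise-error study scale: ~500-voxel
# territory, contiguous lesions, outcome independent of lesions.
fwer_spec <- function(seed, n_subjects = 100) {
  grid <- voxel_grid(c(10, 10, 10))
  idx <- arrayInd(seq_len(prod(grid$shape)), grid$shape)
  territory <- rowSums(idx >= 2 & idx <= 9) == 3   # 8^3 = 512 voxels
  simulation_spec(
    grid = grid, n_subjects = n_subjects, territory = territory,
    regions = list(), effects = c(age = 0.05, lesion_volume = 0.08,
                                  followup_time = 0.01),
    size_meanlog = log(40), size_sdlog = 0.6, noise_sd = 4, seed = seed
  )
}
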