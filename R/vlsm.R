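#' Design specification for the voxel-wise GLM
#'
#' At every voxel i the model is
#'
#'   S = b0 + b1*L_i + b2*age + b3*vol + b4*fup (+ interactions) + eps
#'
#' with L_i the binary lesion indicator at that voxel. The design is
#' identical across voxels except the lesion column, which the fitting engine
#' exploits. An intercept is included by default: without one the covariates
#' absorb the outcome's mean and standardized coefficients lose meaning
#' (standard GLM practice in the VLSM lineage). Covariates enter
#' unstandardized; standardization happens only when importance maps are
#' derived. Interaction terms (age x volume and volume x follow-up) are
#' available but off by default.
#'
#' Only voxels lesioned in at least `min_lesion_count` subjects and spared in
#' at least `min_nonlesion_count` are testable (the usual VLSM minimum-
#' overlap convention; 5/5 by default).
#'
#' @param covariates Covariate column names, in order (may be empty for a
#'   lesion-only model).
#' @param include_interactions Add `age:lesion_volume` and
#'   `lesion_volume:followup_time` columns (default FALSE).
#' @param min_lesion_count,min_nonlesion_count Testability thresholds
#'   (default 5 each, both >= 1).
#' @param intercept Include an intercept (default TRUE).
#' @return A `design_spec` object.
#' @export
design_spec <- function(covariates = c("age", "lesion_volume",
                                       "followup_time"),
                        include_interactions = FALSE,
                        min_lesion_count = 5L,
                        min_nonlesion_count = 5L,
                        intercept = TRUE) {
  covariates <- as.character(covariates)
  if (anyDuplicated(covariates)) abort("Covariate names must be unique.")
  if (min_lesion_count < 1L || min_nonlesion_count < 1L) {
    abort("Minimum lesion/non-lesion counts must be >= 1.")
  }
  if (include_interactions &&
      !all(c("age", "lesion_volume", "followup_time") %in% covariates)) {
    abort("Interactions need the age, lesion_volume and followup_time covariates.")
  }
  structure(list(
    covariates = covariates,
    include_interactions = isTRUE(include_interactions),
    min_lesion_count = as.integer(min_lesion_count),
    min_nonlesion_count = as.integer(min_nonlesion_count),
    intercept = isTRUE(intercept)
  ), class = "design_spec")
}

#' Testable-voxel mask
#'
#' @param cohort A `lesion_cohort`.
#' @param spec A `design_spec`.
#' @return Logical vector over the grid: TRUE where the voxel is lesioned in
#'   >= `min_lesion_count` subjects and spared in >= `min_nonlesion_count`.
#' @export
testable_voxel_mask <- function(cohort, spec = design_spec()) {
  rs <- rowSums(cohort$lesions)
  n <- n_subjects(cohort)
  mask <- rs >= spec$min_lesion_count & (n - rs) >= spec$min_nonlesion_count
  if (!any(mask)) warn("No testable voxels under the current design spec.")
  mask
}

# Shared design matrix (everything but the lesion column).
design_base <- function(table, spec) {
  tab <- as.data.frame(table)
  cols <- list()
  if (spec$intercept) cols[["(Intercept)"]] <- rep(1, nrow(tab))
  for (cv in spec$covariates) {
    if (!cv %in% names(tab)) abort(sprintf("Covariate '%s' not in table.", cv))
    cols[[cv]] <- tab[[cv]]
  }
  if (spec$include_interactions) {
    cols[["age:lesion_volume"]] <- tab$age * tab$lesion_volume
    cols[["lesion_volume:followup_time"]] <- tab$lesion_volume * tab$followup_time
  }
  if (!length(cols)) {
    matrix(numeric(0), nrow = nrow(tab), ncol = 0)
  } else {
    do.call(cbind, cols)
  }
}

# Precompute the pieces shared across voxels and permutations: the QR of the
# covariate block Z, the Z-residualized lesion columns, and their squared
# norms. Frisch-Waugh-Lovell: the lesion coefficient and its t in the full
# model [Z, L_i] equal those from regressing the Z-residualized outcome on
# the Z-residualized lesion column, with the full model's residual df.
vlsm_precompute <- function(cohort, table, spec, testable = NULL) {
  if (!identical(as.character(table$subject_id), cohort$subject_ids)) {
    abort("Covariate table rows must match the cohort's subject order.")
  }
  n <- n_subjects(cohort)
  if (is.null(testable)) testable <- testable_voxel_mask(cohort, spec)
  voxels <- which(testable)
  Z <- design_base(table, spec)
  p_z <- ncol(Z)
  if (n <= p_z + 1L) abort("More model terms than subjects.")
  Lt <- t(cohort$lesions[voxels, , drop = FALSE]) # n x Vt
  storage.mode(Lt) <- "double"
  if (p_z > 0) {
    qz <- qr(Z)
    if (qz$rank < p_z) abort("Covariate design block is rank deficient.")
    Ltil <- qr.resid(qz, Lt)
  } else {
    qz <- NULL
    Ltil <- Lt
  }
  d <- colSums(Ltil^2)
  # voxels whose lesion column lies in span(Z) (e.g. constant after
  # residualization) cannot identify a lesion effect: drop them
  degenerate <- d <= n * 1e-10
  if (any(degenerate)) {
    inform(sprintf("Dropped %d rank-deficient voxel(s) from the testable mask.",
                   sum(degenerate)))
    voxels <- voxels[!degenerate]
    Lt <- Lt[, !degenerate, drop = FALSE]
    Ltil <- Ltil[, !degenerate, drop = FALSE]
    d <- d[!degenerate]
    testable[] <- FALSE
    testable[voxels] <- TRUE
  }
  list(qz = qz, Z = Z, Lt = Lt, Ltil = Ltil, d = d,
       voxels = voxels, testable = testable,
       df = n - p_z - 1L, n = n, p_z = p_z)
}

# Lesion-term t statistics for an outcome vector (or matrix of outcome
# columns), given the precomputed design. Returns a Vt x B matrix.
lesion_t_stats <- function(pre, y) {
  y <- as.matrix(y)
  ytil <- if (!is.null(pre$qz)) qr.resid(pre$qz, y) else y
  num <- crossprod(pre$Ltil, ytil)            # Vt x B, = Ltil' ytil
  yty <- colSums(ytil^2)                       # B
  rss <- pmax(sweep(-(num^2) / pre$d, 2, yty, `+`), 0)
  mse <- rss / pre$df
  tval <- (num / pre$d) / sqrt(mse / pre$d)
  list(t = tval, beta = num / pre$d, rss = rss, mse = mse)
}

#' Fit the independent per-voxel general linear models
#'
#' Ordinary least squares of the outcome on \[intercept, lesion indicator,
#' covariates(, interactions)\] at every testable voxel. The covariate block
#' is shared across voxels, so the engine residualizes the lesion columns
#' against it once and recovers each voxel's exact OLS solution
#' (Frisch-Waugh-Lovell); results are identical to refitting the full model
#' voxel by voxel. Voxels whose lesion column is collinear with the
#' covariate block are dropped from the testable mask with a logged count.
#'
#' @param cohort A `lesion_cohort`.
#' @param table A `covariate_table` aligned to the cohort.
#' @param spec A `design_spec`.
#' @return A `voxel_fit` object: `testable` (logical over the grid), `voxels`
#'   (indices), `coefficients` (Vt x p matrix, lesion column first),
#'   `t` (lesion-term t per voxel), `mse`, `df`, `covariate_variances`,
#'   `grid`, `n`, `spec`.
#' @export
fit_voxelwise_glm <- function(cohort, table, spec = design_spec()) {
  pre <- vlsm_precompute(cohort, table, spec)
  if (length(pre$voxels) == 0L) {
    warn("Empty testable mask; returning an empty fit.")
  }
  y <- table$outcome
  st <- lesion_t_stats(pre, y)
  beta_l <- drop(st$beta)
  # remaining coefficients: regress (y - L_i * beta_l) on Z
  if (pre$p_z > 0) {
    resid_mat <- y - sweep(pre$Lt, 2, beta_l, `*`)   # n x Vt
    beta_z <- qr.coef(pre$qz, resid_mat)             # p_z x Vt
    coefs <- cbind(lesion = beta_l, t(beta_z))
  } else {
    coefs <- cbind(lesion = beta_l)
  }
  covs <- spec$covariates
  var_x <- if (length(covs)) {
    vapply(covs, function(cv) var(as.data.frame(table)[[cv]]), numeric(1))
  } else {
    setNames(numeric(0), character(0))
  }
  if (spec$include_interactions) {
    tab <- as.data.frame(table)
    var_x <- c(var_x,
               `age:lesion_volume` = var(tab$age * tab$lesion_volume),
               `lesion_volume:followup_time` =
                 var(tab$lesion_volume * tab$followup_time))
  }
  structure(list(
    grid = cohort$grid,
    testable = pre$testable,
    voxels = pre$voxels,
    coefficients = coefs,
    t = drop(st$t),
    mse = drop(st$mse),
    df = pre$df,
    covariate_variances = var_x,
    outcome_variance = var(y),
    n = pre$n,
    spec = spec
  ), class = "voxel_fit")
}

#' @export
print.voxel_fit <- function(x, ...) {
  cat("<voxel_fit> ", length(x$voxels), " testable voxels, n = ", x$n,
      " subjects, residual df = ", x$df, "\n", sep = "")
  if (length(x$t)) {
    cat("  lesion t: median ", signif(stats::median(x$t), 4), ", max ",
        signif(max(x$t), 4), "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn fit_voxelwise_glm One row per testable voxel: coefficients,
#'   lesion t, MSE.
#' @param x A `voxel_fit`.
#' @param ... Unused.
#' @export
tidy.voxel_fit <- function(x, ...) {
  out <- tibble(voxel = x$voxels, t_lesion = x$t, mse = x$mse)
  dplyr::bind_cols(out, as_tibble(x$coefficients))
}

#' @describeIn fit_voxelwise_glm One-row fit summary.
#' @export
glance.voxel_fit <- function(x, ...) {
  tibble(
    n = x$n, n_testable = length(x$voxels), df_residual = x$df,
    max_t = if (length(x$t)) max(x$t) else NA_real_,
    interactions = x$spec$include_interactions
  )
}

#' Extract the lesion t-score (eloquence) map
#'
#' Voxels with higher lesion-term t-scores are deemed more eloquent: a
#' lesion there is associated with worse outcome after covariate adjustment.
#' The threshold is unset (NA) until the permutation module supplies one.
#'
#' @param fit A `voxel_fit`.
#' @return An `eloquence_map`: `grid`, `t` (full-grid vector, NA off the
#'   testable mask), `testable`, `threshold` (NA), `surviving` (NULL).
#' @export
lesion_t_map <- function(fit) {
  stopifnot(inherits(fit, "voxel_fit"))
  tvol <- rep(NA_real_, n_voxels(fit$grid))
  tvol[fit$voxels] <- fit$t
  if (length(fit$voxels) == 0L) warn("Empty testable mask: empty eloquence map.")
  structure(list(
    grid = fit$grid, t = tvol, testable = fit$testable,
    threshold = NA_real_, surviving = NULL
  ), class = "eloquence_map")
}

#' @export
print.eloquence_map <- function(x, ...) {
  nt <- sum(x$testable)
  cat("<eloquence_map> ", nt, " testable voxels", sep = "")
  if (!is.na(x$threshold)) {
    cat("; threshold ", signif(x$threshold, 4), "; ",
        sum(x$surviving), " surviving", sep = "")
  }
  cat("\n")
  invisible(x)
}
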