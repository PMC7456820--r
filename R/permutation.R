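#' Max-t permutation null distribution and FWER threshold
#'
#' Builds the non-parametric null distribution of the maximum lesion-term
#' t-score over all testable voxels by permuting the outcome vector across
#' subjects (lesions and covariates fixed) and refitting every voxel, then
#' takes the empirical (1 - alpha) quantile as the family-wise error
#' threshold. The quantile is the ceiling((1-alpha) * B)-th order statistic
#' of the B max-t draws — conservative, guaranteeing FWER <= alpha
#' marginally. The observed statistic is not added to the null sample by
#' default (pure threshold use); `add_observed = TRUE` enables the +1
#' convention for exact p-values. Outcome-only permutation tests the strong
#' null that the outcome is independent of lesions and covariates jointly;
#' this is the scheme of the classical VLSM max-statistic correction and is
#' the documented default.
#'
#' @param cohort A `lesion_cohort`.
#' @param table A `covariate_table` aligned to the cohort.
#' @param spec A `design_spec`.
#' @param n_permutations Number of random permutations (>= 100; default
#'   1000).
#' @param alpha Nominal family-wise error level in (0, 1) (default 0.05).
#' @param seed Integer seed; the seed expands deterministically into the
#'   whole permutation sequence.
#' @param two_sided Use max |t| instead of max signed t (default FALSE: the
#'   deficit-increasing direction only, matching the single positive
#'   max-t threshold convention).
#' @param exhaustive Enumerate all n! permutations instead of sampling
#'   (requires n <= 8; `n_permutations` and `seed` are then ignored).
#' @param add_observed Include the observed (identity-permutation) max t in
#'   the null sample (default FALSE).
#'
#' @return A `permutation_result`: `max_t` (the null sample), `threshold`,
#'   `n_permutations`, `alpha`, `seed`, `two_sided`, `exhaustive`.
#' @export
permutation_max_t <- function(cohort, table, spec = design_spec(),
                              n_permutations = 1000L, alpha = 0.05,
                              seed, two_sided = FALSE,
                              exhaustive = FALSE, add_observed = FALSE) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  pre <- vlsm_precompute(cohort, table, spec)
  if (length(pre$voxels) == 0L) abort("No testable voxels to permute.")
  y <- table$outcome
  n <- pre$n

  if (exhaustive) {
    if (n > 8L) abort("Exhaustive enumeration is limited to n <= 8 subjects.")
    perms <- all_permutations(n)
    seed <- NA_integer_
  } else {
    n_permutations <- as.integer(n_permutations)
    if (n_permutations < 100L) {
      abort("At least 100 permutations are required (the null is too coarse below that for alpha = 0.05).")
    }
    if (missing(seed) || is.null(seed)) {
      abort("An explicit integer `seed` is required.")
    }
    set.seed(as.integer(seed))
    perms <- replicate(n_permutations, sample.int(n), simplify = FALSE)
  }
  B <- length(perms)

  # the permutation stream is applied in canonical (sorted-ID) subject
  # order, so jointly reordering all inputs cannot change the threshold
  ord <- order(cohort$subject_ids, method = "radix")
  y_can <- y[ord]

  max_t <- numeric(B)
  chunk <- 256L
  for (start in seq(1L, B, by = chunk)) {
    idx <- start:min(start + chunk - 1L, B)
    Y <- vapply(perms[idx], function(p) {
      yp <- numeric(n)
      yp[ord] <- y_can[p]
      yp
    }, numeric(n))
    tmat <- lesion_t_stats(pre, Y)$t
    stat <- if (two_sided) abs(tmat) else tmat
    max_t[idx] <- apply(stat, 2, max)
  }
  if (add_observed) {
    obs <- lesion_t_stats(pre, y)$t
    max_t <- c(max_t, max(if (two_sided) abs(obs) else obs))
    B <- B + 1L
  }
  threshold <- sort(max_t)[ceiling((1 - alpha) * B)]
  structure(list(
    max_t = max_t, threshold = threshold, n_permutations = B,
    alpha = alpha, seed = if (exhaustive) NA_integer_ else as.integer(seed),
    two_sided = two_sided, exhaustive = exhaustive
  ), class = "permutation_result")
}

# All n! permutations of 1..n as a list (n small).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (i in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = i - 1L)
    }
  }
  out
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> ", x$n_permutations, " permutations",
      if (x$exhaustive) " (exhaustive)", "; alpha = ", x$alpha,
      "; max-t threshold = ", signif(x$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn permutation_max_t One-row summary of the null distribution.
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @export
glance.permutation_result <- function(x, ...) {
  tibble(
    n_permutations = x$n_permutations, alpha = x$alpha,
    threshold = x$threshold,
    null_median = stats::median(x$max_t), null_max = max(x$max_t),
    two_sided = x$two_sided, exhaustive = x$exhaustive
  )
}

#' Apply a permutation threshold to an eloquence map
#'
#' Marks as surviving every testable voxel whose t-score is at or above the
#' threshold; only surviving voxels ("true positive eloquent voxels") enter
#' the importance maps downstream.
#'
#' @param map An `eloquence_map` from [lesion_t_map()].
#' @param result A `permutation_result` (or a bare numeric threshold).
#' @return The map with `threshold` set and `surviving` filled in.
#' @export
apply_threshold <- function(map, result) {
  stopifnot(inherits(map, "eloquence_map"))
  threshold <- if (inherits(result, "permutation_result")) {
    result$threshold
  } else {
    as.numeric(result)
  }
  surviving <- map$testable & !is.na(map$t) & map$t >= threshold
  if (!any(surviving)) {
    warn("No voxels survive the permutation threshold.")
  }
  map$threshold <- threshold
  map$surviving <- surviving
  map
}
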