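#' Screen covariates for multicollinearity
#'
#' Before the covariates enter the voxel-wise models they are screened in two
#' steps: pairwise Spearman rank correlations (average ranks for ties,
#' two-sided p-values) and variance inflation factors,
#' VIF_j = 1 / (1 - R^2_j), where R^2_j comes from regressing covariate j on
#' the remaining covariates with an intercept. VIF is a property of the
#' design alone, so it is computed without reference to the outcome. A pair
#' with |r_s| at or above `cor_threshold` raises an informational flag; a
#' covariate with VIF at or above `vif_threshold` raises a blocking flag
#' (the conventional "VIF < 5" no-multicollinearity criterion). Perfect
#' collinearity is reported as infinite VIF and flagged, not an exception.
#'
#' @param table A `covariate_table` (or data frame with the covariate
#'   columns).
#' @param covariates Character vector of covariate column names.
#' @param cor_threshold Informational |r_s| flag threshold (default 0.1).
#' @param vif_threshold Blocking VIF flag threshold (default 5).
#'
#' @return A `collinearity_report`: list with `spearman` (k x k matrix),
#'   `p_values` (k x k), `vif` (tibble: covariate, r_squared, vif, flagged),
#'   `pair_flags` (tibble of flagged pairs), `blocking` (logical), and the
#'   thresholds.
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_spec(
#'   grid = voxel_grid(c(8, 8, 8)), n_subjects = 50, seed = 7))
#' check_collinearity(sim$covariates)
check_collinearity <- function(table,
                               covariates = c("age", "lesion_volume",
                                              "followup_time"),
                               cor_threshold = 0.1,
                               vif_threshold = 5) {
  X <- as.data.frame(table)[, covariates, drop = FALSE]
  if (nrow(X) < 3L) abort("At least 3 subjects are required.")
  constant <- vapply(X, function(v) var(v) == 0, logical(1))
  if (any(constant)) {
    abort(paste0("Constant covariate(s): ",
                 paste(covariates[constant], collapse = ", ")))
  }
  k <- length(covariates)

  rs <- cor(X, method = "spearman")
  pv <- matrix(NA_real_, k, k, dimnames = dimnames(rs))
  diag(pv) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ct <- suppressWarnings(
        cor.test(X[[i]], X[[j]], method = "spearman", exact = FALSE))
      pv[i, j] <- pv[j, i] <- ct$p.value
    }
  }

  vif_tbl <- purrr::map_dfr(seq_len(k), function(j) {
    if (k == 1L) {
      return(tibble(covariate = covariates[j], r_squared = 0, vif = 1))
    }
    fit <- lm(X[[j]] ~ ., data = X[, -j, drop = FALSE])
    # degenerate fits (R^2 -> 1) are handled explicitly below
    r2 <- suppressWarnings(summary(fit))$r.squared
    tibble(covariate = covariates[j], r_squared = r2,
           vif = if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2))
  })
  vif_tbl$flagged <- vif_tbl$vif >= vif_threshold

  pairs <- which(upper.tri(rs) & abs(rs) >= cor_threshold, arr.ind = TRUE)
  pair_flags <- tibble(
    covariate_1 = covariates[pairs[, 1]],
    covariate_2 = covariates[pairs[, 2]],
    spearman = rs[pairs],
    p_value = pv[pairs]
  )

  structure(list(
    spearman = rs, p_values = pv, vif = vif_tbl, pair_flags = pair_flags,
    blocking = any(vif_tbl$flagged),
    cor_threshold = cor_threshold, vif_threshold = vif_threshold,
    n = nrow(X)
  ), class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("<collinearity_report> n =", x$n, "subjects,",
      nrow(x$vif), "covariates\n")
  cat("Spearman rank correlations:\n")
  print(round(x$spearman, 3))
  cat("Variance inflation factors (design-only; flag at >=",
      x$vif_threshold, "):\n")
  print(as.data.frame(x$vif), row.names = FALSE)
  if (nrow(x$pair_flags)) {
    cat("Pairs with |r_s| >=", x$cor_threshold, "(informational):\n")
    print(as.data.frame(x$pair_flags), row.names = FALSE)
  }
  cat(if (x$blocking) "BLOCKING: multicollinearity flag raised.\n"
      else "No blocking multicollinearity flag.\n")
  invisible(x)
}

#' @describeIn check_collinearity Tidy the pairwise Spearman correlations
#'   into one row per covariate pair.
#' @param x A `collinearity_report`.
#' @param ... Unused.
#' @export
tidy.collinearity_report <- function(x, ...) {
  covs <- rownames(x$spearman)
  idx <- which(upper.tri(x$spearman), arr.ind = TRUE)
  tibble(
    covariate_1 = covs[idx[, 1]],
    covariate_2 = covs[idx[, 2]],
    spearman = x$spearman[idx],
    p_value = x$p_values[idx],
    flagged = abs(x$spearman[idx]) >= x$cor_threshold
  )
}

#' @describeIn check_collinearity One-row summary (max |r_s|, max VIF,
#'   blocking status).
#' @export
glance.collinearity_report <- function(x, ...) {
  off <- x$spearman[upper.tri(x$spearman)]
  tibble(
    n = x$n,
    n_covariates = nrow(x$vif),
    max_abs_spearman = if (length(off)) max(abs(off)) else NA_real_,
    max_vif = max(x$vif$vif),
    blocking = x$blocking
  )
}

#' Write a collinearity report as JSON
#'
#' @param report A `collinearity_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collinearity_report <- function(report, path) {
  jsonlite::write_json(list(
    n = report$n,
    covariates = report$vif$covariate,
    spearman = report$spearman,
    p_values = report$p_values,
    vif = report$vif,
    pair_flags = report$pair_flags,
    blocking = report$blocking,
    thresholds = list(spearman = report$cor_threshold,
                      vif = report$vif_threshold),
    note = "VIF is computed from the covariate design alone; it does not depend on the outcome."
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
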