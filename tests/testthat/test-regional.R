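# A hand-built importance_maps object on a small grid, bypassing the fit:
# regional aggregation is pure arithmetic on the normalized maps.
toy_maps <- function(grid, voxels, normalized) {
  surviving <- rep(FALSE, prod(grid$shape))
  surviving[voxels] <- TRUE
  structure(list(
    grid = grid, surviving = surviving, voxels = voxels,
    raw = normalized, normalized = normalized,
    bounds = tibble::tibble(covariate = colnames(normalized),
                            min = 0, max = 1),
    convention = "covariate_variance"
  ), class = "importance_maps")
}

toy_parc <- function(grid, assignment) {
  labels <- integer(prod(grid$shape))
  for (r in seq_along(assignment)) labels[assignment[[r]]] <- r
  parcellation(grid, labels, tibble::tibble(
    label = seq_along(assignment),
    name = paste0("region_", seq_along(assignment))))
}

test_that("regional means average normalized importance over the overlap", {
  grid <- voxel_grid(c(4, 4, 1))
  voxels <- 1:8
  norm <- cbind(age = rep(0.7, 8), lesion_volume = seq(0, 0.7, 0.1),
                followup_time = rep(0.2, 8))
  maps <- toy_maps(grid, voxels, norm)
  parc <- toy_parc(grid, list(1:4, 5:8, 9:12))   # region 3: no overlap
  tab <- regional_means(maps, parc)

  expect_equal(tab$name, c("region_1", "region_2"))   # zero-overlap omitted
  expect_equal(tab$n_voxels, c(4L, 4L))
  expect_equal(tab$age, c(0.7, 0.7))                  # mean of a constant
  expect_equal(tab$lesion_volume, c(mean(c(0, 0.1, 0.2, 0.3)),
                                    mean(c(0.4, 0.5, 0.6, 0.7))))

  # all-ones map gives exactly 1 everywhere
  ones <- toy_maps(grid, voxels,
                   cbind(age = rep(1, 8), lesion_volume = rep(1, 8),
                         followup_time = rep(1, 8)))
  tab1 <- regional_means(ones, parc)
  expect_true(all(tab1$age == 1 & tab1$lesion_volume == 1 &
                    tab1$followup_time == 1))

  other_grid <- voxel_grid(c(4, 4, 1), voxel_size = c(2, 2, 2))
  expect_error(regional_means(maps, toy_parc(other_grid, list(1:4))),
               "grid")
})

test_that("the overlap filter retains regions by count or percentile", {
  base <- tibble::tibble(
    label = 1:3, name = c("a", "b", "c"), n_voxels = c(100L, 400L, 900L),
    age = c(0.1, 0.2, 0.3), lesion_volume = c(0.3, 0.2, 0.1),
    followup_time = c(0.5, 0.5, 0.5))
  class(base) <- c("regional_importance", class(tibble::tibble()))

  # the study's convention: absolute threshold 400 voxels keeps 2 of 3
  kept <- overlap_filter(base, mode = "absolute", value = 400)
  expect_equal(kept$name, c("b", "c"))
  # absolute mode is idempotent
  expect_equal(tibble::as_tibble(overlap_filter(kept, mode = "absolute",
                                        value = 400)),
               tibble::as_tibble(kept), ignore_attr = TRUE)
  # threshold 0 is the identity
  expect_equal(tibble::as_tibble(overlap_filter(base, mode = "absolute", value = 0)),
               tibble::as_tibble(base), ignore_attr = TRUE)

  # percentile mode: regions at or above the interpolated percentile
  big <- base[rep(1, 100), ]
  big$n_voxels <- 1:100
  big$label <- 1:100; big$name <- paste0("r", 1:100)
  class(big) <- c("regional_importance", class(tibble::tibble()))
  kept50 <- overlap_filter(big, mode = "percentile", value = 50)
  cutoff <- quantile(1:100, 0.5, type = 7, names = FALSE)
  expect_equal(kept50$n_voxels, which(1:100 >= cutoff))

  expect_warning(out <- overlap_filter(base, mode = "absolute",
                                       value = 1e6),
                 "every region")
  expect_equal(nrow(out), 0)
})

test_that("average-linkage clustering matches a hand-traced merge sequence", {
  # three 1-D profiles at 0, 1, 3: d(a,b) = 1, d(b,c) = 2, d(a,c) = 3.
  # average linkage: merge {a,b} at height 1, then {ab},c at (3+2)/2 = 2.5
  tab <- tibble::tibble(
    label = 1:3, name = c("a", "b", "c"), n_voxels = c(10L, 10L, 10L),
    age = c(0, 1, 3), lesion_volume = c(0, 0, 0),
    followup_time = c(0, 0, 0))
  class(tab) <- c("regional_importance", class(tibble::tibble()))
  cl <- cluster_regions(tab)
  expect_equal(cl$hclust$height, c(1, 2.5))
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))
  td <- tidy(cl)
  expect_equal(td$height, c(1, 2.5))
  expect_equal(td$size, c(2L, 3L))

  # identical rows merge first at height 0
  tab2 <- tab
  tab2$age <- c(0.5, 2, 0.5)
  cl2 <- cluster_regions(tab2)
  expect_equal(cl2$hclust$height[1], 0)
  expect_equal(sort(cl2$hclust$merge[1, ]), c(-3, -1))

  # duplicating every row: all duplicate pairs merge at height 0 first
  tab4 <- dplyr::bind_rows(tibble::as_tibble(tab), tibble::as_tibble(tab))
  tab4$name <- paste0(tab4$name, rep(c("", "_dup"), each = 3))
  class(tab4) <- c("regional_importance", class(tibble::tibble()))
  cl4 <- cluster_regions(tab4)
  expect_equal(cl4$hclust$height[1:3], c(0, 0, 0))

  expect_error(cluster_regions(tab[1, ]), "At least 2")
})

test_that("clustering is invariant to row order up to relabelling", {
  set.seed(9)
  tab <- tibble::tibble(
    label = 1:8, name = paste0("r", 1:8), n_voxels = rep(50L, 8),
    age = runif(8), lesion_volume = runif(8), followup_time = runif(8))
  class(tab) <- c("regional_importance", class(tibble::tibble()))
  cl1 <- cluster_regions(tab)
  ord <- sample(8)
  tab2 <- tab[ord, ]
  class(tab2) <- c("regional_importance", class(tibble::tibble()))
  cl2 <- cluster_regions(tab2)
  d1 <- as.matrix(cophenetic(cl1$hclust))
  d2 <- as.matrix(cophenetic(cl2$hclust))
  expect_equal(d1[tab$name, tab$name], d2[tab$name, tab$name],
               tolerance = 1e-12)
})

test_that("the dominant covariate is the argmax with fixed-order tie breaks", {
  tab <- tibble::tibble(
    label = 1:3, name = c("a", "b", "c"), n_voxels = rep(10L, 3),
    age = c(0.9, 0.4, 0.2), lesion_volume = c(0.2, 0.4, 0.9),
    followup_time = c(0.1, 0.1, 0.9))
  class(tab) <- c("regional_importance", class(tibble::tibble()))
  out <- dominant_covariate(tab)
  expect_equal(out$dominant, c("age", "age", "lesion_volume"))
  expect_equal(out$tie, c(FALSE, TRUE, TRUE))
})

test_that("regional outputs write to CSV and JSON", {
  tab <- tibble::tibble(
    label = 1:3, name = c("a", "b", "c"), n_voxels = c(10L, 20L, 30L),
    age = c(0.9, 0.4, 0.2), lesion_volume = c(0.2, 0.5, 0.9),
    followup_time = c(0.1, 0.1, 0.8))
  class(tab) <- c("regional_importance", class(tibble::tibble()))
  tab <- dominant_covariate(tab)
  cl <- cluster_regions(tab)
  dir <- withr::local_tempdir()
  write_regional_results(tab, cl, dir)
  back <- readr::read_csv(file.path(dir, "regional_importance.csv"),
                          show_col_types = FALSE)
  expect_equal(back$dominant, c("age", "lesion_volume", "lesion_volume"))
  link <- readr::read_csv(file.path(dir, "regional_linkage.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(link), 2)
  meta <- jsonlite::read_json(file.path(dir, "regional_clustering.json"))
  expect_equal(meta$linkage, "average")
})
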