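rand_matrix <- function(nf, nr, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(nf * nr), nf, nr)
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- paste0("R", seq_len(nr))
  dplyr::bind_cols(tibble::tibble(feature = paste0("f", seq_len(nf))), out)
}

test_that("feature selection applies the 10-region and complete-case rules", {
  m <- rand_matrix(3, 22)
  m[1, 1 + 1:13] <- NA        # 9 observed -> fails clustering rule
  m[2, 2] <- NA               # 21 observed -> clustering yes, pca no
  cl <- select_features(m, "clustering")
  expect_setequal(cl$feature, c("f2", "f3"))
  pc <- select_features(m, "pca")
  expect_equal(pc$feature, "f3")
  all_na <- m
  all_na[, -1] <- NA_real_
  expect_error(select_features(all_na, "clustering"), "threshold")
  # complete matrices: both modes identical
  full <- rand_matrix(4, 12)
  expect_equal(select_features(full, "clustering"),
               select_features(full, "pca"))
})

test_that("autoscale centres and scales features, dropping constants", {
  m <- mk <- rand_matrix(3, 8)
  mk[2, -1] <- 5
  expect_warning(s <- autoscale(mk), "constant")
  expect_setequal(s$feature, c("f1", "f3"))
  vals <- as.matrix(s[, -1])
  expect_equal(rowMeans(vals), c(0, 0), ignore_attr = TRUE)
  expect_equal(apply(vals, 1, stats::sd), c(1, 1), ignore_attr = TRUE)
  expect_equal(autoscale(s), s, tolerance = 1e-12)  # idempotent
})

test_that("minimum imputation fills gaps with the per-feature minimum", {
  m <- rand_matrix(2, 6)
  m[1, 3] <- NA
  expect_message(imp <- impute_min(m), "imputed")
  expect_equal(imp[[3]][1], min(unlist(m[1, -1]), na.rm = TRUE))
  expect_false(anyNA(imp))
})

test_that("Ward.D2 merges match hand computation and the naive oracle", {
  line <- tibble::tibble(feature = c("a", "b", "c"),
                         R1 = c(0, 0.1, 10))
  hc <- ward_cluster(line)
  expect_equal(hc$height[1], 0.1)       # near pair joins first
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))

  dup <- tibble::tibble(feature = c("a", "b"), R1 = c(1, 1), R2 = c(2, 2))
  expect_equal(ward_cluster(dup)$height[1], 0)
  expect_error(ward_cluster(dup[1, ]), "2 rows")

  set.seed(21)
  for (k in 1:10) {
    X <- matrix(stats::rnorm(12), 6, 2)
    hc <- ward_cluster(X)
    expect_equal(hc$height, oracle_ward_heights(X), tolerance = 1e-9)
    expect_true(all(diff(hc$height) >= -1e-12))
    # heights invariant under row permutation
    perm <- sample(6)
    expect_equal(sort(ward_cluster(X[perm, ])$height), sort(hc$height),
                 tolerance = 1e-9)
  }
})

test_that("PCA is orthonormal, sign-deterministic and reconstructs the
           scaled matrix", {
  m <- rand_matrix(6, 10, seed = 5)
  pc <- gag_pca(m)
  L <- as.matrix(pc$loadings[, -1])
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-12)
  # sign convention: largest-|.| loading of each component positive
  for (j in seq_len(ncol(L))) {
    expect_gt(L[which.max(abs(L[, j])), j], 0)
  }
  # reconstruction of the autoscaled data
  S <- as.matrix(pc$scores[, -1])
  X <- t(as.matrix(autoscale(m)[, -1]))
  expect_equal(S %*% t(L), X, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA handles collinear and duplicated-region input", {
  base <- stats::rnorm(8)
  m <- tibble::tibble(feature = c("f1", "f2", "f3"))
  m <- dplyr::bind_cols(m, tibble::as_tibble(
    as.data.frame(rbind(base, 2 * base, -base))))
  names(m)[-1] <- paste0("R", 1:8)
  pc <- gag_pca(m)
  expect_equal(pc$explained[1], 1, tolerance = 1e-9)

  m2 <- rand_matrix(5, 4, seed = 8)
  m2$R4 <- m2$R3                        # duplicated region
  pc2 <- gag_pca(m2)
  s <- as.matrix(pc2$scores[, -1])
  expect_equal(s[3, ], s[4, ], ignore_attr = TRUE)

  const <- tibble::tibble(feature = "f1", R1 = 1, R2 = 1, R3 = 1)
  expect_error(suppressWarnings(gag_pca(const)), "rank")
})

test_that("heatmap ordering groups planted blocks contiguously", {
  set.seed(31)
  block <- rbind(
    matrix(stats::rnorm(5 * 8, mean = rep(c(3, -3), each = 4 * 5)), 5, 8),
    matrix(stats::rnorm(5 * 8, mean = rep(c(-3, 3), each = 4 * 5)), 5, 8))
  m <- tibble::as_tibble(as.data.frame(block))
  names(m) <- paste0("R", 1:8)
  m <- dplyr::bind_cols(tibble::tibble(feature = paste0("f", 1:10)), m)
  ho <- heatmap_order(m)
  pos <- match(paste0("f", 1:5), ho$row_order)
  expect_equal(max(pos) - min(pos), 4)  # first block contiguous
  expect_setequal(ho$col_order, paste0("R", 1:8))
  expect_equal(dim(ho$display), c(10, 8))

  two <- tibble::tibble(feature = c("a", "b"), R1 = c(1, 2), R2 = c(2, 1))
  ho2 <- heatmap_order(two)
  expect_setequal(ho2$row_order, c("a", "b"))

  flat <- tibble::tibble(feature = c("a", "b"), R1 = c(1, 1), R2 = c(1, 1))
  ho3 <- heatmap_order(flat)
  expect_true(all(ho3$display == 0))
})

test_that("tidy and glance methods expose cluster and PCA results", {
  m <- rand_matrix(5, 6, seed = 13)
  hc <- ward_cluster(m)
  td <- generics::tidy(hc)
  expect_equal(nrow(td), 4)
  expect_true(all(diff(td$height) >= -1e-12))
  expect_equal(generics::glance(hc)$n, 5)

  pc <- gag_pca(m)
  sc <- generics::tidy(pc, "scores")
  expect_true(all(c("region", "component", "value") %in% names(sc)))
  gl <- generics::glance(pc)
  expect_equal(gl$n_regions, 6)
  expect_equal(gl$n_features, 5)
})
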