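#' Select features for clustering or PCA
#'
#' Clustering keeps features quantified in at least `min_regions` regions
#' (remaining gaps are handled downstream, see [impute_min()]); PCA keeps
#' complete-case features only, since ordinary PCA has no native notion of
#' missingness.
#'
#' @param matrix Wide quantification tibble (`feature` + region columns).
#' @param mode `"clustering"` or `"pca"`.
#' @param min_regions Minimum quantified regions in clustering mode.
#' @return The selected quantification tibble.
#' @export
select_features <- function(matrix, mode = c("clustering", "pca"),
                            min_regions = 10) {
  mode <- match.arg(mode)
  vals <- quant_values(matrix)
  n_obs <- rowSums(!is.na(vals))
  keep <- if (mode == "clustering") n_obs >= min_regions else
    n_obs == ncol(vals)
  if (!any(keep)) {
    stop("no feature passes the ", mode, " selection rule; ",
         "consider lowering the threshold", call. = FALSE)
  }
  matrix[keep, , drop = FALSE]
}

#' Impute residual missing values with the feature minimum
#'
#' For features that passed the clustering selection but still have gaps,
#' substitutes each missing entry with the smallest observed value of that
#' feature — a proxy for abundances below the detection limit.
#'
#' @param matrix Wide quantification tibble.
#' @return The tibble with no missing entries among selected features.
#' @export
impute_min <- function(matrix) {
  vals <- quant_values(matrix)
  n_imp <- sum(is.na(vals))
  if (n_imp > 0) {
    for (i in seq_len(nrow(vals))) {
      miss <- is.na(vals[i, ])
      if (any(miss)) vals[i, miss] <- min(vals[i, !miss])
    }
    message(n_imp, " missing entries imputed with per-feature minima")
    matrix[, quant_regions(matrix)] <- vals
  }
  matrix
}

#' Autoscale features to zero mean and unit variance
#'
#' Centres and scales each feature (row) across regions. Constant features
#' carry no variance information and are dropped with a warning.
#'
#' @param matrix Wide quantification tibble with no missing values.
#' @return The scaled tibble.
#' @export
autoscale <- function(matrix) {
  vals <- quant_values(matrix)
  if (anyNA(vals)) {
    stop("autoscale requires a complete matrix; select or impute first",
         call. = FALSE)
  }
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) dropped before scaling",
            call. = FALSE)
    matrix <- matrix[sds > 0, , drop = FALSE]
    vals <- vals[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  vals <- (vals - rowMeans(vals)) / sds
  matrix[, quant_regions(matrix)] <- vals
  matrix
}

# z-score rows, mapping constant rows to 0 rather than NaN
zscore_rows <- function(vals) {
  ctr <- vals - rowMeans(vals)
  sds <- apply(vals, 1, stats::sd)
  ctr[sds > 0, ] <- ctr[sds > 0, , drop = FALSE] / sds[sds > 0]
  ctr[sds == 0, ] <- 0
  ctr
}

#' Ward.D2 hierarchical clustering of matrix rows
#'
#' Agglomerative clustering with Euclidean distances under the Ward.D2
#' criterion (the Lance-Williams recurrence applied to squared
#' distances), as implemented by [stats::hclust()]. Merge heights equal
#' `sqrt(2 * delta-ESS)` of each merge and are non-decreasing. The module
#' is fully deterministic: no randomness enters anywhere.
#'
#' @param matrix Wide quantification tibble (rows are clustered) or a
#'   plain numeric matrix with rownames.
#' @return An object of class `gag_ward` (inheriting from `hclust`) with
#'   labels taken from the feature column or rownames. Use
#'   [generics::tidy()] for the merge table and [stats::cutree()] for
#'   cluster assignments.
#' @export
ward_cluster <- function(matrix) {
  if (is.data.frame(matrix)) {
    vals <- quant_values(matrix)
    rownames(vals) <- matrix$feature
  } else {
    vals <- as.matrix(matrix)
    if (is.null(rownames(vals))) rownames(vals) <- seq_len(nrow(vals))
  }
  if (nrow(vals) < 2) {
    stop("clustering needs at least 2 rows", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(vals), method = "ward.D2")
  class(hc) <- c("gag_ward", class(hc))
  hc
}

#' @export
tidy.gag_ward <- function(x, ...) {
  tibble::tibble(
    merge1 = x$merge[, 1],
    merge2 = x$merge[, 2],
    height = x$height
  )
}

#' @export
glance.gag_ward <- function(x, ...) {
  tibble::tibble(
    n = length(x$order),
    max_height = max(x$height),
    method = x$method
  )
}

#' Principal component analysis of regions over autoscaled features
#'
#' Regions are the observations, features the variables; variables are
#' autoscaled (unit variance) before decomposition unless `scale. =
#' FALSE`. The singular value decomposition of [stats::prcomp()] is used,
#' with a deterministic sign convention: each loading vector is oriented
#' so that its largest-magnitude element is positive.
#'
#' @param matrix Wide quantification tibble (features x regions,
#'   complete cases).
#' @param scale. Scale variables to unit variance (default `TRUE`).
#' @return Object of class `gag_pca`: list with `scores` (region x
#'   component tibble), `loadings` (feature x component tibble),
#'   `explained` (variance fractions), `sdev`.
#' @export
gag_pca <- function(matrix, scale. = TRUE) {
  vals <- quant_values(matrix)
  if (anyNA(vals)) {
    stop("PCA requires complete-case features; run select_features(mode = \"pca\")",
         call. = FALSE)
  }
  x <- t(vals)  # regions x features
  colnames(x) <- matrix$feature
  if (nrow(x) < 2) stop("PCA needs at least 2 regions", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (scale. && any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) dropped before PCA",
            call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) == 0 || all(apply(x, 2, stats::sd) == 0)) {
    stop("matrix has rank 0 after scaling; PCA undefined", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  # orient each component so its largest-|.| loading is positive
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(region = rownames(x)),
                              tibble::as_tibble(pc$x)),
    loadings = dplyr::bind_cols(tibble::tibble(feature = colnames(x)),
                                tibble::as_tibble(pc$rotation)),
    explained = expl,
    sdev = pc$sdev
  ), class = "gag_pca")
}

#' @export
print.gag_pca <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "regions over", nrow(x$loadings),
      "features\n")
  cat("explained variance:",
      paste0(sprintf("PC%d %.1f%%", seq_len(min(3, length(x$explained))),
                     100 * x$explained[seq_len(min(3, length(x$explained)))]),
             collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.gag_pca <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  wide <- x[[matrix]]
  id <- names(wide)[1]
  tidyr::pivot_longer(wide, -dplyr::all_of(id), names_to = "component",
                      values_to = "value")
}

#' @export
glance.gag_pca <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x$scores),
    n_features = nrow(x$loadings),
    pc1_explained = x$explained[1],
    pc2_explained = if (length(x$explained) > 1) x$explained[2] else NA_real_
  )
}

#' Dendrogram-ordered display matrix for a clustered heatmap
#'
#' Orders features and regions by their respective Ward.D2 dendrograms
#' and returns the feature-wise z-scored display matrix (constant
#' features displayed as zero), the form in which clustered omics
#' heatmaps are drawn.
#'
#' @param matrix Wide quantification tibble after clustering selection
#'   (and imputation if gaps remain).
#' @return List with `row_order`, `col_order` (character vectors),
#'   `display` (ordered z-scored matrix), `row_cluster` and `col_cluster`
#'   (`gag_ward` objects).
#' @export
heatmap_order <- function(matrix) {
  vals <- quant_values(matrix)
  if (anyNA(vals)) {
    stop("heatmap ordering requires a complete matrix; impute first",
         call. = FALSE)
  }
  rownames(vals) <- matrix$feature
  z <- zscore_rows(vals)
  rc <- ward_cluster(z)
  cc <- ward_cluster(t(z))
  ro <- rownames(z)[rc$order]
  co <- colnames(z)[cc$order]
  list(row_order = ro, col_order = co,
       display = z[ro, co, drop = FALSE],
       row_cluster = rc, col_cluster = cc)
}
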