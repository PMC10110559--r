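#' Pipeline configuration
#'
#' Builds (or loads from YAML) the configuration consumed by
#' [run_pipeline()].
#'
#' @param metadata Path to the region metadata table.
#' @param protein_matrix Optional path to a protein LFQ matrix.
#' @param gag_matrix Optional path to a GAG analyte amount matrix.
#' @param grouping Grouping variable: `"morphology"`, `"mucin"` or
#'   `"stroma"`.
#' @param comparisons List of length-2 character vectors `c(group_a,
#'   group_b)`; `NULL` compares every group pair.
#' @param alpha Nominal significance level.
#' @param min_per_group,min_groups Quantification filter thresholds
#'   (see [filter_quantified()]).
#' @param cluster_min_regions Clustering feature-selection threshold.
#' @param protein_log2 Log2-transform protein intensities before
#'   clustering/PCA (GAG matrices are analysed as relative percentages,
#'   untransformed).
#' @param outdir Output directory (created if needed).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(metadata, protein_matrix = NULL,
                            gag_matrix = NULL, grouping = "morphology",
                            comparisons = NULL, alpha = 0.05,
                            min_per_group = 3, min_groups = 2,
                            cluster_min_regions = 10, protein_log2 = TRUE,
                            outdir = "gagomics_out") {
  cfg <- as.list(environment())
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!cfg$grouping %in% c("morphology", "mucin", "stroma")) {
    stop("grouping must be morphology, mucin or stroma", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return List of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$comparisons)) {
    vals$comparisons <- lapply(vals$comparisons, unlist)
  }
  do.call(pipeline_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full region-comparison pipeline
#'
#' Chains the analysis stages: read inputs, derive the region grouping,
#' filter features by quantification counts, exact rank-sum comparison of
#' every configured group pair with fold changes, per-region and
#' per-group GAG sulfation summaries, Ward.D2 clustering with heatmap
#' ordering, and scaled PCA. All result tables are written as TSV into
#' `config$outdir` together with a machine-readable JSON run log
#' (inputs, parameters, package version, whether the relaxed minimal-p
#' rule fired). Any stage error aborts with a stage-named message.
#'
#' @param config A [pipeline_config()] or path to a YAML file.
#' @return Invisibly, a list with the in-memory results (`de`,
#'   `gag_summaries`, `heatmap`, `pca`, `run_log`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  meta <- stage("read_metadata", read_region_table(config$metadata))
  groups <- stage("derive_groups", derive_groups(meta, config$grouping))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  run_log <- list(
    package = "gagomics",
    version = as.character(utils::packageVersion("gagomics")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = list(metadata = config$metadata,
                  protein_matrix = config$protein_matrix,
                  gag_matrix = config$gag_matrix),
    parameters = list(grouping = config$grouping, alpha = config$alpha,
                      min_per_group = config$min_per_group,
                      min_groups = config$min_groups,
                      cluster_min_regions = config$cluster_min_regions,
                      protein_log2 = config$protein_log2),
    relaxed_alpha_comparisons = list()
  )
  out <- list(run_log = run_log)

  comparisons <- config$comparisons
  if (is.null(comparisons)) {
    gl <- sort(unique(groups$group))
    comparisons <- if (length(gl) >= 2) {
      utils::combn(gl, 2, simplify = FALSE)
    } else list()
  }

  analysis_matrix <- NULL
  if (!is.null(config$protein_matrix)) {
    mat <- stage("read_protein_matrix",
                 read_quant_matrix(config$protein_matrix, "protein"))
    filt <- stage("filter_quantified",
                  filter_quantified(mat, groups, config$min_per_group,
                                    config$min_groups))
    de <- stage("compare_groups", purrr::map(comparisons, function(pr) {
      compare_groups(filt, groups, pr[1], pr[2], alpha = config$alpha)
    }))
    names(de) <- purrr::map_chr(comparisons, paste, collapse = "_vs_")
    for (nm in names(de)) {
      write_table(de[[nm]], file.path(config$outdir,
                                      paste0("de_", nm, ".tsv")))
      if (any(de[[nm]]$relaxed, na.rm = TRUE)) {
        out$run_log$relaxed_alpha_comparisons[[nm]] <- list(
          alpha_used = sort(unique(
            de[[nm]]$alpha_used[which(de[[nm]]$relaxed)])),
          note = "minimal achievable p of the group sizes exceeds alpha")
      }
    }
    out$de <- de
    analysis_matrix <- if (config$protein_log2) {
      m <- filt
      m[, quant_regions(m)] <- log2(quant_values(m))
      m
    } else filt
  }

  if (!is.null(config$gag_matrix)) {
    gmat <- stage("read_gag_matrix",
                  read_quant_matrix(config$gag_matrix, "gag"))
    long <- gag_matrix_to_long(gmat)
    summ <- stage("gag_summaries", summarize_profiles(long))
    summ <- dplyr::left_join(summ, groups, by = "region")
    write_table(summ, file.path(config$outdir, "gag_region_summaries.tsv"))
    gsum <- summ |>
      dplyr::filter(!is.na(.data$group)) |>
      dplyr::group_by(.data$group, .data$gag_class) |>
      dplyr::summarise(dplyr::across(
        c("total_pmol", "avg_sulfation", "ratio_6s4s",
          "no_mono", "no_di", "no_total"),
        ~ mean(.x, na.rm = TRUE)), .groups = "drop")
    write_table(gsum, file.path(config$outdir, "gag_group_summaries.tsv"))
    out$gag_summaries <- list(region = summ, group = gsum)
    if (is.null(analysis_matrix)) {
      rel <- relative_abundance(long) |>
        dplyr::transmute(feature = .data$analyte, region = .data$region,
                         value = .data$rel_pct) |>
        tidyr::pivot_wider(names_from = "region", values_from = "value")
      analysis_matrix <- rel
    }
  }

  if (!is.null(analysis_matrix)) {
    cl_mat <- stage("clustering", {
      sel <- select_features(analysis_matrix, "clustering",
                             min_regions = config$cluster_min_regions)
      impute_min(sel)
    })
    ho <- stage("heatmap_order", heatmap_order(cl_mat))
    write_table(tidy(ho$col_cluster),
                file.path(config$outdir, "clustering_linkage.tsv"))
    disp <- tibble::as_tibble(ho$display, rownames = "feature")
    write_table(disp, file.path(config$outdir, "heatmap_matrix.tsv"))
    out$heatmap <- ho

    pca_res <- stage("pca", {
      sel <- select_features(analysis_matrix, "pca")
      gag_pca(sel)
    })
    write_table(pca_res$scores, file.path(config$outdir, "pca_scores.tsv"))
    write_table(pca_res$loadings,
                file.path(config$outdir, "pca_loadings.tsv"))
    out$pca <- pca_res
  }

  jsonlite::write_json(out$run_log,
                       file.path(config$outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(out)
}
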