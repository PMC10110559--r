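read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

ABSENT_SCORE <- c("–", "-", "", "NA")

#' Read a region metadata table
#'
#' Reads a TSV/CSV with columns `region`, `patient`, `morphology`,
#' `mucin`, `stroma`. Scores are semiquantitative 1-3 grades; an en dash,
#' ASCII dash, empty cell or `NA` marks an absent score (normal regions
#' never carry scores). Morphology labels are case-normalised to
#' `normal`, `papillary`, `tubular`, `solid`.
#'
#' @param path File path.
#' @return Validated tibble with columns `region`, `patient`,
#'   `morphology`, `mucin`, `stroma`.
#' @export
read_region_table <- function(path) {
  raw <- read_delim_auto(path)
  names(raw) <- tolower(names(raw))
  need <- c("region", "patient", "morphology", "mucin", "stroma")
  if (!all(need %in% names(raw))) {
    stop("region table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  parse_score <- function(x, col) {
    x <- as.character(x)
    x[trimws(x) %in% ABSENT_SCORE | is.na(x)] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & (is.na(v) | v != round(v) | v < 1 | v > 3))
    if (length(bad) > 0) {
      stop(sprintf("invalid %s score '%s' at row %d (expected 1-3 or absent)",
                   col, x[bad[1]], bad[1]), call. = FALSE)
    }
    as.integer(v)
  }
  morph <- tolower(trimws(as.character(raw$morphology)))
  known <- c("normal", "papillary", "tubular", "solid")
  bad <- which(!morph %in% known)
  if (length(bad) > 0) {
    stop(sprintf("unknown morphology label '%s' at row %d",
                 raw$morphology[bad[1]], bad[1]), call. = FALSE)
  }
  out <- tibble::tibble(
    region = as.character(raw$region),
    patient = as.character(raw$patient),
    morphology = morph,
    mucin = parse_score(raw$mucin, "mucin"),
    stroma = parse_score(raw$stroma, "stroma")
  )
  if (anyDuplicated(out$region)) {
    stop("duplicate region identifiers in metadata", call. = FALSE)
  }
  scored_normal <- which(out$morphology == "normal" &
                           (!is.na(out$mucin) | !is.na(out$stroma)))
  if (length(scored_normal) > 0) {
    stop("normal region carries a mucin/stroma score at row ",
         scored_normal[1], call. = FALSE)
  }
  out
}

#' Derive a region grouping from metadata
#'
#' Maps each region to a comparison group: the morphology class, or the
#' score-defined groups `M1`-`M3` (mucin) / `S1`-`S3` (stroma). Regions
#' without the relevant score are excluded from score-based groupings.
#'
#' @param metadata Region metadata tibble (see [read_region_table()]).
#' @param variable `"morphology"`, `"mucin"` or `"stroma"`.
#' @return Tibble with columns `region` and `group`.
#' @export
derive_groups <- function(metadata,
                          variable = c("morphology", "mucin", "stroma")) {
  variable <- match.arg(variable)
  stopifnot(is.data.frame(metadata),
            all(c("region", "morphology") %in% names(metadata)))
  switch(variable,
    morphology = tibble::tibble(region = metadata$region,
                                group = metadata$morphology),
    mucin = {
      keep <- !is.na(metadata$mucin)
      tibble::tibble(region = metadata$region[keep],
                     group = paste0("M", metadata$mucin[keep]))
    },
    stroma = {
      keep <- !is.na(metadata$stroma)
      tibble::tibble(region = metadata$region[keep],
                     group = paste0("S", metadata$stroma[keep]))
    }
  )
}

#' Read a feature-by-region quantification matrix
#'
#' The first column holds unique feature identifiers; remaining columns
#' are regions. For protein (LFQ) matrices zeros denote non-detections
#' and are converted to missing, following the label-free convention;
#' for GAG amount tables zeros are genuine zero amounts and are kept.
#' GAG analyte labels must be parseable Lawrence codes or `+`-joined
#' composites and are normalised on read.
#'
#' @param path File path (TSV or CSV).
#' @param kind `"protein"` or `"gag"`.
#' @return Wide quantification tibble (`feature` + one column per region).
#' @export
read_quant_matrix <- function(path, kind = c("protein", "gag")) {
  kind <- match.arg(kind)
  raw <- read_delim_auto(path)
  if (ncol(raw) < 2) stop("quantification matrix needs at least 2 columns",
                          call. = FALSE)
  feature <- as.character(raw[[1]])
  if (anyDuplicated(feature)) {
    stop("duplicate feature identifier(s): ",
         paste(unique(feature[duplicated(feature)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                     v[bad[1]], bad[1], names(vals)[j]), call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(as.data.frame(vals))
  if (kind == "protein") {
    m[!is.na(m) & m == 0] <- NA
  } else {
    feature <- normalize_analyte_label(feature)
    analyte_info(unique(feature))  # errors on unparseable labels
  }
  dplyr::bind_cols(tibble::tibble(feature = feature),
                   tibble::as_tibble(m))
}

#' Convert between wide GAG matrices and long profile tables
#'
#' @param matrix Wide tibble (`feature` column of analyte labels + one
#'   column per region).
#' @return Long tibble with `region`, `analyte`, `amount`.
#' @export
gag_matrix_to_long <- function(matrix) {
  tidyr::pivot_longer(matrix, -"feature", names_to = "region",
                      values_to = "amount") |>
    dplyr::transmute(region = .data$region, analyte = .data$feature,
                     amount = .data$amount)
}

#' @rdname gag_matrix_to_long
#' @param profiles Long tibble with `region`, `analyte`, `amount`.
#' @export
gag_long_to_matrix <- function(profiles) {
  tidyr::pivot_wider(
    dplyr::transmute(profiles, feature = .data$analyte,
                     region = .data$region, amount = .data$amount),
    names_from = "region", values_from = "amount"
  )
}

#' Write a table as TSV
#'
#' Thin wrapper over [readr::write_tsv()] used for all pipeline outputs.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' Path to a bundled example data file
#'
#' @param file File name under the package's `extdata`, e.g.
#'   `"regions.tsv"` (the transcribed cohort region-annotation table).
#'   With no argument, lists the available files.
#' @return File path (or vector of file names).
#' @export
gagomics_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "gagomics"))
  } else {
    system.file("extdata", file, package = "gagomics", mustWork = TRUE)
  }
}
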