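#' Calibrate peak areas to molar amounts
#'
#' Converts integrated chromatographic peak areas into pmol amounts using
#' per-analyte response factors (area per pmol) from external disaccharide
#' standards. Without a response-factor table all factors default to 1, so
#' areas pass through as amounts; a message notes this.
#'
#' @param areas Data frame with columns `analyte` and `area`; any other
#'   columns (e.g. `region`) are carried through.
#' @param response_factors Optional data frame with columns `analyte` and
#'   `response_factor` (area per pmol, must be positive for every analyte
#'   with a nonzero area).
#' @return A tibble like `areas` with an added `amount` column (pmol) and
#'   normalised analyte labels.
#' @export
calibrate_areas <- function(areas, response_factors = NULL) {
  stopifnot(is.data.frame(areas), all(c("analyte", "area") %in% names(areas)))
  if (any(is.na(areas$area)) || any(areas$area < 0)) {
    stop("peak areas must be non-negative and non-missing", call. = FALSE)
  }
  out <- tibble::as_tibble(areas)
  out$analyte <- normalize_analyte_label(out$analyte)
  if (is.null(response_factors)) {
    message("no response-factor table supplied; assuming 1 area unit per pmol")
    out$amount <- out$area
    return(out)
  }
  stopifnot(is.data.frame(response_factors),
            all(c("analyte", "response_factor") %in% names(response_factors)))
  rf <- tibble::as_tibble(response_factors)
  rf$analyte <- normalize_analyte_label(rf$analyte)
  out <- dplyr::left_join(out, rf[, c("analyte", "response_factor")],
                          by = "analyte")
  bad <- out$area > 0 &
    (is.na(out$response_factor) | out$response_factor <= 0)
  if (any(bad)) {
    stop("missing or non-positive response factor for analyte(s) with ",
         "nonzero area: ", paste(unique(out$analyte[bad]), collapse = ", "),
         call. = FALSE)
  }
  out$amount <- ifelse(out$area == 0, 0, out$area / out$response_factor)
  out$response_factor <- NULL
  out
}

# Attach gag_class / sulfate-count columns to a long amounts table and
# validate amounts. Long layout: one row per (grouping cols ..., analyte).
annotate_profile <- function(profiles) {
  stopifnot(is.data.frame(profiles),
            all(c("analyte", "amount") %in% names(profiles)))
  out <- tibble::as_tibble(profiles)
  out$analyte <- normalize_analyte_label(out$analyte)
  if (any(is.na(out$amount)) || any(out$amount < 0)) {
    stop("analyte amounts must be non-negative and non-missing", call. = FALSE)
  }
  out <- out[, setdiff(names(out), c("gag_class", "n_count", "o_count",
                                     "total_sulfates")), drop = FALSE]
  info <- analyte_info(unique(out$analyte))
  dplyr::left_join(
    out,
    info[, c("label", "gag_class", "n_count", "o_count", "total_sulfates")],
    by = c(analyte = "label")
  )
}

#' Relative disaccharide composition
#'
#' Expresses amounts as percentages of the per-profile total, where a
#' profile is one region and GAG class.
#'
#' @param profiles Long data frame with columns `analyte`, `amount` and the
#'   grouping columns in `by` (default `region`; the GAG class is derived
#'   from the analyte label and always added to the grouping).
#' @param by Character vector of grouping columns defining one profile.
#' @return Tibble with `rel_pct` added; `NA` (with a warning) for profiles
#'   whose total amount is zero.
#' @export
relative_abundance <- function(profiles, by = "region") {
  ann <- annotate_profile(profiles)
  stopifnot(all(by %in% names(ann)))
  grp <- c(by, "gag_class")
  out <- ann |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(rel_pct = if (sum(.data$amount) > 0) {
      100 * .data$amount / sum(.data$amount)
    } else NA_real_) |>
    dplyr::ungroup()
  if (anyNA(out$rel_pct)) {
    warning("profile(s) with zero total amount: relative abundances undefined",
            call. = FALSE)
  }
  out
}

#' Sulfation summary statistics per profile
#'
#' For each region and GAG class computes the total molar amount, the
#' average rate of sulfation (mole-fraction-weighted sulfate groups per
#' disaccharide, between 0 and 3), the 6S/4S ratio (CS: D0a6 over D0a4)
#' and the mono-, di- and total N/O sulfation ratios (HS). Ratios with a
#' zero denominator, and all statistics of an empty (zero-total) profile,
#' are reported as `NA` with a warning, never as zero or infinity.
#'
#' The N/O ratios count sulfate groups rather than disaccharide molecules:
#' the monosulfated stratum compares D0S0 against D2A0+D0A6, the
#' disulfated stratum compares the N-sulfate of D2S0+D0S6 against its one
#' O-sulfate plus the two O-sulfates of D2A6, and the total ratio tallies
#' N versus O sulfate groups across the whole profile (so the trisulfated
#' D2S6 contributes 1 N and 2 O). This convention is the only one under
#' which composite co-eluting peaks are unambiguous.
#'
#' @inheritParams relative_abundance
#' @return Tibble with one row per profile: grouping columns, `gag_class`,
#'   `n_analytes`, `total_pmol`, `avg_sulfation`, `ratio_6s4s` (CS only),
#'   `no_mono`, `no_di`, `no_total` (HS only).
#' @examples
#' p <- tibble::tibble(region = "r1",
#'                     analyte = c("D0a0", "D0a4"),
#'                     amount = c(3, 1))
#' summarize_profiles(p)
#' @export
summarize_profiles <- function(profiles, by = "region") {
  ann <- annotate_profile(profiles)
  stopifnot(all(by %in% names(ann)))
  dup <- ann |>
    dplyr::count(dplyr::across(dplyr::all_of(c(by, "analyte")))) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate analyte labels within a profile: ",
         paste(unique(dup$analyte), collapse = ", "), call. = FALSE)
  }
  ann |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "gag_class")))) |>
    dplyr::group_modify(~ summarize_one_profile(.x, .y$gag_class)) |>
    dplyr::ungroup()
}

summarize_one_profile <- function(df, cls) {
  df$gag_class <- cls
  total <- sum(df$amount)
  if (total == 0) {
    warning("profile with zero total amount: sulfation statistics undefined",
            call. = FALSE)
    return(tibble::tibble(
      n_analytes = nrow(df), total_pmol = 0, avg_sulfation = NA_real_,
      ratio_6s4s = NA_real_, no_mono = NA_real_, no_di = NA_real_,
      no_total = NA_real_
    ))
  }
  frac <- df$amount / total
  avg <- sum(frac * df$total_sulfates)
  r64 <- if (cls == "CS") ratio_6s4s(df, warn = FALSE) else NA_real_
  no <- if (cls == "HS") no_ratios(df, warn = FALSE) else {
    tibble::tibble(no_mono = NA_real_, no_di = NA_real_, no_total = NA_real_)
  }
  tibble::tibble(
    n_analytes = nrow(df), total_pmol = total, avg_sulfation = avg,
    ratio_6s4s = r64, no_mono = no$no_mono, no_di = no$no_di,
    no_total = no$no_total
  )
}

amount_of <- function(df, label) {
  hit <- df$analyte == label
  if (any(hit)) sum(df$amount[hit]) else 0
}

#' 6S/4S ratio of a CS profile
#'
#' Molar ratio of the 6-O-monosulfated (D0a6) to the 4-O-monosulfated
#' (D0a4) chondroitin sulfate disaccharide.
#'
#' @param profile Data frame with columns `analyte` and `amount` describing
#'   a single CS profile; analytes absent from the table count as zero.
#' @param warn Emit a warning when the ratio is undefined (D0a4 amount 0).
#' @return A single number, or `NA` when D0a4 is absent or zero.
#' @export
ratio_6s4s <- function(profile, warn = TRUE) {
  df <- if (all(c("gag_class") %in% names(profile))) profile else
    annotate_profile(profile)
  if (any(df$gag_class != "CS")) {
    stop("ratio_6s4s is defined for CS profiles only", call. = FALSE)
  }
  d4 <- amount_of(df, "D0a4")
  d6 <- amount_of(df, "D0a6")
  if (d4 == 0) {
    if (warn) warning("6S/4S ratio undefined: D0a4 amount is zero",
                      call. = FALSE)
    return(NA_real_)
  }
  d6 / d4
}

#' N/O sulfation ratios of an HS profile
#'
#' Ratios of N-sulfate to O-sulfate group content in a heparan sulfate
#' profile, per sulfation stratum and in total (see
#' [summarize_profiles()] for the counting convention).
#'
#' @param profile Data frame with columns `analyte` and `amount` describing
#'   a single HS profile.
#' @param warn Emit warnings for ratios with zero denominators.
#' @return One-row tibble with `no_mono`, `no_di`, `no_total`; undefined
#'   ratios are `NA`.
#' @export
no_ratios <- function(profile, warn = TRUE) {
  df <- if (all(c("n_count", "o_count") %in% names(profile))) profile else
    annotate_profile(profile)
  if (any(df$gag_class != "HS")) {
    stop("no_ratios is defined for HS profiles only", call. = FALSE)
  }
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      if (warn) warning("N/O ", what, " ratio undefined: zero denominator",
                        call. = FALSE)
      NA_real_
    } else num / den
  }
  mono_n <- amount_of(df, "D0S0")
  mono_o <- amount_of(df, "D2A0+D0A6")
  di_s <- amount_of(df, "D2S0+D0S6")
  di_o2 <- amount_of(df, "D2A6")
  tot_n <- sum(df$amount * df$n_count)
  tot_o <- sum(df$amount * df$o_count)
  tibble::tibble(
    no_mono = safe_ratio(mono_n, mono_o, "monosulfated"),
    no_di = safe_ratio(di_s, di_s + 2 * di_o2, "disulfated"),
    no_total = safe_ratio(tot_n, tot_o, "total")
  )
}
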