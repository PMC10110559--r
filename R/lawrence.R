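#' Lawrence codes recognised by the package
#'
#' The twelve lyase-generated disaccharides commonly quantified in
#' chondroitin sulfate (CS) and heparan sulfate (HS) disaccharide analysis.
#' Lowercase third character ("a", GalNAc) marks a CS code; uppercase
#' ("A" = GlcNAc, "S" = GlcN-NS) marks an HS code.
#'
#' @format Character vector of canonical codes.
#' @export
lawrence_codes <- c(
  "D0a0", "D0a4", "D0a6", "D0a10",
  "D0A0", "D0S0", "D2A0", "D0A6", "D2S0", "D0S6", "D2A6", "D2S6"
)

#' Parse Lawrence disaccharide codes
#'
#' Decodes the compact Lawrence nomenclature for Delta-unsaturated GAG
#' disaccharides: `"D"` for the unsaturated uronic acid, a digit for its
#' 2-O-sulfation (`0` none, `2` sulfated), a hexosamine letter
#' (`a` GalNAc/CS, `A` GlcNAc/HS, `S` N-sulfated GlcN/HS; parsing is
#' case-sensitive) and trailing digits for the O-sulfation of the
#' hexosamine (`0` none, `4` 4-O, `6` 6-O, `10` 4-O + 6-O).
#'
#' @param codes Character vector of Lawrence codes, e.g. `"D0a4"`, `"D2S6"`.
#' @return A tibble with one row per code: `code`, `gag_class` (`"CS"` or
#'   `"HS"`), `hexosamine`, `uronic_2S`, `n_sulfated`, `o_positions`
#'   (list-column of character vectors drawn from `"2-O"`, `"4-O"`,
#'   `"6-O"`), `n_count`, `o_count` and `total_sulfates`.
#' @examples
#' parse_lawrence_code(c("D0a4", "D2S6"))
#' @export
parse_lawrence_code <- function(codes) {
  stopifnot(is.character(codes), length(codes) >= 1)
  rows <- lapply(codes, parse_one_code)
  dplyr::bind_rows(rows)
}

parse_one_code <- function(code) {
  if (!is.character(code) || length(code) != 1 || is.na(code) || !nzchar(code)) {
    stop("Lawrence code must be a non-empty string", call. = FALSE)
  }
  m <- regmatches(code, regexec("^D([02])([aAS])(0|4|6|10)$", code))[[1]]
  if (length(m) == 0) {
    stop(sprintf("cannot parse Lawrence code '%s': expected D<0|2><a|A|S><0|4|6|10>",
                 code), call. = FALSE)
  }
  uronic_2S <- m[2] == "2"
  hex_letter <- m[3]
  gag_class <- if (hex_letter == "a") "CS" else "HS"
  hexosamine <- switch(hex_letter, a = "GalNAc", A = "GlcNAc", S = "GlcN-NS")
  n_sulfated <- hex_letter == "S"
  o_pos <- switch(m[4], "0" = character(), "4" = "4-O", "6" = "6-O",
                  "10" = c("4-O", "6-O"))
  if (uronic_2S) o_pos <- c("2-O", o_pos)
  tibble::tibble(
    code = code,
    gag_class = gag_class,
    hexosamine = hexosamine,
    uronic_2S = uronic_2S,
    n_sulfated = n_sulfated,
    o_positions = list(o_pos),
    n_count = as.integer(n_sulfated),
    o_count = length(o_pos),
    total_sulfates = as.integer(n_sulfated) + length(o_pos)
  )
}

#' Build analyte descriptors from Lawrence codes
#'
#' An analyte is one quantified chromatographic species: either a single
#' disaccharide or a pair of co-eluting isomers reported as one peak
#' (e.g. `"D2A0+D0A6"`). Co-eluting members must belong to the same GAG
#' class and carry identical N- and O-sulfate counts, otherwise the
#' sulfation accounting of the composite peak would be ambiguous.
#'
#' @param codes Character vector of member Lawrence codes (length 1 or 2),
#'   or a single composite label such as `"D2A0+D0A6"` (spaces around the
#'   `+` are tolerated and normalised away).
#' @return One-row tibble: `label` (canonical, `+`-joined), `gag_class`,
#'   `members` (list-column), `n_count`, `o_count`, `total_sulfates`
#'   (all per disaccharide).
#' @examples
#' build_analyte(c("D2A0", "D0A6"))
#' build_analyte("D2S0 + D0S6")
#' @export
build_analyte <- function(codes) {
  stopifnot(is.character(codes), length(codes) >= 1)
  if (length(codes) == 1 && grepl("+", codes, fixed = TRUE)) {
    codes <- strsplit(gsub(" ", "", codes), "+", fixed = TRUE)[[1]]
  }
  if (length(codes) < 1 || length(codes) > 2) {
    stop("an analyte has 1 or 2 member codes, got ", length(codes),
         call. = FALSE)
  }
  parsed <- parse_lawrence_code(codes)
  if (dplyr::n_distinct(parsed$gag_class) > 1) {
    stop("co-eluting members must share a GAG class: ",
         paste(codes, collapse = " vs "), call. = FALSE)
  }
  if (dplyr::n_distinct(parsed$n_count) > 1 ||
      dplyr::n_distinct(parsed$o_count) > 1) {
    stop("co-eluting members must carry identical (N, O) sulfate counts: ",
         paste(sprintf("%s (N=%d, O=%d)", parsed$code, parsed$n_count,
                       parsed$o_count), collapse = " vs "),
         call. = FALSE)
  }
  tibble::tibble(
    label = paste(codes, collapse = "+"),
    gag_class = parsed$gag_class[1],
    members = list(codes),
    n_count = parsed$n_count[1],
    o_count = parsed$o_count[1],
    total_sulfates = parsed$total_sulfates[1]
  )
}

#' Describe a set of analyte labels
#'
#' Vectorised companion of [build_analyte()]: accepts plain Lawrence codes
#' and `+`-joined composite labels and returns one descriptor row per label.
#'
#' @param labels Character vector of analyte labels.
#' @return Tibble with one row per label (see [build_analyte()]).
#' @export
analyte_info <- function(labels) {
  stopifnot(is.character(labels))
  dplyr::bind_rows(lapply(labels, function(l) {
    hit <- .analyte_cache[[l]]
    if (is.null(hit)) {
      hit <- build_analyte(l)
      assign(l, hit, envir = .analyte_cache)
    }
    hit
  }))
}

.analyte_cache <- new.env(parent = emptyenv())

#' Canonical analyte panels used in CS/HS disaccharide analysis
#'
#' @param gag_class `"CS"`, `"HS"` or `"both"`.
#' @return Character vector of analyte labels, composites `+`-joined.
#' @export
default_analytes <- function(gag_class = c("both", "CS", "HS")) {
  gag_class <- match.arg(gag_class)
  cs <- c("D0a0", "D0a4", "D0a6", "D0a10")
  hs <- c("D0A0", "D0S0", "D2A0+D0A6", "D2S0+D0S6", "D2A6", "D2S6")
  switch(gag_class, CS = cs, HS = hs, both = c(cs, hs))
}

normalize_analyte_label <- function(labels) {
  gsub(" ", "", labels, fixed = TRUE)
}
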