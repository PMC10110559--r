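#' Configuration for the synthetic region-cohort generator
#'
#' Bundles every knob of the synthetic data model. Defaults emulate a
#' small FFPE lung-adenocarcinoma cohort profiled region by region: 22
#' regions from 7 patients, morphology-dependent increases in total CS
#' and HS amounts, a shift toward O-sulfation in tumor regions, and
#' log-normal label-free protein intensities with planted fold changes
#' and two-component missingness.
#'
#' The normal-tissue GAG baselines are chosen so that the derived
#' statistics of a noise-free normal profile sit at the values typical of
#' adjacent normal lung (CS 6S/4S about 0.9; HS mono/di/total N/O ratios
#' 0.34 / 0.89 / 0.53). Tumor groups modify the baseline through the
#' `total_multiplier` (amount fold change per morphology), a
#' `sulfated_boost` reweighting sulfated analytes, a morphology-specific
#' `shift_6s4s` acting on D0a6, and an `n_penalty` down-weighting
#' N-sulfated HS analytes (the N-to-O shift).
#'
#' @param seed Integer seed; all generators derive their randomness from it.
#' @param n_patients Number of patients.
#' @param regions_per_patient Integer vector (recycled to `n_patients`)
#'   of regions per patient; the default yields 22 regions.
#' @param morphology_probs Named sampling probabilities over
#'   `normal`, `solid`, `tubular`, `papillary`.
#' @param mucin_present,stroma_present Probability that a tumor region
#'   carries a mucin / stroma score (normal regions never do).
#' @param gag_baseline Named list `CS`/`HS` of normal-tissue analyte
#'   fractions (each summing to 1).
#' @param gag_base_total Named vector: normal-tissue total pmol per class.
#' @param total_multiplier Named list `CS`/`HS` of per-morphology total
#'   amount multipliers.
#' @param sulfated_boost Named vector `CS`/`HS`: tumor reweighting factor
#'   for sulfated analytes.
#' @param shift_6s4s Named per-morphology multiplier on the D0a6 weight.
#' @param n_penalty Tumor down-weighting factor for N-sulfated HS analytes.
#' @param n_proteins Number of proteins in the LFQ matrix.
#' @param de_fraction Fraction of proteins with a planted tumor effect.
#' @param de_fc_range Range the planted fold changes are drawn from
#'   (log-uniform); about half are inverted to model down-regulation.
#' @param de_down_fraction Fraction of planted effects that are decreases.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise (both omics layers).
#' @param missing_mcar Probability of a missing-completely-at-random
#'   dropout per protein measurement.
#' @param censor_quantile Quantile of the log-intensity distribution used
#'   as the soft detection threshold (left-censoring component).
#' @param censor_width Width (log2 units) of the soft censoring curve.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_patients = 7,
    regions_per_patient = c(2, 2, 5, 3, 4, 3, 3),
    morphology_probs = c(normal = 4, solid = 10, tubular = 3,
                         papillary = 5) / 22,
    mucin_present = 0.5,
    stroma_present = 0.85,
    gag_baseline = list(
      CS = c(D0a0 = 0.78, D0a4 = 0.105, D0a6 = 0.095, D0a10 = 0.02),
      HS = c(D0A0 = 0.425, D0S0 = 0.102, `D2A0+D0A6` = 0.300,
             `D2S0+D0S6` = 0.144, D2A6 = 0.009, D2S6 = 0.020)
    ),
    gag_base_total = c(CS = 20, HS = 10),
    total_multiplier = list(
      CS = c(normal = 1, solid = 2.5, papillary = 4.0, tubular = 4.4),
      HS = c(normal = 1, solid = 2.5, papillary = 4.8, tubular = 8.5)
    ),
    sulfated_boost = c(CS = 20, HS = 3),
    shift_6s4s = c(normal = 1, solid = 1.36, tubular = 1.47, papillary = 1),
    n_penalty = 4,
    n_proteins = 300,
    de_fraction = 0.1,
    de_fc_range = c(2, 4),
    de_down_fraction = 0.5,
    noise_cv = 0.2,
    missing_mcar = 0.05,
    censor_quantile = 0.15,
    censor_width = 0.5) {
  cfg <- as.list(environment())
  probs <- c(cfg$morphology_probs, cfg$mucin_present, cfg$stroma_present,
             cfg$missing_mcar, cfg$censor_quantile)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$morphology_probs) - 1) > 1e-8) {
    stop("morphology_probs must sum to 1", call. = FALSE)
  }
  for (cls in names(cfg$gag_baseline)) {
    if (abs(sum(cfg$gag_baseline[[cls]]) - 1) > 1e-8) {
      stop("gag_baseline$", cls, " fractions must sum to 1", call. = FALSE)
    }
  }
  if (any(unlist(cfg$total_multiplier) <= 0) || any(cfg$sulfated_boost <= 0) ||
      cfg$n_penalty <= 0) {
    stop("effect multipliers must be positive", call. = FALSE)
  }
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

#' Generate synthetic region metadata
#'
#' Emulates a region-annotation table: region and patient identifiers,
#' morphological class, and semiquantitative mucin and stroma scores
#' (1 low, 2 medium, 3 high). Normal regions never carry scores; tumor
#' regions carry a score with the configured probability.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with columns `region`, `patient`, `morphology`,
#'   `mucin`, `stroma` (scores are integer or `NA`).
#' @export
generate_metadata <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  rpp <- rep_len(config$regions_per_patient, config$n_patients)
  n <- sum(rpp)
  if (n == 0) {
    return(tibble::tibble(region = character(), patient = character(),
                          morphology = character(), mucin = integer(),
                          stroma = integer()))
  }
  patient <- rep(paste0("P", seq_len(config$n_patients)), rpp)
  morphology <- sample(names(config$morphology_probs), n, replace = TRUE,
                       prob = config$morphology_probs)
  tumor <- morphology != "normal"
  score <- function(present_p) {
    ifelse(tumor & stats::runif(n) < present_p,
           sample(1:3, n, replace = TRUE), NA_integer_)
  }
  tibble::tibble(
    region = paste0("R", seq_len(n)),
    patient = patient,
    morphology = morphology,
    mucin = as.integer(score(config$mucin_present)),
    stroma = as.integer(score(config$stroma_present))
  )
}

# Expected (noise-free) analyte composition of one morphology group.
group_composition <- function(config, gag_class, morphology) {
  base <- config$gag_baseline[[gag_class]]
  info <- analyte_info(names(base))
  w <- base
  if (morphology != "normal") {
    boost <- config$sulfated_boost[[gag_class]]
    w <- w * ifelse(info$total_sulfates > 0, boost, 1)
    if (gag_class == "CS" && "D0a6" %in% names(w)) {
      w["D0a6"] <- w["D0a6"] * config$shift_6s4s[[morphology]]
    }
    if (gag_class == "HS") {
      w <- w * ifelse(info$n_count > 0, 1 / config$n_penalty, 1)
    }
  }
  w / sum(w)
}

#' Generate synthetic GAG disaccharide profiles
#'
#' For each region and GAG class, expected analyte amounts are the
#' group-level composition times the group total-amount multiplier times
#' the class base total; observed amounts add mean-preserving
#' multiplicative log-normal noise with the configured CV.
#'
#' @param config A [synthetic_config()].
#' @param metadata Region metadata, e.g. from [generate_metadata()].
#' @return List with `amounts` (long tibble: `region`, `gag_class`,
#'   `analyte`, `amount`) and `truth` (list: `expected` per-group expected
#'   amounts, `total_multiplier`, `groups` region-to-group table).
#' @export
generate_gag_dataset <- function(config, metadata) {
  stopifnot(inherits(config, "synthetic_config"),
            is.data.frame(metadata))
  set.seed(config$seed + 1L)
  s <- sqrt(log(1 + config$noise_cv^2))
  expected <- purrr::map_dfr(names(config$gag_baseline), function(cls) {
    purrr::map_dfr(unique(metadata$morphology), function(m) {
      comp <- group_composition(config, cls, m)
      tibble::tibble(
        group = m, gag_class = cls, analyte = names(comp),
        expected_amount = unname(comp) * config$gag_base_total[[cls]] *
          config$total_multiplier[[cls]][[m]]
      )
    })
  })
  amounts <- purrr::map_dfr(seq_len(nrow(metadata)), function(i) {
    exp_i <- expected[expected$group == metadata$morphology[i], ]
    noise <- exp(stats::rnorm(nrow(exp_i), -s^2 / 2, s))
    tibble::tibble(
      region = metadata$region[i],
      gag_class = exp_i$gag_class,
      analyte = exp_i$analyte,
      amount = exp_i$expected_amount * noise
    )
  })
  list(
    amounts = amounts,
    truth = list(
      expected = expected,
      total_multiplier = config$total_multiplier,
      groups = tibble::tibble(region = metadata$region,
                              group = metadata$morphology)
    )
  )
}

#' Generate a synthetic label-free protein quantification matrix
#'
#' Protein baselines are drawn on the log2-intensity scale; planted
#' differentially abundant proteins are multiplied by their fold change
#' in every tumor region (morphology other than `"normal"`); values
#' receive multiplicative log-normal noise, then two-component
#' missingness: missing-completely-at-random dropouts plus soft
#' left-censoring below a detection threshold (low intensities are more
#' likely missing).
#'
#' @param config A [synthetic_config()].
#' @param metadata Region metadata, e.g. from [generate_metadata()].
#' @return List with `matrix` (wide tibble: `feature` + one column per
#'   region, `NA` = not quantified) and `truth` (tibble: `feature`,
#'   `is_de`, `fold_change` — tumor over normal, 1 for null proteins).
#' @export
generate_protein_dataset <- function(config, metadata) {
  stopifnot(inherits(config, "synthetic_config"),
            is.data.frame(metadata), nrow(metadata) > 0)
  set.seed(config$seed + 2L)
  np <- config$n_proteins
  nr <- nrow(metadata)
  s <- sqrt(log(1 + config$noise_cv^2))
  base_log2 <- stats::rnorm(np, mean = 25, sd = 2)
  n_de <- round(config$de_fraction * np)
  is_de <- c(rep(TRUE, n_de), rep(FALSE, np - n_de))
  fc <- rep(1, np)
  if (n_de > 0) {
    lo <- log(config$de_fc_range[1])
    hi <- log(config$de_fc_range[2])
    fc[is_de] <- exp(stats::runif(n_de, lo, hi))
    down <- stats::runif(n_de) < config$de_down_fraction
    fc[is_de][down] <- 1 / fc[is_de][down]
  }
  tumor <- metadata$morphology != "normal"
  expected <- outer(2^base_log2, rep(1, nr))
  expected[, tumor] <- expected[, tumor, drop = FALSE] * fc
  noise <- matrix(exp(stats::rnorm(np * nr, -s^2 / 2, s)), np, nr)
  intensity <- expected * noise
  li <- log2(intensity)
  if (config$censor_quantile > 0) {
    thresh <- stats::quantile(li, config$censor_quantile)
    p_censor <- stats::plogis((thresh - li) / config$censor_width)
  } else {
    p_censor <- matrix(0, np, nr)
  }
  miss <- matrix(stats::runif(np * nr), np, nr) < p_censor |
    matrix(stats::runif(np * nr), np, nr) < config$missing_mcar
  intensity[miss] <- NA_real_
  mat <- tibble::as_tibble(as.data.frame(intensity))
  names(mat) <- metadata$region
  mat <- dplyr::bind_cols(
    tibble::tibble(feature = sprintf("PROT%04d", seq_len(np))), mat)
  list(
    matrix = mat,
    truth = tibble::tibble(feature = mat$feature, is_de = is_de,
                           fold_change = fc)
  )
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper chaining [generate_metadata()],
#' [generate_gag_dataset()] and [generate_protein_dataset()].
#'
#' @param config A [synthetic_config()].
#' @return List with `metadata`, `gag` and `protein` components.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  metadata <- generate_metadata(config)
  list(
    metadata = metadata,
    gag = generate_gag_dataset(config, metadata),
    protein = generate_protein_dataset(config, metadata)
  )
}
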