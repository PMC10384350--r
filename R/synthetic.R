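# Synthetic fixtures: random grammar-valid glycosides, simulated CID
# spectra with a simple noise model, and an additive retention-time
# heuristic encoding the observed chromatographic trends.

#' Retention-time model coefficients
#'
#' An additive reversed-phase retention model. Only the signs of the
#' coefficients are constrained by the observed chromatographic trends
#' (sulfation, side-chain oxygenation and extra monosaccharides shorten
#' retention; acetoxy groups, the 18(20)-lactone and side-chain
#' saturation lengthen it); the magnitudes are free parameters chosen to
#' keep predictions within the observed 4.3-18.9 min elution window.
#'
#' @param intercept Baseline retention (min).
#' @param sulf_first,sulf_extra Effect of the first / each additional
#'   sulfate (min; negative).
#' @param acetoxy Per acetoxy group (positive).
#' @param lac18_20,lac18_16 Lactone-cycle effects (positive).
#' @param extra_unit Per monosaccharide beyond four (negative).
#' @param branch Branched chain (negative).
#' @param sidechain_oxy Oxygen-bearing side chain beyond the acetoxy
#'   (OH, =O at R2-R4; negative).
#' @param saturated Fully saturated side chain (positive).
#' @param rt_range Clipping window (min).
#' @return A list of class `rt_model`.
#' @export
rt_model <- function(intercept = 12, sulf_first = -0.3, sulf_extra = -1.2,
                     acetoxy = 1.5, lac18_20 = 1.3, lac18_16 = 0.4,
                     extra_unit = -0.25, branch = -0.4, sidechain_oxy = -1.8,
                     saturated = 0.8, rt_range = c(4.3, 18.9)) {
  structure(
    list(
      intercept = intercept, sulf_first = sulf_first, sulf_extra = sulf_extra,
      acetoxy = acetoxy, lac18_20 = lac18_20, lac18_16 = lac18_16,
      extra_unit = extra_unit, branch = branch, sidechain_oxy = sidechain_oxy,
      saturated = saturated, rt_range = rt_range
    ),
    class = "rt_model"
  )
}

#' Predict retention time of a glycoside
#'
#' Deterministic additive model (see [rt_model()]); predictions are
#' clipped to the model's elution window.
#'
#' @param g A [glycoside()].
#' @param model An [rt_model()].
#' @return Predicted retention time in minutes.
#' @export
predict_rt <- function(g, model = rt_model()) {
  g <- validate_glycoside(g)
  ns <- sum(g$glycan$sulfated)
  a <- g$aglycon
  rt <- model$intercept +
    (ns >= 1) * model$sulf_first + max(ns - 1, 0) * model$sulf_extra +
    a$n_acetoxy * model$acetoxy +
    switch(a$lactone, lac18_20 = model$lac18_20, lac18_16 = model$lac18_16, 0) +
    max(nrow(g$glycan) - 4, 0) * model$extra_unit +
    (length(unique(g$glycan$branch)) > 1) * model$branch
  if (!is.na(a$side_chain_class)) {
    row <- side_chain_classes() |> filter(.data$class_id == a$side_chain_class)
    oxy <- any(unlist(row[, c("r2", "r3", "r4")]) %in% c("OH", "=O"))
    rt <- rt + oxy * model$sidechain_oxy +
      (row$double_bonds == "sat") * model$saturated
  }
  min(max(rt, model$rt_range[1]), model$rt_range[2])
}

#' Simulation configuration
#'
#' @param noise_sigma_mz Gaussian m/z error (Da) added to every true
#'   fragment peak.
#' @param spurious_peak_fraction Fraction of additional uniformly placed
#'   noise peaks, relative to the number of true peaks.
#' @param intensity_base Named base intensities per ion-type group.
#' @param intensity_log_sd Log-normal intensity jitter (sd on the log
#'   scale).
#' @param rt_sigma Gaussian retention-time error (min).
#' @param rt_for_tetrasulfated If `FALSE` (default), tetrasulfated
#'   records get `NA` retention times: their reversed-phase elution is
#'   not reproducible and such standards are measured by direct
#'   injection.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(noise_sigma_mz = 0, spurious_peak_fraction = 0,
                       intensity_base = c(
                         precursor = 25, Y = 100, B = 60, C = 20, Z = 20,
                         secondary = 35, sulfate = 45, diagnostic = 50,
                         sidechain = 25, A02 = 15
                       ),
                       intensity_log_sd = 0.3, rt_sigma = 0.05,
                       rt_for_tetrasulfated = FALSE) {
  stopifnot(spurious_peak_fraction >= 0, spurious_peak_fraction <= 1)
  structure(
    list(
      noise_sigma_mz = noise_sigma_mz,
      spurious_peak_fraction = spurious_peak_fraction,
      intensity_base = intensity_base, intensity_log_sd = intensity_log_sd,
      rt_sigma = rt_sigma, rt_for_tetrasulfated = rt_for_tetrasulfated
    ),
    class = "sim_config"
  )
}

.ion_group <- function(ion_type) {
  dplyr::case_when(
    ion_type == "precursor" ~ "precursor",
    ion_type %in% c("Y", "B", "C", "Z", "A02") ~ ion_type,
    startsWith(ion_type, "loss_HSO4") | startsWith(ion_type, "loss_SO3") ~ "sulfate",
    startsWith(ion_type, "diagnostic") ~ "diagnostic",
    startsWith(ion_type, "sidechain") ~ "sidechain",
    TRUE ~ "secondary"
  )
}

#' Generate a random grammar-valid glycoside
#'
#' Draws a structure obeying the natural-product grammar: xylose as the
#' first (aglycon-attached) unit, methylated monosaccharides only in
#' terminal positions, 2-6 units with an optional branch at the first or
#' second main-chain unit, and 0-4 sulfates. Chain-length and
#' sulfate-count frequencies follow the composition of the reference
#' compound collection (biosides are rare, tetraosides the mode;
#' non-sulfated and monosulfated compounds dominate). When a structure
#' is sulfated, the first sulfate is placed on the root xylose (the
#' predominant natural motif); additional sulfates go on random other
#' units. The aglycon gets a random neutral mass in 450-600 Da, a
#' lactone state, an acetoxy count consistent with its side-chain class,
#' and one of the 13 catalogued side-chain classes. Uses the current R
#' random-number stream: set a seed for reproducibility.
#'
#' @param name Compound name to assign.
#' @return A [glycoside()] (grammar-validated).
#' @export
generate_structure <- function(name = "synthetic") {
  n_units <- sample(2:6, 1, prob = c(2, 3, 76, 65, 45))
  branch_len <- 0L
  if (n_units >= 5 && stats::runif(1) < 0.6) {
    branch_len <- sample(1:min(2, n_units - 4), 1)
  }
  main_len <- n_units - branch_len

  terminal_pool <- c("MeGlc", "MeXyl", "Glc", "Qui", "Xyl")
  terminal_prob <- c(0.35, 0.25, 0.2, 0.1, 0.1)
  interior_pool <- c("Qui", "Glc", "Xyl")
  interior_prob <- c(0.4, 0.4, 0.2)

  main_codes <- c(
    "Xyl",
    if (main_len > 2) sample(interior_pool, main_len - 2, replace = TRUE,
                             prob = interior_prob),
    if (main_len > 1) sample(terminal_pool, 1, prob = terminal_prob)
  )
  units <- tibble(
    unit = seq_len(main_len), code = main_codes,
    parent = c(NA_integer_, seq_len(main_len - 1)),
    sulfated = FALSE, branch = "main"
  )
  if (branch_len > 0) {
    anchor <- sample(1:2, 1)
    bcodes <- c(
      if (branch_len > 1) sample(interior_pool, branch_len - 1, replace = TRUE,
                                 prob = interior_prob),
      sample(terminal_pool, 1, prob = terminal_prob)
    )
    units <- dplyr::bind_rows(units, tibble(
      unit = main_len + seq_len(branch_len), code = bcodes,
      parent = c(anchor, if (branch_len > 1) main_len + seq_len(branch_len - 1)),
      sulfated = FALSE, branch = "b1"
    ))
  }

  n_sulf <- sample(0:4, 1, prob = c(61, 55, 43, 23, 9))
  n_sulf <- min(n_sulf, n_units)
  if (n_sulf >= 1) {
    units$sulfated[1] <- TRUE  # root xylose, the predominant natural motif
    if (n_sulf >= 2) {
      extra <- sample(units$unit[-1], n_sulf - 1)
      units$sulfated[units$unit %in% extra] <- TRUE
    }
  }

  cls <- side_chain_classes()
  cl <- cls[sample(nrow(cls), 1), ]
  n_acetoxy <- as.integer(cl$r1 == "OAc") + stats::rbinom(1, 1, 0.15)
  lac <- sample(c("lac18_20", "lac18_16", "none"), 1, prob = c(0.78, 0.09, 0.13))

  glycoside(
    name = name,
    aglycon = aglycon(
      mass = stats::runif(1, 450, 600), lactone = lac, n_acetoxy = n_acetoxy,
      side_chain_class = cl$class_id
    ),
    glycan = glycan_tree(units),
    species = "synthetic", grammar = TRUE
  )
}

#' Simulate a CID spectrum for a glycoside
#'
#' Generates the theoretical fragment set ([theoretical_spectrum()],
#' monoisotopic mode) and turns it into a peak list: ion-type-dependent
#' base intensities with log-normal jitter, Gaussian m/z error, and a
#' configurable fraction of spurious uniform peaks. Retention time comes
#' from [predict_rt()] plus Gaussian error. With zero noise and zero
#' spurious fraction the peak m/z set equals the theoretical set
#' exactly. Per-peak charge states are retained (`peak_charge`).
#'
#' The random draws are arranged so that, at a fixed RNG seed, the same
#' standard-normal errors underlie every noise level: spectra simulated
#' at increasing `noise_sigma_mz` from the same seed are nested
#' perturbations of the same ideal spectrum.
#'
#' @param g A [glycoside()].
#' @param config A [sim_config()].
#' @param rtm An [rt_model()].
#' @param ... Passed to [theoretical_spectrum()].
#' @return An [ms_spectrum()] with per-peak charges.
#' @export
simulate_spectrum <- function(g, config = sim_config(), rtm = rt_model(), ...) {
  g <- validate_glycoside(g)
  frags <- theoretical_spectrum(g, mode = "mono", ...)
  prec <- attr(frags, "precursor")
  n <- nrow(frags)

  base <- config$intensity_base[.ion_group(frags$ion_type)]
  base[is.na(base)] <- 10
  jitter <- exp(stats::rnorm(n, 0, config$intensity_log_sd))
  eps <- stats::rnorm(n)
  mz <- frags$mz + config$noise_sigma_mz * eps

  n_spur <- round(config$spurious_peak_fraction * n)
  spur_mz <- stats::runif(max(n_spur, 1), 100, prec$mz * prec$charge)[seq_len(n_spur)]
  spur_int <- stats::runif(max(n_spur, 1), 1, 25)[seq_len(n_spur)]

  rt_eps <- stats::rnorm(1, 0, config$rt_sigma)
  rt <- if (prec$n_sulfates >= 4 && !config$rt_for_tetrasulfated) {
    NA_real_
  } else {
    predict_rt(g, rtm) + rt_eps
  }

  ms_spectrum(
    mz = c(mz, spur_mz),
    intensity = c(as.numeric(base) * jitter, spur_int),
    peak_charge = c(frags$charge, rep(1L, n_spur)),
    precursor_mz = prec$mz, charge = prec$charge, polarity = "negative",
    rt = rt, id = g$name,
    metadata = list(NAME = g$name, ADDUCT = prec$adduct)
  )
}

#' Simulate a paired structure set and spectral library
#'
#' Draws `n` grammar-valid structures and simulates one spectrum each;
#' fully deterministic for a fixed seed (byte-identical MGF output).
#'
#' @param n Number of compounds.
#' @param seed Integer seed.
#' @param config A [sim_config()].
#' @param ... Passed to [simulate_spectrum()].
#' @return A list with `structures` (list of glycosides) and `spectra`
#'   (list of [ms_spectrum()]).
#' @export
simulate_library <- function(n, seed = 1L, config = sim_config(), ...) {
  set.seed(seed)
  structures <- purrr::map(seq_len(n), function(i) {
    generate_structure(name = sprintf("syn_%03d", i))
  })
  spectra <- purrr::map(structures, simulate_spectrum, config = config, ...)
  list(structures = structures, spectra = spectra)
}
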