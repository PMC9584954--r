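# Standard amino-acid residue masses (Da). Average masses follow the
# ExPASy compute-pI/MW table; monoisotopic masses follow Unimod.
RESIDUE_MASS_AVG <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
RESIDUE_MASS_MONO <- c(
  A = 71.037114,  R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, E = 129.042593, Q = 128.058578, G = 57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P = 97.052764,  S = 87.032028,
  T = 101.047679, W = 186.079313, Y = 163.063329, V = 99.068414
)
WATER_MASS_AVG <- 18.01528
WATER_MASS_MONO <- 18.010565

#' Native-MS configuration
#'
#' @param proton_mass_da Mass of the charge carrier in Da. Defaults to the
#'   physical proton mass; set to 1 to reproduce the integer-proton
#'   deconvolution formula `mass = (m/z)*z - z` exactly (at ~288 kDa the
#'   difference is ~2 Da, far below the 0.1 kDa reporting precision).
#' @param tolerance_da Absolute mass tolerance (Da) for stoichiometry
#'   matching; if `NULL`, `tolerance_rel` is used instead.
#' @param tolerance_rel Relative mass tolerance for stoichiometry matching,
#'   as a fraction of the observed mass (default 0.001, i.e. 0.1%).
#' @param mass_mode `"average"` (intact complexes) or `"monoisotopic"`
#'   (peptide-level work) residue masses for [sequence_mass()].
#' @param max_charge Largest charge considered by [infer_charges()].
#' @param max_mass_cv Largest relative standard deviation of the implied
#'   masses accepted by [infer_charges()] before the series is declared
#'   non-consecutive.
#' @param max_compositions Cap on the enumeration size of
#'   [match_stoichiometry()].
#'
#' @return A list of class `mass_config`.
#' @export
mass_config <- function(proton_mass_da = 1.007276,
                        tolerance_da = NULL,
                        tolerance_rel = 0.001,
                        mass_mode = c("average", "monoisotopic"),
                        max_charge = 100L,
                        max_mass_cv = 1e-3,
                        max_compositions = 1e6) {
  mass_mode <- match.arg(mass_mode)
  stopifnot(proton_mass_da > 0, tolerance_rel > 0,
            is.null(tolerance_da) || tolerance_da > 0)
  structure(
    list(proton_mass_da = proton_mass_da, tolerance_da = tolerance_da,
         tolerance_rel = tolerance_rel, mass_mode = mass_mode,
         max_charge = as.integer(max_charge), max_mass_cv = max_mass_cv,
         max_compositions = max_compositions),
    class = "mass_config"
  )
}

#' Neutral mass of one charge-state peak
#'
#' Converts an electrospray peak at m/z `mz` carrying charge `z` to the
#' neutral mass `z * mz - z * m_proton`, i.e. the observed ion mass minus
#' its charge-carrying protons.
#'
#' @param mz m/z in Thomson (vectorized).
#' @param z Positive integer charge (vectorized, recycled against `mz`).
#' @param config A [mass_config()].
#' @return Neutral mass(es) in Da.
#' @export
#' @examples
#' peak_mass(10301, 28, mass_config(proton_mass_da = 1))  # 288400
peak_mass <- function(mz, z, config = mass_config()) {
  if (missing(z) || is.null(z) || any(is.na(z))) {
    stop("charge 'z' is required; use infer_charges() on a raw m/z series")
  }
  stopifnot(all(mz > 0), all(z >= 1), all(z == round(z)))
  z * mz - z * config$proton_mass_da
}

#' Deconvolute a charge-state series into a mass estimate
#'
#' Each (m/z, z) peak is converted to a neutral mass with [peak_mass()];
#' the reported mass is the mean across peaks, with the sample (n-1)
#' standard deviation as its dispersion (0 for a single peak).
#'
#' @param peaks Data frame with columns `mz` and `z`.
#' @param config A [mass_config()].
#' @return A list of class `mass_estimate`: `mean_da`, `sd_da`, `n_peaks`.
#' @export
deconvolve_series <- function(peaks, config = mass_config()) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) == 0L) stop("empty peak list")
  if (!all(c("mz", "z") %in% names(peaks)) || any(is.na(peaks$z))) {
    stop("all peaks need a charge; use infer_charges() first")
  }
  masses <- peak_mass(peaks$mz, peaks$z, config)
  structure(
    list(mean_da = mean(masses),
         sd_da = if (length(masses) > 1L) stats::sd(masses) else 0,
         n_peaks = length(masses)),
    class = "mass_estimate"
  )
}

#' @export
format.mass_estimate <- function(x, ...) {
  sprintf("mass %.1f +/- %.1f Da (n = %d peaks)",
          x$mean_da, x$sd_da, x$n_peaks)
}

#' @export
print.mass_estimate <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Infer charges for a consecutive charge-state series
#'
#' Automates manual charge-state assignment for a series of peaks assumed
#' to be consecutive charge states of a single species. The spacing of an
#' adjacent pair fixes the charge of the lower-m/z peak,
#' `z = round((mz_high - m_proton) / (mz_high - mz_low))`; candidate
#' consecutive assignments around that estimate are scored by the relative
#' standard deviation of the implied neutral masses, and the
#' minimum-variance assignment is returned. If even the best assignment
#' leaves the implied masses dispersed beyond `config$max_mass_cv`
#' (relative), the peaks are not a consecutive series of one species and an
#' error is raised.
#'
#' @param mzs Numeric vector of m/z values (any order; >= 2 values).
#' @param config A [mass_config()].
#' @return Data frame with columns `mz` (descending) and `z` (ascending
#'   consecutive charges).
#' @export
infer_charges <- function(mzs, config = mass_config()) {
  if (length(mzs) < 2L) {
    stop("charge inference needs at least 2 peaks of a series")
  }
  stopifnot(all(mzs > 0))
  mzs <- sort(mzs, decreasing = TRUE)
  n <- length(mzs)
  p <- config$proton_mass_da
  z_top_est <- round((mzs[1L] - p) / (mzs[1L] - mzs[2L])) - 1L
  cand <- seq(max(1L, z_top_est - 3L), min(config$max_charge, z_top_est + 3L))
  score <- vapply(cand, function(z0) {
    zz <- z0 + 0:(n - 1L)
    m <- zz * mzs - zz * p
    stats::sd(m) / mean(m)
  }, numeric(1))
  best <- cand[which.min(score)]
  if (min(score) > config$max_mass_cv) {
    stop(sprintf(paste0(
      "peaks do not form a consecutive charge-state series: best ",
      "assignment (z = %d..%d) leaves relative mass dispersion %.2g ",
      "(limit %.2g)"), best, best + n - 1L, min(score), config$max_mass_cv))
  }
  data.frame(mz = mzs, z = best + 0:(n - 1L))
}

#' Mass of a protein sequence
#'
#' Sum of residue masses (average or monoisotopic per
#' `config$mass_mode`) plus one water, plus any modification deltas.
#'
#' @param sequence Protein sequence over the 20-letter amino-acid alphabet
#'   (an empty string yields the water mass).
#' @param config A [mass_config()].
#' @param modifications Optional data frame with columns `position`,
#'   `delta_da`; deltas are summed onto the mass.
#' @return Mass in Da.
#' @export
#' @examples
#' sequence_mass("G")   # glycine + water, ~75.07 Da
sequence_mass <- function(sequence, config = mass_config(),
                          modifications = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  tab <- if (config$mass_mode == "average") RESIDUE_MASS_AVG
         else RESIDUE_MASS_MONO
  water <- if (config$mass_mode == "average") WATER_MASS_AVG
           else WATER_MASS_MONO
  aa <- strsplit(sequence, "")[[1L]]
  known <- aa %in% names(tab)
  if (!all(known)) {
    stop(sprintf("unknown residue '%s' at position %d",
                 aa[!known][1L], which(!known)[1L]))
  }
  m <- sum(tab[aa]) + water
  if (!is.null(modifications) && nrow(modifications) > 0L) {
    if (any(modifications$position < 1L |
              modifications$position > length(aa))) {
      stop("modification position outside the sequence")
    }
    m <- m + sum(modifications$delta_da)
  }
  m
}

#' Component specification table for stoichiometry matching
#'
#' @param name Component names (e.g. `"alpha"`, `"beta"`, `"h"`,
#'   `"gamma"`, `"f430"`).
#' @param mass_da Component masses in Da.
#' @param min_count,max_count Copy-number bounds per component.
#' @param group Optional group labels; components sharing a label are
#'   jointly constrained by `group_sums`.
#' @return Data frame of class `component_spec`.
#' @export
component_spec <- function(name, mass_da, min_count, max_count,
                           group = NA_character_) {
  stopifnot(all(mass_da > 0), all(min_count >= 0),
            all(min_count <= max_count))
  structure(
    data.frame(name = name, mass_da = mass_da,
               min_count = as.integer(min_count),
               max_count = as.integer(max_count),
               group = group, stringsAsFactors = FALSE),
    class = c("component_spec", "data.frame")
  )
}

#' Assign complex stoichiometries to an observed mass
#'
#' Enumerates every copy-number vector within the per-component bounds of
#' `components`, discards vectors violating the group-sum constraints,
#' keeps those whose total mass lies within the matching tolerance of the
#' observed mass, and ranks the survivors by absolute mass deviation
#' (ties broken lexicographically on the count vector, so the ranking is
#' deterministic).
#'
#' A group-sum constraint expresses interchangeable occupancy of a slot:
#' e.g. tagged and untagged gamma subunits sharing one "G-slot" group with
#' required sum 2 means the complex carries exactly two gamma subunits in
#' any tagged/untagged combination.
#'
#' @param observed A `mass_estimate` (from [deconvolve_series()]) or a
#'   single numeric mass in Da.
#' @param components A [component_spec()] table.
#' @param config A [mass_config()]; its `tolerance_da`/`tolerance_rel`
#'   define the matching window and `max_compositions` caps the
#'   enumeration.
#' @param group_sums Named integer vector of required group sums, e.g.
#'   `c(G = 2)`.
#' @return Data frame ranked best-first: one column per component count,
#'   plus `total_mass_da` and `delta_da` (observed - total). Zero rows if
#'   nothing matches.
#' @export
match_stoichiometry <- function(observed, components,
                                config = mass_config(),
                                group_sums = NULL) {
  obs <- if (inherits(observed, "mass_estimate")) observed$mean_da
         else as.numeric(observed)
  stopifnot(length(obs) == 1L, obs > 0, nrow(components) >= 1L)
  n_comb <- prod(components$max_count - components$min_count + 1)
  if (n_comb > config$max_compositions) {
    stop("composition space has ", format(n_comb, big.mark = ","),
         " candidates; tighten the per-component bounds")
  }
  grid <- do.call(expand.grid, c(
    stats::setNames(
      Map(seq, components$min_count, components$max_count),
      components$name),
    KEEP.OUT.ATTRS = FALSE
  ))
  if (!is.null(group_sums)) {
    for (g in names(group_sums)) {
      members <- components$name[!is.na(components$group) &
                                   components$group == g]
      if (length(members) == 0L) stop("group '", g, "' has no members")
      ok <- rowSums(grid[, members, drop = FALSE]) == group_sums[[g]]
      grid <- grid[ok, , drop = FALSE]
    }
  }
  if (nrow(grid) == 0L) return(.empty_composition(components))
  total <- as.matrix(grid) %*% components$mass_da[
    match(names(grid), components$name)]
  tol <- config$tolerance_da %||% (config$tolerance_rel * obs)
  delta <- obs - total[, 1L]
  keep <- abs(delta) <= tol
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L) return(.empty_composition(components))
  out <- cbind(grid, total_mass_da = total[keep, 1L],
               delta_da = delta[keep])
  ord <- do.call(order, c(list(abs(out$delta_da)),
                          out[, components$name, drop = FALSE]))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_composition <- function(components) {
  out <- as.data.frame(stats::setNames(
    rep(list(integer()), nrow(components)), components$name))
  out$total_mass_da <- numeric()
  out$delta_da <- numeric()
  out
}
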