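#' Default dinucleotide photoreactivity weights
#'
#' Relative propensities of the four dipyrimidine classes to form each
#' photoproduct type under UV. Only the relative structure matters: the
#' absolute scale is always set by [calibrate_scale()] against a target CPD
#' density. Defaults follow the literature-typical rank orders (CPDs form
#' preferentially at TT, 6-4PPs at TC).
#'
#' @return list with `cpd` and `pp64` named weight vectors over
#'   TT/TC/CT/CC.
#' @export
default_photoproduct_weights <- function() {
  list(cpd = c(TT = 1.0, TC = 0.5, CT = 0.25, CC = 0.1),
       pp64 = c(TT = 0.3, TC = 1.0, CT = 0.1, CC = 0.05))
}

#' Dipyrimidine site set a fragment exposes on one strand
#'
#' For terminal (smeary) fragments the nominal set extends to the
#' population-mean telomere length, matching the mean length stored in
#' `fragment$length_kb`.
#'
#' @param locus a `subtelomere_locus`.
#' @param fragment one-row fragment from [digest()].
#' @param strand `"C-rich"` or `"G-rich"`.
#' @return site table as from [scan_dipyrimidine_sites()].
#' @export
fragment_sites <- function(locus, fragment, strand) {
  stopifnot(nrow(fragment) == 1)
  hi <- fragment$end
  if (isTRUE(fragment$terminal) && !is.null(locus$telomere)) {
    hi <- locus$telomere$start + round(locus$telomere$mean) - 1L
  }
  scan_dipyrimidine_sites(locus, strand, region = c(fragment$start, hi))
}

#' Per-site lesion probabilities at a UV dose
#'
#' Linear-dose model: the probability that site i carries a CPD is
#' `min(alpha * dose * w_cpd(dinuc_i), 1)`, and similarly for 6-4PPs with a
#' scale chosen so that total 6-4PP yield is `1/cpd64_ratio` of total CPD
#' yield over the site set. Probabilities of the two photoproduct types at
#' one site are capped to sum to at most 1 (at most one lesion per site per
#' molecule).
#'
#' @param sites site table from [scan_dipyrimidine_sites()] or
#'   [fragment_sites()].
#' @param dose UV dose (J/m^2); the study design uses 180.
#' @param alpha probability scale per (J/m^2 x weight), usually from
#'   [calibrate_scale()].
#' @param weights see [default_photoproduct_weights()].
#' @param cpd64_ratio total CPD : 6-4PP yield ratio (default 3).
#' @param length_kb fragment length in kb used for density computations.
#' @return a `lesion_profile` object.
#' @export
lesion_probabilities <- function(sites, dose, alpha,
                                 weights = default_photoproduct_weights(),
                                 cpd64_ratio = 3, length_kb = NULL) {
  stopifnot(dose >= 0, alpha >= 0, all(unlist(weights) >= 0))
  w_cpd <- unname(weights$cpd[sites$dinuc])
  w_64 <- unname(weights$pp64[sites$dinuc])
  raw_cpd <- alpha * dose * w_cpd
  if (any(raw_cpd > 1)) {
    warning("lesion probabilities saturate (alpha * dose * w > 1) at ",
            sum(raw_cpd > 1), " site(s)")
  }
  p_cpd <- pmin(raw_cpd, 1)
  sum64 <- sum(w_64)
  alpha_64 <- if (cpd64_ratio > 0 && sum64 > 0) {
    alpha * sum(w_cpd) / (cpd64_ratio * sum64)
  } else 0
  p_64 <- pmin(alpha_64 * dose * w_64, 1)
  p_64 <- pmin(p_64, 1 - p_cpd)
  structure(list(sites = sites, dose = dose, alpha = alpha,
                 alpha_64 = alpha_64, weights = weights,
                 cpd64_ratio = cpd64_ratio,
                 p_cpd = as.numeric(p_cpd), p_64 = as.numeric(p_64),
                 length_kb = length_kb),
            class = "lesion_profile")
}

#' Calibrate the lesion scale to a target CPD density
#'
#' Closed-form calibration in the linear (unsaturated) regime: with
#' `p_i = alpha * dose * w_i`, the expected density `sum(p_i) / L` equals
#' `target_density` when `alpha = target_density * L / (dose * sum(w_i))`.
#'
#' @param sites site table for the fragment strand being calibrated.
#' @param dose UV dose (J/m^2).
#' @param length_kb fragment length L (kb).
#' @param target_density target expected CPD density (CPD/kb), e.g. the 0-h
#'   densities printed for the Y' Southern fragments.
#' @param weights see [default_photoproduct_weights()].
#' @return the scale `alpha`.
#' @export
calibrate_scale <- function(sites, dose, length_kb, target_density,
                            weights = default_photoproduct_weights()) {
  stopifnot(target_density >= 0, length_kb > 0)
  if (target_density == 0) return(0)
  if (nrow(sites) == 0) {
    stop("cannot calibrate: fragment has no dipyrimidine sites on this strand",
         call. = FALSE)
  }
  if (dose <= 0) stop("cannot calibrate at zero dose", call. = FALSE)
  sw <- sum(weights$cpd[sites$dinuc])
  alpha <- target_density * length_kb / (dose * sw)
  if (alpha * dose * max(weights$cpd[sites$dinuc]) > 1) {
    stop("target density unreachable without saturating site probabilities",
         call. = FALSE)
  }
  alpha
}

#' Expected photoproduct density of a profile
#'
#' @param profile a `lesion_profile`.
#' @param type `"CPD"` or `"6-4PP"`.
#' @param length_kb fragment length (kb); defaults to the profile's.
#' @return expected lesions per kb.
#' @export
expected_density <- function(profile, type = c("CPD", "6-4PP"),
                             length_kb = NULL) {
  type <- match.arg(type)
  L <- length_kb %||% profile$length_kb
  stopifnot(!is.null(L), L > 0)
  if (nrow(profile$sites) == 0) {
    warning("empty fragment: density is 0")
    return(0)
  }
  p <- if (type == "CPD") profile$p_cpd else profile$p_64
  sum(p) / L
}

#' Sample per-molecule lesion configurations
#'
#' Each site of each molecule is independently lesioned with its profile
#' probability; at most one lesion (of one type) per site per molecule. The
#' return is a sparse table: one row per lesion.
#'
#' @param profile a `lesion_profile`.
#' @param n_molecules number of molecules (>= 1).
#' @param seed integer seed.
#' @return a `molecule_lesions` data.frame with columns `molecule`,
#'   `site` (row index into `profile$sites`), `pos`, `top_lo`, `strand`,
#'   `type`; attributes `n_molecules` and `profile`.
#' @export
sample_molecule_lesions <- function(profile, n_molecules, seed) {
  stopifnot(n_molecules >= 1)
  sites <- profile$sites
  p_tot <- profile$p_cpd + profile$p_64
  with_seed(seed, {
    rows <- vector("list", nrow(sites))
    active <- which(p_tot > 0)
    for (i in active) {
      k <- stats::rbinom(1, n_molecules, p_tot[i])
      if (k == 0) next
      mols <- sample.int(n_molecules, k)
      is_cpd <- stats::runif(k) < profile$p_cpd[i] / p_tot[i]
      rows[[i]] <- data.frame(molecule = mols, site = i,
                              type = ifelse(is_cpd, "CPD", "6-4PP"),
                              stringsAsFactors = FALSE)
    }
    out <- if (any(!vapply(rows, is.null, logical(1)))) {
      do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    } else {
      data.frame(molecule = integer(), site = integer(), type = character())
    }
    out$pos <- sites$pos[out$site]
    out$top_lo <- sites$top_lo[out$site]
    out$strand <- sites$strand[out$site]
    out <- out[order(out$molecule, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    structure(out, n_molecules = as.integer(n_molecules),
              profile = profile, class = c("molecule_lesions", "data.frame"))
  })
}
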