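#' Gel noise configuration
#'
#' Multiplicative lognormal band noise (sdlog `band_sigma`, median 1) plus a
#' per-lane lognormal loading factor (sdlog `loading_sigma`). With both at 0
#' the simulator is deterministic given the molecule population.
#'
#' @param band_sigma,loading_sigma log-scale standard deviations.
#' @return list with the two sigmas.
#' @export
noise_config <- function(band_sigma = 0.1, loading_sigma = 0.15) {
  stopifnot(band_sigma >= 0, loading_sigma >= 0)
  list(band_sigma = band_sigma, loading_sigma = loading_sigma)
}

new_dataset <- function(lanes, assay, strain, replicate, locus,
                        provenance = list()) {
  structure(list(lanes = lanes, assay = assay, strain = strain,
                 replicate = replicate, locus_name = locus$name,
                 provenance = provenance),
            class = "time_course_dataset")
}

#' @export
print.time_course_dataset <- function(x, ...) {
  cat(sprintf("<time_course_dataset> %s | strain %s | replicate %s | %d lanes\n",
              x$assay, x$strain, as.character(x$replicate),
              length(unique(x$lanes$lane_id))))
  invisible(x)
}

# Zero-CPD probability per molecule at repair time t. For terminal
# fragments, returns a per-molecule vector given sampled telomere tract
# lengths `telo_len`; only CPDs count (T4 endo-V does not nick 6-4PPs).
zero_cpd_prob <- function(locus, profile, rates, t, telo_len = NULL) {
  p <- profile$p_cpd * exp(-rates * t)
  sites <- profile$sites
  if (is.null(telo_len) || is.null(locus$telomere)) {
    return(prod(1 - p))
  }
  rep_start <- locus$telomere$start
  in_rep <- sites$top_hi >= rep_start
  q_core <- prod(1 - p[!in_rep])
  if (!any(in_rep)) return(rep(q_core, length(telo_len)))
  ord <- order(sites$top_hi[in_rep])
  rep_hi <- sites$top_hi[in_rep][ord]
  cumlog <- cumsum(log1p(-p[in_rep][ord]))
  idx <- findInterval(rep_start + telo_len - 1L, rep_hi)
  q_core * exp(c(0, cumlog)[idx + 1L])
}

sample_telomere_lengths <- function(locus, n) {
  tl <- locus$telomere
  if (is.null(tl)) return(NULL)
  round(rtrunc_norm(n, tl$mean, tl$sd, tl$bounds[1], tl$bounds[2]))
}

#' Simulate T4 endonuclease V Southern lanes for one fragment
#'
#' For each repair time, DNA of one aliquot is split into a mock lane (band
#' intensity proportional to all molecules) and a +T4 lane (band intensity
#' proportional to molecules with zero CPDs on the probed strand: any CPD is
#' nicked and the molecule leaves the full-length band). 6-4PPs are never
#' cut. Terminal fragments run as a smear; their intensity integrates all
#' molecules regardless of sampled telomere length into one band value. A
#' -UV lane pair (zero-lesion population) is always included.
#'
#' Because molecules are independent and identically distributed, the
#' zero-CPD count is drawn exactly as Binomial(n, prod(1 - p_i(t))) (per
#' sampled telomere length for terminal fragments); `method = "molecule"`
#' instead samples every molecule's lesion set explicitly and gives the
#' same distribution (used as a cross-check).
#'
#' @param locus a `subtelomere_locus`.
#' @param fragment one-row fragment with `probed_strand` set
#'   ([assign_probe_strand()]).
#' @param profile `lesion_profile` over the fragment's probed-strand sites.
#' @param rate_model a `repair_rate_model`.
#' @param times repair times in hours (0 must be included for downstream
#'   percent-repair analysis).
#' @param n_molecules molecules per lane (>= 100 recommended).
#' @param noise see [noise_config()].
#' @param seed integer seed.
#' @param method `"binomial"` (exact shortcut, default) or `"molecule"`.
#' @return a `time_course_dataset`.
#' @export
simulate_t4v_lanes <- function(locus, fragment, profile, rate_model,
                               times = c(0, 0.5, 1, 2, 4), n_molecules,
                               noise = noise_config(), seed,
                               method = c("binomial", "molecule")) {
  method <- match.arg(method)
  stopifnot(nrow(fragment) == 1)
  if (is.na(fragment$probed_strand)) {
    stop("fragment must have probed_strand set", call. = FALSE)
  }
  if (n_molecules < 100) {
    warning("n_molecules < 100: zero-class estimator variance will be high")
  }
  rates <- site_rates(rate_model, profile$sites)
  strain <- rate_model$strain
  is_term <- isTRUE(fragment$terminal)

  lane_rows <- list()
  emit <- function(treatment, time, channel, count, lane_seed) {
    with_seed(lane_seed, {
      loading <- lognormal_noise(1, noise$loading_sigma)
      eps <- lognormal_noise(1, noise$band_sigma)
    })
    lane_rows[[length(lane_rows) + 1L]] <<- data.frame(
      lane_id = paste(strain, "t4v", fragment$name, fragment$probed_strand,
                      treatment, format(time), channel, sep = "|"),
      assay = "t4v", strain = strain, treatment = treatment, time = time,
      channel = channel, band = fragment$name,
      intensity = loading * count * eps, count = count,
      probed_strand = fragment$probed_strand,
      length_kb = fragment$length_kb, stringsAsFactors = FALSE)
  }

  zero_class_count <- function(t, aliquot_seed) {
    with_seed(aliquot_seed, {
      if (method == "binomial") {
        telo <- if (is_term) sample_telomere_lengths(locus, n_molecules)
        q0 <- zero_cpd_prob(locus, profile, rates, t, telo)
        if (length(q0) == 1) {
          stats::rbinom(1, n_molecules, q0)
        } else {
          sum(stats::runif(n_molecules) < q0)
        }
      } else {
        mols <- sample_molecule_lesions(profile, n_molecules,
                                        seed = derive_seed(aliquot_seed, "mol"))
        mols <- apply_repair(mols, rate_model, t,
                             seed = derive_seed(aliquot_seed, "rep"))
        cpd <- mols[mols$type == "CPD", , drop = FALSE]
        if (is_term) {
          telo <- sample_telomere_lengths(locus, n_molecules)
          lim <- locus$telomere$start + telo[cpd$molecule] - 1L
          cpd <- cpd[cpd$top_lo + 1L <= lim |
                       cpd$top_lo < locus$telomere$start, , drop = FALSE]
        }
        n_molecules - length(unique(cpd$molecule))
      }
    })
  }

  # -UV pair: unirradiated aliquot, no lesions at all.
  emit("-UV", NA_real_, "mock", n_molecules, derive_seed(seed, "noUV", "mock"))
  emit("-UV", NA_real_, "t4v", n_molecules, derive_seed(seed, "noUV", "t4v"))
  for (t in times) {
    n0 <- zero_class_count(t, derive_seed(seed, strain, t, "aliquot"))
    emit("+UV", t, "mock", n_molecules, derive_seed(seed, strain, t, "mock"))
    emit("+UV", t, "t4v", n0, derive_seed(seed, strain, t, "t4v"))
  }
  lanes <- do.call(rbind, lane_rows)
  new_dataset(lanes, "t4v", strain, NA_integer_, locus,
              provenance = list(seed = seed, n_molecules = n_molecules,
                                times = times, noise = noise,
                                fragment = fragment$name, method = method))
}

#' Default natural polymerase-arrest sites for an extension window
#'
#' Natural stops are sequence features where Taq polymerase pauses even on
#' undamaged templates; they appear in -UV lanes. Positions are drawn
#' deterministically from the window given the seed.
#'
#' @param window result of [primer_extension_window()].
#' @param n number of stops.
#' @param prob per-encounter stop probability (default 0.02).
#' @param seed integer seed.
#' @return data.frame with `top` (top-strand coordinate) and `prob`.
#' @export
default_natural_stops <- function(window, n = 3, prob = 0.02, seed = 1) {
  with_seed(seed, {
    k <- min(n, length(window$path))
    data.frame(top = sort(sample(window$path, k)), prob = prob)
  })
}

#' Simulate primer-extension (polymerase stop) lanes
#'
#' Per molecule, extension proceeds from the primer 3' end along the
#' template and terminates at the first event encountered: a template
#' photoproduct (CPD or 6-4PP; blockage probability 1), a natural stop
#' (with its own probability), or the fragment end (full-length band). Band
#' intensity at a position is proportional to the number of molecules
#' stopping there. -UV lanes are generated from a zero-lesion population
#' and carry only natural stops and full-length signal.
#'
#' @param locus a `subtelomere_locus`.
#' @param primer list from [make_primer()].
#' @param profile `lesion_profile` over the window's template-strand sites.
#' @param rate_model a `repair_rate_model`.
#' @param times repair times (hours).
#' @param n_molecules molecules per lane.
#' @param natural_stops data.frame `top`/`prob`
#'   (see [default_natural_stops()]); may have zero rows.
#' @param noise see [noise_config()].
#' @param seed integer seed.
#' @param enzymes enzymes defining the template fragment.
#' @return a `time_course_dataset` whose bands are keyed
#'   `stop_<template position>` (lesion stops), `ns_<template position>`
#'   (natural stops) and `full`.
#' @export
simulate_primer_extension_lanes <- function(locus, primer, profile,
                                            rate_model,
                                            times = c(0, 0.5, 1, 2, 4),
                                            n_molecules, natural_stops,
                                            noise = noise_config(), seed,
                                            enzymes) {
  win <- primer_extension_window(locus, primer, enzymes)
  strand <- win$template_strand
  sites <- profile$sites
  stopifnot(all(sites$strand == strand))
  strain <- rate_model$strain

  # Encounter index of each site along the polymerase path: the polymerase
  # meets the 3'-most template base of the dinucleotide first.
  enc_pos_site <- if (strand == "C-rich") sites$top_lo else sites$top_hi
  site_enc <- match(enc_pos_site, win$path)
  if (anyNA(site_enc)) {
    stop("profile contains sites outside the extension window", call. = FALSE)
  }
  ns <- natural_stops
  ns_enc <- match(ns$top, win$path)
  if (anyNA(ns_enc)) {
    stop("natural stops outside the extension window", call. = FALSE)
  }
  ns_own <- top_to_own(locus, strand, ns$top)
  site_own <- sites$pos
  band_keys <- c(paste0("stop_", site_own), paste0("ns_", ns_own), "full")

  simulate_lane <- function(lesions, lane_seed) {
    first_enc <- rep(Inf, n_molecules)
    if (nrow(lesions) > 0) {
      enc <- site_enc[lesions$site]
      agg <- tapply(enc, lesions$molecule, min)
      first_enc[as.integer(names(agg))] <- agg
    }
    stop_band <- rep(NA_character_, n_molecules)
    with_seed(lane_seed, {
      extending <- rep(TRUE, n_molecules)
      for (j in order(ns_enc)) {
        eligible <- extending & ns_enc[j] < first_enc
        hit <- eligible & stats::runif(n_molecules) < ns$prob[j]
        stop_band[hit] <- paste0("ns_", ns_own[j])
        extending <- extending & !hit
      }
    })
    lesion_stop <- is.finite(first_enc) & is.na(stop_band)
    if (any(lesion_stop)) {
      own_at <- site_own[match(first_enc[lesion_stop], site_enc)]
      # several sites can share an encounter index only if coincident;
      # map via first match on encounter order
      stop_band[lesion_stop] <- paste0("stop_", own_at)
    }
    stop_band[is.na(stop_band)] <- "full"
    counts <- table(factor(stop_band, levels = band_keys))
    as.integer(counts)
  }

  lane_rows <- list()
  emit <- function(treatment, time, counts, lane_seed) {
    with_seed(lane_seed, {
      loading <- lognormal_noise(1, noise$loading_sigma)
      eps <- lognormal_noise(length(counts), noise$band_sigma)
    })
    lane_rows[[length(lane_rows) + 1L]] <<- data.frame(
      lane_id = paste(strain, "ext", primer$name, treatment, format(time),
                      sep = "|"),
      assay = "primer_extension", strain = strain, treatment = treatment,
      time = time, channel = primer$name, band = band_keys,
      intensity = loading * counts * eps, count = counts,
      probed_strand = strand, length_kb = win$fragment$length_kb,
      stringsAsFactors = FALSE)
  }

  no_lesions <- data.frame(molecule = integer(), site = integer(),
                           type = character())
  emit("-UV", NA_real_,
       simulate_lane(no_lesions, derive_seed(seed, "noUV", "events")),
       derive_seed(seed, "noUV", "noise"))
  for (t in times) {
    mols <- sample_molecule_lesions(
      profile, n_molecules, seed = derive_seed(seed, strain, t, "lesions"))
    mols <- apply_repair(mols, rate_model, t,
                         seed = derive_seed(seed, strain, t, "repair"))
    emit("+UV", t, simulate_lane(mols, derive_seed(seed, strain, t, "events")),
         derive_seed(seed, strain, t, "noise"))
  }
  lanes <- do.call(rbind, lane_rows)
  new_dataset(lanes, "primer_extension", strain, NA_integer_, locus,
              provenance = list(seed = seed, n_molecules = n_molecules,
                                times = times, noise = noise,
                                primer = primer$name, enzymes = enzymes))
}
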