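#' Poisson zero-class CPD density from a mock / +T4 lane pair
#'
#' T4 endo-V nicks every CPD, so the fraction of molecules remaining in the
#' full-length band is the Poisson zero class: `I_t4 / I_mock =
#' exp(-D * L)`, giving `D = -ln(I_t4 / I_mock) / L` CPDs per kb on the
#' probed strand. Intensity ratios above 1 (noise) are clipped to density 0
#' and flagged.
#'
#' @param i_mock,i_t4 band intensities of the mock and T4-treated lanes
#'   (vectorized; both > 0).
#' @param length_kb fragment length L in kb (> 0).
#' @return densities (CPD/kb) with attribute `clipped` marking ratios > 1.
#' @export
cpd_density_from_bands <- function(i_mock, i_t4, length_kb) {
  if (any(i_mock <= 0) || any(i_t4 <= 0)) {
    stop("band intensities must be positive", call. = FALSE)
  }
  if (any(length_kb <= 0)) stop("fragment length must be positive",
                                call. = FALSE)
  ratio <- i_t4 / i_mock
  clipped <- ratio > 1
  d <- -log(pmin(ratio, 1)) / length_kb
  flag_value(d, clipped, "clipped")
}

#' Percent repair from time-0 and time-t damage levels
#'
#' `100 * (D0 - Dt) / D0`, applied to zero-class densities for the Southern
#' assay and to background-corrected band frequencies for the extension
#' assay. The 0-h value corresponds to 100% damage, i.e. exactly 0% repair.
#'
#' @param d0 damage at time 0 (density or frequency; > 0 for a defined
#'   result).
#' @param dt damage at the repair time point.
#' @return percent repair (vectorized); `NA` with attribute `undefined`
#'   where `d0 <= 0`. Negative values (noise) are reported, not clipped.
#' @export
percent_repair <- function(d0, dt) {
  undefined <- d0 <= 0
  out <- ifelse(undefined, NA_real_, 100 * (d0 - dt) / d0)
  out[!undefined & dt == d0] <- 0
  flag_value(out, undefined, "undefined")
}

#' Band frequencies within a lane
#'
#' Normalizes each band's intensity by the whole-lane signal, which cancels
#' lane loading factors by construction.
#'
#' @param lane data.frame of one lane's rows (needs `band`, `intensity`).
#' @return the lane with a frequency column `F` (sums to 1).
#' @export
band_frequencies <- function(lane) {
  total <- sum(lane$intensity)
  if (nrow(lane) == 0 || total <= 0) {
    stop("lane has no positive signal", call. = FALSE)
  }
  lane$F <- lane$intensity / total
  lane
}

#' Background-correct UV-lane band frequencies with the -UV lane
#'
#' Subtracts per band the frequency measured in the non-irradiated lane
#' (natural stops, background smear); negative differences clip to 0.
#'
#' @param f_uv,f_nouv named frequency vectors (band key -> frequency);
#'   missing keys count as 0.
#' @return corrected named frequencies over the union of keys, with
#'   attribute `clipped` naming bands clipped at 0.
#' @export
background_correct <- function(f_uv, f_nouv) {
  keys <- union(names(f_uv), names(f_nouv))
  a <- f_uv[keys]; a[is.na(a)] <- 0
  b <- f_nouv[keys]; b[is.na(b)] <- 0
  corr <- pmax(a - b, 0)
  names(corr) <- keys
  flag_value(corr, keys[(a - b) < 0], "clipped")
}

lane_freq_vector <- function(lanes, sel) {
  sub <- lanes[sel, , drop = FALSE]
  sub <- band_frequencies(sub)
  stats::setNames(sub$F, sub$band)
}

#' Percent-repair curves for every photoproduct band of extension datasets
#'
#' For each primer lane set: compute band frequencies, background-correct
#' each UV lane with the -UV lane, then convert to percent repair from the
#' 0-h frequency. Bands with non-positive 0-h corrected frequency are
#' excluded (with a message). Only photoproduct bands (`stop_*`) yield
#' curves; natural-stop and full-length bands are bookkeeping.
#'
#' @param datasets a `time_course_dataset` or list of them (replicates).
#' @return data.frame: `strain`, `replicate`, `channel` (primer), `band`,
#'   `strand`, `time`, `percent`, `f0`.
#' @export
pd_repair_curves <- function(datasets) {
  if (inherits(datasets, "time_course_dataset")) datasets <- list(datasets)
  out <- list()
  for (ds in datasets) {
    lanes <- ds$lanes[ds$lanes$assay == "primer_extension", , drop = FALSE]
    if (nrow(lanes) == 0) next
    for (ch in unique(lanes$channel)) {
      lch <- lanes[lanes$channel == ch, , drop = FALSE]
      if (!any(lch$treatment == "-UV") ||
          !any(lch$treatment == "+UV" & lch$time == 0)) {
        stop("dataset must contain a -UV lane and a 0-h lane", call. = FALSE)
      }
      f_nouv <- lane_freq_vector(lch, lch$treatment == "-UV")
      times <- sort(unique(lch$time[lch$treatment == "+UV"]))
      corr <- lapply(times, function(t) {
        background_correct(
          lane_freq_vector(lch, lch$treatment == "+UV" & lch$time == t),
          f_nouv)
      })
      names(corr) <- as.character(times)
      f0 <- corr[["0"]]
      pd_bands <- grep("^stop_", names(f0), value = TRUE)
      dead <- pd_bands[f0[pd_bands] <= 0]
      if (length(dead) > 0) {
        message(sprintf("excluding %d band(s) with F(0) <= 0 after correction: %s",
                        length(dead), paste(dead, collapse = ", ")))
        pd_bands <- setdiff(pd_bands, dead)
      }
      for (t in times) {
        ft <- corr[[as.character(t)]]
        pr <- percent_repair(f0[pd_bands], ft[pd_bands])
        out[[length(out) + 1L]] <- data.frame(
          strain = ds$strain, replicate = ds$replicate, channel = ch,
          band = pd_bands,
          strand = lch$probed_strand[1], time = t,
          percent = as.numeric(pr), f0 = as.numeric(f0[pd_bands]),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Zero-class density and percent-repair curve from a T4 endo-V dataset
#'
#' @param datasets a `time_course_dataset` or list of them.
#' @return data.frame: `strain`, `replicate`, `band`, `strand`, `time`,
#'   `density` (CPD/kb) and `percent` (repair relative to the 0-h density).
#' @export
t4v_repair_curves <- function(datasets) {
  if (inherits(datasets, "time_course_dataset")) datasets <- list(datasets)
  out <- list()
  for (ds in datasets) {
    lanes <- ds$lanes[ds$lanes$assay == "t4v" & ds$lanes$treatment == "+UV", ,
                      drop = FALSE]
    if (nrow(lanes) == 0) next
    lanes$key <- paste(lanes$band, lanes$probed_strand, sep = "@")
    for (key in unique(lanes$key)) {
      lb <- lanes[lanes$key == key, , drop = FALSE]
      band <- lb$band[1]
      times <- sort(unique(lb$time))
      dens <- vapply(times, function(t) {
        i_mock <- lb$intensity[lb$time == t & lb$channel == "mock"]
        i_t4 <- lb$intensity[lb$time == t & lb$channel == "t4v"]
        as.numeric(cpd_density_from_bands(i_mock, i_t4, lb$length_kb[1]))
      }, numeric(1))
      d0 <- dens[times == 0]
      out[[length(out) + 1L]] <- data.frame(
        strain = ds$strain, replicate = ds$replicate, band = band,
        strand = lb$probed_strand[1], time = times, density = dens,
        percent = as.numeric(percent_repair(rep(d0, length(times)), dens)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group photoproduct bands into positional clusters
#'
#' Bands whose template positions are within `max_gap` nucleotides of the
#' next are grouped, mirroring the vertical-bar cluster convention of
#' sequencing-gel figures; clusters are named with roman numerals in
#' positional order.
#'
#' @param positions named numeric vector: band key -> template position.
#' @param max_gap maximum within-cluster gap (nt).
#' @return named list: cluster id -> character vector of band keys.
#' @export
define_pd_clusters <- function(positions, max_gap = 10) {
  ord <- order(positions)
  pos <- positions[ord]
  breaks <- c(0, cumsum(diff(pos) > max_gap))
  groups <- split(names(pos), breaks)
  stats::setNames(groups, tolower(as.character(utils::as.roman(
    seq_along(groups)))))
}

#' Aggregate per-photoproduct repair curves into a cluster summary
#'
#' Per-time mean across member photoproducts (and replicates); the standard
#' error is reported only for clusters of at least 3 members - single- and
#' two-member clusters carry `se_defined = FALSE` and are excluded from
#' ANOVA comparisons.
#'
#' @param curves output of [pd_repair_curves()].
#' @param clusters named list: cluster id -> band keys
#'   (see [define_pd_clusters()]).
#' @return data.frame of class `cluster_summary`: `cluster`, `time`,
#'   `mean`, `se`, `n_members`, `n_values`, `se_defined`.
#' @export
aggregate_cluster <- function(curves, clusters) {
  out <- list()
  for (cl in names(clusters)) {
    members <- clusters[[cl]]
    sub <- curves[curves$band %in% members, , drop = FALSE]
    if (nrow(sub) == 0) stop(sprintf("empty cluster: %s", cl), call. = FALSE)
    n_members <- length(unique(sub$band))
    for (t in sort(unique(sub$time))) {
      v <- sub$percent[sub$time == t]
      v <- v[!is.na(v)]
      se_def <- n_members >= 3
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, time = t, mean = mean(v),
        se = if (se_def && length(v) > 1) stats::sd(v) / sqrt(length(v))
             else NA_real_,
        n_members = n_members, n_values = length(v), se_defined = se_def,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cluster_summary", "data.frame")
  res
}

#' Compare band-fraction profiles between two time points
#'
#' Two-sample Kolmogorov-Smirnov test on the per-band lane fractions of all
#' replicates at a reference and a comparison time: the no-repair control
#' (rad14 deletion) should be indistinguishable from 0 h while repairing
#' strains shift signal from photoproduct bands to full length.
#'
#' @param datasets extension `time_course_dataset`(s).
#' @param t_ref,t_cmp times to compare (hours).
#' @return `htest` from [stats::ks.test()].
#' @export
compare_timepoint_profiles <- function(datasets, t_ref = 0, t_cmp = 4) {
  if (inherits(datasets, "time_course_dataset")) datasets <- list(datasets)
  grab <- function(t) {
    unlist(lapply(datasets, function(ds) {
      lanes <- ds$lanes[ds$lanes$assay == "primer_extension" &
                          ds$lanes$treatment == "+UV" & ds$lanes$time == t, ,
                        drop = FALSE]
      unlist(lapply(split(lanes, lanes$channel), function(l)
        unname(lane_freq_vector(l, rep(TRUE, nrow(l))))))
    }))
  }
  suppressWarnings(stats::ks.test(grab(t_ref), grab(t_cmp)))
}
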