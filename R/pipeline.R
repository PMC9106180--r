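select_fragment <- function(locus, enzymes, which) {
  frags <- digest(locus, enzymes)
  frag <- if (identical(which, "terminal")) {
    frags[frags$terminal, , drop = FALSE][1, , drop = FALSE]
  } else if (identical(which, "junction")) {
    j <- junction_fragments(locus, frags)
    if (nrow(j) == 0) stop("locus has no Y'/Y' junction fragment",
                           call. = FALSE)
    j[1, , drop = FALSE]
  } else if (is.numeric(which)) {
    frags[which, , drop = FALSE]
  } else {
    frags[frags$name == which, , drop = FALSE]
  }
  if (nrow(frag) != 1 || is.na(frag$start)) {
    stop("fragment selection did not resolve to one fragment", call. = FALSE)
  }
  frag
}

#' Default study-design experiment plan for a Y' locus
#'
#' The four strand-specific Southern measurements of the study design: the
#' ~4.7 kb HindIII/EcoRI junction fragment (0-h calibration targets 0.67
#' and 0.56 CPD/kb on the C- and G-rich strand) and the 1.3 kb XhoI
#' terminal fragment (0.58 and 0.36 CPD/kb).
#'
#' @param n_molecules molecules per lane.
#' @return plan list for [run_experiment()].
#' @export
default_t4v_plan <- function(n_molecules = 10000) {
  list(
    assays = list(
      list(type = "t4v", name = "Y47_C", enzymes = c("HindIII", "EcoRI"),
           fragment = "junction", strand = "C-rich", target_density = 0.67),
      list(type = "t4v", name = "Y47_G", enzymes = c("HindIII", "EcoRI"),
           fragment = "junction", strand = "G-rich", target_density = 0.56),
      list(type = "t4v", name = "Y13_C", enzymes = "XhoI",
           fragment = "terminal", strand = "C-rich", target_density = 0.58),
      list(type = "t4v", name = "Y13_G", enzymes = "XhoI",
           fragment = "terminal", strand = "G-rich", target_density = 0.36)),
    times = c(0, 0.5, 1, 2, 4), n_molecules = n_molecules, dose = 180,
    noise = noise_config(), rates = list(k_ggr = 0.25, k_tcr = 0.33))
}

#' Default primer-extension plan for an X-element locus
#'
#' Four extension primers in the layout of the X-element assays: forward
#' primers a and b reading the C-rich strand, reverse primers c and d
#' reading the G-rich strand, each paired with the restriction digest that
#' releases its template fragment.
#'
#' @param locus an X-element `subtelomere_locus` (from [x_locus_plan()]).
#' @param n_molecules molecules per lane.
#' @param target_density photoproduct calibration target within the
#'   extension windows (CPD/kb). The default keeps the expected number of
#'   lesions per extension window low enough that first-stop shadowing
#'   (upstream lesions masking downstream bands) perturbs recovered
#'   percent-repair values by about a point or less.
#' @return plan list for [run_experiment()].
#' @export
default_extension_plan <- function(locus, n_molecules = 20000,
                                   target_density = 0.15) {
  x_start <- locus$elements$start[locus$elements$label == "XC"][1]
  if (is.na(x_start)) stop("locus has no X-element", call. = FALSE)
  primers <- list(
    a = make_primer(locus, "C-rich", c(x_start - 80L, x_start - 61L), "a"),
    b = make_primer(locus, "C-rich", c(x_start + 250L, x_start + 269L), "b"),
    c = make_primer(locus, "G-rich", c(x_start + 200L, x_start + 219L), "c"),
    d = make_primer(locus, "G-rich", c(x_start + 650L, x_start + 669L), "d"))
  enz <- list(a = "HhaI", b = "RsaI", c = "RsaI", d = "HhaI")
  assays <- lapply(names(primers), function(nm) {
    list(type = "primer_extension", name = paste0("ext_", nm),
         primer = primers[[nm]], enzymes = enz[[nm]],
         target_density = target_density)
  })
  list(assays = assays, times = c(0, 0.5, 1, 2, 4),
       n_molecules = n_molecules, dose = 180, noise = noise_config(),
       rates = list(k_ggr = 0.25, k_tcr = 0.33))
}

#' Run a full simulated repair experiment
#'
#' Orchestrates the assays of a plan over strains and replicates: builds
#' fragments/extension windows, calibrates the lesion scale per assay,
#' simulates every lane, and returns one dataset per (strain, replicate).
#' All randomness derives from named substreams of `master_seed`, so the
#' same call is bit-reproducible and adding strains or replicates never
#' perturbs existing ones.
#'
#' @param locus a `subtelomere_locus`.
#' @param strains character vector of strain names.
#' @param plan plan list (see [default_t4v_plan()],
#'   [default_extension_plan()]).
#' @param replicates number of independent replicate experiments.
#' @param master_seed integer master seed.
#' @return an `experiment_set`: list of `time_course_dataset`s with the
#'   plan and seed attached.
#' @export
run_experiment <- function(locus, strains, plan, replicates = 1,
                           master_seed) {
  noise <- do.call(noise_config, plan$noise %||% list())
  rates <- plan$rates %||% list()
  weights <- plan$weights %||% default_photoproduct_weights()
  dose <- plan$dose %||% 180
  times <- plan$times %||% c(0, 0.5, 1, 2, 4)
  nmol <- plan$n_molecules %||% 5000

  # Assay geometry and calibration are strain-independent: resolve once.
  prepared <- lapply(plan$assays, function(spec) {
    if (spec$type == "t4v") {
      frag <- select_fragment(locus, spec$enzymes, spec$fragment)
      if (!is.null(spec$probe)) {
        frag <- assign_probe_strand(locus, frag, spec$probe)
      } else {
        frag$probed_strand <- spec$strand
      }
      sites <- fragment_sites(locus, frag, frag$probed_strand)
      alpha <- calibrate_scale(sites, dose, frag$length_kb,
                               spec$target_density, weights)
      profile <- lesion_probabilities(sites, dose, alpha, weights,
                                      length_kb = frag$length_kb)
      list(spec = spec, fragment = frag, profile = profile)
    } else if (spec$type == "primer_extension") {
      win <- primer_extension_window(locus, spec$primer, spec$enzymes)
      sites <- scan_dipyrimidine_sites(locus, win$template_strand,
                                       region = range(win$path))
      alpha <- calibrate_scale(sites, dose, win$window_len / 1000,
                               spec$target_density, weights)
      profile <- lesion_probabilities(sites, dose, alpha, weights,
                                      length_kb = win$window_len / 1000)
      ns <- spec$natural_stops %||%
        default_natural_stops(win, seed = derive_seed(master_seed, "ns",
                                                      spec$name))
      list(spec = spec, window = win, profile = profile, natural_stops = ns)
    } else stop(sprintf("unknown assay type: %s", spec$type), call. = FALSE)
  })

  datasets <- list()
  for (strain in strains) {
    model <- repair_rate_model(locus, strain,
                               k_ggr = rates$k_ggr %||% 0.25,
                               k_tcr = rates$k_tcr %||% 0.33)
    for (rep_i in seq_len(replicates)) {
      lane_sets <- lapply(prepared, function(pp) {
        seed <- derive_seed(master_seed, strain, rep_i, pp$spec$name)
        if (pp$spec$type == "t4v") {
          simulate_t4v_lanes(locus, pp$fragment, pp$profile, model,
                             times = times, n_molecules = nmol,
                             noise = noise, seed = seed)$lanes
        } else {
          simulate_primer_extension_lanes(
            locus, pp$spec$primer, pp$profile, model, times = times,
            n_molecules = nmol, natural_stops = pp$natural_stops,
            noise = noise, seed = seed, enzymes = pp$spec$enzymes)$lanes
        }
      })
      ds <- new_dataset(do.call(rbind, lane_sets), "experiment", strain,
                        rep_i, locus,
                        provenance = list(master_seed = master_seed,
                                          strain = strain,
                                          replicate = rep_i))
      datasets[[length(datasets) + 1L]] <- ds
    }
  }
  structure(datasets, class = "experiment_set", plan = plan,
            master_seed = master_seed, locus_name = locus$name)
}

#' Per-replicate cluster mean curves
#'
#' Reduces per-photoproduct curves to one observation per replicate and
#' time (the mean over the cluster's member bands): the replication unit
#' entering the ANOVA comparisons, avoiding pseudo-replication of member
#' photoproducts.
#'
#' @param curves output of [pd_repair_curves()].
#' @param bands member band keys of the cluster.
#' @return data.frame with `replicate`, `time`, `percent`.
#' @export
per_replicate_cluster_means <- function(curves, bands) {
  sub <- curves[curves$band %in% bands & !is.na(curves$percent), ,
                drop = FALSE]
  out <- stats::aggregate(percent ~ replicate + time, data = sub,
                          FUN = mean)
  out[order(out$replicate, out$time), , drop = FALSE]
}

#' Simulate a configured experiment and write its dataset files
#'
#' Validates the config, builds the locus, runs [run_experiment()] and
#' writes `lanes.tsv`, `provenance.json` and locus BED annotation to
#' `out_dir`. Nothing is written when validation fails.
#'
#' @param config config list or YAML path (see [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisible list of output paths.
#' @export
cmd_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  locus <- config_to_locus(config)
  plan <- config[c("assays", "times", "n_molecules", "dose", "noise",
                   "rates", "weights")]
  exps <- run_experiment(locus, config$strains, plan,
                         replicates = config$replicates,
                         master_seed = config$master_seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(lanes = file.path(out_dir, "lanes.tsv"),
                provenance = file.path(out_dir, "provenance.json"),
                elements_bed = file.path(out_dir, "elements.bed"))
  write_lanes_tsv(exps, paths$lanes)
  write_provenance_json(
    list(master_seed = config$master_seed, strains = config$strains,
         replicates = config$replicates, times = config$times,
         n_molecules = config$n_molecules, dose = config$dose,
         noise = config$noise, rates = config$rates,
         locus = list(name = locus$name,
                      seed = config$locus$seed %||% config$master_seed)),
    paths$provenance)
  locus_bed(locus, "elements", paths$elements_bed)
  invisible(paths)
}

#' Analyze dataset files: curves, cluster summaries, strain comparisons
#'
#' Reads a lane TSV (simulated or imported densitometry), computes per-band
#' repair curves, positional cluster summaries per strain, pairwise strain
#' comparisons (two-way ANOVA + Sidak) with TCR classification, and a BED
#' track of 4-h percent repair per photoproduct position.
#'
#' @param data path to a lanes TSV or the directory containing `lanes.tsv`.
#' @param config config list or YAML path (used to rebuild the locus for
#'   coordinates and to name comparisons; `config$comparisons` is a list of
#'   strain pairs, default `list(c("WT","rad26"))` when both are present).
#' @param out_dir output directory.
#' @return invisible list with the computed tables and output paths.
#' @export
cmd_analyze <- function(data, config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  lanes_path <- if (dir.exists(data)) file.path(data, "lanes.tsv") else data
  if (!file.exists(lanes_path)) stop("lanes TSV not found: ", lanes_path,
                                     call. = FALSE)
  datasets <- read_lanes_tsv(lanes_path)
  locus <- config_to_locus(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  curves <- pd_repair_curves(datasets)
  t4v <- t4v_repair_curves(datasets)
  out <- list(curves = curves, t4v = t4v)

  paths <- list()
  wtsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  if (!is.null(curves) && nrow(curves) > 0) {
    wtsv(curves, "pd_curves.tsv")
    band_pos <- curves[!duplicated(curves$band), c("band", "strand")]
    summaries <- list(); cluster_sets <- list()
    for (strand in unique(band_pos$strand)) {
      bands <- band_pos$band[band_pos$strand == strand]
      pos <- stats::setNames(as.integer(sub("^stop_", "", bands)), bands)
      cluster_sets[[strand]] <- define_pd_clusters(pos)
    }
    for (strain in unique(curves$strain)) {
      for (strand in names(cluster_sets)) {
        sub <- curves[curves$strain == strain & curves$strand == strand, ,
                      drop = FALSE]
        if (nrow(sub) == 0) next
        present <- Filter(function(b) any(b %in% sub$band),
                          cluster_sets[[strand]])
        if (length(present) == 0) next
        cs <- aggregate_cluster(sub, present)
        cs$strain <- strain; cs$strand <- strand
        summaries[[paste(strain, strand)]] <- cs
      }
    }
    summary_tab <- do.call(rbind, summaries)
    wtsv(summary_tab, "cluster_summary.tsv")
    out$cluster_summary <- summary_tab
    out$clusters <- cluster_sets

    comparisons <- config$comparisons %||% (
      if (all(c("WT", "rad26") %in% curves$strain))
        list(c("WT", "rad26")) else list())
    comp_rows <- list()
    for (pair in comparisons) {
      for (strand in names(cluster_sets)) {
        for (cl in names(cluster_sets[[strand]])) {
          bands <- cluster_sets[[strand]][[cl]]
          if (length(bands) < 3) next  # single/small clusters: no ANOVA
          ca <- per_replicate_cluster_means(
            curves[curves$strain == pair[1] & curves$strand == strand, ],
            bands)
          cb <- per_replicate_cluster_means(
            curves[curves$strain == pair[2] & curves$strand == strand, ],
            bands)
          if (nrow(ca) == 0 || nrow(cb) == 0) next
          cmp <- two_way_anova_sidak(ca, cb, labels = pair)
          pt <- cmp$per_time
          pt$cluster <- cl; pt$strand <- strand
          pt$pair <- paste(pair, collapse = "-")
          comp_rows[[length(comp_rows) + 1L]] <- pt
        }
      }
    }
    if (length(comp_rows) > 0) {
      comp_tab <- do.call(rbind, comp_rows)
      wtsv(comp_tab, "comparisons.tsv")
      out$comparisons <- comp_tab
    }
    bed_path <- file.path(out_dir, "repair_4h.bed")
    repair_track_bed(curves, locus, bed_path)
    paths[["repair_4h.bed"]] <- bed_path
  }
  if (!is.null(t4v) && nrow(t4v) > 0) wtsv(t4v, "t4v_curves.tsv")
  out$paths <- paths
  invisible(out)
}
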