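#' Write simulated (or imported) gel lanes to a tidy TSV
#'
#' One row per band per lane: strain, replicate, assay, treatment, time,
#' channel, band, intensity plus fragment metadata. The same format is
#' accepted back by [read_lanes_tsv()], so real densitometry tables can be
#' analyzed by the same downstream functions.
#'
#' @param datasets a `time_course_dataset`, a list of them, or an
#'   `experiment_set`.
#' @param file output path.
#' @return the combined data.frame, invisibly.
#' @export
write_lanes_tsv <- function(datasets, file) {
  df <- lanes_table(datasets)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

lanes_table <- function(datasets) {
  if (inherits(datasets, "time_course_dataset")) datasets <- list(datasets)
  do.call(rbind, lapply(datasets, function(ds) {
    lanes <- ds$lanes
    lanes$replicate <- ds$replicate
    lanes
  }))
}

#' Read a tidy lane TSV back into per-(strain, replicate) datasets
#'
#' @param file path written by [write_lanes_tsv()] (or hand-made with the
#'   same columns; minimally `strain`, `replicate`, `assay`, `treatment`,
#'   `time`, `channel`, `band`, `intensity`).
#' @return list of `time_course_dataset` objects.
#' @export
read_lanes_tsv <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  split_keys <- interaction(df$strain, df$replicate, drop = TRUE)
  lapply(split(df, split_keys), function(sub) {
    structure(list(lanes = sub, assay = "experiment",
                   strain = sub$strain[1], replicate = sub$replicate[1],
                   locus_name = NA_character_, provenance = list(file = file)),
              class = "time_course_dataset")
  })
}

#' Serialize provenance (or any parameter list) to JSON
#'
#' @param x a list.
#' @param file output path.
#' @export
write_provenance_json <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' Read and validate a run configuration (YAML)
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a config list (already parsed).
#' @export
validate_run_config <- function(config) {
  if (is.null(config$master_seed)) stop("config: master_seed is mandatory",
                                        call. = FALSE)
  if (is.null(config$locus)) stop("config: locus section missing",
                                  call. = FALSE)
  if (identical(config$locus$type, "fasta")) {
    if (is.null(config$locus$fasta) || !file.exists(config$locus$fasta)) {
      stop("config: locus FASTA path missing or not found", call. = FALSE)
    }
  }
  if (is.null(config$assays) || length(config$assays) == 0) {
    stop("config: at least one assay must be defined", call. = FALSE)
  }
  config$strains <- config$strains %||% "WT"
  vapply(config$strains, function(s) strain_genotype(s)$name, character(1))
  config$replicates <- config$replicates %||% 1L
  config$times <- config$times %||% c(0, 0.5, 1, 2, 4)
  config$n_molecules <- config$n_molecules %||% 5000L
  config$dose <- config$dose %||% 180
  config$noise <- config$noise %||% list()
  config$rates <- config$rates %||% list()
  config
}

#' Build the locus described by a config
#'
#' @param config validated config list.
#' @return a `subtelomere_locus`.
#' @export
config_to_locus <- function(config) {
  lc <- config$locus
  if (identical(lc$type, "fasta")) {
    return(load_locus_fasta(lc$fasta, lc$annotation))
  }
  plan <- if (!is.null(lc$preset)) {
    switch(lc$preset,
           yprime = yprime_locus_plan(),
           x = x_locus_plan(),
           stop(sprintf("unknown locus preset: %s", lc$preset),
                call. = FALSE))
  } else lc$plan
  build_synthetic_subtelomere(plan, seed = lc$seed %||% config$master_seed,
                              name = lc$name %||% "config_locus")
}

locus_granges <- function(locus, starts, ends, strand = "*", ...) {
  GenomicRanges::GRanges(
    seqnames = locus$name,
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = strand, ...)
}

strand_to_bed <- function(strand) ifelse(strand == "G-rich", "+", "-")

#' Export locus annotation as BED
#'
#' Elements, restriction cut sites or dipyrimidine sites as a BED track
#' (0-based half-open on disk; internal coordinates are 1-based inclusive
#' on the top/G-rich strand, which is written as `+`; the C-rich strand as
#' `-`).
#'
#' @param locus a `subtelomere_locus`.
#' @param what `"elements"`, `"restriction"` or `"sites"`.
#' @param file output BED path; when `NULL` the `GRanges` is returned.
#' @param strand for `what = "sites"`: which strand to scan.
#' @return `GRanges` (invisibly when written).
#' @export
locus_bed <- function(locus, what = c("elements", "restriction", "sites"),
                      file = NULL, strand = "G-rich") {
  what <- match.arg(what)
  gr <- switch(what,
    elements = {
      el <- locus$elements
      g <- locus_granges(locus, el$start, pmin(el$end, locus$length))
      g$name <- el$label
      g
    },
    restriction = {
      rs <- locus$restriction_sites
      g <- locus_granges(locus, rs$cut, rs$cut + 1L)
      g$name <- rs$enzyme
      g
    },
    sites = {
      s <- scan_dipyrimidine_sites(locus, strand,
                                   region = c(1L, locus$length))
      g <- locus_granges(locus, s$top_lo, s$top_hi,
                         strand = strand_to_bed(s$strand))
      g$name <- paste0(s$dinuc, "_", s$pos)
      g
    })
  if (!is.null(file)) {
    rtracklayer::export(gr, file, format = "BED")
    return(invisible(gr))
  }
  gr
}

#' Export a 4-h percent-repair track of photoproduct positions as BED
#'
#' @param curves output of [pd_repair_curves()] (band keys `stop_<pos>`,
#'   positions in the template strand's own frame).
#' @param locus the locus the curves derive from.
#' @param file output BED path; when `NULL` returns the `GRanges`.
#' @param t time point to export (default 4 h).
#' @return `GRanges` with `score` = mean percent repair at `t`.
#' @export
repair_track_bed <- function(curves, locus, file = NULL, t = 4) {
  sub <- curves[curves$time == t & grepl("^stop_", curves$band), ,
                drop = FALSE]
  agg <- stats::aggregate(percent ~ band + strand, data = sub, FUN = mean)
  own <- as.integer(sub("^stop_", "", agg$band))
  tops <- vapply(seq_along(own), function(i)
    own_to_top(locus, agg$strand[i], own[i]), numeric(1))
  lo <- pmin(tops, vapply(seq_along(own), function(i)
    own_to_top(locus, agg$strand[i], own[i] + 1L), numeric(1)))
  gr <- locus_granges(locus, lo, lo + 1L,
                      strand = strand_to_bed(agg$strand))
  gr$name <- agg$band
  gr$score <- agg$percent
  if (!is.null(file)) {
    rtracklayer::export(gr, file, format = "BED")
    return(invisible(gr))
  }
  gr
}
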