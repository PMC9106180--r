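find_strand_matches <- function(locus, pattern) {
  hits <- list()
  for (strand in c("G-rich", "C-rich")) {
    s <- strand_seq(locus, strand)
    m <- gregexpr(pattern, s, fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      for (p in as.integer(m)) {
        hits[[length(hits) + 1L]] <- data.frame(
          strand = strand, own_start = p,
          own_end = p + nchar(pattern) - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(strand = character(), own_start = integer(),
                      own_end = integer()))
  }
  do.call(rbind, hits)
}

#' Determine which strand a Southern probe (or primer) reports
#'
#' A single-stranded oligonucleotide detects the strand it hybridizes to:
#' the strand containing the reverse complement of the probe sequence. The
#' match must be unique across both strands of the whole locus and fall
#' within the fragment; zero or multiple matches are rejected, mirroring the
#' cross-hybridization problems of repetitive subtelomeric DNA.
#'
#' @param locus a `subtelomere_locus`.
#' @param fragment one-row fragment data.frame from [digest()].
#' @param probe probe/primer sequence 5'->3' (ACGT only).
#' @return `fragment` with `probed_strand` set.
#' @export
assign_probe_strand <- function(locus, fragment, probe) {
  stopifnot(nrow(fragment) == 1)
  assert_dna(probe, "probe")
  hits <- find_strand_matches(locus, revcomp(probe))
  if (nrow(hits) != 1) {
    stop(sprintf("probe not unique: %d match(es) across both strands",
                 nrow(hits)), call. = FALSE)
  }
  tops <- sort(own_to_top(locus, hits$strand, c(hits$own_start, hits$own_end)))
  if (tops[1] < fragment$start || tops[2] > fragment$end) {
    stop("probe target lies outside the fragment", call. = FALSE)
  }
  fragment$probed_strand <- hits$strand
  fragment
}

#' Design a primer annealing to a given strand segment
#'
#' Returns the oligonucleotide that anneals to `strand` over the top-strand
#' coordinates `anneal_top` (the reverse complement of the template
#' segment). Used to derive the locus-specific extension primers of the
#' polymerase-stop assay from a synthetic sequence.
#'
#' @param locus a `subtelomere_locus`.
#' @param strand template strand the primer anneals to.
#' @param anneal_top `c(lo, hi)` top-strand coordinates of the annealing
#'   site.
#' @param name primer name.
#' @return list with `name`, `seq`, `strand`, `anneal_top`.
#' @export
make_primer <- function(locus, strand, anneal_top, name = "primer") {
  stopifnot(length(anneal_top) == 2, anneal_top[1] <= anneal_top[2],
            anneal_top[1] >= 1, anneal_top[2] <= built_length(locus))
  segment_top <- substr(locus$seq_top, anneal_top[1], anneal_top[2])
  seq <- switch(strand,
                "C-rich" = segment_top,
                "G-rich" = revcomp(segment_top),
                stop(sprintf("unknown strand label: %s", strand),
                     call. = FALSE))
  list(name = name, seq = seq, strand = strand,
       anneal_top = as.integer(anneal_top))
}

#' Resolve the extension window of a primer within a restriction fragment
#'
#' Locates the primer's unique annealing site, identifies the restriction
#' fragment containing it, and returns the template positions the
#' polymerase copies: extension proceeds from the primer 3' end along the
#' template 3'->5', i.e. toward the telomere for C-rich templates (forward
#' primers) and toward the centromere for G-rich templates (reverse
#' primers), until the fragment end.
#'
#' @param locus a `subtelomere_locus`.
#' @param primer list from [make_primer()] (or with a `seq` entry).
#' @param enzymes enzymes defining the template fragments.
#' @return list with `template_strand`, `fragment`, `path` (top-strand
#'   coordinates of template positions in the order the polymerase reaches
#'   them), and `window_len`.
#' @export
primer_extension_window <- function(locus, primer, enzymes) {
  hits <- find_strand_matches(locus, revcomp(primer$seq))
  if (nrow(hits) != 1) {
    stop(sprintf("primer not unique: %d match(es) across both strands",
                 nrow(hits)), call. = FALSE)
  }
  strand <- hits$strand
  tops <- sort(own_to_top(locus, strand, c(hits$own_start, hits$own_end)))
  frags <- digest(locus, enzymes)
  in_frag <- which(frags$start <= tops[1] & frags$end >= tops[2])
  if (length(in_frag) != 1) {
    stop("primer annealing site is not contained in a single fragment",
         call. = FALSE)
  }
  frag <- frags[in_frag, , drop = FALSE]
  frag$probed_strand <- strand
  if (strand == "C-rich") {
    if (tops[2] >= frag$end) stop("empty extension window", call. = FALSE)
    path <- seq.int(tops[2] + 1L, frag$end)
  } else {
    if (tops[1] <= frag$start) stop("empty extension window", call. = FALSE)
    path <- seq.int(tops[1] - 1L, frag$start)
  }
  list(template_strand = strand, fragment = frag, path = path,
       window_len = length(path))
}

.known_strains <- c("WT", "rad26", "sir2", "sir2rad26", "rad14")

#' Genotype flags for the strains of the study design
#'
#' Flags are `TRUE` when the gene is functional: `rad26` (TCR), `sir2`
#' (subtelomeric silencing), `rad14` (core NER; its loss abolishes all NER).
#'
#' @param strain one of WT, rad26, sir2, sir2rad26, rad14 (a trailing
#'   delta/`d` suffix is accepted, e.g. `"rad26d"`).
#' @return list of logical flags plus the normalized name.
#' @export
strain_genotype <- function(strain) {
  key <- gsub("(Δ|delta|d)$", "", gsub("Δ", "", strain))
  key <- .known_strains[match(tolower(key), tolower(.known_strains))]
  if (is.na(key)) stop(sprintf("unknown strain: %s", strain), call. = FALSE)
  list(name = key,
       rad26 = !key %in% c("rad26", "sir2rad26"),
       sir2 = !key %in% c("sir2", "sir2rad26"),
       rad14 = key != "rad14")
}

#' Transcription units active in a given strain
#'
#' TERRA-class units always use the C-rich strand as template (the
#' transcript is G-rich); CUT-like units use the G-rich strand. Units
#' conditioned on SIR2 loss (`condition == "sir2d"`, e.g. the TERRA
#' extension downstream of the mapped TSS) are active only in sir2-deleted
#' backgrounds; rad26 or rad14 loss changes repair, not this annotation.
#'
#' @param locus a `subtelomere_locus`.
#' @param strain strain name, see [strain_genotype()].
#' @return the locus with `transcription_units` restricted to active units
#'   (an `active` flag is also kept on the full table).
#' @export
annotate_transcription <- function(locus, strain) {
  g <- strain_genotype(strain)
  tu <- locus$transcription_units
  active <- rep(FALSE, nrow(tu))
  if (nrow(tu) > 0) {
    active <- tu$condition == "always" | (tu$condition == "sir2d" & !g$sir2)
  }
  locus$transcription_units$active <- active
  locus$active_units <- tu[active, , drop = FALSE]
  locus$strain <- g$name
  locus
}

# Chromatin accessibility factor at top-strand positions for a strain:
# silenced-domain factors apply only when Sir2 is present.
accessibility_at <- function(locus, strain, top_pos) {
  g <- strain_genotype(strain)
  acc <- rep(1, length(top_pos))
  if (!g$sir2) return(acc)
  dom <- locus$chromatin_domains
  for (i in seq_len(nrow(dom))) {
    inside <- top_pos >= dom$start[i] & top_pos <= dom$end[i]
    acc[inside] <- pmin(acc[inside], dom$factor[i])
  }
  acc
}

# TRUE where a site lies on the template strand of a transcription unit
# active in `strain`.
on_template_at <- function(locus, strain, strand, top_pos) {
  loc <- annotate_transcription(locus, strain)
  tu <- loc$active_units
  tau <- rep(FALSE, length(top_pos))
  if (is.null(tu) || nrow(tu) == 0) return(tau)
  tu <- tu[tu$template_strand == strand, , drop = FALSE]
  for (i in seq_len(nrow(tu))) {
    tau <- tau | (top_pos >= tu$start[i] & top_pos <= tu$end[i])
  }
  tau
}
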