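.element_labels <- c("upstream", "XC", "XR", "Y'-long", "Y'-short",
                     "terminal-repeat")
.default_element_lengths <- c("upstream" = 1000, "XC" = 475, "XR" = 255,
                              "Y'-long" = 6700, "Y'-short" = 5200)

# Intra-Y' restriction geometry (bp). Each Y' element carries one EcoRI site
# at ECO_HEAD (+SMALL_REGION when the small ~0.3 kb variable region, "v1",
# is present) from its start, one HindIII site at HIND_TAIL (+SMALL_REGION
# for v1) from its end, and one XhoI site at XHO_TAIL from its end. These
# placements reproduce the published fragment scheme: HindIII/EcoRI junction
# fragments of 4.4/4.7/5.0 kb between adjacent Y' elements, a ~3.0 kb HindIII
# terminal fragment (2.7 kb Y' + ~0.3 kb telomeric repeats) and a 1.3 kb
# XhoI terminal fragment.
.ECO_HEAD <- 2000L
.HIND_TAIL <- 2400L
.SMALL_REGION <- 300L
.XHO_TAIL <- 975L

#' Element plan for a tandem Y'-element telomere
#'
#' Convenience plan mirroring a Y' subtelomere: upstream flank, X-element
#' (XC + XR), the requested Y' elements and the terminal C1-3A/TG1-3 repeat
#' tract.
#'
#' @param sizes character vector, one of `"long"`/`"short"` per Y' element.
#' @param variants `"v1"` (small 0.3 kb variable region present) or `"v2"`
#'   (absent), one per Y' element.
#' @return a list of element specifications for
#'   [build_synthetic_subtelomere()].
#' @export
yprime_locus_plan <- function(sizes = c("long", "long"),
                              variants = c("v1", "v1")) {
  stopifnot(length(sizes) == length(variants), length(sizes) >= 1)
  plan <- list(list(label = "upstream"), list(label = "XC"),
               list(label = "XR"))
  for (i in seq_along(sizes)) {
    plan[[length(plan) + 1L]] <- list(
      label = paste0("Y'-", match.arg(sizes[i], c("long", "short"))),
      variant = match.arg(variants[i], c("v1", "v2")))
  }
  plan[[length(plan) + 1L]] <- list(label = "terminal-repeat")
  plan
}

#' Element plan for an X-only telomere (Tel15L-like)
#'
#' X-element telomere without Y' elements: upstream flank, the ~730 bp
#' X-element split into its XC and XR (STR) regions, and terminal repeats.
#'
#' @param upstream_len length of the centromere-proximal flank (bp).
#' @return element plan list.
#' @export
x_locus_plan <- function(upstream_len = 1000) {
  list(list(label = "upstream", length = upstream_len),
       list(label = "XC"), list(label = "XR"),
       list(label = "terminal-repeat"))
}

normalize_plan <- function(plan) {
  if (length(plan) == 0) stop("empty element plan", call. = FALSE)
  lapply(plan, function(el) {
    if (is.character(el)) el <- list(label = el)
    if (is.null(el$label) || !el$label %in% .element_labels) {
      stop(sprintf("unknown element label: %s",
                   el$label %||% "<missing>"), call. = FALSE)
    }
    if (grepl("^Y'", el$label)) {
      el$variant <- el$variant %||% "v1"
      if (!el$variant %in% c("v1", "v2")) {
        stop(sprintf("unknown Y' variant: %s", el$variant), call. = FALSE)
      }
    }
    if (is.null(el$length) && el$label != "terminal-repeat") {
      el$length <- unname(.default_element_lengths[el$label])
      if (identical(el$variant, "v2")) el$length <- el$length - .SMALL_REGION
    }
    if (!is.null(el$length) && el$length <= 0) {
      stop("element lengths must be positive", call. = FALSE)
    }
    el
  })
}

check_yprime_pairing <- function(plan) {
  labs <- vapply(plan, `[[`, character(1), "label")
  for (i in seq_len(length(plan) - 1L)) {
    if (grepl("^Y'", labs[i]) && labs[i + 1L] == "Y'-short" &&
        identical(plan[[i]]$variant, "v2")) {
      stop("disallowed Y' variant pairing: a v2 Y' element followed by a ",
           "Y'-short element does not occur", call. = FALSE)
    }
  }
  invisible(plan)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Imperfectly repetitive telomeric tract: TG1-3 on the G-rich (top) strand,
# equivalently C1-3A on the C-rich strand. Built to `n` bases.
telomere_repeat_seq <- function(n) {
  units <- sample(c("TG", "TGG", "TGGG"), ceiling(n / 2), replace = TRUE)
  substr(paste(units, collapse = ""), 1L, n)
}

#' Build a synthetic annotated subtelomeric locus
#'
#' Generates a two-strand sequence model of a yeast chromosome end from an
#' ordered element plan (centromere to telomere). Element base composition is
#' uniform random except the terminal repeat tract, which follows the
#' C1-3A/TG1-3 motif family. The terminal tract length is drawn from a
#' truncated normal (mean 325 bp, sd 50 bp, bounds 175-475 bp); the repeat
#' sequence itself is synthesized out to the upper bound so that per-molecule
#' telomere lengths sampled later can exceed the locus draw. Restriction
#' sites are placed so the published Y' fragment scheme is reproduced (see
#' [digest()]).
#'
#' @param plan element plan: list of `list(label, length, variant)` entries
#'   (labels among upstream, XC, XR, Y'-long, Y'-short, terminal-repeat), or
#'   a plain character vector of labels. See [yprime_locus_plan()] and
#'   [x_locus_plan()].
#' @param seed integer seed; the same plan + seed always yields an identical
#'   locus.
#' @param name locus name.
#' @param telomere_mean,telomere_sd,telomere_bounds truncated-normal
#'   parameters of the terminal repeat tract length (bp).
#' @param overhang_len 3' single-stranded overhang length (nt, 8-14); drawn
#'   uniformly if `NULL`.
#' @return a `subtelomere_locus` object: list with the top (G-rich) strand
#'   sequence 5'->3' centromere->telomere, element table, restriction sites,
#'   transcription units, chromatin domains and telomere-length metadata.
#' @export
build_synthetic_subtelomere <- function(plan, seed, name = "synthetic_locus",
                                        telomere_mean = 325,
                                        telomere_sd = 50,
                                        telomere_bounds = c(175, 475),
                                        overhang_len = NULL) {
  plan <- normalize_plan(plan)
  check_yprime_pairing(plan)
  labs <- vapply(plan, `[[`, character(1), "label")
  if ("terminal-repeat" %in% labs &&
      which(labs == "terminal-repeat") != length(labs)) {
    stop("terminal-repeat must be the last (telomere-proximal) element",
         call. = FALSE)
  }

  with_seed(seed, {
    seqs <- character(length(plan))
    starts <- integer(length(plan))
    ends <- integer(length(plan))
    variants <- character(length(plan))
    pos <- 0L
    telomere <- NULL
    for (i in seq_along(plan)) {
      el <- plan[[i]]
      if (el$label == "terminal-repeat") {
        drawn <- round(rtrunc_norm(1, telomere_mean, telomere_sd,
                                   telomere_bounds[1], telomere_bounds[2]))
        built <- ceiling(telomere_bounds[2])
        seqs[i] <- telomere_repeat_seq(built)
        starts[i] <- pos + 1L
        ends[i] <- pos + as.integer(drawn)
        telomere <- list(mean = telomere_mean, sd = telomere_sd,
                         bounds = telomere_bounds, drawn = as.integer(drawn),
                         start = pos + 1L)
        pos <- ends[i]
      } else {
        n <- as.integer(el$length)
        seqs[i] <- random_dna(n)
        starts[i] <- pos + 1L
        ends[i] <- pos + n
        pos <- ends[i]
      }
      variants[i] <- el$variant %||% NA_character_
    }
    elements <- data.frame(label = labs, start = starts, end = ends,
                           variant = variants, stringsAsFactors = FALSE)
    seq_top <- paste(seqs, collapse = "")
    length_nominal <- ends[length(plan)]

    restriction <- locus_restriction_sites(elements)
    tu <- default_transcription_units(elements, length_nominal)
    chrom <- default_chromatin_domains(elements, length_nominal)
    if (is.null(overhang_len)) overhang_len <- sample(8:14, 1)
    if (overhang_len < 8 || overhang_len > 14) {
      stop("overhang_len must lie in [8, 14] nt", call. = FALSE)
    }

    locus <- structure(list(
      name = name, seq_top = seq_top, length = length_nominal,
      elements = elements, restriction_sites = restriction,
      transcription_units = tu, chromatin_domains = chrom,
      telomere = telomere, overhang_len = as.integer(overhang_len),
      provenance = list(seed = seed, plan = plan)
    ), class = "subtelomere_locus")
    validate_locus(locus)
    locus
  })
}

# Cut positions: a site at p cuts between top-strand positions p and p+1.
locus_restriction_sites <- function(elements) {
  out <- list()
  add <- function(enzyme, cut) {
    out[[length(out) + 1L]] <<- data.frame(enzyme = enzyme,
                                           cut = as.integer(cut))
  }
  for (i in seq_len(nrow(elements))) {
    el <- elements[i, ]
    if (grepl("^Y'", el$label)) {
      small <- if (identical(el$variant, "v1")) .SMALL_REGION else 0L
      add("EcoRI", el$start - 1L + .ECO_HEAD + small)
      add("HindIII", el$end - (.HIND_TAIL + small))
      add("XhoI", el$end - .XHO_TAIL)
    }
  }
  if (any(elements$label == "XC") && !any(grepl("^Y'", elements$label))) {
    x_start <- elements$start[elements$label == "XC"][1]
    if (x_start > 121L) add("RsaI", x_start - 121L)
    add("HhaI", x_start + 367L)
  }
  if (length(out) == 0) {
    return(data.frame(enzyme = character(), cut = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$cut), , drop = FALSE]
}

# Default transcription-unit annotation. TERRA is a G-rich transcript, so its
# template is always the C-rich strand; subTERRA-CUT-like units run toward
# the centromere and use the G-rich strand as template. `condition` encodes
# strain dependence: "always", or "sir2d" for units de-repressed by SIR2 loss.
default_transcription_units <- function(elements, L) {
  has_y <- any(grepl("^Y'", elements$label))
  has_x <- any(elements$label == "XC")
  rep_start <- if (any(elements$label == "terminal-repeat")) {
    elements$start[elements$label == "terminal-repeat"][1]
  } else L + 1L
  units <- list()
  add <- function(name, template, start, end, condition) {
    units[[length(units) + 1L]] <<- data.frame(
      name = name, template_strand = template,
      start = as.integer(max(1L, start)), end = as.integer(min(L, end)),
      condition = condition, stringsAsFactors = FALSE)
  }
  if (has_y) {
    y_start <- min(elements$start[grepl("^Y'", elements$label)])
    add("TERRA", "C-rich", rep_start - 1000L, L, "always")
    add("subTERRA-XUT", "C-rich", y_start, rep_start - 1001L, "always")
    add("subTERRA-CUT", "G-rich", y_start, rep_start - 1301L, "always")
  } else if (has_x) {
    x_start <- elements$start[elements$label == "XC"][1]
    add("TERRA-proximal", "C-rich", x_start, x_start + 104L, "always")
    add("TERRA-TSS", "C-rich", x_start + 380L, L, "sir2d")
    add("X-CUT", "G-rich", x_start - 200L, x_start - 1L, "sir2d")
  }
  if (length(units) == 0) {
    return(data.frame(name = character(), template_strand = character(),
                      start = integer(), end = integer(),
                      condition = character()))
  }
  do.call(rbind, units)
}

# Sir-silenced telomere-proximal chromatin: accessibility factor < 1 applies
# only in SIR2+ genotypes (sir2-delta restores factor 1 everywhere).
default_chromatin_domains <- function(elements, L) {
  rep_start <- if (any(elements$label == "terminal-repeat")) {
    elements$start[elements$label == "terminal-repeat"][1]
  } else L + 1L
  if (any(elements$label == "XC") && !any(grepl("^Y'", elements$label))) {
    start <- elements$start[elements$label == "XC"][1]
  } else {
    start <- max(1L, rep_start - 1500L)
  }
  data.frame(start = as.integer(start), end = as.integer(L), factor = 0.5)
}

validate_locus <- function(locus) {
  el <- locus$elements
  stopifnot(nrow(el) >= 1)
  if (is.unsorted(el$start) ||
      any(el$start[-1] != el$end[-nrow(el)] + 1L) || el$start[1] != 1L) {
    stop("element intervals must be contiguous, ordered and non-overlapping",
         call. = FALSE)
  }
  if (!is.null(locus$telomere)) {
    rep_seq <- substr(locus$seq_top, locus$telomere$start,
                      locus$telomere$start + locus$telomere$drawn - 1L)
    if (!grepl("^T?(G{1,3}T)*G{0,3}$", rep_seq)) {
      stop("terminal repeat tract does not match the TG1-3 motif family",
           call. = FALSE)
    }
  }
  if (locus$overhang_len < 8L || locus$overhang_len > 14L) {
    stop("overhang length outside [8, 14] nt", call. = FALSE)
  }
  tu <- locus$transcription_units
  if (nrow(tu) > 0) {
    stopifnot(all(tu$template_strand %in% c("C-rich", "G-rich")),
              all(tu$start >= 1), all(tu$end <= locus$length))
  }
  invisible(locus)
}

#' Load a real subtelomeric locus from FASTA plus an annotation config
#'
#' @param fasta path to a single-record FASTA of the top (G-rich) strand,
#'   written 5'->3' centromere->telomere. Degenerate bases are rejected.
#' @param annotation a list (e.g. parsed from YAML via [read_run_config()])
#'   with `elements`, `restriction_sites`, optional `transcription_units`,
#'   `chromatin_domains`, `telomere` and `overhang_len` entries using the
#'   same columns as the synthetic builder.
#' @return a `subtelomere_locus`.
#' @export
load_locus_fasta <- function(fasta, annotation) {
  set <- Biostrings::readDNAStringSet(fasta)
  if (length(set) != 1) stop("FASTA must contain exactly one record",
                             call. = FALSE)
  seq_top <- as.character(set[[1]])
  assert_dna(seq_top, "FASTA sequence")
  as_df <- function(x) if (is.data.frame(x)) x else
    do.call(rbind, lapply(x, function(r) as.data.frame(r)))
  el <- as_df(annotation$elements)
  locus <- structure(list(
    name = annotation$name %||% names(set)[1],
    seq_top = seq_top, length = nchar(seq_top), elements = el,
    restriction_sites = if (!is.null(annotation$restriction_sites))
      as_df(annotation$restriction_sites) else
        data.frame(enzyme = character(), cut = integer()),
    transcription_units = if (!is.null(annotation$transcription_units))
      as_df(annotation$transcription_units) else
        default_transcription_units(el, nchar(seq_top)),
    chromatin_domains = if (!is.null(annotation$chromatin_domains))
      as_df(annotation$chromatin_domains) else
        default_chromatin_domains(el, nchar(seq_top)),
    telomere = annotation$telomere,
    overhang_len = as.integer(annotation$overhang_len %||% 11L),
    provenance = list(fasta = fasta)
  ), class = "subtelomere_locus")
  validate_locus(locus)
  locus
}

#' @export
print.subtelomere_locus <- function(x, ...) {
  cat(sprintf("<subtelomere_locus> %s: %d bp (top strand = G-rich)\n",
              x$name, x$length))
  cat("elements:\n")
  print(x$elements, row.names = FALSE)
  cat(sprintf("restriction sites: %d | transcription units: %d | overhang: %d nt\n",
              nrow(x$restriction_sites), nrow(x$transcription_units),
              x$overhang_len))
  invisible(x)
}

# Full built top-strand length (telomeric repeats synthesized to the upper
# truncation bound); >= locus$length.
built_length <- function(locus) nchar(locus$seq_top)

# Strand sequence in its own 5'->3' frame.
strand_seq <- function(locus, strand) {
  switch(strand,
         "G-rich" = locus$seq_top,
         "C-rich" = revcomp(locus$seq_top),
         stop(sprintf("unknown strand label: %s", strand), call. = FALSE))
}

# Convert a position in a strand's own 5'->3' frame to the top-strand
# coordinate, and back. The C-rich strand is the reverse complement of the
# top strand, so its own frame runs telomere->centromere.
own_to_top <- function(locus, strand, pos) {
  if (strand == "G-rich") pos else built_length(locus) - pos + 1L
}
top_to_own <- function(locus, strand, pos) own_to_top(locus, strand, pos)
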