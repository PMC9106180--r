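#' Scan a strand for dipyrimidine (potential photoproduct) sites
#'
#' Reports every pair of adjacent pyrimidines on the requested strand, read
#' 5'->3' in that strand's own frame. Overlapping sites (TTT gives TT at two
#' positions) are both reported, since either pair can form a photoproduct.
#'
#' @param locus a `subtelomere_locus`.
#' @param strand `"C-rich"` or `"G-rich"`.
#' @param region optional `c(lo, hi)` top-strand coordinates restricting the
#'   scan (both bases of a site must fall inside); defaults to the whole
#'   built sequence including the full telomeric tract.
#' @return data.frame with one row per site: `pos` (1-based coordinate of
#'   the 5' base in the strand's own frame), `strand`, `dinuc` (TT/TC/CT/CC),
#'   and `top_lo`/`top_hi` (top-strand coordinates of the two bases).
#' @export
scan_dipyrimidine_sites <- function(locus, strand, region = NULL) {
  s <- strand_seq(locus, strand)
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  pyr <- bases %in% c("C", "T")
  n <- length(bases)
  if (n < 2) {
    idx <- integer(0)
  } else {
    idx <- which(pyr[-n] & pyr[-1])
  }
  sites <- data.frame(
    pos = idx, strand = rep(strand, length(idx)),
    dinuc = paste0(bases[idx], bases[idx + 1L]),
    stringsAsFactors = FALSE)
  tops <- own_to_top(locus, strand, c(sites$pos, sites$pos + 1L))
  k <- length(idx)
  sites$top_lo <- pmin(tops[seq_len(k)], tops[k + seq_len(k)])
  sites$top_hi <- pmax(tops[seq_len(k)], tops[k + seq_len(k)])
  if (!is.null(region)) {
    stopifnot(length(region) == 2, region[1] <= region[2])
    sites <- sites[sites$top_lo >= region[1] & sites$top_hi <= region[2], ,
                   drop = FALSE]
  }
  rownames(sites) <- NULL
  sites[order(sites$pos), , drop = FALSE]
}

#' Assign signed photoproduct indices relative to the X-element start
#'
#' Sites at or telomere-distal of the X-element start are numbered +1, +2,
#' ... in 5'->3' top-strand order; sites centromere-proximal of it are
#' numbered -1, -2, ... moving away. There is no index 0 and -1 is adjacent
#' to +1. Numbering is per strand.
#'
#' @param sites output of [scan_dipyrimidine_sites()].
#' @param locus the locus (must contain an XC element).
#' @return `sites` with a `pd_index` column.
#' @export
number_pd_sites <- function(sites, locus) {
  xc <- locus$elements$start[locus$elements$label == "XC"]
  if (length(xc) == 0) stop("locus has no X-element to number against",
                            call. = FALSE)
  x_start <- xc[1]
  out <- lapply(split(sites, sites$strand), function(ss) {
    ss <- ss[order(ss$top_lo), , drop = FALSE]
    inside <- ss$top_lo >= x_start
    ss$pd_index <- NA_integer_
    ss$pd_index[inside] <- seq_len(sum(inside))
    ss$pd_index[!inside] <- -rev(seq_len(sum(!inside)))
    ss
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' In-silico restriction digestion
#'
#' Cuts the (linear) locus at every site of the named enzymes and returns
#' the resulting fragments. With no sites the whole locus is returned as one
#' fragment. The telomere-proximal fragment is flagged `terminal`; its
#' `length_kb` stores the population-mean length (core + mean telomeric
#' tract), since per-molecule telomere lengths vary and the band runs as a
#' smear.
#'
#' @param locus a `subtelomere_locus`.
#' @param enzymes character vector of enzyme names (e.g.
#'   `c("HindIII", "EcoRI")`).
#' @return data.frame of fragments: `name`, `start`, `end` (1-based
#'   inclusive top-strand coordinates), `length_kb`, `probed_strand` (NA
#'   until [assign_probe_strand()]), `terminal`.
#' @export
digest <- function(locus, enzymes) {
  rs <- locus$restriction_sites
  cuts <- sort(unique(rs$cut[rs$enzyme %in% enzymes]))
  cuts <- cuts[cuts >= 1 & cuts < locus$length]
  bounds <- c(0L, cuts, locus$length)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  frags <- data.frame(
    name = sprintf("%s_frag%02d", paste(enzymes, collapse = "+"),
                   seq_along(starts)),
    start = starts, end = ends,
    length_kb = (ends - starts + 1L) / 1000,
    probed_strand = NA_character_,
    terminal = ends == locus$length,
    stringsAsFactors = FALSE)
  if (!is.null(locus$telomere)) {
    term <- frags$terminal & frags$start <= locus$telomere$start
    core <- locus$telomere$start - frags$start[term]
    frags$length_kb[term] <- (core + locus$telomere$mean) / 1000
  }
  frags
}

#' Identify junction fragments spanning a boundary between two Y' elements
#'
#' @param locus a `subtelomere_locus`.
#' @param fragments output of [digest()].
#' @return the subset of `fragments` containing a Y'/Y' element boundary.
#' @export
junction_fragments <- function(locus, fragments) {
  el <- locus$elements
  y <- which(grepl("^Y'", el$label))
  if (length(y) < 2) return(fragments[0, , drop = FALSE])
  boundaries <- el$end[y[-length(y)]][diff(y) == 1] + 0.5
  keep <- vapply(seq_len(nrow(fragments)), function(i) {
    any(boundaries > fragments$start[i] & boundaries < fragments$end[i])
  }, logical(1))
  fragments[keep, , drop = FALSE]
}
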