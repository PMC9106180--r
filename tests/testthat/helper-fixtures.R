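# Shared fixtures, all generated in code.

# Minimal locus wrapping an arbitrary top-strand sequence (for scanner and
# digestion arithmetic tests).
raw_locus <- function(seq, cuts = data.frame(enzyme = character(),
                                             cut = integer())) {
  structure(list(
    name = "raw", seq_top = seq, length = nchar(seq),
    elements = data.frame(label = "upstream", start = 1L,
                          end = nchar(seq), variant = NA_character_),
    restriction_sites = cuts,
    transcription_units = data.frame(name = character(),
                                     template_strand = character(),
                                     start = integer(), end = integer(),
                                     condition = character()),
    chromatin_domains = data.frame(start = integer(), end = integer(),
                                   factor = numeric()),
    telomere = NULL, overhang_len = 11L, provenance = list()),
    class = "subtelomere_locus")
}

yprime_fixture <- function(seed = 11, sizes = c("long", "long"),
                           variants = c("v1", "v2")) {
  build_synthetic_subtelomere(yprime_locus_plan(sizes, variants),
                              seed = seed)
}

x_fixture <- function(seed = 21) {
  build_synthetic_subtelomere(x_locus_plan(), seed = seed)
}

# Brute-force dipyrimidine scan over a plain sequence string (independent
# oracle for the vectorized scanner).
brute_scan <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- list()
  for (i in seq_len(max(length(b) - 1L, 0L))) {
    if (b[i] %in% c("C", "T") && b[i + 1L] %in% c("C", "T")) {
      out[[length(out) + 1L]] <- data.frame(pos = i,
                                            dinuc = paste0(b[i], b[i + 1L]))
    }
  }
  if (length(out) == 0) return(data.frame(pos = integer(),
                                          dinuc = character()))
  do.call(rbind, out)
}

# Exhaustive first-stop probabilities: enumerate all lesion configurations
# of sites ordered by encounter (probabilities `p`), no natural stops.
enumerate_first_stop <- function(p) {
  k <- length(p)
  probs <- numeric(k + 1L)  # k sites + full length
  for (mask in 0:(2^k - 1L)) {
    has <- as.logical(bitwAnd(mask, 2^(0:(k - 1L))))
    pr <- prod(ifelse(has, p, 1 - p))
    first <- which(has)[1]
    idx <- if (is.na(first)) k + 1L else first
    probs[idx] <- probs[idx] + pr
  }
  probs
}

# T4 zero-class density estimate from a 0-h lane pair of a dataset.
t4v_density_estimate <- function(ds, length_kb) {
  l <- ds$lanes[ds$lanes$treatment == "+UV" & ds$lanes$time == 0, ]
  as.numeric(cpd_density_from_bands(l$intensity[l$channel == "mock"],
                                    l$intensity[l$channel == "t4v"],
                                    length_kb))
}

no_noise <- function() noise_config(band_sigma = 0, loading_sigma = 0)

# Flatten an experiment set to one lane table (rownames normalized).
lanes_df <- function(exps) {
  df <- do.call(rbind, lapply(exps, function(d) {
    l <- d$lanes
    l$replicate <- d$replicate
    l
  }))
  rownames(df) <- NULL
  df
}
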