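test_that("element plans are validated", {
  expect_error(build_synthetic_subtelomere(list(), seed = 1),
               "empty element plan")
  expect_error(build_synthetic_subtelomere(list(list(label = "Z")), seed = 1),
               "unknown element label")
  expect_error(build_synthetic_subtelomere(
    list(list(label = "upstream", length = -5)), seed = 1),
    "positive")
  expect_error(build_synthetic_subtelomere(
    yprime_locus_plan(c("long", "short"), c("v2", "v1")), seed = 1),
    "disallowed Y' variant pairing")
})

test_that("Y' element spans match the published sizes", {
  loc <- build_synthetic_subtelomere(
    list(list(label = "Y'-long"), list(label = "terminal-repeat")), seed = 1)
  el <- loc$elements
  y <- el[el$label == "Y'-long", ]
  expect_equal(y$end - y$start + 1L, 6700L)
  locs <- build_synthetic_subtelomere(
    list(list(label = "Y'-short"), list(label = "terminal-repeat")), seed = 1)
  ys <- locs$elements[locs$elements$label == "Y'-short", ]
  expect_equal(ys$end - ys$start + 1L, 5200L)
})

test_that("locus construction is reproducible and structurally valid", {
  a <- yprime_fixture(seed = 42)
  b <- yprime_fixture(seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, yprime_fixture(seed = 43)))
  # contiguous ordered elements
  el <- a$elements
  expect_true(all(el$start[-1] == el$end[-nrow(el)] + 1L))
  # telomeric tract obeys the motif family on both strands
  rep_seq <- substr(a$seq_top, a$telomere$start,
                    a$telomere$start + a$telomere$drawn - 1L)
  expect_false(grepl("TT|[AC]", substr(rep_seq, 2, nchar(rep_seq) - 1),
                     fixed = FALSE) &&
                 !grepl("^[TG]+$", rep_seq))
  expect_true(grepl("^[TG]+$", rep_seq))
  expect_true(a$overhang_len >= 8 && a$overhang_len <= 14)
})

test_that("terminal-repeat tract lengths follow the truncated normal", {
  set.seed(7)
  draws <- rtrunc_norm(10000, 325, 50, 175, 475)
  expect_lt(abs(mean(draws) - 325), 5)
  expect_lt(abs(sd(draws) - 50), 10)
  expect_true(all(draws >= 175 & draws <= 475))
})

test_that("dipyrimidine scanning matches definition and brute-force oracle", {
  expect_equal(scan_dipyrimidine_sites(raw_locus("ATTGA"), "G-rich")$pos, 2L)
  expect_equal(scan_dipyrimidine_sites(raw_locus("ATTGA"), "G-rich")$dinuc,
               "TT")
  expect_equal(nrow(scan_dipyrimidine_sites(raw_locus("AGAGA"), "G-rich")),
               0L)
  # overlapping TTT reports both
  expect_equal(scan_dipyrimidine_sites(raw_locus("TTT"), "G-rich")$pos,
               c(1L, 2L))
  expect_error(scan_dipyrimidine_sites(raw_locus("ACGT"), "W-rich"),
               "unknown strand")

  set.seed(3)
  seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
  got <- scan_dipyrimidine_sites(raw_locus(seq), "G-rich")
  oracle <- brute_scan(seq)
  expect_equal(got$pos, oracle$pos)
  expect_equal(got$dinuc, oracle$dinuc)

  # mirror consistency: C-rich sites are the G-rich sites of the reverse
  # complement, in the mirrored frame
  got_c <- scan_dipyrimidine_sites(raw_locus(seq), "C-rich")
  rc <- brute_scan(paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "",
                                      fixed = TRUE)[[1]]), collapse = ""))
  expect_equal(got_c$pos, rc$pos)
  expect_equal(got_c$dinuc, rc$dinuc)
})

test_that("digestion partitions the locus and handles edge cases", {
  # single cut arithmetic
  loc <- raw_locus(strrep("A", 1000),
                   cuts = data.frame(enzyme = "EcoRI", cut = 100L))
  f <- digest(loc, "EcoRI")
  expect_equal(f$end - f$start + 1L, c(100L, 900L))
  # no sites: identity fragment
  f0 <- digest(loc, "XhoI")
  expect_equal(nrow(f0), 1L)
  expect_equal(c(f0$start, f0$end), c(1L, 1000L))

  # partition property on a real locus, any enzyme set
  yl <- yprime_fixture(seed = 5)
  for (enz in list("HindIII", "XhoI", c("HindIII", "EcoRI"),
                   c("HindIII", "EcoRI", "XhoI"))) {
    fr <- digest(yl, enz)
    expect_equal(sum(fr$end - fr$start + 1L), yl$length)
  }
})

test_that("Y' junction and terminal fragments reproduce the published scheme", {
  # all allowed adjacent pairings of (size, small-region variant)
  variants <- expand.grid(up_size = c("long", "short"),
                          up_v = c("v1", "v2"),
                          down_size = c("long", "short"),
                          down_v = c("v1", "v2"),
                          stringsAsFactors = FALSE)
  allowed <- variants[!(variants$up_v == "v2" &
                          variants$down_size == "short"), ]
  lens <- vapply(seq_len(nrow(allowed)), function(i) {
    v <- allowed[i, ]
    loc <- build_synthetic_subtelomere(
      yprime_locus_plan(c(v$up_size, v$down_size), c(v$up_v, v$down_v)),
      seed = 100 + i)
    j <- junction_fragments(loc, digest(loc, c("HindIII", "EcoRI")))
    j$length_kb[1]
  }, numeric(1))
  expect_equal(sort(unique(round(lens, 6))), c(4.4, 4.7, 5.0))

  loc <- yprime_fixture(seed = 11)
  ft <- digest(loc, "XhoI")
  expect_equal(ft$length_kb[ft$terminal], 1.3)
  # ~3.0 kb HindIII terminal fragment: 2.7 kb of Y' (v1 terminal element)
  # plus ~0.3 kb mean telomeric repeats
  loc1 <- yprime_fixture(seed = 11, variants = c("v1", "v1"))
  fh <- digest(loc1, "HindIII")
  expect_equal(fh$length_kb[fh$terminal], 3.025, tolerance = 1e-9)
})

test_that("probe strand assignment enforces unique reverse-complement match", {
  loc <- x_fixture(seed = 21)
  frag <- digest(loc, "HhaI")[1, ]
  # probe = reverse complement of a C-rich segment -> detects C-rich.
  # A C-rich-strand segment over top coords [lo, hi] is revcomp(top[lo, hi]),
  # so the probe equals the top-strand subsequence there.
  probe <- substr(loc$seq_top, 200, 224)
  got <- assign_probe_strand(loc, frag, probe)
  expect_equal(got$probed_strand, "C-rich")
  # reverse-complement probe detects the G-rich strand
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", probe), "",
                           fixed = TRUE)[[1]]), collapse = "")
  expect_equal(assign_probe_strand(loc, frag, rc)$probed_strand, "G-rich")
  # repetitive telomeric sequence matches many places -> rejected
  expect_error(assign_probe_strand(loc, frag, "TGTGGTGTG"),
               "probe not unique")
  # unique match outside the fragment -> rejected
  frag2 <- digest(loc, "HhaI")[2, ]
  expect_error(assign_probe_strand(loc, frag2, probe), "outside")
  expect_error(assign_probe_strand(loc, frag, "ACGTN"), "non-ACGT")
})

test_that("primer extension window follows coordinate arithmetic", {
  loc <- x_fixture(seed = 21)
  x_start <- loc$elements$start[loc$elements$label == "XC"][1]
  # reverse primer on the G-rich template: extension runs back to the cut
  pr <- make_primer(loc, "G-rich", c(x_start + 200L, x_start + 219L), "c")
  win <- primer_extension_window(loc, pr, "RsaI")
  cut <- loc$restriction_sites$cut[loc$restriction_sites$enzyme == "RsaI"]
  # window spans (cut, primer-3'-end) exclusive: length = lo - 1 - cut
  expect_equal(win$window_len, (x_start + 200L - 1L) - cut)
  expect_equal(win$path[1], x_start + 199L)
  expect_equal(win$path[win$window_len], cut + 1L)
  expect_equal(win$template_strand, "G-rich")

  # forward primer on the C-rich template: extension runs to the fragment end
  pa <- make_primer(loc, "C-rich", c(x_start - 80L, x_start - 61L), "a")
  wa <- primer_extension_window(loc, pa, "HhaI")
  cut_h <- loc$restriction_sites$cut[loc$restriction_sites$enzyme == "HhaI"]
  expect_equal(wa$window_len, cut_h - (x_start - 61L))
  expect_equal(wa$template_strand, "C-rich")
})

test_that("transcription annotation depends on genotype as designed", {
  loc <- x_fixture(seed = 21)
  wt <- annotate_transcription(loc, "WT")
  expect_equal(wt$active_units$name, "TERRA-proximal")
  expect_equal(wt$active_units$template_strand, "C-rich")
  expect_equal(wt$active_units$end - wt$active_units$start + 1L, 105L)
  s2 <- annotate_transcription(loc, "sir2")
  expect_true(all(c("TERRA-proximal", "TERRA-TSS") %in% s2$active_units$name))
  r26 <- annotate_transcription(loc, "rad26")
  expect_identical(r26$active_units, wt$active_units)
  expect_error(annotate_transcription(loc, "xyz"), "unknown strain")
})

test_that("photoproduct numbering is signed with no zero", {
  loc <- x_fixture(seed = 21)
  sites <- scan_dipyrimidine_sites(loc, "G-rich", region = c(900, 1100))
  numbered <- number_pd_sites(sites, loc)
  expect_false(any(numbered$pd_index == 0))
  ord <- numbered[order(numbered$top_lo), ]
  # indices increase along the top strand; -1 is adjacent to +1 (no 0)
  expect_true(!is.unsorted(ord$pd_index, strictly = TRUE))
  expect_true(any(ord$pd_index < 0) && any(ord$pd_index > 0))
  neg <- ord$pd_index[ord$pd_index < 0]
  pos <- ord$pd_index[ord$pd_index > 0]
  expect_equal(max(neg), -1L)
  expect_equal(min(pos), 1L)
  expect_equal(which(ord$pd_index == 1L), which(ord$pd_index == -1L) + 1L)
})

test_that("BED export converts 1-based internal coordinates losslessly", {
  loc <- x_fixture(seed = 21)
  tmp <- withr::local_tempfile(fileext = ".bed")
  gr <- locus_bed(loc, "elements", tmp)
  reread <- rtracklayer::import(tmp)
  expect_equal(GenomicRanges::start(reread), loc$elements$start)
  expect_equal(GenomicRanges::end(reread),
               pmin(loc$elements$end, loc$length))
  # on-disk BED is 0-based half-open
  raw <- read.table(tmp, sep = "\t")
  expect_equal(raw$V2, loc$elements$start - 1L)
})

test_that("FASTA loading rejects degenerate bases", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">locN", "ACGTNNACGT"), tmp)
  ann <- list(elements = data.frame(label = "upstream", start = 1L,
                                    end = 10L, variant = NA_character_))
  expect_error(load_locus_fasta(tmp, ann), "non-ACGT")
  tmp2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">locA", "ACGTACGTAC"), tmp2)
  loc <- load_locus_fasta(tmp2, ann)
  expect_s3_class(loc, "subtelomere_locus")
  expect_equal(loc$length, 10L)
})
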