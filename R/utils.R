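#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed
#'
#' Folds the master seed and an arbitrary set of string/numeric labels into a
#' 31-bit integer with a polynomial rolling hash. Every stochastic stage of
#' the pipeline draws its seed this way (one named substream per strain,
#' time, replicate, purpose), so adding replicates or strains never perturbs
#' the random numbers of earlier ones.
#'
#' @param master integer master seed.
#' @param ... labels (character or numeric) naming the substream.
#' @return a positive integer seed < 2^31.
#' @export
derive_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                         character(1)), collapse = "/")
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Sample from a truncated normal distribution
#'
#' Exact inverse-CDF sampler used for telomeric-repeat tract lengths
#' (population mean 325 bp, sd 50 bp, truncated to \[175, 475\] bp by
#' default elsewhere in the package).
#'
#' @param n number of draws.
#' @param mean,sd parameters of the parent normal.
#' @param lower,upper truncation bounds.
#' @return numeric vector of length `n`.
#' @export
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower < upper)
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Multiplicative lognormal noise with median 1 (sigma on the log scale).
lognormal_noise <- function(n, sigma) {
  if (is.null(sigma) || sigma <= 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = 0, sdlog = sigma)
}

# Reverse complement of a plain character DNA string (ACGT only).
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Attach a logical flag attribute (used for clipped/undefined results that
# are reported rather than dropped).
flag_value <- function(x, flag, name = "flagged") {
  attr(x, name) <- flag
  x
}

is_pyrimidine <- function(base) base %in% c("C", "T")

assert_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT (degenerate or invalid) bases; %s",
                 what, "degenerate bases are rejected, not coerced"),
         call. = FALSE)
  }
  invisible(seq)
}
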