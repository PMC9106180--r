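#' Two-way ANOVA with Sidak-adjusted per-time contrasts
#'
#' Fixed-effects two-factor ANOVA (group, time, interaction) on
#' percent-repair observations, followed by per-time group contrasts using
#' the pooled residual variance, Sidak-adjusted for the number of time
#' points compared: `p_adj = 1 - (1 - p)^m`. Observations are expected to
#' be per-replicate cluster means (one value per replicate x time), which
#' avoids pseudo-replication of member photoproducts. With a single time
#' point the ANOVA collapses to the two-sample t-test (F = t^2).
#'
#' @param curves_a,curves_b data.frames with `time`, `percent` and
#'   `replicate` columns (e.g. per-replicate cluster means), one per group.
#' @param times time points to contrast; defaults to the shared positive
#'   times (0 h is 0% by construction and is not compared).
#' @param labels group labels.
#' @return a `comparison_result`: list with `anova` (the full table),
#'   `interaction_p`, `per_time` (difference, t, raw and adjusted p,
#'   significance stars), `m`.
#' @export
two_way_anova_sidak <- function(curves_a, curves_b, times = NULL,
                                labels = c("A", "B")) {
  prep <- function(d, g) data.frame(group = g, time = d$time,
                                    replicate = d$replicate,
                                    value = d$percent)
  dat <- rbind(prep(curves_a, labels[1]), prep(curves_b, labels[2]))
  dat <- dat[!is.na(dat$value), , drop = FALSE]
  if (is.null(times)) {
    times <- sort(intersect(unique(curves_a$time), unique(curves_b$time)))
    times <- times[times > 0]
  }
  dat <- dat[dat$time %in% c(0, times), , drop = FALSE]
  reps <- with(dat, table(group, time))
  if (any(reps[, colnames(reps) %in% format(times)] < 2)) {
    stop("need >= 2 replicate observations per group and time",
         call. = FALSE)
  }
  dat$group <- factor(dat$group, levels = labels)
  dat$ftime <- factor(dat$time)
  multi_time <- nlevels(dat$ftime) > 1

  if (multi_time) {
    fit <- stats::aov(value ~ group * ftime, data = dat)
    tab <- summary(fit)[[1]]
    interaction_p <- tab["group:ftime", "Pr(>F)"]
    mse <- tab["Residuals", "Mean Sq"]
    df <- tab["Residuals", "Df"]
  } else {
    fit <- stats::aov(value ~ group, data = dat)
    tab <- summary(fit)[[1]]
    interaction_p <- NA_real_
    mse <- tab["Residuals", "Mean Sq"]
    df <- tab["Residuals", "Df"]
  }
  m <- length(times)
  per_time <- do.call(rbind, lapply(times, function(t) {
    va <- dat$value[dat$group == labels[1] & dat$time == t]
    vb <- dat$value[dat$group == labels[2] & dat$time == t]
    diff <- mean(va) - mean(vb)
    se <- sqrt(mse * (1 / length(va) + 1 / length(vb)))
    tstat <- if (se > 0) diff / se else 0
    p <- 2 * stats::pt(-abs(tstat), df)
    data.frame(time = t, diff = diff, t = tstat, df = df, p_raw = p,
               p_adj = 1 - (1 - p)^m)
  }))
  per_time$stars <- significance_stars(per_time$p_adj)
  structure(list(labels = labels, anova = tab,
                 interaction_p = interaction_p, per_time = per_time, m = m,
                 adjustment = "sidak"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s vs %s (Sidak m = %d)\n",
              x$labels[1], x$labels[2], x$m))
  if (!is.na(x$interaction_p)) {
    cat(sprintf("interaction p = %.4g\n", x$interaction_p))
  }
  print(x$per_time, row.names = FALSE)
  invisible(x)
}

#' Significance stars in the figure-legend convention
#'
#' @param p numeric p-values.
#' @return character: `****` p < 1e-4, `***` < 1e-3, `**` < 0.01,
#'   `*` < 0.05, `ns` otherwise.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

#' Transcription-coupled repair contribution at 4 hours
#'
#' Difference in repair extent between a TCR-proficient and a
#' TCR-deficient genotype of otherwise matched background (WT vs rad26, or
#' sir2 vs sir2 rad26): positive deltas on template-strand clusters measure
#' the TCR share of NER. A cluster is classified `TCR-assisted` when the
#' delta exceeds `threshold` percentage points and (when a comparison is
#' supplied) the per-time adjusted p at `t` is below `alpha`; otherwise
#' `GGR-only`.
#'
#' @param summary_with,summary_without `cluster_summary` rows (or any
#'   data.frames with `cluster`, `time`, `mean`) of the genotype with and
#'   without TCR, covering the same clusters and times.
#' @param t time point of the contrast (hours, default 4).
#' @param threshold minimum delta in percentage points (default 10).
#' @param comparison optional `comparison_result` supplying adjusted
#'   p-values; without it significance defaults to `TRUE` (threshold-only
#'   classification).
#' @param alpha significance level for the adjusted p.
#' @return data.frame: `cluster`, `repair_with`, `repair_without`, `delta`,
#'   `significant`, `classification`.
#' @export
tcr_contribution <- function(summary_with, summary_without, t = 4,
                             threshold = 10, comparison = NULL,
                             alpha = 0.05) {
  clusters <- unique(summary_with$cluster)
  if (!setequal(clusters, unique(summary_without$cluster))) {
    stop("mismatched subjects: the two summaries cover different clusters",
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(clusters, function(cl) {
    rw <- summary_with$mean[summary_with$cluster == cl &
                              summary_with$time == t]
    ro <- summary_without$mean[summary_without$cluster == cl &
                                 summary_without$time == t]
    if (length(rw) != 1 || length(ro) != 1) {
      stop(sprintf("time %s missing for cluster %s", format(t), cl),
           call. = FALSE)
    }
    data.frame(cluster = cl, repair_with = rw, repair_without = ro,
               delta = rw - ro, stringsAsFactors = FALSE)
  }))
  out$significant <- TRUE
  if (!is.null(comparison)) {
    p <- comparison$per_time$p_adj[comparison$per_time$time == t]
    out$significant <- rep(length(p) == 1 && p < alpha, nrow(out))
  }
  out$classification <- ifelse(out$delta >= threshold & out$significant,
                               "TCR-assisted", "GGR-only")
  out
}

#' Strand bias of repair at a time point
#'
#' Ratio of C-rich to G-rich strand repair extent; e.g. ~40% vs ~13%
#' removal gives a ~3-fold bias.
#'
#' @param summary_c,summary_g data.frames with `time` and `mean` (percent
#'   repair) for the two strands.
#' @param t time point (hours).
#' @return the ratio, or flagged `NA` when the denominator is <= 0.
#' @export
strand_bias <- function(summary_c, summary_g, t) {
  rc <- summary_c$mean[summary_c$time == t]
  rg <- summary_g$mean[summary_g$time == t]
  if (length(rc) != 1 || length(rg) != 1) {
    stop(sprintf("time %s absent from one of the summaries", format(t)),
         call. = FALSE)
  }
  if (rg <= 0) return(flag_value(NA_real_, TRUE, "undefined"))
  rc / rg
}
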