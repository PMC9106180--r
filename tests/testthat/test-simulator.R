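test_that("T4 lanes: undamaged or 6-4PP-only profiles leave the ratio at 1", {
  loc <- yprime_fixture(seed = 11)
  frag <- junction_fragments(loc, digest(loc, c("HindIII", "EcoRI")))[1, ]
  frag$probed_strand <- "C-rich"
  sites <- fragment_sites(loc, frag, "C-rich")
  model <- repair_rate_model(loc, "WT")

  none <- lesion_probabilities(sites, 0, 0, length_kb = frag$length_kb)
  ds <- simulate_t4v_lanes(loc, frag, none, model, times = 0,
                           n_molecules = 5000, noise = no_noise(), seed = 1)
  expect_equal(t4v_density_estimate(ds, frag$length_kb), 0)

  # 6-4PPs block polymerases but are not nicked by T4 endo-V
  only64 <- lesion_probabilities(sites, 180, 0, length_kb = frag$length_kb)
  only64$p_64 <- rep(0.002, nrow(sites))
  ds64 <- simulate_t4v_lanes(loc, frag, only64, model, times = 0,
                             n_molecules = 5000, noise = no_noise(), seed = 2)
  expect_equal(t4v_density_estimate(ds64, frag$length_kb), 0)
})

test_that("T4 zero-class estimate recovers the calibrated density", {
  loc <- yprime_fixture(seed = 11)
  frag <- junction_fragments(loc, digest(loc, c("HindIII", "EcoRI")))[1, ]
  frag$probed_strand <- "C-rich"
  sites <- fragment_sites(loc, frag, "C-rich")
  alpha <- calibrate_scale(sites, 180, frag$length_kb, 0.67)
  prof <- lesion_probabilities(sites, 180, alpha, length_kb = frag$length_kb)
  model <- repair_rate_model(loc, "WT")
  n <- 200000
  ds <- simulate_t4v_lanes(loc, frag, prof, model, times = 0,
                           n_molecules = n, noise = no_noise(), seed = 5)
  est <- t4v_density_estimate(ds, frag$length_kb)
  q0 <- prod(1 - prof$p_cpd)
  se_d <- sqrt((1 - q0) / (n * q0)) / frag$length_kb
  expect_lt(abs(est - 0.67), 3 * se_d)
})

test_that("binomial shortcut and molecule-level simulation agree", {
  loc <- yprime_fixture(seed = 11)
  frag <- digest(loc, "XhoI"); frag <- frag[frag$terminal, ]
  frag$probed_strand <- "C-rich"
  sites <- fragment_sites(loc, frag, "C-rich")
  alpha <- calibrate_scale(sites, 180, frag$length_kb, 0.58)
  prof <- lesion_probabilities(sites, 180, alpha, length_kb = frag$length_kb)
  model <- repair_rate_model(loc, "WT")
  est <- function(method, i) {
    ds <- simulate_t4v_lanes(loc, frag, prof, model, times = 0,
                             n_molecules = 5000, noise = no_noise(),
                             seed = derive_seed(9, method, i),
                             method = method)
    t4v_density_estimate(ds, frag$length_kb)
  }
  mb <- vapply(1:40, function(i) est("binomial", i), numeric(1))
  mm <- vapply(1:40, function(i) est("molecule", i), numeric(1))
  # same generative law: means agree within Monte-Carlo error
  se <- sqrt(var(mb) / 40 + var(mm) / 40)
  expect_lt(abs(mean(mb) - mean(mm)), 3 * se)
})

test_that("zero-class estimator is consistent: bias shrinks with n", {
  loc <- yprime_fixture(seed = 11)
  frag <- junction_fragments(loc, digest(loc, c("HindIII", "EcoRI")))[1, ]
  frag$probed_strand <- "G-rich"
  sites <- fragment_sites(loc, frag, "G-rich")
  alpha <- calibrate_scale(sites, 180, frag$length_kb, 0.45)
  prof <- lesion_probabilities(sites, 180, alpha, length_kb = frag$length_kb)
  model <- repair_rate_model(loc, "WT")
  run <- function(n, reps) {
    vapply(seq_len(reps), function(i) {
      ds <- simulate_t4v_lanes(loc, frag, prof, model, times = 0,
                               n_molecules = n, noise = no_noise(),
                               seed = derive_seed(13, n, i))
      t4v_density_estimate(ds, frag$length_kb)
    }, numeric(1))
  }
  small <- run(1000, 200)
  big <- run(100000, 200)
  rmse <- function(x) sqrt(mean((x - 0.45)^2))
  expect_lt(rmse(big), rmse(small))
  expect_lt(abs(mean(big) - 0.45), 0.45 * 0.01)
})

test_that("extension lanes: band fractions sum to 1 and degenerate cases", {
  loc <- x_fixture(seed = 21)
  x_start <- loc$elements$start[loc$elements$label == "XC"][1]
  pr <- make_primer(loc, "G-rich", c(x_start + 200L, x_start + 219L), "c")
  win <- primer_extension_window(loc, pr, "RsaI")
  sites <- scan_dipyrimidine_sites(loc, "G-rich", region = range(win$path))
  model <- repair_rate_model(loc, "WT")
  ns0 <- data.frame(top = integer(), prob = numeric())

  # zero lesions, zero natural stops, noise off -> all signal at full length
  none <- lesion_probabilities(sites, 0, 0)
  ds0 <- simulate_primer_extension_lanes(loc, pr, none, model, times = 0,
                                         n_molecules = 2000,
                                         natural_stops = ns0,
                                         noise = no_noise(), seed = 1,
                                         enzymes = "RsaI")
  l0 <- ds0$lanes[ds0$lanes$treatment == "+UV", ]
  expect_equal(l0$count[l0$band == "full"], 2000)
  expect_equal(sum(l0$count), 2000)

  # one certain lesion nearest the primer takes all the signal
  certain <- lesion_probabilities(sites, 0, 0)
  first_site <- which.max(sites$top_hi)  # first met: largest top for G-rich
  certain$p_cpd[first_site] <- 1
  ds1 <- simulate_primer_extension_lanes(loc, pr, certain, model, times = 0,
                                         n_molecules = 2000,
                                         natural_stops = ns0,
                                         noise = no_noise(), seed = 2,
                                         enzymes = "RsaI")
  l1 <- ds1$lanes[ds1$lanes$treatment == "+UV", ]
  expect_equal(l1$count[l1$band == paste0("stop_", sites$pos[first_site])],
               2000)
  expect_equal(l1$count[l1$band == "full"], 0)

  # with noise off, fractions sum to exactly 1 per lane
  alpha <- calibrate_scale(sites, 180, win$window_len / 1000, 0.5)
  prof <- lesion_probabilities(sites, 180, alpha)
  ds <- simulate_primer_extension_lanes(
    loc, pr, prof, model, times = c(0, 2), n_molecules = 3000,
    natural_stops = default_natural_stops(win, seed = 3),
    noise = no_noise(), seed = 4, enzymes = "RsaI")
  for (lid in unique(ds$lanes$lane_id)) {
    lane <- ds$lanes[ds$lanes$lane_id == lid, ]
    expect_equal(sum(lane$intensity / sum(lane$intensity)), 1)
    expect_equal(sum(lane$count), 3000)
  }
})

test_that("first-stop fractions match the exhaustive-enumeration oracle", {
  loc <- x_fixture(seed = 21)
  x_start <- loc$elements$start[loc$elements$label == "XC"][1]
  pr <- make_primer(loc, "G-rich", c(x_start + 200L, x_start + 219L), "c")
  win <- primer_extension_window(loc, pr, "RsaI")
  sites <- scan_dipyrimidine_sites(loc, "G-rich", region = range(win$path))
  # 5 active sites with assorted probabilities, all other sites silent
  prof <- lesion_probabilities(sites, 0, 0)
  active <- round(seq(1, nrow(sites), length.out = 5))
  p_active <- c(0.30, 0.05, 0.18, 0.40, 0.02)
  prof$p_cpd[active] <- p_active
  model <- repair_rate_model(loc, "rad14")  # freeze lesions
  n <- 200000
  ds <- simulate_primer_extension_lanes(
    loc, pr, prof, model, times = 0, n_molecules = n,
    natural_stops = data.frame(top = integer(), prob = numeric()),
    noise = no_noise(), seed = 6, enzymes = "RsaI")
  lane <- ds$lanes[ds$lanes$treatment == "+UV", ]
  # encounter order for a G-rich template: decreasing top coordinate
  ord <- order(-sites$top_hi[active])
  expected <- enumerate_first_stop(p_active[ord])
  got <- c(lane$count[match(paste0("stop_", sites$pos[active][ord]),
                            lane$band)], lane$count[lane$band == "full"]) / n
  for (i in seq_along(expected)) {
    se <- sqrt(expected[i] * (1 - expected[i]) / n)
    expect_lt(abs(got[i] - expected[i]), 3 * se + 1e-9)
  }
})

test_that("-UV extension lanes are invariant to dose and repair model", {
  loc <- x_fixture(seed = 21)
  x_start <- loc$elements$start[loc$elements$label == "XC"][1]
  pr <- make_primer(loc, "C-rich", c(x_start - 80L, x_start - 61L), "a")
  win <- primer_extension_window(loc, pr, "HhaI")
  sites <- scan_dipyrimidine_sites(loc, "C-rich", region = range(win$path))
  ns <- default_natural_stops(win, seed = 8)
  lanes_noUV <- function(alpha, strain) {
    prof <- lesion_probabilities(sites, 180, alpha)
    ds <- simulate_primer_extension_lanes(
      loc, pr, prof, repair_rate_model(loc, strain), times = 0,
      n_molecules = 2000, natural_stops = ns, noise = noise_config(),
      seed = 11, enzymes = "HhaI")
    l <- ds$lanes[ds$lanes$treatment == "-UV", ]
    l[, c("band", "count", "intensity")]  # signal, not strain labels
  }
  expect_identical(lanes_noUV(0, "WT"), lanes_noUV(5e-4, "rad14"))
})

test_that("experiments are byte-reproducible and substreams are stable", {
  loc <- x_fixture(seed = 21)
  plan <- default_extension_plan(loc, n_molecules = 500)
  plan$times <- c(0, 4)
  plan$assays <- plan$assays[1]
  a <- run_experiment(loc, c("WT", "rad26"), plan, replicates = 2,
                      master_seed = 77)
  b <- run_experiment(loc, c("WT", "rad26"), plan, replicates = 2,
                      master_seed = 77)
  expect_identical(lanes_df(a), lanes_df(b))
  expect_equal(length(a), 4)
  # adding a replicate leaves earlier replicates untouched
  c3 <- run_experiment(loc, c("WT", "rad26"), plan, replicates = 3,
                       master_seed = 77)
  sub <- lanes_df(c3)
  sub <- sub[sub$replicate <= 2, ]
  rownames(sub) <- NULL
  expect_identical(lanes_df(a), sub)
})
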