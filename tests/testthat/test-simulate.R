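test_that("noise epochs match the target amplitude scaling and are reproducible", {
  cfg <- tiny_config(noise_sd = 10)
  v <- simulate_noise_epochs(200, cfg, seed = 42)
  # pooled per-channel SD over a large seeded draw
  sds <- apply(v, 2, stats::sd)
  expect_true(all(abs(sds - 10) < 1))

  expect_identical(v, simulate_noise_epochs(200, cfg, seed = 42))
  expect_false(identical(v[1, , ], simulate_noise_epochs(200, cfg, seed = 43)[1, , ]))

  cfg0 <- tiny_config(noise_sd = 0)
  expect_true(all(simulate_noise_epochs(5, cfg0, seed = 1) == 0))
  expect_error(tiny_config(noise_sd = -1), "non-negative")
})

test_that("noise has the stated spatial and spectral structure", {
  cfg <- tiny_config(noise_sd = 10, channel_corr = 0.6, pink_frac = 0.8)
  v <- simulate_noise_epochs(150, cfg, seed = 5)
  # neighbouring channels correlate strongly through the shared pink part,
  # distant channels much less
  cc <- cor(cbind(as.vector(v[, 1, ]), as.vector(v[, 2, ]),
                  as.vector(v[, 8, ])))
  expect_gt(cc[1, 2], 0.3)
  expect_lt(cc[1, 3], cc[1, 2])
  # 1/f character: low-frequency spectral mass exceeds high-frequency mass
  sp <- rowMeans(apply(v[, 1, ], 1, function(x) Mod(stats::fft(x))^2))
  ns <- length(sp)
  expect_gt(mean(sp[2:6]), mean(sp[floor(ns / 2) + (-4:0)]))
})

test_that("signal injection is additive, windowed and envelope-shaped", {
  cfg <- tiny_config()
  times <- make_times(cfg$epoch_span, cfg$sampling_rate)
  epochs <- array(0, dim = c(3, 8, length(times)))

  # zero amplitude leaves the input untouched
  same <- inject_signal(epochs, rep(0, 3), rep(1 / sqrt(8), 8),
                        c(100, 260), times)
  expect_identical(same, epochs)

  # boxcar on one channel raises the in-window mean by exactly the amplitude
  pat <- c(1, rep(0, 7))
  out <- inject_signal(array(0, dim = c(1, 8, length(times))), 2, pat,
                       c(100, 260), times, envelope = "boxcar")
  idx <- which(times >= 100 & times < 260)
  expect_equal(mean(out[1, 1, idx]), 2)
  expect_true(all(out[1, 1, -idx] == 0))
  expect_true(all(out[1, 2:8, ] == 0))

  # half-cosine tapers to ~0 at the edges and peaks mid-window
  hc <- inject_signal(array(0, dim = c(1, 8, length(times))), 2, pat,
                      c(100, 260), times)
  prof <- hc[1, 1, idx]
  expect_lt(prof[1], max(prof) / 4)
  expect_equal(which.max(prof), ceiling(length(prof) / 2), tolerance = 1)

  expect_error(inject_signal(epochs, rep(1, 3), pat, c(100, 600), times),
               "outside epoch")
  expect_error(inject_signal(epochs, rep(1, 2), pat, c(100, 200), times),
               "amplitudes length")
})

test_that("two-class injection produces the expected class-mean difference", {
  # direct averaging oracle: amplitudes +/- a with a >> noise
  cfg <- tiny_config(noise_sd = 1)
  times <- make_times(cfg$epoch_span, cfg$sampling_rate)
  n <- 100
  a <- 50
  pat <- default_spatial_pattern(8)
  epochs <- simulate_noise_epochs(n, cfg, seed = 3)
  amps <- rep(c(a, -a), each = n / 2)
  out <- inject_signal(epochs, amps, pat, c(100, 260), times,
                       envelope = "boxcar")
  idx <- which(times >= 100 & times < 260)
  m1 <- apply(out[1:(n / 2), , idx], 2, mean)
  m2 <- apply(out[(n / 2 + 1):n, , idx], 2, mean)
  expect_equal(m1 - m2, 2 * a * pat, tolerance = 0.05)
})

test_that("behavior generator reproduces group ordering and response-rating coupling", {
  cfg <- sim_config(n_participants = 12,
                    group_sizes = c(never = 4, current = 4, past = 4),
                    n_images = 60, n_channels = 8,
                    epoch_span = c(-100, 300), signal_window = c(100, 260),
                    early_window = c(0, 80))
  truth <- draw_ground_truth(cfg, seed = 11)
  beh <- simulate_behavior(cfg, truth, seed = 12)
  tab <- beh$table[beh$table$dimension == "appealing", ]
  gm <- tapply(tab$mean_rating, tab$group, mean)
  # currently-vaping rate highest, never-vaped lowest
  expect_gt(gm[["current"]], gm[["past"]])
  expect_gt(gm[["past"]], gm[["never"]])
  gy <- tapply(tab$yes_count, tab$group, mean)
  expect_gt(gy[["current"]], gy[["never"]])

  # per-image Yes counts and mean ratings are positively coupled
  co <- image_level_correlation(beh$responses, "appealing")
  expect_gt(co$r_yes, 0)
  expect_lt(co$r_no, 0)

  # exchangeability: identical group offsets leave only sampling differences
  cfg0 <- sim_config(n_participants = 30,
                     group_sizes = c(never = 10, current = 10, past = 10),
                     n_images = 40, n_channels = 8,
                     epoch_span = c(-100, 300), signal_window = c(100, 260),
                     early_window = c(0, 80),
                     behavior_params = list(group_mean = c(never = 0, current = 0, past = 0)))
  t0 <- draw_ground_truth(cfg0, seed = 21)
  b0 <- simulate_behavior(cfg0, t0, seed = 22)
  tb <- b0$table[b0$table$dimension == "wanting", ]
  a <- oneway_anova_bonferroni(tb$mean_rating, tb$group)
  expect_gt(a$p, 0.01)
})

test_that("generate_study composes a full consistent study deterministically", {
  cfg <- tiny_config(signal_amplitude = 3)
  st <- generate_study(cfg, seed = 9)
  expect_length(st$datasets, 4)
  for (ds in st$datasets) {
    expect_equal(nrow(ds$trials), 60)
    expect_equal(as.vector(table(ds$trials$dimension)), c(20, 20, 20))
  }
  st2 <- generate_study(cfg, seed = 9)
  expect_identical(st$datasets[[2]]$voltages, st2$datasets[[2]]$voltages)
  expect_identical(st$behavior, st2$behavior)

  # behavioral/neural consistency: Yes trials carry higher injected amplitude
  ds <- st$datasets[[2]]
  amp <- st$truth$amplitude[ds$participant_id, ds$trials$image_id]
  keep <- ds$trials$response != "none"
  expect_gt(mean(amp[keep][ds$trials$response[keep] == "yes"]),
            mean(amp[keep][ds$trials$response[keep] == "no"]))
})

test_that("zero-amplitude studies carry no class information", {
  cfg <- tiny_config(signal_amplitude = 0, n_images = 40)
  st <- generate_study(cfg, seed = 30)
  times <- st$datasets[[1]]$times
  idx <- which(times >= 100 & times < 260)
  # class-mean difference within the (uninjected) signal window shrinks
  # with trial count
  diff_for <- function(ds, k) {
    sel <- ds$trials$dimension == "appealing"
    v <- ds$voltages[sel, , idx][seq_len(k), , ]
    y <- ds$trials$response[sel][seq_len(k)]
    if (length(unique(y)) < 2) return(NA_real_)
    abs(mean(v[y == "yes", , ]) - mean(v[y == "no", , ]))
  }
  d_small <- diff_for(st$datasets[[2]], 8)
  d_large <- diff_for(st$datasets[[2]], 40)
  expect_lt(d_large, d_small + 1)  # no growth; typically a clear shrink
  expect_lt(d_large, 2)            # near zero at 40 trials, noise_sd = 10
})

test_that("within-window SNR increases with signal amplitude", {
  amps <- c(0, 2, 6, 12)
  snr <- vapply(amps, function(a) {
    cfg <- tiny_config(signal_amplitude = a, n_images = 30, seed = 1)
    st <- generate_study(cfg, seed = 17)
    ds <- st$datasets[[2]]
    times <- ds$times
    idx <- which(times >= 100 & times < 260)
    amp <- st$truth$amplitude[ds$participant_id, ds$trials$image_id]
    sig <- apply(ds$voltages[, , idx], 1, mean)
    if (a == 0) 0 else abs(stats::cor(sig, amp))
  }, numeric(1))
  expect_true(all(diff(snr) > 0))
})
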