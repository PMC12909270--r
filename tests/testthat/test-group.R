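test_that("one-tailed paired t matches hand computation and the stats oracle", {
  # d = (1, 2, 3): mean 2, SD 1, n 3 -> t = 2 / (1/sqrt(3)) = 3.4641, df 2
  r <- paired_t_onetailed(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$t, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2)
  expect_equal(r$p, 0.0371, tolerance = 1e-3)
  # independent oracle
  tt <- t.test(c(2, 4, 6), c(1, 2, 3), paired = TRUE, alternative = "greater")
  expect_equal(r$t, unname(tt$statistic))
  expect_equal(r$p, tt$p.value)

  # zero-variance differences are degenerate
  r0 <- paired_t_onetailed(c(1, 1, 1), c(1, 1, 1))
  expect_true(r0$degenerate)
  expect_equal(r0$p, 1)
  rp <- paired_t_onetailed(c(2, 2, 2), c(1, 1, 1))
  expect_equal(rp$p, 0)

  # symmetry: negating all differences maps p to 1 - p
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(paired_t_onetailed(a, b)$p, 1 - paired_t_onetailed(b, a)$p)
})

test_that("cluster finding follows the threshold-and-contiguity rule", {
  p <- c(0.2, 0.01, 0.02, 0.3, 0.04)
  t <- c(1, 3, 2.5, 0.5, 2)
  cl <- find_clusters(p, t, 0.05)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$start, c(2, 5))
  expect_equal(cl$end, c(3, 5))
  expect_equal(cl$mass, c(5.5, 2))

  expect_equal(nrow(find_clusters(rep(0.5, 6), rep(1, 6))), 0)
  all_in <- find_clusters(rep(0.01, 6), rep(2, 6))
  expect_equal(nrow(all_in), 1)
  expect_equal(c(all_in$start, all_in$end), c(1, 6))
  # negative-t windows never join clusters even when p is small
  neg <- find_clusters(c(0.01, 0.01, 0.01), c(2, -2, 2))
  expect_equal(nrow(neg), 2)
})

test_that("exhaustive sign-flip null equals a brute-force enumeration", {
  set.seed(11)
  diffs <- matrix(rnorm(5 * 3, mean = 1.2), 5, 3)  # 5 participants, 3 windows
  res <- cluster_permutation_test(diffs, exhaustive = TRUE)

  # independent brute-force oracle over all 2^5 sign assignments
  oracle_max <- function(D) {
    tt <- apply(D, 2, function(x) t.test(x, alternative = "greater"))
    tv <- vapply(tt, function(z) unname(z$statistic), numeric(1))
    pv <- vapply(tt, function(z) z$p.value, numeric(1))
    supra <- pv < 0.05 & tv > 0
    if (!any(supra)) return(0)
    r <- rle(supra); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    max(vapply(which(r$values), function(i) sum(tv[starts[i]:ends[i]]),
               numeric(1)))
  }
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), 5)))
  null <- apply(signs, 1, function(s) oracle_max(diffs * s))
  expect_equal(sort(res$null_max_mass), sort(null), tolerance = 1e-10)

  obs <- oracle_max(diffs)
  for (i in seq_len(nrow(res$clusters)))
    expect_equal(res$clusters$cluster_p[i],
                 sum(null >= res$clusters$mass[i]) / 32, tolerance = 1e-12)
})

test_that("a strong contiguous effect yields exactly one covering cluster", {
  set.seed(12)
  n <- 12; W <- 50
  diffs <- matrix(rnorm(n * W, 0, 0.5), n, W)
  diffs[, 10:40] <- diffs[, 10:40] + 10   # effect >> noise
  res <- cluster_permutation_test(diffs, n_permutations = 500, seed = 2)
  sig <- res$clusters[res$clusters$cluster_p < 0.05, ]
  expect_equal(nrow(sig), 1)
  expect_equal(c(sig$start, sig$end), c(10, 40))
  expect_true(all(which(res$significant) == 10:40))
  # mask only covers supra-threshold windows
  expect_true(all(res$p_uncorrected[res$significant] < res$alpha_forming))
})

test_that("cluster p decreases with effect amplitude", {
  set.seed(13)
  base <- matrix(rnorm(10 * 30), 10, 30)
  p_at <- vapply(c(0.3, 0.8, 1.6), function(a) {
    d <- base; d[, 12:18] <- d[, 12:18] + a
    res <- cluster_permutation_test(d, n_permutations = 300, seed = 4)
    if (nrow(res$clusters) == 0) return(1)
    min(res$clusters$cluster_p)
  }, numeric(1))
  expect_true(all(diff(p_at) <= 0))
})

test_that("permutation count and degenerate inputs are validated", {
  d <- matrix(rnorm(20), 5, 4)
  expect_warning(cluster_permutation_test(d, n_permutations = 50, seed = 1),
                 "fewer than 100")
  expect_error(cluster_permutation_test(d, n_permutations = 0), ">= 1")
  expect_error(cluster_permutation_test(d[1, , drop = FALSE]), "at least 2")
})

test_that("feature weights recover an injected spatial pattern", {
  # signal confined to 6 known channels of a 16-channel montage; amplitude
  # well above the noise floor and a steep response model so the Yes/No
  # classes are cleanly tied to the injected component
  nc <- 16
  true_ch <- c(3, 4, 5, 11, 12, 13)
  pat <- numeric(nc); pat[true_ch] <- 1
  pat <- pat / sqrt(sum(pat^2))
  bp <- list(group_mean = c(never = 0, current = 0, past = 0),
             yes_intercept = 0, yes_slope = 6)
  cfg <- sim_config(n_participants = 10, group_sizes = c(4, 4, 2),
                    n_images = 240, n_channels = nc,
                    epoch_span = c(-100, 300), signal_window = c(100, 260),
                    early_window = c(0, 80), early_amplitude_frac = 0,
                    signal_amplitude = 80, noise_sd = 8,
                    spatial_pattern = pat, behavior_params = bp)
  st <- generate_study(cfg, seed = 51)
  datasets <- lapply(st$datasets, baseline_correct)
  grid <- build_windows(datasets[[1]]$times, 512, 10)
  in_sig <- which(grid$times_ms >= 120 & grid$times_ms < 240)
  fw <- feature_weight_map(datasets, "appealing", in_sig, grid,
                           decode_params(min_per_class = 5), seed = 1)
  top6 <- order(fw$weight_z, decreasing = TRUE)[1:6]
  expect_setequal(top6, true_ch)
  expect_true(all(fw$significant[true_ch]))
  expect_false(any(fw$significant[-true_ch]))

  # spatially uniform pattern: standardization removes the common level
  patu <- rep(1 / sqrt(nc), nc)
  cfgu <- sim_config(n_participants = 6, group_sizes = c(2, 2, 2),
                     n_images = 60, n_channels = nc,
                     epoch_span = c(-100, 300), signal_window = c(100, 260),
                     early_window = c(0, 80), early_amplitude_frac = 0,
                     signal_amplitude = 80, noise_sd = 8,
                     spatial_pattern = patu, behavior_params = bp)
  stu <- generate_study(cfgu, seed = 52)
  fwu <- feature_weight_map(lapply(stu$datasets, baseline_correct),
                            "appealing", in_sig, grid,
                            decode_params(min_per_class = 5), seed = 1)
  expect_lt(max(abs(fwu$weight_z)), 1.5)
})
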