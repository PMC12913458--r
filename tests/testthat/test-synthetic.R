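test_that("templates are unit-norm, well separated and seed-deterministic", {
  tpl <- make_templates(4, 54, seed = 42)
  expect_equal(dim(tpl$maps), c(4, 54))
  expect_equal(unname(rowSums(tpl$maps^2)), rep(1, 4), tolerance = 1e-12)
  cs <- abs(tcrossprod(tpl$maps)); diag(cs) <- 0
  expect_lte(max(cs), 0.6)
  tpl2 <- make_templates(4, 54, seed = 42)
  expect_identical(tpl$maps, tpl2$maps)
  expect_false(identical(tpl$maps, make_templates(4, 54, seed = 1)$maps))

  one <- make_templates(1, 8, seed = 3)
  expect_equal(sum(one$maps^2), 1, tolerance = 1e-12)
  expect_error(make_templates(5, 4), "invalid config")
})

test_that("semi-Markov label simulation honors absorbing, cyclic and mixing chains", {
  # absorbing chain stays put
  expect_equal(unique(simulate_labels(diag(4), 5, 2, 100, seed = 1,
                                      start = 2)), 2L)
  # deterministic cycle with fixed dwell 3
  cyc <- matrix(0, 4, 4); cyc[cbind(1:4, c(2, 3, 4, 1))] <- 1
  expect_equal(simulate_labels(cyc, 3, Inf, 12, seed = 1, start = 0),
               rep(0:3, each = 3))
  # uniform chain: occupancies near 1/4 (stationary distribution of the
  # embedded semi-Markov process with equal dwell means)
  P <- matrix(1 / 3, 4, 4); diag(P) <- 0
  lab <- simulate_labels(P, 13, 2, 100000, seed = 7)
  expect_equal(length(lab), 100000L)
  occ <- tabulate(lab + 1, 4) / length(lab)
  expect_true(all(abs(occ - 0.25) <= 0.02))
  # invalid matrices rejected
  expect_error(simulate_labels(matrix(0.4, 2, 2), 5, 2, 10), "sum to 1")
})

test_that("synthesized recordings are rank-1 per sample and reproducible", {
  tpl <- make_templates(4, 16, seed = 5)
  P <- matrix(1 / 3, 4, 4); diag(P) <- 0
  lab <- simulate_labels(P, 10, 2, 512, seed = 2)
  gains <- matrix(0, 4, 5); gains[, 3] <- 10 # single band
  rec <- synthesize_recording(lab, tpl, gains, noise_sd = 0, seed = 3)
  nrm <- sqrt(colSums(rec$data^2))
  live <- which(nrm > 1e-8)
  cors <- vapply(live, function(t)
    abs(sum(rec$data[, t] / nrm[t] * tpl$maps[lab[t] + 1, ])), numeric(1))
  expect_true(all(cors > 1 - 1e-9))
  # all gains zero, no noise -> silence
  rec0 <- synthesize_recording(lab, tpl, matrix(0, 4, 5), noise_sd = 0)
  expect_equal(max(abs(rec0$data)), 0)
  # determinism
  reca <- synthesize_recording(lab, tpl, gains, noise_sd = 1, seed = 9)
  recb <- synthesize_recording(lab, tpl, gains, noise_sd = 1, seed = 9)
  expect_identical(reca$data, recb$data)
})

test_that("planted state-band gain raises that state's source band power", {
  tpl <- make_templates(4, 8, seed = 1)
  P <- matrix(1 / 3, 4, 4); diag(P) <- 0
  lab <- simulate_labels(P, 13, 2, 128 * 60, seed = 4)
  gains <- matrix(5, 4, 5)
  gains[4, 1] <- 10 # state 3 delta gain 2x state 0's
  rec <- synthesize_recording(lab, tpl, gains, noise_sd = 0.1, seed = 6)
  es <- eeg_epochs(array(rec$data, c(1, nrow(rec$data), ncol(rec$data))),
                   fs = 128, ch_names = rec$ch_names)
  ml <- ms_labels(list(lab), K = 4, fs = 128)
  p3 <- suppressWarnings(state_band_powers(es, ml, 3))
  p0 <- suppressWarnings(state_band_powers(es, ml, 0))
  expect_gt(p3[["delta"]], p0[["delta"]])
})

test_that("cohort generation is reproducible and plants the configured offsets", {
  cfg <- generator_config(n_per_group = 2, duration = 10, seed = 31)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$recordings[[1]]$data, co2$recordings[[1]]$data)
  expect_identical(co1$ground_truth$labels, co2$ground_truth$labels)
  expect_equal(as.character(unique(co1$groups)), c("NT", "ASD"))
  # zero offsets -> parameter records identical across groups
  g <- generator_config(n_per_group = 2, duration = 5,
                        dwell_mean = list(rep(13, 4), rep(13, 4)),
                        band_gains = list(matrix(5, 4, 5), matrix(5, 4, 5)),
                        seed = 1)
  co0 <- generate_cohort(g)
  pa <- co0$ground_truth$params[[1]]; pb <- co0$ground_truth$params[[3]]
  expect_identical(pa$dwell_mean, pb$dwell_mean)
  expect_identical(pa$band_gains, pb$band_gains)
  # planted shorter dwells -> shorter planted inter-transition intervals
  cfg2 <- generator_config(n_per_group = 20, duration = 20, seed = 11)
  co <- generate_cohort(cfg2)
  iti <- vapply(co$ground_truth$labels,
                function(l) suppressWarnings(mean_iti(l)), numeric(1))
  expect_lt(mean(iti[co$groups == "ASD"]), mean(iti[co$groups == "NT"]))
})

test_that("planted label coverages sum to one and effects are gain-monotone", {
  cfg <- generator_config(n_per_group = 1, duration = 10, seed = 2)
  co <- generate_cohort(cfg)
  for (l in co$ground_truth$labels)
    expect_equal(sum(tabulate(l + 1, 4)) / length(l), 1)
  # extracted state-band power rises monotonically with the planted gain
  tpl <- make_templates(4, 8, seed = 9)
  P <- matrix(1 / 3, 4, 4); diag(P) <- 0
  lab <- simulate_labels(P, 13, 2, 128 * 40, seed = 5)
  es_for <- function(gain) {
    g <- matrix(5, 4, 5); g[2, 3] <- gain
    rec <- synthesize_recording(lab, tpl, g, noise_sd = 0.1, seed = 8)
    es <- eeg_epochs(array(rec$data, c(1, nrow(rec$data), ncol(rec$data))),
                     fs = 128, ch_names = rec$ch_names)
    suppressWarnings(
      state_band_powers(es, ms_labels(list(lab), 4, 128), 1))[["alpha"]]
  }
  pw <- vapply(c(2, 6, 18), es_for, numeric(1))
  expect_true(all(diff(pw) > 0))
})
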