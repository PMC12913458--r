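test_that("GFP is the per-sample population SD across channels", {
  expect_equal(gfp_curve(matrix(c(1, -1, 0, 0), 4, 1)), sqrt(0.5),
               tolerance = 1e-12)
  expect_equal(gfp_curve(matrix(5, 6, 3)), rep(0, 3))
  set.seed(4)
  ep <- matrix(rnorm(8 * 64), 8)
  expect_equal(gfp_curve(ep), gfp_oracle(ep), tolerance = 1e-12)
  expect_error(gfp_curve(matrix(1, 1, 10)), "2 channels")
})

test_that("GFP peak picking keeps strict local maxima with spacing", {
  expect_equal(microstatr:::find_peaks(c(1, 3, 1, 5, 1), 1), c(2, 4))
  expect_equal(microstatr:::find_peaks(1:10, 1), integer(0)) # monotone
  # plateau takes the leftmost sample
  expect_equal(microstatr:::find_peaks(c(0, 2, 2, 2, 0), 1), 2)
  # spacing conflict resolved by height
  expect_equal(microstatr:::find_peaks(c(0, 3, 0, 5, 0, 1, 0), 3), 4)
  # returned maps are unit norm
  set.seed(1)
  es <- epoch_recording(eeg_recording(matrix(rnorm(6 * 512), 6), 128))
  maps <- extract_peak_maps(es)
  expect_gt(nrow(maps), 0)
  expect_equal(unname(rowSums(maps^2)), rep(1, nrow(maps)), tolerance = 1e-9)
})

test_that("K-means recovers well-separated clusters and orders by size", {
  set.seed(5)
  v <- t(qr.Q(qr(matrix(rnorm(64), 8)))[, 1:4]) # 4 orthonormal rows
  maps <- v[c(rep(1, 40), rep(2, 30), rep(3, 20), rep(4, 10)), ]
  maps <- maps + 0 # exact copies
  tpl <- learn_templates(maps, K = 4, seed = 1)
  sims <- abs(tpl$maps %*% t(v))
  expect_true(all(apply(sims, 1, max) >= 0.999))
  # ordered by descending cluster size
  expect_equal(tpl$sizes, c(40, 30, 20, 10))
  expect_equal(which.max(sims[1, ]), 1L) # biggest cluster = first planted row
  expect_error(learn_templates(maps[1:3, ], K = 4), "at least K")
})

test_that("back-fitting labels by best template match with stated tie and zero rules", {
  v <- t(qr.Q(qr(matrix(rnorm(36, 1), 6)))[, 1:4])
  tpl <- template_set(v)
  # sample equal to template 2 -> label 2; negated -> not 2 under signed match
  x <- cbind(v[3, ], -v[3, ], v[1, ] * 7)
  lab <- assign_labels(x, tpl)
  expect_equal(lab[1], 2L)
  expect_false(lab[2] == 2L)
  expect_equal(lab[3], 0L) # scale invariant
  expect_equal(assign_labels(x, tpl, ignore_polarity = TRUE)[2], 2L)
  # zero-norm samples carry the previous label; leading zero -> state 0
  z <- cbind(rep(0, 6), v[2, ], rep(0, 6))
  labz <- assign_labels(z, tpl)
  expect_equal(labz, c(0L, 1L, 1L))
  expect_error(assign_labels(matrix(1, 3, 2), tpl), "mismatch")
})

test_that("labels are scale-invariant, complete, and recover planted sequences", {
  tpl <- make_templates(4, 16, seed = 2)
  P <- matrix(1 / 3, 4, 4); diag(P) <- 0
  lab <- simulate_labels(P, 12, 2, 2048, seed = 3)
  gains <- matrix(6, 4, 5)
  rec <- synthesize_recording(lab, tpl, gains, noise_sd = 0, seed = 4)
  es <- eeg_epochs(array(rec$data, c(1, 16, 2048)), fs = 128)
  got <- assign_labels(es, tpl, ignore_polarity = TRUE)
  flat <- flatten_labels(got)
  expect_equal(length(flat), 2048)
  expect_true(all(flat >= 0 & flat < 4))
  expect_gte(mean(flat == lab), 0.9) # noise-free agreement
  es2 <- eeg_epochs(array(3.7 * rec$data, c(1, 16, 2048)), fs = 128)
  expect_identical(flatten_labels(assign_labels(es2, tpl,
                                                ignore_polarity = TRUE)),
                   flat)
})

test_that("templates learned from a low-noise cohort match the planted maps", {
  cfg <- generator_config(n_per_group = 2, duration = 20, noise_sd = 0.05,
                          seed = 17)
  co <- generate_cohort(cfg)
  pl <- ms_pipeline(co$recordings, seed = 42)
  sims <- abs(pl$templates$maps %*% t(co$ground_truth$templates$maps))
  # greedy one-to-one assignment on |correlation|
  match_sim <- numeric(4)
  M <- sims
  for (i in 1:4) {
    w <- which(M == max(M), arr.ind = TRUE)[1, ]
    match_sim[i] <- M[w[1], w[2]]
    M[w[1], ] <- -1; M[, w[2]] <- -1
  }
  expect_true(all(match_sim >= 0.95))
})

test_that("recovered coverage tracks planted coverage under moderate noise", {
  # heterogeneous dwell means give states genuinely different coverages
  dm <- list(c(7, 10, 14, 20), c(7, 10, 14, 20))
  cfg <- generator_config(n_per_group = 3, duration = 30, dwell_mean = dm,
                          seed = 29)
  co <- generate_cohort(cfg)
  pl <- ms_pipeline(co$recordings, seed = 42)
  sims <- abs(pl$templates$maps %*% t(co$ground_truth$templates$maps))
  cov_planted <- t(vapply(co$ground_truth$labels,
                          function(l) tabulate(l + 1, 4) / length(l),
                          numeric(4)))
  perm <- apply(sims, 2, which.max) # planted k -> learned perm[k]
  cov_rec <- t(vapply(pl$labels, function(l)
    tabulate(flatten_labels(l) + 1, 4) / length(flatten_labels(l)),
    numeric(4)))[, perm, drop = FALSE]
  expect_gte(cor(as.vector(cov_planted), as.vector(cov_rec)), 0.8)
})
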