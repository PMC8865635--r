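test_that("pairwise RDMs are symmetric, zero-diagonal and trial-consistent", {
  des <- small_design(n_runs = 4, n_stim = 8, n_ch = 8)
  s <- generate_subject(des, quiet_effects(), "HC", seed = 1)
  rdm <- compute_rdm(s, 250)
  expect_equal(dim(rdm), c(8, 8))
  expect_true(isSymmetric(rdm))
  expect_equal(unname(diag(rdm)), rep(0, 8))
  expect_true(all(rdm >= 0 & rdm <= 1))
  expect_equal(rownames(rdm), as.character(1:8))
  # a cell equals leave-one-trial-out CV on exactly those trials
  tt <- nearest_sample(s, 250)
  tr <- which(s$stimulus_id %in% c(1, 2))
  x <- s$data[tr, , tt]
  y <- c("a", "b")[match(s$stimulus_id[tr], c(1, 2))]
  expect_equal(rdm["1", "2"], loo_cv_accuracy(x, y))
  single <- manual_epochs(array(rnorm(2 * 2 * 10), c(2, 2, 10)),
                          stimulus_id = 1:2,
                          class_label = c("animate", "inanimate"))
  expect_error(compute_rdm(single, 50), "at least 2 trials")
})

test_that("RDM cells saturate for separated stimuli and not for merged ones", {
  # two stimuli far apart, a third duplicating the first
  set.seed(2)
  mk <- function(center) matrix(rnorm(6 * 2, center, 0.1), 6, 2)
  d <- array(0, c(18, 2, 10))
  d[1:6, , ] <- mk(5); d[7:12, , ] <- mk(-5); d[13:18, , ] <- mk(5)
  ep <- manual_epochs(d, stimulus_id = rep(1:3, each = 6),
                      class_label = rep(c("animate", "inanimate", "animate"),
                                        each = 6))
  rdm <- compute_rdm(ep, 50)
  expect_equal(rdm["1", "2"], 1)
  expect_equal(rdm["2", "3"], 1)
  expect_lt(rdm["1", "3"], 0.8)
})

test_that("RDM series stack slices on the requested time axis", {
  des <- small_design(n_runs = 3, n_stim = 8, n_ch = 8)
  s <- generate_subject(des, quiet_effects(), "HC", seed = 4)
  ser <- compute_rdm_series(s, c(-50, 100, 250))
  expect_s3_class(ser, "rdm_series")
  expect_equal(dim(ser$rdm), c(8, 8, 3))
  expect_equal(ser$times_ms, c(-50, 100, 250))
  expect_equal(ser$rdm[, , 3], compute_rdm(s, 250))
})

test_that("identical cohorts give zero RDM distance and a null p-value", {
  des <- small_design(n_runs = 3, n_stim = 8, n_ch = 8)
  subs <- lapply(1:4, function(i)
    generate_subject(des, quiet_effects(), "HC", seed = i))
  ser <- lapply(subs, compute_rdm_series, times_ms = c(-50, 100, 250))
  res <- suppressWarnings(
    rdm_distance_timecourse(ser, ser, n_perm = 200, seed = 1))
  expect_equal(res$distance, rep(0, 3))
  expect_gt(res$p_value, 0.5)
  # disjoint subject sets with shared statistics stay non-significant
  ser2 <- lapply(5:8, function(i)
    compute_rdm_series(generate_subject(des, quiet_effects(), "HC", seed = i),
                       times_ms = c(-50, 100, 250)))
  res2 <- suppressWarnings(
    rdm_distance_timecourse(ser, ser2, n_perm = 200, seed = 1))
  expect_gt(res2$p_value, 0.05)
  expect_length(res2$distance, 3)
  expect_true(all(res2$scaled >= 0 & res2$scaled <= 1))
})

test_that("distance scaling honours its anchors and monotonicity", {
  anchors <- c(min = 0, baseline = 20, max = 100)
  d <- c(0, 10, 20, 60, 100)
  s <- scale_distance(d, anchors, baseline_image = 0.5)
  expect_equal(s[1], 0)
  expect_equal(s[5], 1)
  expect_equal(s[3], 0.5, tolerance = 1e-6)   # baseline maps to its image
  expect_true(all(diff(s) > 0))
  # concavity: the map lies at or above the linear one
  expect_true(all(s >= d / 100 - 1e-12))
  # an image below the linear map is unattainable: linear fallback + warning
  expect_warning(lin <- scale_distance(d, c(min = 0, baseline = 80, max = 100),
                                       baseline_image = 0.5), "linear")
  expect_equal(lin, d / 100)
  expect_warning(scale_distance(c(-5, 50), anchors, 0.5), "clamped")
})

test_that("cell-wise comparison flags exactly the manipulated cell", {
  set.seed(7)
  mk <- function(bump) {
    m <- matrix(0, 4, 4, dimnames = list(1:4, 1:4))
    m[upper.tri(m)] <- 0.5 + rnorm(6, 0, 0.02)
    m["1", "2"] <- m["1", "2"] + bump
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  hc <- lapply(1:10, function(i) mk(0.4))
  mci <- lapply(1:10, function(i) mk(0))
  res <- rdm_cellwise_comparison(hc, mci)
  expect_true(res$flags["1", "2"])
  expect_true(res$flags["2", "1"])            # symmetric output
  expect_equal(sum(res$flags, na.rm = TRUE), 2)
  expect_true(all(is.na(diag(res$p))))
})

test_that("MDS embedding preserves an equilateral configuration", {
  r <- matrix(1, 3, 3); diag(r) <- 0
  emb <- mds_embed(r, dims = 2)
  dd <- as.matrix(dist(emb$points))
  off <- dd[upper.tri(dd)]
  expect_lt(diff(range(off)) / mean(off), 0.01)
  expect_lt(emb$stress, 0.01)
  # a noisy RDM still embeds with distances correlated to the input
  set.seed(9)
  p <- matrix(rnorm(12), 6, 2)
  r2 <- as.matrix(dist(p))
  emb2 <- mds_embed(r2, dims = 2, seed = 2)
  d2 <- as.matrix(dist(emb2$points))
  expect_gt(cor(r2[upper.tri(r2)], d2[upper.tri(d2)]), 0.99)
  # duplicate stimuli (zero off-diagonal distance) do not break the fit
  r3 <- r2; r3[1, 2] <- r3[2, 1] <- 0
  expect_silent(mds_embed(r3, dims = 2))
  expect_error(mds_embed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
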