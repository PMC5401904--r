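test_that("dF/F is zero for constant traces and recovers relative changes", {
  rec <- fluorescence_recording(matrix(80, 3, 300))
  dff <- compute_dff(rec)
  expect_true(all(dff == 0))
  # a trace spending most of its time at baseline recovers x in F0*(1+x)
  x <- rep(0, 300)
  x[150:152] <- 0.5
  rec2 <- fluorescence_recording(rbind(60 * (1 + x), rep(60, 300)))
  dff2 <- compute_dff(rec2)
  expect_equal(dff2[1, ], x, tolerance = 1e-12)
})

test_that("noiseless simulator output round-trips through dF/F", {
  set <- generate_cluster_set(1, "control_like", seed = 5,
                              indicator_args = list(noise_sd = 0))
  dff <- compute_dff(set$recording[[1]])
  truth <- set$truth_raster[[1]]$onsets
  # isolated interior events only: the 1% claim is about a clean single
  # transient — tails of neighbouring events inside the 100-frame rolling
  # window shift the 20th-percentile baseline, and truncated windows at the
  # recording edges do the same
  ev <- which(truth == 1L, arr.ind = TRUE)
  isolated <- vapply(seq_len(nrow(ev)), function(k) {
    others <- which(truth[ev[k, 1], ] == 1L)
    others <- others[others != ev[k, 2]]
    gap_prior <- ev[k, 2] - others[others < ev[k, 2]]
    gap_next <- others[others > ev[k, 2]] - ev[k, 2]
    all(gap_prior > 100) && all(gap_next > 50) &&
      ev[k, 2] > 60 && ev[k, 2] <= ncol(truth) - 60
  }, logical(1))
  peaks <- dff[ev[isolated, , drop = FALSE]]
  expect_gt(length(peaks), 0)
  expect_true(all(abs(peaks - 0.3) / 0.3 < 0.01))
})

test_that("dF/F input contracts are enforced", {
  expect_error(compute_dff(fluorescence_recording(matrix(1, 3, 50))),
               "fewer frames")
  expect_error(
    compute_dff(fluorescence_recording(matrix(-1, 3, 200))),
    "non-positive")
  expect_error(fluorescence_recording(matrix(1, 1, 100)), "2 neurons")
  expect_error(fluorescence_recording(matrix(NA_real_, 3, 100)), "missing")
})

test_that("onset detection handles empty, single and stacked transients", {
  # all-zero dF/F: empty raster
  z <- matrix(0, 3, 300)
  expect_equal(sum(detect_events(z)$onsets), 0)
  # one clean transient detected exactly once at its onset frame
  ip <- indicator_params(noise_sd = 0)
  r <- make_raster(2, 300, cbind(1, 120))
  det <- detect_events(compute_dff(spikes_to_fluorescence(r, ip)))
  expect_equal(which(det$onsets[1, ] == 1L), 120)
  expect_equal(sum(det$onsets), 1)
  # a second event riding the first one's decay tail is still found
  r2 <- make_raster(2, 300, rbind(c(1, 120), c(1, 130)))
  det2 <- detect_events(compute_dff(spikes_to_fluorescence(r2, ip)))
  expect_equal(which(det2$onsets[1, ] == 1L), c(120, 130))
})

test_that("noiseless simulated clusters are recovered exactly", {
  for (s in c(3, 8)) {
    set <- generate_cluster_set(1, "control_like", seed = s,
                                indicator_args = list(noise_sd = 0))
    det <- detect_events(compute_dff(set$recording[[1]]))
    expect_true(rasters_agree(set$truth_raster[[1]], det))
  }
})

test_that("raising the detection threshold never adds events", {
  set <- generate_cluster_set(1, "control_like", seed = 6)
  dff <- compute_dff(set$recording[[1]])
  counts <- vapply(c(2, 3, 4, 6), function(z) {
    sum(detect_events(dff, detection_params(z_threshold = z))$onsets)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("false positives on pure-noise traces stay below 0.5 per neuron", {
  fp <- vapply(1:50, function(s) {
    rec <- spikes_to_fluorescence(make_raster(4, 1200),
                                  indicator_params(), seed = s)
    mean(rowSums(detect_events(compute_dff(rec))$onsets))
  }, numeric(1))
  expect_lt(mean(fp), 0.5)
})

test_that("activity masks count neurons with at least one onset", {
  expect_equal(active_mask(make_raster(5, 50)), rep(FALSE, 5))
  m <- make_raster(10, 50, cbind(3, 20))
  expect_equal(which(active_mask(m)), 3)
  # round trip: mask equals ground-truth spiking neurons
  set <- generate_cluster_set(1, "control_like", seed = 4,
                              indicator_args = list(noise_sd = 0))
  det <- detect_events(compute_dff(set$recording[[1]]))
  expect_equal(active_mask(det), active_mask(set$truth_raster[[1]]))
})

test_that("detection preserves raster shape and records metadata", {
  set <- generate_cluster_set(1, "mutant_like", seed = 2)
  rec <- set$recording[[1]]
  det <- detect_events(compute_dff(rec))
  expect_equal(dim(det$onsets), dim(rec$values))
  expect_equal(det$dt_s, rec$dt_s)
  qc <- detection_qc(det)
  expect_equal(qc$n_events, sum(det$onsets))
  expect_equal(qc$active_percent, active_fraction(det))
})
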