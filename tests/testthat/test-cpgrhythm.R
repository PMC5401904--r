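test_that("the envelope rectifies and integrates as specified", {
  sr <- 100
  flat <- rep(3, 500)
  expect_true(all(vr_envelope(flat, sr) == 0))
  # pure square burst: plateau proportional to amplitude
  x <- rep(0, 1000)
  x[401:600] <- 2
  env <- vr_envelope(x, sr, smooth_window_s = 0.1)
  expect_equal(max(env), 2, tolerance = 1e-9)
  env_half <- vr_envelope(x / 2, sr, smooth_window_s = 0.1)
  expect_equal(max(env_half), 1, tolerance = 1e-9)
  expect_error(vr_envelope(x, sr, smooth_window_s = 20), "longer")
  # on noisy bursts the envelope raises the burst/baseline contrast
  p <- generate_vr_traces(vr_sim_spec("alternating", seed = 1))
  burst_idx <- p$left > 0.5
  raw_snr <- mean(abs(p$left[burst_idx])) / sd(p$left[!burst_idx])
  e <- vr_envelope(p$left, p$sample_rate_hz)
  env_snr <- mean(e[burst_idx]) / sd(e[!burst_idx])
  expect_gt(env_snr, raw_snr)
})

test_that("burst detection is exact on clean square bursts", {
  sr <- 100
  x <- rep(0, 2000)
  truth_on <- c(201, 701, 1201)
  for (o in truth_on) x[o:(o + 149)] <- 1
  bt <- detect_bursts(vr_envelope(x, sr), sr)
  expect_equal(nrow(bt), 3)
  expect_equal(bt$onset_s, (truth_on - 1) / sr, tolerance = 1.5 / sr)
  expect_equal(bt$offset_s, (truth_on + 148) / sr, tolerance = 1.5 / sr)
  # flat trace: no bursts
  expect_equal(nrow(detect_bursts(vr_envelope(rep(0.5, 500), sr), sr)), 0)
})

test_that("noisy synthetic bursts are recovered without extras", {
  hits <- vapply(1:50, function(s) {
    p <- generate_vr_traces(vr_sim_spec("alternating", noise_sd = 0.2,
                                        seed = s))
    bt <- detect_bursts(vr_envelope(p$left, p$sample_rate_hz),
                        p$sample_rate_hz)
    truth <- p$truth$left_bursts
    if (nrow(bt) != nrow(truth)) return(FALSE)
    all(abs(bt$onset_s - truth$onset_s) <= 0.1)
  }, logical(1))
  expect_true(all(hits))
})

test_that("cycle phases realise the textbook coordination patterns", {
  left <- tibble::tibble(onset_s = c(0, 2, 4, 6), offset_s = c(1, 3, 5, 7))
  mid <- tibble::tibble(onset_s = c(1, 3, 5), offset_s = c(1.5, 3.5, 5.5))
  expect_equal(cycle_phases(left, mid), rep(0.5, 3))
  sync <- tibble::tibble(onset_s = c(0, 2, 4), offset_s = c(1, 3, 5))
  expect_equal(cycle_phases(left, sync), rep(0, 3))
  short <- tibble::tibble(onset_s = c(0, 2), offset_s = c(1, 3))
  ph <- cycle_phases(short, mid)
  expect_length(ph, 0)
  expect_true(attr(ph, "no_rhythm"))
})

test_that("classification applies the circular decision rule", {
  alt <- classify_rhythm(rep(0.5, 20))
  expect_equal(alt$label, "alternating")
  expect_equal(alt$resultant_length, 1)
  syn <- classify_rhythm(rep(0, 20))
  expect_equal(syn$label, "synchronous")
  # wrapped phases near 1 count as synchronous too
  expect_equal(classify_rhythm(c(rep(0.98, 10), rep(0.02, 10)))$label,
               "synchronous")
  # concentrated but off both anchors: arrhythmic
  expect_equal(classify_rhythm(rep(0.25, 20))$label, "arrhythmic")
  expect_equal(classify_rhythm(numeric(0))$label, "no_rhythm")
  set.seed(1)
  expect_equal(classify_rhythm(runif(40))$label, "arrhythmic")
  expect_error(classify_rhythm(c(0.5, 1.2)), "0, 1")
})

test_that("arrhythmic generator phases look uniform to a Rayleigh test", {
  rejected <- vapply(1:50, function(s) {
    p <- generate_vr_traces(vr_sim_spec("arrhythmic", seed = s))
    ph <- p$truth$phases
    # independent oracle: compare R against the closed-form critical value
    r <- Mod(mean(exp(2i * pi * ph)))
    r < rayleigh_r_crit(length(ph), 0.05)
  }, logical(1))
  expect_gte(mean(rejected), 0.9)
  # and the packaged Rayleigh test agrees on a known uniform sample
  set.seed(3)
  expect_gt(rayleigh_test(runif(100))$p_value, 0.05)
  expect_lt(rayleigh_test(rep(c(0.49, 0.51), 25))$p_value, 1e-6)
})

test_that("end-to-end mode recovery holds at default noise", {
  modes <- c("alternating", "synchronous", "arrhythmic")
  ok <- vapply(1:50, function(s) {
    labels <- vapply(modes, function(m) {
      p <- generate_vr_traces(vr_sim_spec(m, seed = s))
      classify_vr_pair(p)$label
    }, character(1))
    all(labels == modes)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # silent mode yields no rhythm at all
  p0 <- generate_vr_traces(vr_sim_spec("silent", seed = 1))
  expect_equal(classify_vr_pair(p0)$label, "no_rhythm")
})

test_that("classification is invariant to trace amplitude scaling", {
  p <- generate_vr_traces(vr_sim_spec("alternating", seed = 8))
  a <- classify_vr_pair(p)
  p$left <- 40 * p$left
  p$right <- 40 * p$right
  b <- classify_vr_pair(p)
  expect_equal(a$label, b$label)
  expect_equal(a$phases, b$phases, tolerance = 1e-9)
})

test_that("swapping the sides preserves the alternating/synchronous labels", {
  for (m in c("alternating", "synchronous")) {
    p <- generate_vr_traces(vr_sim_spec(m, seed = 5))
    swapped <- p
    swapped$left <- p$right
    swapped$right <- p$left
    expect_equal(classify_vr_pair(swapped)$label, m)
  }
})
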