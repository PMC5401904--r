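test_that("synchronous grouping matches hand-built cases", {
  # one neuron firing alone five times, well separated
  solo <- make_raster(4, 100, cbind(1, c(10, 30, 50, 70, 90)))
  expect_equal(as.integer(synchronous_groups(solo)), rep(1L, 5))
  # all neurons in one frame form one full group
  all_at_once <- make_raster(6, 50, cbind(1:6, 20))
  expect_equal(as.integer(synchronous_groups(all_at_once)), 6L)
  # chained frames merge transitively
  chain <- make_raster(3, 50, rbind(c(1, 10), c(2, 11), c(3, 12)))
  expect_equal(as.integer(synchronous_groups(chain, 1)), 3L)
  expect_equal(sort(as.integer(synchronous_groups(chain, 0 + 1))), 3L)
})

test_that("group decomposition equals brute-force connected components", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(2:5, 1)
    nf <- sample(5:20, 1)
    m <- matrix(rbinom(n * nf, 1, 0.15), n, nf)
    w <- sample(1:3, 1)
    expect_equal(sort(as.integer(synchronous_groups(m, w))),
                 brute_force_groups(m, w))
  }
})

test_that("widening the synchrony window never shrinks groups", {
  set.seed(7)
  for (rep in 1:10) {
    m <- matrix(rbinom(8 * 100, 1, 0.05), 8, 100)
    for (w in 1:4) {
      a <- synchronous_groups(m, w)
      b <- synchronous_groups(m, w + 1)
      expect_lte(length(b), length(a))
      expect_gte(max(c(0, b)), max(c(0, a)))
    }
  }
})

test_that("synchrony histograms obey the conservation laws", {
  sizes <- c(1L, 1L, 2L)
  h <- synchrony_histogram(sizes, 3)
  expect_equal(h$count[h$bin == "1"], 2)
  expect_equal(h$count[h$bin == "2"], 1)
  expect_equal(h$count[h$bin == "all"], 0)
  h2 <- synchrony_histogram(3L, 3)
  expect_equal(h2$count[h2$bin == "all"], 1)
  expect_equal(sum(h2$count), 1)
  expect_error(synchrony_histogram(c(1, 4), 3), "cluster_size")
  # conservation on simulated data: counts sum to groups, sizes to onsets
  set <- generate_cluster_set(3, "mutant_like", seed = 9)
  for (i in 1:3) {
    r <- set$truth_raster[[i]]
    g <- synchronous_groups(r)
    h <- synchrony_histogram(g, set$n_neurons[i])
    expect_equal(sum(h$count), length(g))
    expect_equal(sum(h$size * h$count), sum(as.integer(g)))
  }
})

test_that("active fractions and their 12-bin histogram are exact", {
  expect_equal(active_fraction(make_raster(10, 30)), 0)
  expect_equal(active_fraction(make_raster(4, 30, cbind(1:4, 5))), 100)
  expect_equal(active_fraction(make_raster(12, 30, cbind(1:3, 5))), 25)
  h <- bin_active_fractions(c(0, 0, 100))
  expect_equal(h$count[h$bin == "0"], 2)
  expect_equal(h$count[h$bin == "100"], 1)
  expect_equal(sum(h$count), 3)
  h2 <- bin_active_fractions(50)
  expect_equal(h2$count[h2$bin == "[50,60)"], 1)
  expect_error(bin_active_fractions(c(10, 105)), "0, 100")
  # uniform draws land evenly in the ten interior bins
  set.seed(1)
  v <- runif(1000, 1e-9, 100 - 1e-9)
  hu <- bin_active_fractions(v)
  interior <- hu$count[!(hu$bin %in% c("0", "100"))]
  expect_equal(sum(interior), 1000)
  # 4 sigma binomial band around 100 per bin
  expect_true(all(abs(interior - 100) < 4 * sqrt(1000 * 0.1 * 0.9)))
})

test_that("response frequencies count onsets and pool across clusters", {
  r <- make_raster(3, 50, rbind(c(2, 10), c(2, 30), c(3, 40)))
  f <- response_frequencies(r)
  expect_equal(f$n_events, c(0L, 2L, 1L))
  h <- frequency_histogram(f)
  expect_equal(h$n_neurons[h$frequency == 1], 1)
  expect_equal(h$n_neurons[h$frequency == 2], 1)
  expect_equal(attr(h, "n_zero"), 1L)
  # pooled histogram conserves total onsets
  set <- generate_cluster_set(3, "control_like", seed = 11)
  f3 <- response_frequencies(set$truth_raster)
  expect_equal(sum(f3$n_events),
               sum(vapply(set$truth_raster, function(r) sum(r$onsets),
                          numeric(1))))
})

test_that("the log-log fit is exact on analytic power laws", {
  # counts proportional to f^-2: slope -2 to machine precision
  h <- tibble::tibble(frequency = 1:10, n_neurons = 1e6 * (1:10)^-2)
  fit <- fit_power_law(h)
  expect_true(fit$fitted)
  expect_equal(fit$slope, -2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # flat counts: slope 0
  flat <- tibble::tibble(frequency = 1:8, n_neurons = rep(7, 8))
  expect_equal(fit_power_law(flat)$slope, 0, tolerance = 1e-12)
  # fewer than three non-empty bins: no fit
  thin <- tibble::tibble(frequency = 1:5, n_neurons = c(3, 0, 0, 2, 0))
  unfit <- fit_power_law(thin)
  expect_false(unfit$fitted)
  expect_true(is.na(unfit$slope))
  expect_equal(glance(unfit)$fitted, FALSE)
  expect_equal(nrow(tidy(fit)), 2)
})

test_that("sampled power-law frequencies recover the exponent region", {
  # parameter recovery at the study scale: 280 neurons, support 1..64
  slopes <- vapply(1:20, function(s) {
    f <- sample_response_frequencies(280, 0.981, c(1, 64), seed = s)
    fit_power_law(frequency_histogram(f))$slope
  }, numeric(1))
  # the log-log LS estimator is known to flatten the tail; the mean must
  # land near the generating exponent (see the methods vignette)
  expect_lt(abs(mean(slopes) - (-0.981)), 0.15)
  expect_lt(sd(slopes), 0.1)
})

test_that("complete synchronisation is classified from the group sizes", {
  expect_true(classify_full_sync(make_raster(5, 40, cbind(1:5, 10))))
  near <- make_raster(5, 40, cbind(1:4, 10))
  expect_false(classify_full_sync(near))
  expect_false(classify_full_sync(make_raster(5, 40)))
})

test_that("Mann-Whitney comparisons reproduce exact and degenerate cases", {
  # fully separated n1 = n2 = 4: exact two-sided p = 2/70
  a <- matrix(c(1, 2, 3, 4), ncol = 1)
  b <- matrix(c(5, 6, 7, 8), ncol = 1)
  colnames(a) <- colnames(b) <- "bin1"
  cmp <- compare_groups(a, b)
  expect_equal(cmp$p_value, 2 / 70, tolerance = 1e-12)
  expect_equal(cmp$signif, "*")
  # identical groups: uninformative bin
  same <- matrix(rep(2, 4), ncol = 1)
  cmp2 <- compare_groups(same, same)
  expect_equal(cmp2$u_statistic, 8)
  expect_equal(cmp2$p_value, 1)
  expect_equal(cmp2$signif, "ns")
  expect_error(compare_groups(matrix(1, 1, 1), matrix(1, 3, 1)),
               "at least 2")
})

test_that("study-sized group comparison returns a full bin table", {
  ctrl <- generate_cluster_set(10, "control_like", seed = 21)
  mut <- generate_cluster_set(8, "mutant_like", seed = 22)
  hist_of <- function(set, i) {
    synchrony_histogram(synchronous_groups(set$truth_raster[[i]]),
                        set$n_neurons[i])
  }
  hc <- lapply(seq_len(nrow(ctrl)), function(i) hist_of(ctrl, i))
  hm <- lapply(seq_len(nrow(mut)), function(i) hist_of(mut, i))
  mc <- bind_synchrony_histograms(hc)
  mm <- bind_synchrony_histograms(hm)
  expect_equal(ncol(mc), 13)  # 1..11, pooled >=12, all
  cmp <- compare_groups(mc, mm)
  expect_gte(nrow(cmp), 12)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_true(all(cmp$p_bonferroni >= cmp$p_value))
  # the all bin separates the two wiring regimes decisively here
  expect_lt(cmp$p_value[cmp$bin == "all"], 0.005)
})
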