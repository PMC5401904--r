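test_that("puncta scenes honour their spec and ground truth", {
  spec <- puncta_scene_spec(n_pairs = 16, field_um = 105.9,
                            coloc_fraction = 1, seed = 2)
  sc <- generate_puncta_scene(spec)
  expect_length(sc$polylines_a, 16)
  expect_equal(nrow(sc$pairs), 16)
  # every A punctum has a true partner within the jitter radius
  expect_true(all(sc$spots_a$truth))
  cnt <- count_colocalized(sc$spots_a, sc$spots_b, radius_um = 0.5)
  expect_equal(as.integer(cnt), nrow(sc$spots_a))
  # determinism
  sc2 <- generate_puncta_scene(spec)
  expect_equal(sc$spots_a, sc2$spots_a)
  expect_error(puncta_scene_spec(field_um = 1), "too small")
})

test_that("chance colocalization matches the 1-D overlap expectation", {
  # coloc_fraction 0, small pair separation: expected matches per A spot
  # ~ 2 * sqrt(r^2 - s^2) * density_B along the partner neurite
  spec_of <- function(s) puncta_scene_spec(
    n_pairs = 4, field_um = 50, pair_separation_um = 0.1,
    puncta_per_um = 0.2, coloc_fraction = 0, seed = s)
  res <- vapply(1:50, function(s) {
    sc <- generate_puncta_scene(spec_of(s))
    c(as.integer(count_colocalized(sc$spots_a, sc$spots_b, 0.5)),
      nrow(sc$spots_a))
  }, numeric(2))
  rate <- sum(res[1, ]) / sum(res[2, ])
  expected <- 2 * sqrt(0.5^2 - 0.1^2) * 0.2
  se <- sd(res[1, ] / res[2, ]) / sqrt(50)
  expect_lt(abs(rate - expected), 4 * se + 0.01)
})

test_that("colocalized fractions are recovered within 0.1 after chance correction", {
  chance_rate <- 2 * sqrt(0.5^2 - 0.1^2) * 0.1
  est <- vapply(1:50, function(s) {
    sc <- generate_puncta_scene(puncta_scene_spec(
      n_pairs = 4, field_um = 50, pair_separation_um = 0.1,
      puncta_per_um = 0.1, coloc_fraction = 0.5, seed = 100 + s))
    n_a <- nrow(sc$spots_a)
    cnt <- as.integer(count_colocalized(sc$spots_a, sc$spots_b, 0.5))
    cnt / n_a - chance_rate
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.1)
})

test_that("colocalization counting is bounded, monotone and symmetric", {
  set.seed(5)
  a <- tibble::tibble(x_um = runif(30, 0, 20), y_um = runif(30, 0, 20))
  b <- tibble::tibble(x_um = runif(25, 0, 20), y_um = runif(25, 0, 20))
  for (r in c(0.2, 0.5, 1, 2)) {
    cnt <- as.integer(count_colocalized(a, b, r))
    expect_lte(cnt, min(nrow(a), nrow(b)))
    expect_equal(cnt, as.integer(count_colocalized(b, a, r)))
  }
  counts <- vapply(c(0.1, 0.3, 0.6, 1, 3),
                   function(r) as.integer(count_colocalized(a, b, r)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  # identical sets match completely; empty sets match nothing
  expect_equal(as.integer(count_colocalized(a, a, 0.1)), nrow(a))
  empty <- tibble::tibble(x_um = numeric(0), y_um = numeric(0))
  expect_equal(as.integer(count_colocalized(a, empty, 0.5)), 0L)
  expect_error(count_colocalized(a, b, -1), "non-negative")
})

test_that("neurite pairing applies the side-by-side criterion", {
  line <- cbind(seq(0, 20, 0.5), rep(5, 41))
  identical_pair <- pair_neurites(list(line), list(line))
  expect_equal(nrow(identical_pair), 1)
  expect_equal(identical_pair$mean_separation_um, 0, tolerance = 1e-9)
  far <- cbind(seq(0, 20, 0.5), rep(6, 41))  # 1 um away
  expect_equal(nrow(pair_neurites(list(line), list(far))), 0)
  near <- cbind(seq(0, 20, 0.5), rep(5.3, 41))  # 0.3 um away
  accepted <- pair_neurites(list(line), list(near))
  expect_equal(nrow(accepted), 1)
  expect_equal(accepted$mean_separation_um, 0.3, tolerance = 1e-6)
  expect_error(pair_neurites(list(matrix(1, 1, 2)), list(line)),
               "two points")
  # generated scenes at 0.3 um separation yield all 16 pairs
  sc <- generate_puncta_scene(puncta_scene_spec(
    n_pairs = 16, pair_separation_um = 0.3, seed = 4))
  pr <- pair_neurites(sc$polylines_a, sc$polylines_b)
  expect_equal(sum(pr$id_a == pr$id_b), 16)
})

test_that("spot detection recovers rendered puncta to sub-pixel accuracy", {
  px <- 0.1
  truth <- tibble::tibble(
    x_um = c(3, 8, 12, 16.5, 5.2), y_um = c(4, 15, 7, 11, 17.8))
  img <- render_puncta_image(truth, field_um = 20, pixel_size_um = px,
                             psf_sigma_um = 0.15)
  found <- detect_spots(img, psf_sigma_um = 0.15, pixel_size_um = px)
  expect_equal(nrow(found), nrow(truth))
  d <- vapply(seq_len(nrow(truth)), function(i) {
    min(sqrt((found$x_um - truth$x_um[i])^2 +
               (found$y_um - truth$y_um[i])^2))
  }, numeric(1))
  expect_true(all(d < px))  # within one pixel of the truth
  # blank image: no spots
  blank <- matrix(0, 100, 100)
  expect_equal(nrow(detect_spots(blank, 0.15, px)), 0)
  # two spots closer than one PSF sigma merge into a single detection
  close_pair <- tibble::tibble(x_um = c(10, 10.1), y_um = c(10, 10))
  img2 <- render_puncta_image(close_pair, 20, px, 0.15)
  expect_equal(nrow(detect_spots(img2, 0.15, px)), 1)
})

test_that("per-field densities count only in-field spots", {
  spots <- tibble::tibble(x_um = c(1, 5, 25), y_um = c(1, 5, 5))
  expect_equal(density_per_field(spots, 20), 2)
  expect_equal(density_per_field(spots, c(0, 30, 0, 30)), 3)
  empty <- tibble::tibble(x_um = numeric(0), y_um = numeric(0))
  expect_equal(density_per_field(empty, 20), 0)
})

test_that("one-way ANOVA and Tukey follow the classical decomposition", {
  # identical groups: F = 0, p = 1
  d0 <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  g0 <- group_test(d0, v, g)
  expect_equal(g0$anova$f_statistic, 0)
  expect_equal(g0$anova$p_value, 1)
  # two groups: F equals t^2
  set.seed(2)
  d2 <- data.frame(v = c(rnorm(6), rnorm(6, 1)),
                   g = rep(c("a", "b"), each = 6))
  tt <- t.test(v ~ g, data = d2, var.equal = TRUE)
  g2 <- group_test(d2, v, g)
  expect_equal(g2$anova$f_statistic, unname(tt$statistic)^2,
               tolerance = 1e-10)
  # three-group fixture checked against hand-worked sums of squares
  d3 <- data.frame(v = c(6, 8, 4, 5, 3, 4,
                         8, 12, 9, 11, 6, 8,
                         13, 9, 11, 8, 7, 12),
                   g = rep(c("a", "b", "c"), each = 6))
  means <- tapply(d3$v, d3$g, mean)
  grand <- mean(d3$v)
  ss_between <- 6 * sum((means - grand)^2)
  ss_within <- sum((d3$v - means[d3$g])^2)
  f_hand <- (ss_between / 2) / (ss_within / 15)
  g3 <- group_test(d3, v, g)
  expect_equal(g3$anova$f_statistic, f_hand, tolerance = 1e-10)
  expect_equal(nrow(tidy(g3)), 3)  # all pairwise Tukey comparisons
  expect_error(group_test(data.frame(v = 1:3, g = c("a", "a", "b")), v, g),
               "at least 2")
})

test_that("survival ratios reproduce the chimera worked examples", {
  expect_equal(survival_ratio(29, 78), 37.2)
  expect_equal(survival_ratio(31, 831), 3.7)
  expect_equal(survival_ratio(0, 100), 0)
  # scale invariance
  expect_equal(survival_ratio(5 * 29, 5 * 78), survival_ratio(29, 78))
  expect_error(survival_ratio(5, 0), "positive")
  expect_error(survival_ratio(10, 5), "double_positive")
  tbl <- survival_table(data.frame(
    region = c("hypothalamus", "midbrain"),
    double_positive = c(31, 922), total = c(831, 8019),
    reported = c(3.7, 11.2)))
  expect_equal(tbl$percent, c(3.7, 11.5))
  expect_equal(tbl$matches_reported, c(TRUE, FALSE))
})
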