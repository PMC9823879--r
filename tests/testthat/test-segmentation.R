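# helpers ------------------------------------------------------------------

spike_hist <- function(levels, masses) {
  counts <- integer(256)
  counts[levels + 1L] <- masses
  counts
}

test_that("tri-level objective is zero for one-point histograms", {
  h <- spike_hist(120, 900)
  for (t1 in c(10, 119, 200)) {
    expect_equal(otsu_trilevel_objective(h, t1, t1 + 20), 0)
  }
})

test_that("three equal spikes give the closed-form three-point variance", {
  h <- spike_hist(c(10, 100, 200), c(5, 5, 5))
  # analytic: equal masses at 10/100/200, mu = 310/3,
  # variance = mean of (x - mu)^2
  mu <- mean(c(10, 100, 200))
  v_exp <- mean((c(10, 100, 200) - mu)^2)
  for (t1 in c(10, 50, 99)) {
    for (t2 in c(100, 150, 199)) {
      expect_equal(otsu_trilevel_objective(h, t1, t2), v_exp)
    }
  }
  # any split separating the spikes dominates splits that merge them
  expect_lt(otsu_trilevel_objective(h, 5, 150), v_exp)
  expect_lt(otsu_trilevel_objective(h, 101, 150), v_exp)
})

test_that("objective ignores zero-count bins and validates thresholds", {
  h1 <- spike_hist(c(30, 90, 170), c(3, 7, 2))
  expect_equal(otsu_trilevel_objective(h1, 50, 120),
               otsu_trilevel_objective(h1, 60, 130))
  expect_error(otsu_trilevel_objective(h1, 120, 50), "t1 < t2")
  expect_error(otsu_trilevel_objective(h1, 120, 120), "t1 < t2")
  expect_error(otsu_trilevel_objective(integer(10), 3, 5), "256 bins")
})

test_that("mayfly threshold search matches the exhaustive oracle", {
  # three-spike histogram wrapped in an image + full mask
  img <- gray_image(matrix(rep(c(10, 100, 200), each = 25), 5, 15),
                    matrix(TRUE, 5, 15))
  ex <- otsu_trilevel_exhaustive(brain_histogram(img))
  res <- moa_otsu_trilevel(img)
  expect_equal(res$value, ex$value, tolerance = 1e-12)
  expect_true(res$t1 >= 10 && res$t1 < 100)
  expect_true(res$t2 >= 100 && res$t2 < 200)
})

test_that("noiseless phantom thresholds separate the tissue intensities", {
  cfg <- tiny_phantom_cfg()
  ph <- generate_phantom(cfg, "CON", 1)
  st <- skull_strip(ph$image)
  res <- moa_otsu_trilevel(st)
  expect_true(res$t1 >= cfg$csf_intensity && res$t1 < cfg$gm_intensity)
  expect_true(res$t2 >= cfg$gm_intensity && res$t2 < cfg$wm_intensity)
})

test_that("search stays within 0.5% of the exhaustive optimum across seeds", {
  ph <- generate_phantom(phantom_config(noise_sigma = 10, seed = 21),
                         "CON", 1)
  st <- skull_strip(ph$image)
  ex <- otsu_trilevel_exhaustive(brain_histogram(st))
  hits <- vapply(1:20, function(s) {
    par <- mayfly_params(bounds = cbind(c(1, 1), c(254, 254)),
                         n_flies = 30, max_iter = 60, seed = s)
    moa_otsu_trilevel(st, par)$value >= 0.995 * ex$value
  }, TRUE)
  expect_gte(sum(hits), 19)
})

test_that("ICM is a fixed point on a correctly initialized noiseless phantom", {
  ph <- generate_phantom(tiny_phantom_cfg(), "CON", 1)
  st <- skull_strip(ph$image)
  th <- moa_otsu_trilevel(st)
  init <- threshold_labels(st, th$t1, th$t2)
  ref <- mrf_refine(st, init)
  expect_equal(ref$labels, init)
  expect_length(ref$energy, 1)   # converged after one unchanged sweep
})

test_that("ICM restores salted labels and its energy never increases", {
  ph <- generate_phantom(tiny_phantom_cfg(), "CON", 1)
  st <- skull_strip(ph$image)
  th <- moa_otsu_trilevel(st)
  clean <- threshold_labels(st, th$t1, th$t2)
  in_mask <- which(st$brain_mask)
  corrupt <- withr::with_seed(4, sample(in_mask, round(0.02 * length(in_mask))))
  noisy <- clean
  noisy[corrupt] <- withr::with_seed(5,
    (noisy[corrupt] + sample(1:2, length(corrupt), TRUE)) %% 3L)
  ref <- mrf_refine(st, noisy, mrf_config(max_sweeps = 50))
  expect_true(all(diff(ref$energy) <= 1e-6))
  expect_gte(mean(ref$labels[corrupt] == clean[corrupt]), 0.95)
})

test_that("energy is non-increasing on noisy inputs for 4- and 8-neighborhoods", {
  ph <- generate_phantom(tiny_phantom_cfg(noise_sigma = 12, seed = 3),
                         "SCZ", 2)
  st <- skull_strip(ph$image)
  th <- moa_otsu_trilevel(st)
  init <- threshold_labels(st, th$t1, th$t2)
  for (nb in c(4L, 8L)) {
    ref <- mrf_refine(st, init, mrf_config(neighborhood = nb))
    expect_true(all(diff(ref$energy) <= 1e-6))
  }
})

test_that("tissue extraction recovers noiseless ground truth exactly", {
  cfg <- tiny_phantom_cfg()
  ph <- generate_phantom(cfg, "CON", 1)
  st <- skull_strip(ph$image)
  seg <- segment_slice(st)
  lab <- phantom_labels()
  gm_gt <- ph$labels == lab[["gm"]] & st$brain_mask
  wm_gt <- ph$labels == lab[["wm"]] & st$brain_mask
  expect_equal(seg$tissues$gm_mask, gm_gt)
  expect_equal(seg$tissues$wm_mask, wm_gt)
  expect_equal(sum(seg$tissues$gm_mask & seg$tissues$wm_mask), 0)
})

test_that("tissue masks partition the brain mask with the dark class", {
  ph <- generate_phantom(tiny_phantom_cfg(noise_sigma = 8, seed = 6),
                         "CON", 3)
  st <- skull_strip(ph$image)
  seg <- segment_slice(st)
  dark <- st$brain_mask & !seg$tissues$gm_mask & !seg$tissues$wm_mask
  expect_equal((seg$tissues$gm_mask | seg$tissues$wm_mask | dark),
               st$brain_mask)
  expect_true(all(seg$tissues$gm_mask | seg$tissues$wm_mask |
                    !st$brain_mask | dark))
})

test_that("swapping GM and WM intensities swaps the extracted masks", {
  base <- tiny_phantom_cfg()
  # a swapped config would violate csf < gm < wm, so relabel via the image
  ph <- generate_phantom(base, "CON", 1)
  img_swapped <- ph$image$pixels
  img_swapped[ph$image$pixels == base$gm_intensity] <- base$wm_intensity
  img_swapped[ph$image$pixels == base$wm_intensity] <- base$gm_intensity
  st1 <- skull_strip(ph$image)
  st2 <- skull_strip(gray_image(img_swapped))
  s1 <- segment_slice(st1)
  s2 <- segment_slice(st2)
  expect_equal(s2$tissues$gm_mask, s1$tissues$wm_mask)
  expect_equal(s2$tissues$wm_mask, s1$tissues$gm_mask)
})

test_that("degenerate segmentations are rejected", {
  img <- gray_image(matrix(100, 32, 32), matrix(TRUE, 32, 32))
  labels <- matrix(0L, 32, 32)  # single non-empty class
  expect_error(extract_tissues(img, labels), "degenerate segmentation")
})
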