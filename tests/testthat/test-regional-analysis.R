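test_that("AHA segmentation partitions the wall into 17 labelled segments", {
  run <- study_noisy_run()
  seg <- run$seg
  geom <- run$geom

  # equal thirds of the 30 cavity slices
  expect_length(seg$slice_groups$basal, 10)
  expect_length(seg$slice_groups$mid, 10)
  expect_length(seg$slice_groups$apical, 10)
  # basal slices sit closer to the base (higher slice index) than apical
  expect_gt(min(seg$slice_groups$basal), max(seg$slice_groups$apical))

  # labels partition the mask
  expect_equal(sum(!is.na(seg$labels)), sum(geom$mask))
  expect_setequal(unique(seg$labels[!is.na(seg$labels)]), 1:17)

  # symmetric annulus: each basal segment holds ~1/6 of the basal ring
  counts <- tabulate(seg$labels[!is.na(seg$labels)], 17)
  basal <- counts[1:6]
  expect_lt(max(abs(basal - mean(basal))) / mean(basal), 0.05)
  # cap slices are the apex
  expect_equal(counts[17], sum(geom$mask[, , geom$cap_slices]))
})

test_that("rotating the angular origin permutes sector labels cyclically", {
  ph <- small_phantom()
  s0 <- aha_segment(ph$geom, origin = 0)
  s60 <- aha_segment(ph$geom, origin = 60)
  sel <- !is.na(s0$labels) & s0$labels <= 6
  mapped <- s0$labels[sel]
  rotated <- s60$labels[sel]
  # origin + 60 shifts each basal sector down by one (mod 6)
  expect_true(all(rotated == ((mapped - 2) %% 6) + 1))
  expect_equal(sort(unique(rotated)), 1:6)

  one_slice <- small_spec(n_cavity_slices = 2L)
  expect_error(aha_segment(make_lv_geometry(one_slice)), "at least 3")
})

test_that("anisotropy mask keeps FA >= threshold", {
  fa <- array(c(0.46, 0.05, NA, 0.1), c(2, 2, 1))
  m <- fa_mask(fa)
  expect_identical(as.vector(m), c(TRUE, FALSE, FALSE, TRUE))
  expect_true(all(fa_mask(fa, threshold = 0)[!is.na(fa)]))
})

test_that("transmural profiles reproduce the linear helix rule", {
  ph <- small_phantom()
  seg <- aha_segment(ph$geom)
  ha <- helix_angle(ph$fibers$e1, ph$geom)
  prof <- transmural_profiles(ha$ha, ph$geom, seg, valid = ha$valid)

  expect_equal(unique(prof$depth_mid), c(10, 30, 50, 70, 90))
  expect_equal(prof$layer_name[prof$layer == 3],
               rep("mid-wall", 3))
  target <- c(48, 24, 0, -24, -48)
  # the wall of this compact phantom is ~4.6 voxels thick, so bin means
  # carry a few degrees of discretization; within-layer SD is bounded by
  # the rule's spread across a 20 % depth bin (24 deg uniform -> ~6.9 deg)
  for (reg in unique(prof$region)) {
    p <- prof[prof$region == reg, ]
    expect_lt(max(abs(p$mean - target)), 4)
    expect_true(all(p$sd < 8))
  }

  expect_error(transmural_profiles(ha$ha, ph$geom, seg,
                                   regions = "papillary"),
               "no usable voxels")
})

test_that("gradients are consistent with layer means", {
  prof <- structure(data.frame(
    region = "basal", layer = 1:5,
    layer_name = c("endocardial", "sub-endocardial", "mid-wall",
                   "sub-epicardial", "epicardial"),
    depth_mid = c(10, 30, 50, 70, 90),
    mean = c(48, 24, 0, -24, -48), sd = 1, n = 100),
    class = c("transmural_profile", "data.frame"))
  g <- transmural_gradients(prof)
  expect_equal(g$gradient[g$type == "adjacent"], rep(-1.2, 4))
  expect_equal(g$gradient[g$type == "total"], -1.2)

  # constant profile -> zero gradients; total = mean of adjacent for equal bins
  prof$mean <- rep(5, 5)
  g0 <- transmural_gradients(prof)
  expect_true(all(g0$gradient == 0))
  prof$mean <- c(10, 3, -4, 8, 2)
  g1 <- transmural_gradients(prof)
  expect_equal(mean(g1$gradient[g1$type == "adjacent"]),
               g1$gradient[g1$type == "total"], tolerance = 1e-12)

  prof2 <- prof[1, ]
  expect_error(transmural_gradients(prof2), "two non-empty layers")
})

test_that("segment statistics take medians over valid voxels", {
  ph <- small_phantom()
  seg <- aha_segment(ph$geom)
  dims <- dim(ph$geom$mask)
  fa <- array(NA_real_, dims); fa[ph$geom$mask] <- 0.46
  adc <- array(NA_real_, dims); adc[ph$geom$mask] <- 0.63e-3

  st <- segment_statistics(list(fa = fa, adc = adc), seg)
  expect_equal(st$segments$fa, rep(0.46, 17))
  expect_equal(st$regions$adc, rep(0.63e-3, 5))
  expect_equal(sum(st$segments$n_voxels), sum(ph$geom$mask))

  # locality: doubling one segment's voxels changes only that segment
  fa2 <- fa
  fa2[!is.na(seg$labels) & seg$labels == 4] <- 0.92
  st2 <- segment_statistics(list(fa = fa2), seg)
  expect_equal(st2$segments$fa[4], 0.92)
  expect_equal(st2$segments$fa[-4], rep(0.46, 16))

  # midpoint convention for even counts
  expect_equal(stats::median(c(1, 2, 3, 4)), 2.5)
  lab <- array(NA_integer_, c(4, 1, 1)); lab[] <- 1L
  tiny_seg <- structure(list(labels = lab,
                             regions = data.frame(segment = 1:17,
                                                  region = "basal")),
                        class = "aha_segmentation")
  vals <- array(c(1, 2, 3, 4), c(4, 1, 1))
  expect_warning(sm <- segment_statistics(list(fa = vals), tiny_seg),
                 "empty segments")
  expect_equal(sm$segments$fa[1], 2.5)
})

test_that("protocol comparison reports identity and pairing errors", {
  set.seed(5)
  make_stats <- function(hearts, shift = 0) {
    do.call(rbind, lapply(hearts, function(h) {
      data.frame(heart = h, segment = 1:17,
                 region = c(rep("basal", 6), rep("mid-cavity", 6),
                            rep("apical", 4), "apex"),
                 adc = 0.63e-3 + shift + stats::rnorm(17, sd = 1e-5),
                 fa = 0.46 + shift + stats::rnorm(17, sd = 0.01),
                 abs_e2a = 30 + stats::rnorm(17, sd = 1))
    }))
  }
  stats_ref <- make_stats(1:6)

  cmp <- compare_to_reference(stats_ref, stats_ref)
  expect_true(all(cmp$bias$percent_deviation == 0))
  expect_equal(cmp$bias_range$min, c(0, 0))
  expect_equal(cmp$bias_range$max, c(0, 0))
  expect_false(any(cmp$tests$significant))
  expect_true(all(cmp$tests$p_value == 1))

  # an injected shift is detected and the bias range reflects min/max
  stats_up <- make_stats(1:6, shift = 0.2)
  cmp2 <- compare_to_reference(stats_up, stats_ref)
  expect_true(any(cmp2$tests$significant[cmp2$tests$metric == "fa"]))
  expect_true(all(cmp2$bias_range$max >= cmp2$bias_range$min))

  expect_error(compare_to_reference(make_stats(1:6), make_stats(2:7)),
               "unpaired hearts")
  expect_error(compare_to_reference(make_stats(1:3), make_stats(1:3)),
               "at least 5")
})

test_that("statistics are permutation safe", {
  set.seed(9)
  x <- stats::rnorm(11); y <- stats::rnorm(11)
  w1 <- wilcoxon_paired(x, y)
  p <- sample(11)
  w2 <- wilcoxon_paired(x[p], y[p])
  expect_equal(w1, w2)
})
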