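cfg <- analysis_config()

test_that("ROI classification follows the lag-difference and ratio rules", {
  # instantaneous step 100 -> 200 saturates the lag statistic
  step_tr <- c(rep(100, 300), rep(200, 300))
  const_tr <- rep(150, 600)
  slow_tr <- 100 + 80 * 0.5 * (1 - cos(2 * pi * (0:599) / 600))  # 60 s wave
  fl <- fluor_matrix(rbind(step_tr, const_tr, slow_tr), frame_rate = 10)
  cls <- classify_rois(fl, cfg)
  expect_equal(cls$label[1], "active_neuron")
  expect_equal(cls$max_norm_delta[1], 1)
  expect_equal(cls$label[2], "inactive")
  expect_equal(cls$fluor_ratio[2], 0)
  expect_equal(cls$label[3], "active_astrocyte")

  # non-positive baseline demands offset correction
  fl_neg <- fluor_matrix(rbind(const_tr - 200, const_tr), frame_rate = 10)
  expect_error(classify_rois(fl_neg, cfg), "offset")
})

test_that("classifier recovers generator labels on the default population", {
  acc <- vapply(1:5, function(s) {
    g <- gen_calcium_population(seed = s)
    mean(classify_rois(g$fluor, cfg)$label == g$truth$labels)
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("classification statistics have the stated affine behaviour", {
  g <- gen_calcium_population(calcium_sim_params(n_frames = 600), seed = 6)
  cls <- classify_rois(g$fluor, cfg)
  # gain and offset leave the lag statistic and all labels unchanged
  fl2 <- fluor_matrix(3 * g$fluor$F + 40, frame_rate = 10)
  cls2 <- classify_rois(fl2, cfg)
  expect_equal(cls2$label, cls$label)
  expect_equal(cls2$max_norm_delta, cls$max_norm_delta)
  # the fluorescence ratio is gain-invariant but offset-sensitive
  fl3 <- fluor_matrix(3 * g$fluor$F, frame_rate = 10)
  cls3 <- classify_rois(fl3, cfg)
  expect_equal(cls3$fluor_ratio, cls$fluor_ratio)
  non_neuron <- !is.na(cls$fluor_ratio) & cls$fluor_ratio > 0
  expect_false(isTRUE(all.equal(cls2$fluor_ratio[non_neuron],
                                cls$fluor_ratio[non_neuron])))
})

test_that("ROI order does not affect classification or synchrony", {
  g <- gen_calcium_population(calcium_sim_params(n_frames = 600), seed = 12)
  cls <- classify_rois(g$fluor, cfg)
  perm <- sample(seq_len(nrow(g$fluor$F)))
  flp <- fluor_matrix(g$fluor$F[perm, ], frame_rate = 10, roi_ids = perm)
  clsp <- classify_rois(flp, cfg)
  expect_equal(clsp$label, cls$label[perm])
  expect_equal(clsp$max_norm_delta, cls$max_norm_delta[perm])

  neu <- which(g$truth$labels == "active_neuron")
  syn <- synchrony(g$fluor$F[neu, ], cfg)
  synp <- synchrony(g$fluor$F[rev(neu), ], cfg)
  expect_equal(synp$scores$corr_sum, rev(syn$scores$corr_sum))
  expect_equal(synp$top_k_mean_norm, syn$top_k_mean_norm)
})

test_that("neuron event counting recovers constructed transients", {
  # three well-separated noiseless transients
  tr <- rep(100, 300)
  kern <- c(20, 40, 40 * exp(-(1:20) / 8))
  for (at in c(50, 150, 250)) {
    tr[at:(at + length(kern) - 1L)] <- 100 + kern
  }
  ev <- count_neuron_events(tr, 10, cfg)
  expect_equal(ev$n_events, 3)
  expect_equal(ev$rate_hz, 3 / 30)

  # monotone trace has no events
  expect_equal(count_neuron_events(seq(100, 200, length.out = 200), 10,
                                   cfg)$n_events, 0)

  # ensemble rate recovery for Poisson transients at 0.2 Hz
  rates <- vapply(1:10, function(s) {
    g <- gen_calcium_population(
      calcium_sim_params(n_astrocytes = 0, n_inactive = 0), seed = s)
    mean(vapply(seq_len(nrow(g$fluor$F)), function(r)
      count_neuron_events(g$fluor$F[r, ], 10, cfg)$rate_hz, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.2) / 0.2, 0.15)
})

test_that("astrocyte summary averages the most active astrocytes", {
  mk_cls <- function(ratios) {
    data.frame(roi_id = seq_along(ratios),
               label = rep("active_astrocyte", length(ratios)),
               max_norm_delta = 0, fluor_ratio = ratios)
  }
  expect_equal(astrocyte_summary(mk_cls(c(0.5, 0.4, 0.3, 0.1)),
                                 cfg)$mean_ratio, 0.4)
  one <- astrocyte_summary(mk_cls(0.7), cfg)
  expect_equal(one$mean_ratio, 0.7)
  expect_true(one$flagged_short)
  none <- data.frame(roi_id = 1, label = "inactive", max_norm_delta = 0,
                     fluor_ratio = 0.01)
  expect_warning(res <- astrocyte_summary(none, cfg), "no astrocytes")
  expect_true(is.na(res$mean_ratio))
})

test_that("synchrony is 1 for identical traces and bounded in [-1, 1]", {
  x <- sin(seq(0, 30, length.out = 500)) + 5
  syn <- synchrony(matrix(rep(x, 5), 5, byrow = TRUE), cfg)
  expect_equal(syn$top_k_mean_norm, 1)
  expect_true(all(abs(syn$scores$corr_norm) <= 1))

  set.seed(31)
  F <- matrix(rnorm(6 * 400), 6)
  syn2 <- synchrony(F, cfg)
  expect_true(all(syn2$scores$corr_norm >= -1 & syn2$scores$corr_norm <= 1))

  expect_error(synchrony(matrix(rnorm(400), 1), cfg), ">= 2")
})

test_that("independent traces score near zero and shared drive raises synchrony", {
  set.seed(77)
  null_scores <- vapply(1:10, function(i) {
    synchrony(matrix(rnorm(10 * 1800), 10), cfg)$top_k_mean_norm
  }, numeric(1))
  expect_lt(abs(mean(null_scores)),
            3 * stats::sd(null_scores) / sqrt(length(null_scores)) + 1e-3)

  ok <- vapply(1:10, function(s) {
    g1 <- gen_calcium_population(
      calcium_sim_params(shared_drive_fraction = 0.9), seed = s)
    g0 <- gen_calcium_population(
      calcium_sim_params(shared_drive_fraction = 0), seed = s)
    n1 <- g1$truth$labels == "active_neuron"
    n0 <- g0$truth$labels == "active_neuron"
    synchrony(g1$fluor$F[n1, ], cfg)$top_k_mean_norm >
      synchrony(g0$fluor$F[n0, ], cfg)$top_k_mean_norm
  }, logical(1))
  expect_true(all(ok))
})

test_that("PSD band-area ratio matches spectral expectations", {
  # flat white-noise spectrum at 10 Hz sampling: full/high area ~ 5 / 4.9
  set.seed(13)
  r <- vapply(1:20, function(i) {
    psd_ratio(matrix(rnorm(1800), 1), frame_rate = 10, cfg = cfg)$top_k_mean
  }, numeric(1))
  expect_lt(abs(mean(r) - 5 / 4.9) / (5 / 4.9), 0.05)

  # a pure 1 Hz line lies entirely above the 0.1 Hz cutoff
  t <- (0:1799) / 10
  r1 <- psd_ratio(matrix(sin(2 * pi * 1 * t), 1), frame_rate = 10,
                  cfg = cfg)$top_k_mean
  expect_lt(r1, 1.05)

  # slow 0.05 Hz oscillation concentrates power below the cutoff
  slow1 <- psd_ratio(matrix(sin(2 * pi * 0.05 * t) + 0.05 * rnorm(1800), 1),
                     frame_rate = 10, cfg = cfg)$top_k_mean
  slow2 <- psd_ratio(matrix(sin(2 * pi * 0.05 * t) + 0.005 * rnorm(1800), 1),
                     frame_rate = 10, cfg = cfg)$top_k_mean
  expect_gt(slow1, 5)
  expect_gt(slow2, slow1)

  # the ratio is >= 1 for arbitrary signals
  set.seed(14)
  for (i in 1:5) {
    x <- cumsum(rnorm(700)) + rnorm(700)
    expect_gte(psd_ratio(matrix(x, 1), frame_rate = 10, cfg = cfg)$top_k_mean, 1)
  }

  # neurons are ranked by event count before averaging the top k
  g <- gen_calcium_population(
    calcium_sim_params(n_astrocytes = 0, n_inactive = 0, n_neurons = 12),
    seed = 15)
  rep_ <- psd_ratio(g$fluor, cfg = cfg)
  expect_equal(rep_$top_k, 10)
  ord <- order(-rep_$ratios$event_count)
  expect_true(all(rep_$ratios$event_count[ord[1:10]] >=
                    max(rep_$ratios$event_count[ord[11:12]])))
})
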