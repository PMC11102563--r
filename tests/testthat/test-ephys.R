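cfg <- analysis_config()
fs <- 20000

test_that("spike detection matches a brute-force enumeration oracle", {
  expect_equal(detect_spikes(rep(-60, 1000), fs, cfg), integer(0))

  g <- gen_current_clamp(ephys_sim_params(noise_sd = 0), seed = 1)
  s <- g$truth$rheobase_step + 3L
  tr <- g$sweeps$traces[s, ]
  expect_equal(detect_spikes(tr, fs, cfg), g$truth$apex_samples[[s]])

  # oracle equivalence on noisy short traces
  set.seed(21)
  for (rep in 1:5) {
    g2 <- gen_current_clamp(ephys_sim_params(noise_sd = 2, fi_slope = 0.08),
                            stimulus_protocol("current_clamp", n_steps = 38,
                                              step_duration = 100),
                            seed = 100 + rep)
    for (s in c(10L, 25L, 38L)) {
      tr <- g2$sweeps$traces[s, ]
      expect_equal(detect_spikes(tr, fs, cfg), oracle_detect(tr, fs))
    }
  }
})

test_that("refractory pruning keeps the earlier, larger event", {
  v <- rep(-60, 4000)
  bump <- function(v, at, hw, h) {
    idx <- (at - hw):(at + hw)
    v[idx] <- pmax(v[idx], -60 + h * (1 - abs(idx - at) / hw))
    v
  }
  v <- bump(v, 2000, 15, 80)   # apex at 2000
  v <- bump(v, 2040, 15, 70)   # 2 ms later, smaller
  expect_equal(detect_spikes(v, fs, cfg), 2000L)
})

test_that("evoked-AP totals match generator ground truth and exclusion rule", {
  g <- gen_current_clamp(ephys_sim_params(rheobase_step = 5), seed = 2)
  ev <- count_evoked_aps(g$sweeps, cfg)
  expect_false(ev$excluded)
  expect_equal(ev$total, sum(g$truth$spike_counts[1:32]))
  expect_equal(ev$per_step, g$truth$spike_counts[1:32])

  # hippocampal convention counts 30 steps
  cfg30 <- analysis_config(n_steps_counted = 30)
  expect_equal(count_evoked_aps(g$sweeps, cfg30)$total,
               sum(g$truth$spike_counts[1:30]))

  # cells needing more than 50 pA of holding current are excluded
  g51 <- gen_current_clamp(ephys_sim_params(holding_current = 51), seed = 2)
  ev51 <- count_evoked_aps(g51$sweeps, cfg)
  expect_true(ev51$excluded)
  expect_equal(ev51$reason, "holding>50pA")
  expect_true(is.na(ev51$total))
  # 50 pA exactly is retained ("more than 50 pA")
  g50 <- gen_current_clamp(ephys_sim_params(holding_current = 50), seed = 2)
  expect_false(count_evoked_aps(g50$sweeps, cfg)$excluded)

  # all-subthreshold family -> 0
  gsub <- gen_current_clamp(ephys_sim_params(rheobase_step = 38), seed = 2)
  expect_equal(count_evoked_aps(gsub$sweeps, cfg)$total, 0L)

  # fewer sweeps than counted steps -> error
  short <- gen_current_clamp(
    ephys_sim_params(),
    stimulus_protocol("current_clamp", n_steps = 20), seed = 2)
  expect_error(count_evoked_aps(short$sweeps, cfg), "20 sweeps")
})

test_that("adding one spike to a counted step raises the total by one", {
  g <- gen_current_clamp(ephys_sim_params(rheobase_step = 10, noise_sd = 0),
                         seed = 4)
  before <- count_evoked_aps(g$sweeps, cfg)$total
  tr <- g$sweeps$traces
  idx <- 1000:1040  # subthreshold step 1 is flat there
  tr[1, idx] <- -60 + 80 * (1 - abs(idx - 1020) / 20)
  g$sweeps$traces <- tr
  expect_equal(count_evoked_aps(g$sweeps, cfg)$total, before + 1L)
})

test_that("noiseless template spikes are recovered within discretization", {
  for (seed in 1:3) {
    p <- ephys_sim_params(noise_sd = 0,
                          threshold_mV = -42 + seed, amplitude_mV = 75 + seed,
                          width_ms = 1.5 + 0.25 * seed, fahp5_mV = 6 + seed)
    g <- gen_current_clamp(p, seed = seed)
    sh <- spike_shape(g$sweeps, cfg)
    tmpl <- g$truth$template
    expect_equal(sh$rheobase_step, g$truth$rheobase_step + 1L)
    expect_lt(abs(sh$threshold_mV - tmpl$threshold_mV), 0.05)
    expect_lt(abs(sh$amplitude_mV - tmpl$amplitude_mV), 0.05)
    expect_lt(abs(sh$width_ms - tmpl$width_ms), 1000 / fs)  # one sample
    expect_lt(abs(sh$fahp5_mV - tmpl$fahp5_mV), 0.05)
  }
})

test_that("a spike returning to threshold and staying flat has zero fAHP", {
  n <- 8000
  v <- rep(-45, n)
  v[1000:1200] <- seq(-45, -40, length.out = 201)  # slow approach
  v[1200:1240] <- seq(-40, 0, length.out = 41)     # steep rise, apex 1240
  v[1241:1280] <- seq(0, -40, length.out = 41)[-1] # fall to threshold
  v[1281:n] <- -40                                 # flat at threshold
  sh <- spike_shape(
    sweep_set(matrix(v, 1), fs, stimulus_protocol("current_clamp", 1)), cfg)
  expect_equal(sh$threshold_mV, -40)
  expect_equal(sh$fahp5_mV, 0)
})

test_that("gaussian spikes reproduce the closed-form width", {
  # for v = base + A exp(-(t-t0)^2 / 2 sigma^2) the second derivative's
  # first pre-apex maximum sits at t0 - sqrt(3) sigma, so the detected
  # threshold is base + A e^{-3/2} and the full width at half maximum of
  # the remaining amplitude is 2 sigma sqrt(2 ln(2 / (1 + e^{-3/2})))
  sigma_ms <- 0.8; A <- 100
  t_ms <- (seq_len(8000) - 1) / fs * 1000
  v <- -60 + A * exp(-((t_ms - 200)^2) / (2 * sigma_ms^2))
  sh <- spike_shape(
    sweep_set(matrix(v, 1), fs, stimulus_protocol("current_clamp", 1)), cfg)
  e32 <- exp(-1.5)
  expect_lt(abs(sh$threshold_mV - (-60 + A * e32)), 1)
  expect_lt(abs(sh$width_ms / (2 * sigma_ms * sqrt(2 * log(2 / (1 + e32))))
                - 1), 0.02)

  # silent family -> informative error
  gs <- gen_current_clamp(ephys_sim_params(rheobase_step = 38), seed = 1)
  expect_error(spike_shape(gs$sweeps, cfg), "no rheobase spike")
})

test_that("IV extraction matches the generator and the constant-sweep oracle", {
  z <- function(v) 0 * v
  # flat zero sweeps -> all entries zero
  gz <- gen_voltage_clamp(vc_sim_params(na_map = z, kfast_map = z,
                                        kslow_map = z, noise_sd = 0),
                          seed = 1)
  ivz <- extract_iv(gz$sweeps, cfg)
  expect_true(all(ivz$na_peak == 0 & ivz$kfast == 0 & ivz$kslow == 0))

  # constant-current sweeps: kfast = kslow = constant / C
  proto <- stimulus_protocol("voltage_clamp")
  const <- matrix(150, proto$n_steps, 2000)
  ssc <- sweep_set(const, fs, proto, capacitance = 30)
  ivc <- extract_iv(ssc, cfg)
  expect_true(all(ivc$kfast == 5))
  expect_true(all(ivc$kslow == 5))
  expect_true(all(ivc$na_peak == 0))  # clipped at zero for outward current

  # generator plateau and sodium peaks are recovered exactly
  gk <- gen_voltage_clamp(
    vc_sim_params(na_map = z, kfast_map = z,
                  kslow_map = function(v) ifelse(v == 80, 10, 0),
                  noise_sd = 0), seed = 1)
  ivk <- extract_iv(gk$sweeps, cfg)
  expect_equal(ivk$kslow[ivk$test_potential_mV == 80], 10)
  gn <- gen_voltage_clamp(
    vc_sim_params(na_map = function(v) ifelse(abs(v + 10) < 1e-9, -120, 0),
                  kfast_map = z, kslow_map = z, noise_sd = 0), seed = 1)
  ivn <- extract_iv(gn$sweeps, cfg)
  expect_equal(ivn$na_peak[ivn$test_potential_mV == -10], -120)

  expect_error(extract_iv(sweep_set(const, fs, proto), cfg), "capacitance")
})

test_that("IV window statistics restrict and compare groups correctly", {
  mk <- function(offset, seed) {
    extract_iv(gen_voltage_clamp(
      vc_sim_params(kslow_map = function(v) ifelse(v > -30,
                                                   (70 + offset) * (v + 30) / 110,
                                                   0),
                    noise_sd = 0),
      seed = seed)$sweeps, cfg)
  }
  tabs <- list(mk(0, 1), mk(0, 2), mk(5, 3), mk(5, 4))
  grp <- c("a", "a", "b", "b")
  ws <- iv_window_stats(tabs, grp, cfg)

  # the -20..0 mV window on a 10 mV ladder keeps exactly 3 potentials
  na_pots <- unique(ws$potential_means$test_potential_mV[
    ws$potential_means$current == "na_peak"])
  expect_equal(sort(na_pots), c(-20, -10, 0))
  k_pots <- unique(ws$potential_means$test_potential_mV[
    ws$potential_means$current == "kslow"])
  expect_equal(sort(k_pots), c(40, 50, 60, 70, 80))

  # noiseless separation in kslow -> overwhelming significance
  expect_lt(ws$tests$p_value[ws$tests$current == "kslow"], 1e-6)

  # identical groups -> F exactly 0
  tabs2 <- list(tabs[[1]], tabs[[2]], tabs[[1]], tabs[[2]])
  ws2 <- iv_window_stats(tabs2, c("a", "a", "b", "b"), cfg)
  expect_equal(ws2$tests$statistic[ws2$tests$current == "kslow"], 0)

  # an empty restriction window errors
  cfg_bad <- analysis_config(na_window = c(-25, -21))
  expect_error(iv_window_stats(tabs, grp, cfg_bad), "empty")
})

test_that("EPSC summaries handle silent and single-event traces", {
  # noise-only trace -> no events, rate zero, silent cell retained
  g0 <- gen_epsc(epsc_sim_params(rate = 0, noise_sd = 2), seed = 1)
  s0 <- detect_epscs(g0$trace, cfg)
  expect_equal(s0$n_events, 0)
  expect_equal(s0$rate_hz, 0)
  expect_true(is.na(s0$mean_amplitude_pA))

  # one injected event -> rate = 1 / duration
  tr <- g0$trace
  kern_t <- seq_len(2000) / fs
  kern <- exp(-kern_t / 0.005) - exp(-kern_t / 0.001)
  tr$samples[200000:201999] <- tr$samples[200000:201999] - 30 * kern / max(kern)
  s1 <- detect_epscs(tr, cfg)
  expect_equal(s1$n_events, 1)
  expect_equal(s1$rate_hz, 1 / tr$duration)
  expect_lt(abs(s1$mean_amplitude_pA - 30) / 30, 0.1)
})

test_that("pooled ECDFs obey the definition and shift with their inputs", {
  f <- pooled_ecdf(list(a = c(1, 2, 3)))$a
  expect_equal(f(2), 2 / 3)
  expect_equal(f(3), 1)

  g <- pooled_ecdf(list(a = rep(5, 4)))$a
  expect_equal(g(5), 1)
  expect_equal(g(5 - 1e-9), 0)

  expect_error(pooled_ecdf(list(a = 1:3, b = numeric(0))), "empty group")

  # adding 10 pA to every amplitude right-shifts the curve exactly
  set.seed(9)
  amp <- rexp(200, 1 / 20)
  fs2 <- pooled_ecdf(list(ctrl = amp, mut = amp + 10))
  x <- seq(5, 80, by = 2.5)
  expect_equal(fs2$mut(x), fs2$ctrl(x - 10))
})
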