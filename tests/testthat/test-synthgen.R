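test_that("current-clamp generator obeys its closed-form spike counts", {
  # one spike per step at and above rheobase when the f-I gain is zero
  for (rheo in c(0L, 3L, 10L)) {
    g <- gen_current_clamp(
      ephys_sim_params(rheobase_step = rheo, fi_slope = 0, noise_sd = 0),
      seed = 1)
    expect_equal(sum(g$truth$spike_counts[1:32]), 32 - rheo)
  }
  # rheobase beyond the ladder -> silent cell
  g0 <- gen_current_clamp(
    ephys_sim_params(rheobase_step = 38, fi_slope = 0.5, noise_sd = 0),
    seed = 1)
  expect_true(all(g0$truth$spike_counts == 0))
  # overfull steps are rejected
  expect_error(
    gen_current_clamp(ephys_sim_params(rheobase_step = 0, fi_slope = 2),
                      seed = 1),
    "do not fit")
})

test_that("noiseless spike template round-trips through detection", {
  g <- gen_current_clamp(ephys_sim_params(noise_sd = 0, amplitude_mV = 80),
                         seed = 1)
  s <- g$truth$rheobase_step + 1L
  apexes <- detect_spikes(g$sweeps$traces[s, ], g$sweeps$sampling_rate)
  expect_equal(apexes, g$truth$apex_samples[[s]])
  v_apex <- g$sweeps$traces[s, apexes[1]]
  expect_equal(v_apex - g$truth$template$threshold_mV, 80)
})

test_that("generators are deterministic given a seed", {
  a <- gen_current_clamp(ephys_sim_params(), seed = 42)
  b <- gen_current_clamp(ephys_sim_params(), seed = 42)
  expect_identical(a$sweeps$traces, b$sweeps$traces)
  a2 <- gen_epsc(epsc_sim_params(duration = 3), seed = 42)
  b2 <- gen_epsc(epsc_sim_params(duration = 3), seed = 42)
  expect_identical(a2$trace$samples, b2$trace$samples)
  expect_identical(a2$truth$times, b2$truth$times)
  a3 <- gen_calcium_population(calcium_sim_params(n_frames = 200), seed = 42)
  b3 <- gen_calcium_population(calcium_sim_params(n_frames = 200), seed = 42)
  expect_identical(a3$fluor$F, b3$fluor$F)
})

test_that("voltage-clamp generator places exact component peaks", {
  # all conductance maps zero -> flat sweeps
  z <- function(v) 0 * v
  gz <- gen_voltage_clamp(vc_sim_params(na_map = z, kfast_map = z,
                                        kslow_map = z, noise_sd = 0),
                          seed = 1)
  expect_true(all(gz$sweeps$traces == 0))

  # slow potassium plateau of 10 pA/pF at 80 mV
  gk <- gen_voltage_clamp(
    vc_sim_params(na_map = z, kfast_map = z,
                  kslow_map = function(v) ifelse(v == 80, 10, 0),
                  noise_sd = 0), seed = 1)
  C <- gk$sweeps$capacitance
  i80 <- which(step_voltages(gk$sweeps$protocol) == 80)
  n <- ncol(gk$sweeps$traces)
  expect_equal(gk$sweeps$traces[i80, n] / C, 10)

  # sodium transient of -120 pA/pF at -10 mV peaks in the early window
  gn <- gen_voltage_clamp(
    vc_sim_params(na_map = function(v) ifelse(abs(v + 10) < 1e-9, -120, 0),
                  kfast_map = z, kslow_map = z, noise_sd = 0), seed = 1)
  im10 <- which(step_voltages(gn$sweeps$protocol) == -10)
  early <- seq_len(round(0.010 * gn$sweeps$sampling_rate))
  expect_equal(min(gn$sweeps$traces[im10, early]) / C, -120)
})

test_that("EPSC event statistics follow the Poisson construction", {
  # zero rate -> pure noise, zero events
  g0 <- gen_epsc(epsc_sim_params(rate = 0), seed = 1)
  expect_equal(g0$truth$n_events, 0)

  # ensemble mean count matches the Poisson law (2 Hz x 60 s)
  counts <- vapply(1:100, function(s)
    gen_epsc(epsc_sim_params(noise_sd = 0), seed = s)$truth$n_events,
    integer(1))
  expect_lt(abs(mean(counts) - 120), 3 * sqrt(120))

  # degenerate amplitude distribution is reproduced exactly
  ga <- gen_epsc(epsc_sim_params(amp_sd = 0, amp_mean = 30, duration = 30),
                 seed = 2)
  expect_true(all(ga$truth$amplitudes == 30))
})

test_that("calcium population generator has the advertised structure", {
  # full shared drive, no noise or drift -> identical neuron rows
  g1 <- gen_calcium_population(
    calcium_sim_params(n_neurons = 4, n_astrocytes = 0, n_inactive = 0,
                       shared_drive_fraction = 1, noise_sd = 0,
                       drift_amplitude = 0, amplitude_jitter = 0,
                       n_frames = 600), seed = 7)
  expect_true(all(apply(g1$fluor$F, 2, function(col) max(col) == min(col))))
  expect_equal(cor(g1$fluor$F[1, ], g1$fluor$F[2, ]), 1)

  # no active cells -> rows are baseline + wander + noise only
  g2 <- gen_calcium_population(
    calcium_sim_params(n_neurons = 0, n_astrocytes = 0, n_inactive = 5,
                       n_frames = 300), seed = 7)
  expect_equal(nrow(g2$fluor$F), 5)
  expect_true(all(abs(g2$fluor$F - 100) < 10))

  # per-neuron event counts follow the Poisson law (0.2 Hz x 180 s)
  g3 <- gen_calcium_population(
    calcium_sim_params(n_neurons = 50, n_astrocytes = 0, n_inactive = 0),
    seed = 8)
  mean_events <- mean(lengths(g3$truth$events[1:50]))
  expect_lt(abs(mean_events - 36), 3 * sqrt(36) / sqrt(50) + 1)

  # too-short recordings are rejected
  expect_error(calcium_sim_params(n_frames = 10), "twice")
})

test_that("gene-set generator realizes overlap coefficients exactly", {
  om <- diag(4)
  om[1, 2] <- om[2, 1] <- 0.5
  om[3, 4] <- om[4, 3] <- 0.3
  g <- gen_genesets(n_sets = 4, universe_size = 1000, overlap_matrix = om,
                    deg_fraction = 0.1, seed = 2, set_size = 40)
  expect_equal(overlap_coefficient(g$sets[[1]], g$sets[[2]]), 0.5)
  expect_equal(overlap_coefficient(g$sets[[3]], g$sets[[4]]), 0.3)
  expect_equal(overlap_coefficient(g$sets[[1]], g$sets[[3]]), 0)
  expect_true(all(lengths(g$sets) == 40))

  # no differential expression -> zero hits everywhere
  g0 <- gen_genesets(n_sets = 3, universe_size = 500, deg_fraction = 0,
                     seed = 3)
  expect_true(all(g0$truth$hits == 0))

  # infeasible requests fail loudly
  om_bad <- diag(2); om_bad[1, 2] <- om_bad[2, 1] <- 0.33
  expect_error(gen_genesets(2, 500, om_bad, 0.1, seed = 1, set_size = 40),
               "infeasible")
  om_full <- matrix(0.6, 3, 3); diag(om_full) <- 1
  expect_error(gen_genesets(3, 500, om_full, 0.1, seed = 1, set_size = 10),
               "infeasible")
})
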