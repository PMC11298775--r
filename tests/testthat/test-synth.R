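# Synthetic recording generator: spike trains, templates, attenuation,
# rendering, scenarios.

test_that("poisson_spike_train enforces the allowed rate range", {
  expect_error(poisson_spike_train(0, 10), "f_rate")
  expect_error(poisson_spike_train(1, 10), "f_rate")
  expect_error(poisson_spike_train(200, 10), "f_rate")
})

test_that("poisson_spike_train mean count matches the Poisson expectation", {
  # rate*duration = 2000; mean over seeds should sit within 3 SE of it
  counts <- vapply(1:200, function(s)
    length(poisson_spike_train(20, 100, refractory_s = 0, seed = s)),
    numeric(1))
  se <- sqrt(2000) / sqrt(200)
  expect_lt(abs(mean(counts) - 2000), 3 * se)
})

test_that("refractory thinning forces a minimum inter-spike interval", {
  for (s in 1:5) {
    t <- poisson_spike_train(150, 20, refractory_s = 0.005, seed = s)
    expect_true(all(diff(t) >= 0.005 * 30000))
    expect_true(all(diff(t) > 0))
  }
})

test_that("make_template normalises peak at the centre sample", {
  for (fam in c("gaussian", "ricker", "biorthogonal", "daubechies")) {
    w <- make_template(fam, 60, amplitude = 1)
    expect_equal(max(abs(w)), 1, tolerance = 1e-12)
    expect_equal(which.max(abs(w)), 31L)  # ceiling((60+1)/2)
    w2 <- make_template(fam, 61, amplitude = 2.5)
    expect_equal(max(abs(w2)), 2.5, tolerance = 1e-12)
    expect_equal(which.max(abs(w2)), 31L)
  }
  expect_error(make_template("haar", 60), "valid families")
  expect_error(make_template("gaussian", 4), "width_samples")
})

test_that("ricker template has the Mexican-hat sign structure", {
  w <- make_template("ricker", 200)
  signs <- sign(w[abs(w) > 1e-3])
  expect_equal(sum(diff(signs) != 0), 2)  # exactly two zero crossings
})

test_that("distinct template families are not near-duplicates", {
  fams <- c("gaussian", "ricker", "biorthogonal", "daubechies")
  for (i in 1:3) for (j in (i + 1):4) {
    r <- cor(make_template(fams[i], 60), make_template(fams[j], 60))
    expect_lt(abs(r), 0.95)
  }
})

test_that("attenuation gain follows 1/(4 pi sigma r)", {
  expect_equal(attenuation_gain(1, 0.35), 1 / (4 * pi * 0.35),
               tolerance = 1e-12)
  expect_equal(attenuation_gain(1, 0.35), 0.2274, tolerance = 1e-3)
  r <- c(1, 2, 5, 8)
  expect_equal(attenuation_gain(r) / attenuation_gain(2 * r), rep(2, 4))
  g <- attenuation_gain(1:16)
  expect_true(all(diff(g) < 0))
  expect_error(attenuation_gain(0), "> 0")
})

test_that("noise-free rendering is an exact additive superposition", {
  cfg <- synth_config(duration_s = 2, noise_variance = 0)
  out <- render_recording(cfg)
  m <- out$block$samples
  # subtract every ground-truth scaled template: must leave exactly zero
  tr <- out$truth
  pitch <- cfg$channel_pitch_um; off <- cfg$neuron_offset_um
  for (j in seq_along(tr$spike_trains)) {
    tem <- tr$templates[[j]]
    L <- length(tem); p <- ceiling((L + 1) / 2)
    home <- cfg$neuron_channels[j]
    r_ch <- sqrt(off^2 + (abs(seq_len(cfg$n_channels) - 1 - home) * pitch)^2)
    gain <- attenuation_gain(r_ch, cfg$conductivity_sigma) /
      attenuation_gain(off, cfg$conductivity_sigma)
    for (s in tr$spike_trains[[j]]) {
      idx <- (s - p + 1):(s - p + L)
      ok <- idx >= 1 & idx <= nrow(m)
      for (c in seq_len(cfg$n_channels)) {
        m[idx[ok], c] <- m[idx[ok], c] - gain[c] * tem[ok]
      }
    }
  }
  expect_equal(max(abs(m)), 0, tolerance = 1e-12)
  # event bookkeeping
  expect_equal(nrow(tr$events), sum(lengths(tr$spike_trains)))
  expect_false(is.unsorted(tr$events$spike_sample))
})

test_that("home channel receives the strongest copy of each spike", {
  cfg <- synth_config(duration_s = 1, noise_variance = 0)
  out <- render_recording(cfg)
  m <- out$block$samples
  ev <- out$truth$events
  iso <- which(c(Inf, diff(ev$spike_sample)) > 60 &
                 c(diff(ev$spike_sample), Inf) > 60)
  for (k in head(iso, 20)) {
    s <- ev$spike_sample[k]
    win <- max(1, s - 5):min(nrow(m), s + 5)
    peaks <- apply(abs(m[win, , drop = FALSE]), 2, max)
    expect_equal(which.max(peaks) - 1L, ev$home_channel[k])
  }
})

test_that("pure-noise rendering has the configured variance", {
  cfg <- synth_config(duration_s = 3, noise_variance = 0.02,
                      firing_rates_hz = rep(2, 8))
  cfg$amplitude <- rep(0, 8)  # silence the neurons, keep the noise
  out <- render_recording(cfg)
  v <- var(as.numeric(out$block$samples))
  expect_lt(abs(v - 0.02) / 0.02, 0.05)
})

test_that("identical seeds give bit-identical recordings", {
  a <- render_recording(synth_config(duration_s = 1, seed = 11))
  b <- render_recording(synth_config(duration_s = 1, seed = 11))
  expect_identical(a$block$samples, b$block$samples)
  expect_identical(a$truth$events, b$truth$events)
  c <- render_recording(synth_config(duration_s = 1, seed = 12))
  expect_false(identical(a$block$samples, c$block$samples))
})

test_that("scenario constructions satisfy their defining constraints", {
  sim <- synth_scenario("simultaneous", seed = 3, duration_s = 2)
  ev <- sim$truth$events
  t1 <- ev$spike_sample[ev$neuron_id == 1]
  t2 <- ev$spike_sample[ev$neuron_id == 2]
  expect_identical(sort(t1), sort(t2))
  expect_equal(unique(ev$home_channel[ev$neuron_id == 1]), 1)
  expect_equal(unique(ev$home_channel[ev$neuron_id == 2]), 4)
  # the simultaneous pair must have clearly distinct template shapes
  r <- cor(sim$truth$templates[[1]] / max(abs(sim$truth$templates[[1]])),
           sim$truth$templates[[2]] / max(abs(sim$truth$templates[[2]])))
  expect_lt(abs(r), 0.6)

  sh <- synth_scenario("similar_shapes", seed = 3, duration_s = 2)
  tpl <- sh$truth$templates
  # the designated pair (neurons 2 and 6) shares a family with r > 0.95
  w2 <- tpl[[2]] / max(abs(tpl[[2]])); w6 <- tpl[[6]] / max(abs(tpl[[6]]))
  n <- max(length(w2), length(w6)) + 4
  center <- function(w) {  # peak-centred embedding in a common window
    out <- numeric(n)
    p <- which.max(abs(w))
    at <- floor(n / 2) - p + seq_along(w)
    out[at] <- w
    out
  }
  expect_gt(cor(center(w2), center(w6)), 0.95)
  hc <- sh$truth$events
  expect_gt(abs(unique(hc$home_channel[hc$neuron_id == 2]) -
                  unique(hc$home_channel[hc$neuron_id == 6])), 5)

  un <- synth_scenario("unrestricted", seed = 3, duration_s = 2)
  expect_equal(length(unique(un$truth$events$home_channel)), 8)
})

test_that("recording round-trips through the int16 binary format", {
  cfg <- synth_config(duration_s = 0.2)
  out <- render_recording(cfg)
  path <- tempfile()
  write_recording(out$block, path)
  back <- read_recording(path)
  expect_equal(back$sample_rate_hz, out$block$sample_rate_hz)
  expect_equal(back$channel_ids, out$block$channel_ids)
  # int16 quantisation error bounded by half a count
  scale <- max(abs(out$block$samples)) / 30000
  expect_lt(max(abs(back$samples - out$block$samples)), scale)
  file.remove(path, paste0(path, ".cfg"))
})
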