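test_that("autocorrelogram matches the all-pairs oracle and is symmetric", {
  # two spikes 10 ms apart: one pair at +10, one at -10
  tr <- spike_train("u", "M1", c(0.100, 0.110), 1, 250)
  a <- compute_ach(tr, max_lag_ms = 50)
  expect_equal(a$counts[a$lags_ms == 10], 1)
  expect_equal(a$counts[a$lags_ms == -10], 1)
  expect_equal(sum(a$counts), 2)

  single <- spike_train("u", "M1", 0.5, 1, 250)
  expect_true(all(compute_ach(single, 50)$counts == 0))
  expect_error(compute_ach(tr, max_lag_ms = 0), "max_lag")

  set.seed(19)
  for (rep in 1:5) {
    t <- sort(runif(60, 0, 3))
    t <- t[c(TRUE, diff(t) > 0.002)]
    tr <- spike_train("u", "VLT", t, 3)
    a <- compute_ach(tr, max_lag_ms = 300)
    expect_equal(a$counts, ach_oracle(t, 300))
    expect_equal(a$counts, rev(a$counts))  # symmetry
  }
})

test_that("a periodic train shows autocorrelogram peaks at multiples of its period", {
  tr <- spike_train("u", "M1", seq(0.5, 599.5, by = 1), 600, 250)
  a <- compute_ach(tr, max_lag_ms = 2500)
  expect_equal(a$counts[a$lags_ms == 1000], 599)
  expect_equal(a$counts[a$lags_ms == 2000], 598)
  expect_equal(sum(a$counts[abs(a$lags_ms) %in% c(1000, 2000)]), 2 * (599 + 598))
  expect_equal(sum(a$counts), 2 * (599 + 598))
})

test_that("oscillation test detects in-band modulation and rejects out-of-band", {
  tr1 <- gen_spike_train(spike_gen_spec("os-non-burst", osc_freq = 1.0,
                                        mod_depth = 0.9, seed = 31))
  o1 <- oscillation_test(compute_ach(tr1))
  expect_true(o1$oscillatory)
  expect_lt(abs(o1$peak_freq - 1.0), 0.1)

  # modulation at 3 Hz: outside the 0.4-1.5 Hz detection band
  sp3 <- spike_gen_spec("os-non-burst", seed = 32)
  sp3$osc_freq <- 3.0
  o3 <- oscillation_test(compute_ach(gen_spike_train(sp3)))
  expect_false(o3$oscillatory)

  # all-zero autocorrelogram: not oscillatory, no peak
  z <- oscillation_test(compute_ach(spike_train("u", "M1", 0.5, 1, 250), 100))
  expect_false(z$oscillatory)
  expect_true(is.na(z$peak_freq))
})

test_that("burst detection follows the ISI and separation rules exactly", {
  mk <- function(t) spike_train("u", "VLT", t, max(t) + 1)
  b1 <- detect_bursts(mk(c(0, 0.005, 0.200, 0.208, 0.215, 0.400)))
  expect_equal(b1$n_bursts, 2)
  expect_equal(b1$bursts[[1]], 1:2)
  expect_equal(b1$bursts[[2]], 3:5)
  expect_equal(b1$burst_fraction, 2 / 6)

  # second candidate only 45 ms after the first: not counted
  b2 <- detect_bursts(mk(c(0, 0.005, 0.050, 0.055)))
  expect_equal(b2$n_bursts, 1)
  expect_equal(b2$bursts[[1]], 1:2)

  empty <- spike_train("u", "VLT", numeric(0), 1)
  b0 <- detect_bursts(empty)
  expect_equal(b0$n_bursts, 0)
  expect_equal(b0$burst_fraction, 0)
})

test_that("burst detection agrees with the brute-force oracle on random trains", {
  set.seed(77)
  for (rep in 1:300) {
    tr <- random_clumpy_train(200)
    got <- detect_bursts(tr)
    want <- burst_oracle(tr$spike_times)
    expect_identical(got$bursts, want)
    expect_equal(got$n_bursts, length(want))
  }
})

test_that("burst-cell rule is a strict 10% inequality", {
  fake <- function(n_bursts, n_spikes)
    structure(list(bursts = vector("list", n_bursts), n_bursts = n_bursts,
                   n_spikes = n_spikes,
                   burst_fraction = n_bursts / n_spikes),
              class = "burst_set")
  expect_true(burst_cell_test(fake(15, 100)))
  expect_false(burst_cell_test(fake(10, 100)))   # 0.10 is not > 0.10
  expect_false(burst_cell_test(fake(0, 50)))
  expect_warning(res <- burst_cell_test(fake(0, 0)), "zero spikes")
  expect_false(res)
})

test_that("CV recovers analytic values for renewal trains", {
  set.seed(55)
  mk <- function(isis) spike_train("u", "M1", cumsum(isis), sum(isis) + 1, 250)
  regular <- mk(rep(0.1, 100))
  expect_equal(compute_cv(regular), 0)

  expo <- mk(rexp(10000, 5))
  expect_lt(abs(compute_cv(expo) - 1), 0.05)

  gam <- mk(rgamma(10000, shape = 4, rate = 20))
  expect_lt(abs(compute_cv(gam) - 0.5), 0.03)

  expect_warning(cv2 <- compute_cv(mk(0.1)), "ISIs")
  expect_true(is.na(cv2))
})

test_that("classification is the truth table of the two sub-tests", {
  trains <- lapply(c("os-burst", "os-non-burst", "irr-burst", "irr-non-burst"),
                   function(cl) gen_spike_train(spike_gen_spec(cl, seed = 13)))
  labels <- vapply(trains, function(tr) classify_pattern(tr)$label,
                   character(1))
  expect_equal(labels,
               c("os-burst", "os-non-burst", "irr-burst", "irr-non-burst"))
  for (tr in trains) {
    pl <- classify_pattern(tr)
    expect_equal(pl$label, paste0(if (pl$oscillatory) "os" else "irr",
                                  if (pl$burst) "-burst" else "-non-burst"))
    expect_equal(is.na(pl$peak_freq), !pl$oscillatory)
  }
})

test_that("classification is deterministic and time-shift invariant", {
  tr <- gen_spike_train(spike_gen_spec("os-burst", seed = 3))
  p1 <- classify_pattern(tr)
  p2 <- classify_pattern(tr)
  expect_identical(p1, p2)

  shifted <- spike_train(tr$unit_id, tr$region, tr$spike_times + 37.5,
                         tr$duration + 37.5, tr$spike_width)
  p3 <- classify_pattern(shifted)
  expect_equal(p3$label, p1$label)
  expect_equal(p3$burst_fraction, p1$burst_fraction)
  expect_equal(p3$cv, p1$cv)
  a1 <- compute_ach(tr, 500)
  a3 <- compute_ach(shifted, 500)
  expect_identical(a1$counts, a3$counts)
})

test_that("unit-inclusion filters apply region-specific rules", {
  mk <- function(id, region, rate, width, dur = 1200) {
    t <- seq(0.5, dur - 0.5, length.out = max(2, round(rate * dur)))
    spike_train(id, region, t, dur, width)
  }
  m1_ok <- mk("a", "M1", 2, 250)
  m1_fast <- mk("b", "M1", 12, 250)         # rate filter
  m1_wide <- mk("c", "M1", 2, 400)          # width filter
  m1_sparse <- mk("d", "M1", 150 / 1200, 250)  # 150 spikes in 20 min
  vlt_wide <- mk("e", "VLT", 2, 400)        # width not applied to VLT
  kept_m1 <- select_units(list(m1_ok, m1_fast, m1_wide, m1_sparse, vlt_wide),
                          "M1")
  expect_equal(vapply(kept_m1, `[[`, character(1), "unit_id"), "a")
  kept_vlt <- select_units(list(m1_ok, vlt_wide), "VLT")
  expect_equal(vapply(kept_vlt, `[[`, character(1), "unit_id"), "e")

  m1_nowidth <- mk("f", "M1", 2, NA_real_)
  expect_error(select_units(list(m1_nowidth), "M1"), "spike_width")
})
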