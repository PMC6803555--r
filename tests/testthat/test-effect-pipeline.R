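test_that("effect index follows its algebra", {
  expect_equal(compute_index(100, 100), 0)
  expect_equal(compute_index(0, 50), 1)
  expect_equal(compute_index(150, 50), -0.5)
  expect_warning(na <- compute_index(0, 0), "undefined")
  expect_true(is.na(na))
  expect_error(compute_index(-1, 5), "counts")

  set.seed(3)
  for (rep in 1:200) {
    A <- sample(0:200, 1); B <- sample(0:200, 1)
    if (A + B == 0) next
    i1 <- compute_index(A, B)
    expect_equal(i1, -compute_index(B, A))
    expect_lte(abs(i1), 1)
    if (A > 0 && B > 0) expect_lt(abs(i1), 1)
    if (xor(A == 0, B == 0)) expect_equal(abs(i1), 1)
  }
})

test_that("peak normalization maps the max block to 1", {
  expect_equal(peak_normalized_rates(c(before = 2, after = 4)),
               c(before = 0.5, after = 1.0))
  expect_equal(unname(peak_normalized_rates(c(a = 3, b = 3))), c(1, 1))
  expect_equal(peak_normalized_rates(c(solo = 7)), c(solo = 1))
  expect_warning(z <- peak_normalized_rates(c(a = 0, b = 0)), "all-zero")
  expect_true(all(is.na(z)))
})

test_that("per-unit signed-rank test behaves on canonical block pairs", {
  blockA <- epoch("baseline", 0, 600)
  blockB <- epoch("harmaline", 600, 1200)
  # identical spike patterns in both blocks: no change detected
  set.seed(61)
  base <- sort(runif(200, 0, 600))
  tr_same <- spike_train("u", "M1", c(base, base + 600), 1200, 250)
  r0 <- per_unit_rate_change_test(tr_same, blockA, blockB)
  expect_equal(r0$direction, 0L)
  expect_false(r0$significant)
  expect_equal(r0$p_value, 1)

  # counts doubled in every 1-min bin with distinct differences:
  # exact signed-rank p = 2 / 2^10
  counts <- seq(10, 100, by = 10)
  tA <- unlist(lapply(1:10, function(i)
    seq((i - 1) * 60 + 0.1, i * 60 - 0.1, length.out = counts[i])))
  tB <- unlist(lapply(1:10, function(i)
    seq(600 + (i - 1) * 60 + 0.1, 600 + i * 60 - 0.1,
        length.out = 2 * counts[i])))
  tr2 <- spike_train("u", "M1", c(tA, tB), 1200, 250)
  r2 <- per_unit_rate_change_test(tr2, blockA, blockB)
  expect_equal(r2$p_value, 2 / 1024, tolerance = 1e-12)
  expect_equal(r2$direction, 1L)
  expect_true(r2$significant)

  # one block silent against a 5 Hz block
  set.seed(9)
  tr3 <- spike_train("u", "M1", sort(runif(3000, 600, 1200)), 1200, 250)
  r3 <- per_unit_rate_change_test(tr3, blockA, blockB)
  expect_true(r3$significant)
  expect_equal(r3$direction, 1L)

  expect_error(
    per_unit_rate_change_test(tr2, blockA, epoch("dbs_on", 600, 900)),
    "equal length")
})

test_that("pattern proportions count and normalize per period", {
  p1 <- pattern_proportions(list(before = rep("irr-non-burst", 10)))
  expect_equal(p1$proportions["before", "irr-non-burst"], 1)
  expect_equal(sum(p1$proportions["before", ]), 1)

  p2 <- pattern_proportions(list(x = rep(c("os-burst", "os-non-burst",
                                           "irr-burst", "irr-non-burst"),
                                         each = 5)))
  expect_true(all(p2$proportions == 0.25))

  expect_error(pattern_proportions(list(a = character(0))), "no units")
  expect_error(pattern_proportions(list(a = "weird-label")), "unknown")

  # multinomial sampling stays inside binomial 95% intervals of the truth
  mix <- c(0.125, 0.478, 0.048, 0.349)
  set.seed(14)
  ok <- 0L
  for (rep in 1:20) {
    lab <- sample(c("os-burst", "os-non-burst", "irr-burst", "irr-non-burst"),
                  250, replace = TRUE, prob = mix)
    pp <- pattern_proportions(list(p = lab))$proportions[1, ]
    ci <- 1.96 * sqrt(mix * (1 - mix) / 250)
    ok <- ok + sum(abs(pp - mix) <= ci)
  }
  expect_gte(ok / (20 * 4), 0.90)
})

test_that("proportion change test equals the Pearson formula", {
  pt <- pattern_proportions(list(
    before = rep(c("os-burst", "irr-non-burst"), c(30, 70)),
    after = rep(c("os-burst", "irr-non-burst"), c(60, 40))))
  res <- proportion_change_test(pt)
  O <- matrix(c(30, 70, 60, 40), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$chi2, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)

  same <- pattern_proportions(list(
    a = rep(c("os-burst", "irr-non-burst"), c(50, 50)),
    b = rep(c("os-burst", "irr-non-burst"), c(50, 50))))
  res0 <- proportion_change_test(same)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p_value, 1)

  only_osc <- pattern_proportions(list(a = rep("os-burst", 5),
                                       b = rep("os-non-burst", 5)))
  expect_error(proportion_change_test(only_osc), "zero expected")
})

test_that("the full pipeline is deterministic and end-to-end coherent", {
  dir <- withr::local_tempdir()
  make_acceptance_session(dir)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- list(rate_bin_s = 20.48)
  rep1 <- run_pipeline(dir, cfg, out_dir = out1)
  rep2 <- run_pipeline(dir, cfg, out_dir = out2)

  for (f in list.files(out1))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))

  expect_setequal(unique(rep1$patterns$epoch), c("baseline", "harmaline"))
  expect_equal(length(unique(rep1$patterns$unit_id)), 6)
  expect_true(all(c("patterns.csv", "indices.csv", "proportions.csv",
                    "mpr.csv", "report.json") %in% list.files(out1)))
  # tremor injected only in the harmaline epoch shows up in the MPR series
  expect_gt(rep1$mpr$normalized_epoch_mpr[["harmaline"]], 1)
  # indices populated for the baseline->harmaline comparison
  expect_true(all(rep1$indices$comparison == "harmaline"))
  expect_true(all(abs(rep1$indices$index) <= 1))
})

test_that("the pipeline runs without force-plate data", {
  dir <- withr::local_tempdir()
  make_acceptance_session(dir)
  file.remove(file.path(dir, "force.csv"))
  rep <- run_pipeline(dir, list(rate_bin_s = 20.48))
  expect_null(rep$mpr)
  expect_null(rep$moving_area)
  expect_gt(nrow(rep$patterns), 0)
})
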