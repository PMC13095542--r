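# Latin hypercube design, record simulation, dataset assembly.

test_that("LHS stratifies every margin and is seed-reproducible", {
  spec <- sampling_spec(M = 4, seed = 9)
  x <- lhs_sample(spec)
  # exactly one draw per quartile of each parameter's range
  for (j in colnames(x)) {
    tab <- spec$table[spec$table$parameter == j, ]
    u <- (x[, j] - tab$lower) / (tab$upper - tab$lower)
    expect_identical(sort(floor(u * 4)), c(0, 1, 2, 3))
  }
  expect_identical(lhs_sample(spec), x)                 # determinism
  # bounds arithmetic at scale: peak elastance spans [0.1, 2.0]
  big <- lhs_sample(sampling_spec(M = 400, seed = 2))
  expect_true(all(big[, "Emax_LV"] >= 0.1 & big[, "Emax_LV"] <= 2.0))
  expect_true(all(big[, "T"] >= 0.16 - 1e-12 & big[, "T"] <= 1.44 + 1e-12))
  # marginal uniformity: KS distance below 2/sqrt(M)
  for (j in c("Rsar", "TBV")) {
    tab <- spec$table[spec$table$parameter == j, ]
    u <- sort((big[, j] - tab$lower) / (tab$upper - tab$lower))
    ks <- max(abs(u - (seq_along(u) - 0.5) / length(u)))
    expect_lt(ks, 2 / sqrt(400))
  }
})

test_that("simulated records satisfy their construction invariants", {
  ds <- small_dataset()
  expect_equal(ncol(ds$ap), 256)                     # fixed waveform grid
  expect_true(all(ds$scalars[, "LV_EDV"] > ds$scalars[, "LV_ESV"]))
  # elastance bridge round trip on the record's own end-systolic point
  rec <- ds$scalars
  expect_lt(max(abs(rec[, "Pes_lv"] / (rec[, "Ves_lv"] - 5) -
                      ds$labels[, "Emax_LV"]) / ds$labels[, "Emax_LV"]),
            1e-6)
  # via the measured ESV (what the estimator bridge uses): the small
  # physical gap between minimum volume and the volume at peak elastance
  # keeps this within about half a percent
  expect_lt(max(abs(rec[, "Pes_lv"] / (rec[, "LV_ESV"] - 5) -
                      ds$labels[, "Emax_LV"]) / ds$labels[, "Emax_LV"]),
            1e-2)
  expect_true(all(ds$labels[, "Emax_LV"] >= 0.1 &
                    ds$labels[, "Emax_LV"] <= 2.0))
})

test_that("splits are disjoint, exhaustive and proportional", {
  ds <- small_dataset()
  expect_equal(length(ds$split), nrow(ds$labels))
  # 14:2:2 proportions at M = 90 -> 70/10/10
  sp <- cardiolpm:::draw_split(90, seed = 4)
  expect_equal(as.vector(table(sp)), c(70, 10, 10))
  sp2 <- cardiolpm:::draw_split(90, seed = 4)
  expect_identical(sp, sp2)
})

test_that("label-feature consistency: re-simulation reproduces features", {
  ds <- small_dataset()
  set.seed(1)
  for (i in sample(nrow(ds$labels), 2)) {
    th <- c(ds$labels[i, ], T = unname(ds$scalars[i, "T"]),
            TBV = unname(ds$scalars[i, "TBV"]))
    rec <- simulate_sample(th, solver_config(t_end = 30, fs = 500))
    rel_l2 <- sqrt(sum((rec$features$ap - ds$ap[i, ])^2) /
                     sum(ds$ap[i, ]^2))
    expect_lt(rel_l2, 0.01)
    expect_false(rec$features$suction)               # pump-off record
  }
})

test_that("dataset summary quantiles match a brute-force sort", {
  ds <- small_dataset()
  s <- summarize_dataset(ds)
  ap_max <- apply(ds$ap, 1, max)
  srt <- sort(ap_max)
  expect_equal(s$min[s$index == "AP_MAX"], srt[1])
  expect_equal(s$max[s$index == "AP_MAX"], srt[length(srt)])
  expect_equal(s$q25[s$index == "AP_MAX"],
               unname(quantile(ap_max, 0.25)))
  # CO reported in L/min: mean systemic flow of tens of mL/s scales down
  expect_true(all(s[s$index == "CO", c("min", "max")] < 20))
})

test_that("dataset round-trips through the plain-text container", {
  ds <- small_dataset()
  dir <- tempfile("ds")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(unname(back$labels), unname(ds$labels), tolerance = 1e-12)
  expect_equal(unname(back$ap), unname(ds$ap), tolerance = 1e-12)
  expect_identical(as.character(back$split), as.character(ds$split))
  unlink(dir, recursive = TRUE)
})
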