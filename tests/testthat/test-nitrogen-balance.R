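test_that("nitrate partition reproduces the hand-computed linear balance", {
  chem <- chem_series(day = 1, influent_nh4 = 86.4, effluent_nh4 = 0,
                      effluent_no2 = 0, effluent_no3 = 43.2)
  p <- partition_nitrogen(chem)
  expect_equal(p$n2, 43.2)
  expect_equal(p$ap_no3, 43.2 * 0.26 / 2.04, tolerance = 1e-12)
  expect_equal(p$ap_no3, 5.5058824, tolerance = 1e-6)
  expect_equal(p$np_no3, 37.6941176, tolerance = 1e-6)
  expect_equal(p$ratio, 43.2 / 37.6941176, tolerance = 1e-7)
  expect_equal(p$ratio, 1.1460674, tolerance = 1e-6)
})

test_that("zero nitrogen deficit gives zero N2 and a zero ratio", {
  chem <- chem_series(day = 1, influent_nh4 = 100, effluent_nh4 = 40,
                      effluent_no2 = 10, effluent_no3 = 50)
  p <- partition_nitrogen(chem)
  expect_equal(p$n2, 0)
  expect_equal(p$ap_no3, 0)
  expect_equal(p$np_no3, 50)
  expect_equal(p$ratio, 0)
})

test_that("partition additivity and stoichiometric line hold on random records", {
  set.seed(101)
  for (i in 1:50) {
    infl <- runif(1, 50, 150)
    eff <- runif(3, 0, 40)
    chem <- chem_series(day = 1, influent_nh4 = infl, effluent_nh4 = eff[1],
                        effluent_no2 = eff[2], effluent_no3 = eff[3])
    p <- suppressWarnings(partition_nitrogen(chem))
    expect_identical(p$ap_no3 + p$np_no3, eff[3])   # bit-exact additivity
    if (p$n2 > 0)
      expect_equal(p$ap_no3 / p$n2, 0.26 / 2.04, tolerance = 1e-12)
    expect_gte(p$n2, 0)
  }
})

test_that("effluent exceeding influent beyond tolerance warns and floors N2", {
  chem <- chem_series(day = 1, influent_nh4 = 50, effluent_nh4 = 40,
                      effluent_no2 = 10, effluent_no3 = 20)
  expect_warning(p <- partition_nitrogen(chem), "exceeding the influent")
  expect_equal(p$n2, 0)
})

test_that("ratio is undefined (NA) when nitrification-derived nitrate vanishes", {
  # choose NO3 so that the whole measured pool is attributable to anammox:
  # deficit = 66.4 - no3 and np = no3 - deficit * 0.26/2.04 = 0
  no3 <- 66.4 * (0.26 / 2.04) / (1 + 0.26 / 2.04)
  chem <- chem_series(day = 1, influent_nh4 = 86.4, effluent_nh4 = 20,
                      effluent_no2 = 0, effluent_no3 = no3)
  p <- partition_nitrogen(chem)
  expect_equal(p$np_no3, 0, tolerance = 1e-9)
  expect_true(is.na(p$ratio))
})

test_that("ratio is strictly increasing in N2 at fixed npNO3-", {
  np <- 30
  n2 <- seq(1, 60, by = 1)
  no3 <- np + n2 * 0.26 / 2.04
  ratios <- vapply(seq_along(n2), function(i) {
    chem <- chem_series(day = 1, influent_nh4 = 200,
                        effluent_nh4 = 200 - n2[i] - no3[i] - 5,
                        effluent_no2 = 5, effluent_no3 = no3[i])
    partition_nitrogen(chem)$ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("moving average matches a direct windowed mean and handles gaps", {
  # constant series
  expect_equal(moving_average(1:10, rep(3.3, 10), 6.25), rep(3.3, 10))
  # window below sampling interval: identity
  x <- c(4, 8, 15, 16, 23, 42)
  expect_equal(moving_average(1:6, x, 0.9), x)
  # linear series: interior windows are symmetric, so mean = focal value
  v <- as.numeric(1:10)
  sm <- moving_average(1:10, v, 6.25)
  direct <- vapply(1:10, function(i) mean(v[abs(1:10 - i) <= 3.125]),
                   numeric(1))
  expect_equal(sm, direct)
  expect_equal(sm[4:7], v[4:7])
  # NA points are excluded, not propagated
  v2 <- v; v2[5] <- NA
  sm2 <- moving_average(1:10, v2, 6.25)
  expect_false(anyNA(sm2))
  expect_equal(sm2[2], mean(v2[abs(1:10 - 2) <= 3.125], na.rm = TRUE))
  expect_error(moving_average(numeric(0), numeric(0), 2), "empty")
})

test_that("concentration input converts to the rate basis via flow", {
  df <- data.frame(day = 1:3, nh4_in_mgN_d = 86.4,
                   nh4_out_mgN_L = c(1, 2, 3), no2_out_mgN_L = 0.5,
                   no3_out_mgN_L = 10, temp_C = 30, ph = 7.6,
                   do_mgO2_L = 0.2)
  chem <- chem_from_concentrations(df, flow = 0.72)
  expect_s3_class(chem, "chem_series")
  expect_equal(chem$effluent_nh4, c(1, 2, 3) * 0.72)
  expect_equal(chem$effluent_no3, rep(7.2, 3))
  expect_error(chem_from_concentrations(df[, -2], 0.72), "missing")
})
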