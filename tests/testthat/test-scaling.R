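test_that("SMA recovers a perfect line with a degenerate CI", {
  x <- c(0, 1, 2, 3, 4)
  f <- sma_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  expect_equal(f$ci_low, 2)
  expect_equal(f$ci_high, 2)
})

test_that("SMA obeys its closed-form identities against an independent OLS fit", {
  set.seed(21)
  for (k in 1:20) {
    n <- sample(10:60, 1)
    x <- rnorm(n)
    y <- sample(c(-1, 1), 1) * (1.5 * x) + rnorm(n, 0, runif(1, 0.1, 1))
    f <- sma_fit(x, y)
    b_ols <- unname(coef(lm(y ~ x))[2])
    r <- cor(x, y)
    # |b_SMA| = |b_OLS| / |r|, hence |b_SMA| >= |b_OLS|
    expect_equal(abs(f$slope), abs(b_ols) / abs(r), tolerance = 1e-12)
    expect_gte(abs(f$slope), abs(b_ols) - 1e-12)
    # swap symmetry: slope and CI map to their reciprocals
    g <- sma_fit(y, x)
    expect_equal(g$slope, 1 / f$slope, tolerance = 1e-12)
    expect_equal(sort(c(g$ci_low, g$ci_high)),
                 sort(1 / c(f$ci_low, f$ci_high)), tolerance = 1e-12)
  }
})

test_that("SMA slope, CI and R^2 are invariant to log base and raw-scale units", {
  set.seed(22)
  x <- runif(30, 1, 50); y <- 0.2 * x^1.3 * exp(rnorm(30, 0, 0.1))
  f10 <- sma_fit(log10(x), log10(y))
  fln <- sma_fit(log(x), log(y))
  for (fld in c("slope", "ci_low", "ci_high", "r_squared"))
    expect_equal(fln[[fld]], f10[[fld]], tolerance = 1e-12)
  # multiplying a raw variable by a constant only shifts the log intercept
  fu <- sma_fit(log10(x * 10), log10(y / 3))
  for (fld in c("slope", "ci_low", "ci_high", "r_squared"))
    expect_equal(fu[[fld]], f10[[fld]], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fu$intercept, f10$intercept)))
})

test_that("OLS fit matches the hand-computed normal equations and handles flat data", {
  x <- c(0, 1, 2, 3); y <- c(1, 3, 2, 5)
  # by hand: sum((x-1.5)*(y-2.75)) = 5.5, sum((x-1.5)^2) = 5 -> slope 1.1
  f <- ols_fit(x, y)
  expect_equal(f$slope, 1.1)
  expect_equal(f$intercept, 2.75 - 1.1 * 1.5)

  flat <- ols_fit(x, rep(4, 4), h0 = 0)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$ci_low, -flat$ci_high)   # symmetric about 0
  expect_error(sma_fit(x, rep(4, 4)), class = "kelpmech_degenerate_input")
  expect_error(sma_fit(x[1:2], y[1:2]), class = "kelpmech_too_few_points")
})

test_that("scaling classification compares the CI to the null slope", {
  mk <- function(lo, hi, h0) list(ci_low = lo, ci_high = hi, h0_slope = h0)
  expect_equal(classify_scaling(mk(0.96, 1.49, 1)), "isometric")
  expect_equal(classify_scaling(mk(0.54, 0.91, 1)), "negative_allometry")
  expect_equal(classify_scaling(mk(-0.17, 0.21, 0)), "independent")
  expect_equal(classify_scaling(mk(0.98, 1.75, 0)), "positive_allometry")
})

test_that("widening the CI never moves a classification away from the null", {
  set.seed(23)
  for (k in 1:20) {
    s <- simulate_property_scaling(25, runif(1, 0.5, 2), seed = 500 + k,
                                   noise_sd_log = 0.15)
    wide <- sma_fit(log10(s$x), log10(s$y), alpha = 0.01, h0 = 1)
    narrow <- sma_fit(log10(s$x), log10(s$y), alpha = 0.2, h0 = 1)
    if (narrow$classification == "isometric")
      expect_equal(wide$classification, "isometric")
    # and the wider interval really is wider
    expect_gte(narrow$ci_low, wide$ci_low)
    expect_lte(narrow$ci_high, wide$ci_high)
  }
})

test_that("the scaling table recovers generating power laws and logs failures per row", {
  set.seed(24)
  morph <- simulate_morphometrics(seed = 42)$records
  # attach synthetic material properties with known exponents
  juv <- morph[morph$life_stage == "juvenile", ]
  mk_y <- function(slope, int) 10^(int + slope * log10(juv$stipe_length_cm) +
                                   rnorm(nrow(juv), 0, 0.05))
  props <- data.frame(specimen_id = juv$specimen_id,
                      F_max = mk_y(0.7, -1),
                      F_fail = mk_y(0.7, -1),
                      W_fail = mk_y(1.8, -4),
                      epsilon_fail = 0.6 + rnorm(nrow(juv), 0, 0.05),
                      sigma_max = mk_y(0.55, 5),
                      youngs_modulus = mk_y(-1.2, 7.6),
                      toughness = mk_y(1.3, -7),
                      fracture_area = mk_y(0.66, -2))
  tab <- run_scaling_table(morph, props)
  expect_equal(nrow(tab), 9)
  expect_true(all(tab$ci_low <= tab$slope & tab$slope <= tab$ci_high))
  truth <- c(bulb_vs_stipe_adult = 0.70, bulb_vs_stipe_juvenile = 1.19,
             break_area_vs_stipe = 0.66, youngs_modulus_vs_stipe = -1.2,
             sigma_max_vs_stipe = 0.55, epsilon_fail_vs_stipe = 0,
             toughness_vs_stipe = 1.3, F_fail_vs_stipe = 0.7,
             W_fail_vs_stipe = 1.8)
  for (i in seq_len(nrow(tab))) {
    tr <- truth[[tab$regression[i]]]
    expect_gte(tr, tab$ci_low[i] - 0.15)
    expect_lte(tr, tab$ci_high[i] + 0.15)
  }
  expect_equal(tab$method[tab$regression == "epsilon_fail_vs_stipe"], "OLS")

  # empty spec list -> empty report with the full schema
  empty <- run_scaling_table(morph, props, specs = NULL)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("regression", "h0", "method", "n", "slope", "ci_low",
                    "ci_high", "classification", "intercept", "r_squared")
                  %in% names(empty)))

  # a missing variable poisons only its own row
  tab2 <- run_scaling_table(morph, props[, !names(props) %in% "toughness"])
  bad <- tab2[tab2$regression == "toughness_vs_stipe", ]
  expect_true(is.na(bad$slope))
  expect_match(bad$note, "toughness")
  expect_false(anyNA(tab2$slope[tab2$regression != "toughness_vs_stipe"]))
})
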