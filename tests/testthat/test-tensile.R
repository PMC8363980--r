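test_that("failure detection finds the first qualifying drop from the running peak", {
  # single peak, instant 53% drop
  res <- detect_failure(make_record(c(1, 2, 3, 1.4)), smooth = FALSE)
  expect_identical(res$failure_index, 4L)
  expect_equal(res$F_fail, 3)

  # monotone rise: no failure event
  expect_error(detect_failure(make_record(c(1, 2, 3)), smooth = FALSE),
               class = "kelpmech_no_failure_detected")

  # two peaks: a 40% dip does not qualify, the later 62% drop does,
  # and F_fail is the second (higher) peak
  f2 <- c(1, 2, 5, 3, 4, 8, 3)
  res2 <- detect_failure(make_record(f2), smooth = FALSE)
  expect_identical(res2$failure_index, oracle_failure_index(f2))
  expect_equal(res2$F_fail, 8)

  # randomized cross-check against the brute-force scan
  set.seed(101)
  for (k in 1:25) {
    f <- abs(cumsum(rnorm(40))) + 0.5
    f[sample(20:40, 1):40] <- 0.1   # force a late collapse
    idx <- oracle_failure_index(f)
    res <- detect_failure(make_record(f, extension = 0:39), smooth = FALSE)
    expect_identical(res$failure_index, idx)
    expect_equal(res$F_fail, max(f[seq_len(idx)]))
  }
})

test_that("failure detection ignores noise drops below the force floor and samples after the break", {
  # a 75% dip while the running peak is still noise-sized must not trigger
  f <- c(0.02, 0.04, 0.01, 0.5, 1, 2, 3, 1.2)
  res <- detect_failure(make_record(f, extension = 0:7), smooth = FALSE)
  expect_identical(res$failure_index, 8L)

  # appending samples after the first qualifying drop changes nothing
  set.seed(77)
  for (k in 1:10) {
    f <- c(abs(cumsum(rnorm(30))) + 1, 0.01)
    base <- detect_failure(make_record(f, extension = 0:30), smooth = FALSE)
    fext <- c(f, runif(15, 0, max(f)))
    ext <- detect_failure(make_record(fext, extension = 0:45), smooth = FALSE)
    expect_identical(ext$failure_index, base$failure_index)
    expect_equal(ext$F_fail, base$F_fail)
  }
})

test_that("work to failure integrates force over extension in joules", {
  # rectangle: 2 N over 10 mm = 20 N.mm = 0.02 J
  rect <- make_record(c(2, 2, 2), extension = c(0, 5, 10))
  expect_equal(work_to_failure(rect, 3), 0.02)

  # triangle: 0 -> 10 N over 0 -> 5 mm = 25 N.mm = 0.025 J
  tri <- make_record(seq(0, 10, length.out = 11),
                     extension = seq(0, 5, length.out = 11))
  expect_equal(work_to_failure(tri, 11), 0.025)

  # noisy curve matches an explicit panel-by-panel sum
  set.seed(5)
  x <- sort(runif(50, 0, 12)); f <- abs(rnorm(50, 5, 2))
  rec <- make_record(f, extension = x)
  expect_equal(work_to_failure(rec, 50), oracle_trapz(x, f) * 1e-3)

  expect_error(work_to_failure(rect, 1), class = "kelpmech_degenerate_record")
})

test_that("stress-strain conversion applies sigma = F/A and conventional strain", {
  rec <- make_record(c(1, 2, 3), extension = c(0, 5, 10), L0 = 100, area = 1)
  ss <- to_stress_strain(rec)
  expect_equal(nrow(ss), 3)
  expect_equal(ss$stress[1], 1e6)          # 1 N / 1 mm^2 = 1 MPa
  expect_equal(ss$strain[1], 0)            # zero-strain origin
  rec2 <- make_record(c(3, 3, 3), extension = c(0, 5, 10), L0 = 100, area = 2)
  ss2 <- to_stress_strain(rec2)
  expect_equal(ss2$stress[3], 1.5e6)
  expect_equal(ss2$strain[3], 0.1)
})

test_that("modulus estimation is exact on linear curves and skips the toe region", {
  # noiseless linear: exact for every valid window
  eps <- seq(0, 0.2, length.out = 101)
  ss <- data.frame(strain = eps, stress = 5e6 * eps)
  for (w in c(3, 5, 20, 101))
    expect_equal(estimate_modulus(ss, 101, w), 5e6, tolerance = 1e-9)

  # quadratic toe then linear region of slope E: the maximum window slope
  # sits in the linear region, not the toe
  E <- 8e6; eps_t <- 0.05
  eps2 <- seq(0, 0.2, length.out = 201)
  sig <- ifelse(eps2 <= eps_t, E / (2 * eps_t) * eps2^2,
                E * (eps2 - eps_t / 2))
  ss2 <- data.frame(strain = eps2, stress = sig)
  w <- 30
  est <- estimate_modulus(ss2, 201, w)
  slopes <- oracle_window_slopes(eps2, sig, w)
  expect_equal(est, max(slopes), tolerance = 1e-9)
  expect_gt(which.max(slopes), eps_t / 0.2 * 201)   # window starts past the toe
  expect_equal(est, E, tolerance = 1e-9)

  # noisy generator curve at instrument-level noise: within 2% of truth
  simn <- simulate_tensile_test(noise_sd = 0.005 * 3.24, seed = 9)
  pn <- extract_properties(simn$record)
  expect_equal(pn$youngs_modulus, simn$truth$youngs_modulus, tolerance = 0.02)

  expect_error(estimate_modulus(ss, 4, 10), class = "kelpmech_degenerate_record")
  flat <- data.frame(strain = rep(0.1, 20), stress = seq(0, 1e6, length.out = 20))
  expect_error(estimate_modulus(flat, 20, 5), class = "kelpmech_zero_strain_range")
})

test_that("toughness is the area under the stress-strain curve in MJ/m^3", {
  eps <- seq(0, 0.1, length.out = 51)
  ss <- data.frame(strain = eps, stress = 1e6 / 0.1 * eps)  # linear to 1 MPa
  expect_equal(compute_toughness(ss, 51), 0.5 * 1 * 0.1)    # sigma_max*eps/2
  ss0 <- data.frame(strain = eps, stress = rep(0, 51))
  expect_equal(compute_toughness(ss0, 51), 0)
  expect_error(compute_toughness(ss, 1), class = "kelpmech_degenerate_record")
})

test_that("the energy identity toughness * A * L0 = W_fail holds on every record", {
  set.seed(31)
  for (k in 1:20) {
    sim <- simulate_tensile_test(noise_sd = runif(1, 0, 0.03), seed = 3000 + k,
                                 L0 = runif(1, 40, 250), area = runif(1, 0.5, 8))
    p <- extract_properties(sim$record)
    expect_equal(p$toughness * p$fracture_area * p$initial_length * 1e-3,
                 p$W_fail, tolerance = 1e-12)
    expect_equal(p$sigma_max, p$F_max / p$fracture_area * 1e6)
    expect_lte(p$F_fail, p$F_max + 1e-12)
  }
})

test_that("extracted properties scale correctly with force and geometry", {
  sim <- simulate_tensile_test(noise_sd = 0, seed = 1)
  rec <- sim$record
  p <- extract_properties(rec)

  # scaling all forces by c scales sigma_max, toughness, W_fail by c and
  # leaves epsilon_fail unchanged
  rec3 <- rec; rec3$force <- rec$force * 3
  p3 <- extract_properties(rec3)
  expect_equal(p3$sigma_max, 3 * p$sigma_max)
  expect_equal(p3$toughness, 3 * p$toughness)
  expect_equal(p3$W_fail, 3 * p$W_fail)
  expect_equal(p3$epsilon_fail, p$epsilon_fail)

  # doubling L0 with the same extension series halves strain and eps_fail
  # and doubles the modulus estimate
  recL <- rec; recL$initial_length <- 2 * rec$initial_length
  pL <- extract_properties(recL)
  expect_equal(pL$epsilon_fail, p$epsilon_fail / 2)
  expect_equal(pL$youngs_modulus, 2 * p$youngs_modulus, tolerance = 1e-9)
})

test_that("extract_properties honours the closed-form linear case and the exclusion flag", {
  # linear-elastic, E = 10 MPa to sigma_max = 1 MPa: eps_fail = 0.1,
  # toughness = sigma_max * eps_fail / 2 = 0.05 MJ/m^3
  sim <- simulate_tensile_test(youngs_modulus = 1e7, epsilon_fail = 0.1,
                               toe_fraction = 0, sigma_max = NULL,
                               noise_sd = 0, seed = 2)
  p <- extract_properties(sim$record)
  expect_equal(p$epsilon_fail, 0.1)
  expect_equal(p$sigma_max, 1e6)
  expect_equal(p$toughness, 0.05)
  expect_equal(p$youngs_modulus, 1e7, tolerance = 1e-9)

  bad <- make_record(c(1, 2, 3, 0.5), excluded = TRUE)
  expect_error(extract_properties(bad), class = "kelpmech_excluded_specimen")

  tab <- extract_properties_table(list(sim$record, bad))
  expect_equal(nrow(tab$properties), 1)
  expect_equal(tab$exclusions$specimen_id, "t")
})

test_that("record construction enforces the tensile invariants", {
  expect_error(make_record(c(1, 2)), class = "kelpmech_degenerate_record")
  expect_error(make_record(c(1, 2, 3), extension = c(0, 2, 1)),
               class = "kelpmech_invalid_spec")
  expect_error(make_record(c(1, NA, 3)), class = "kelpmech_invalid_spec")
  expect_error(make_record(c(1, 2, 3), L0 = -5), class = "kelpmech_invalid_spec")
  expect_error(make_record(c(1, 2, 3), area = 0), class = "kelpmech_invalid_spec")
})
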