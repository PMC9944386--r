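test_that("first-order amount is exponential decay from the dose", {
  p <- first_order_params(k_a = 1 / 3, a0 = 150)
  expect_equal(first_order_amount(p, 0), 150)
  # k_a = 1/3 1/h, dose 150 mg: after 3 h exactly 150/e remains
  expect_equal(first_order_amount(p, 3), 55.18191617571635,
               tolerance = 1e-14)
  expect_equal(first_order_amount(first_order_params(1 / 3, 0), c(0, 5)),
               c(0, 0))
  expect_error(first_order_amount(p, -1), ">= 0")
  a <- first_order_amount(p, seq(0, 36, by = 0.5))
  expect_true(all(diff(a) < 0))
})

test_that("integrated constants q_b and q_d match direct arithmetic", {
  p <- absorption_params(25, 75, 1, 1, 150)
  expect_equal(q_b(p, 0), 150 + 75 * log(150))
  expect_equal(q_b(p, 1), 150 + 75 * log(150) - 25)
  pd <- absorption_params(1 / 3, 75, 2, 1, 150)
  expect_equal(q_d(pd, 0), log(150) - 0.5)
  expect_equal(q_d(pd, 3), log(150) - 0.5 - 1)
  # a0 = a50: the power ratio collapses to 1/gamma2
  pe <- absorption_params(1, 75, 2, 1, 75)
  expect_equal(q_d(pe, 0), log(75) - 1)
  # both constants decrease linearly in t with slope -k_a_max
  ts <- c(0, 0.5, 2, 7)
  expect_equal(q_b(p, ts), q_b(p, 0) - 25 * ts)
  expect_equal(q_d(pd, ts), q_d(pd, 0) - ts / 3)
})

test_that("q_b and q_d guard their domains", {
  expect_error(q_b(absorption_params(1, 1, 1, 0, 10), 1), "gamma2")
  expect_error(q_b(absorption_params(1, 1, 1, 1, 0), 1), "a0")
  expect_error(q_d(absorption_params(1, 1, 2, 0, 10), 1), "gamma2")
  expect_error(q_d(absorption_params(1, 1, 2, 1, 0), 1), "a0")
})

test_that("every closed form starts exactly at the dose", {
  ts <- 0
  for (b in oracle_grid()) {
    a0 <- b$a0
    expect_lt(abs(amount_closed_form(b, 0) - a0) / a0, 1e-10)
  }
})

test_that("closed forms are monotone decreasing and within (0, a0]", {
  ts <- seq(0, 24, length.out = 200)
  for (b in list(case_b_bundle(1, 0.5), case_b_bundle(4, 0.1),
                 case_d_bundle(2, 0.5),
                 absorption_params(2 / 3, 75, 1, 0, 150))) {
    a <- amount_closed_form(b, ts)
    expect_true(all(diff(a) < 0))
    expect_true(all(a > 0 & a <= b$a0))
  }
})

test_that("case C is first-order absorption at half the maximum rate", {
  p <- absorption_params(2 / 3, 75, 1, 0, 150)
  expect_equal(amount_case_c(p, 3), 150 * exp(-1), tolerance = 1e-15)
  ts <- seq(0, 24, length.out = 50)
  expect_equal(amount_case_c(p, ts), 150 * exp(-ts / 3), tolerance = 1e-15)
  prof <- integrate_modified(p, ts)
  expect_lt(max(rel_err(prof$amounts, 150 * exp(-ts / 3))), 1e-8)
})

test_that("Michaelis-Menten is the gamma2 = 1 member, bit-identical", {
  p <- absorption_params(25, 75, 1, 1, 150)
  ts <- c(0, 0.5, 1, 6, 24)
  expect_identical(michaelis_menten_amount(p, ts), amount_case_b(p, ts))
  expect_error(michaelis_menten_amount(case_b_bundle(2, 0.5), 1),
               "gamma1 = gamma2 = 1")
})

test_that("case B matches adaptive integration on the verification grid", {
  ts <- seq(0, 24, length.out = 50)
  for (g2 in c(0.5, 1, 2)) for (r in c(0.5, 2)) {
    b <- case_b_bundle(g2, r)
    cf <- amount_case_b(b, ts)
    od <- integrate_modified(b, ts)$amounts
    expect_lt(max(rel_err(cf, od)), 1e-6)
  }
})

test_that("near-unity gamma2 curves bracket Michaelis-Menten", {
  # a50 = a0/2, k_a_max = a50 * k_a, k_a = 1/3, dose 150
  ts <- seq(0.25, 36, by = 0.25)
  mk <- function(g2) absorption_params(75 * ref_k, 75, 1, g2, 150)
  lo_g <- amount_case_b(mk(0.98), ts)
  mm <- amount_case_b(mk(1), ts)
  hi_g <- amount_case_b(mk(1.02), ts)
  expect_true(all((lo_g - mm) * (hi_g - mm) < 0))
  for (g2 in c(0.98, 1.02)) {
    od <- integrate_modified(mk(g2), ts)$amounts
    expect_lt(max(rel_err(amount_case_b(mk(g2), ts), od)), 1e-6)
  }
})

test_that("case D matches adaptive integration, including Fig-1-like setup", {
  # gamma1 = 2, gamma2 = 1, a50 = a0/2, k_a_max = 1/3
  p <- absorption_params(1 / 3, 75, 2, 1, 150)
  ts <- c(1, 6, 24)
  cf <- amount_case_d(p, ts)
  od <- integrate_modified(p, ts)$amounts
  expect_lt(max(rel_err(cf, od)), 1e-8)
  # saturation stall: a50 >> a0 freezes absorption at fixed t
  big <- absorption_params(1 / 3, 1e6 * 150, 2, 1, 150)
  expect_lt(abs(amount_case_d(big, 24) - 150) / 150, 1e-4)
})

test_that("power-law case hits zero at the analytic end time when gamma1 < 1", {
  p <- absorption_params(1, 1, 0.5, 0, 100)
  expect_equal(absorption_end_time(p), 40)
  expect_equal(amount_power_law(p, 40), 0)
  expect_equal(amount_power_law(p, c(41, 100)), c(0, 0))
  expect_gt(amount_power_law(p, 39.99), 0)
  # exact quadratic decay before the end time
  ts <- seq(0, 39, by = 1)
  expect_equal(amount_power_law(p, ts), (10 - ts / 4)^2, tolerance = 1e-12)
  # gamma1 > 1: positive for all t, matches the oracle
  q <- absorption_params(scaled_kamax(75, 2, 0), 75, 2, 0, 150)
  ts <- seq(0, 24, length.out = 50)
  expect_lt(max(rel_err(amount_power_law(q, ts),
                        integrate_modified(q, ts)$amounts)), 1e-6)
})

test_that("closed form stays continuous across the B-to-C boundary", {
  ts <- seq(0, 24, length.out = 50)
  pc <- absorption_params(2 / 3, 75, 1, 0, 150)
  pb <- absorption_params(2 / 3, 75, 1, 1e-8, 150)
  expect_lt(max(rel_err(amount_case_b(pb, ts), amount_case_c(pc, ts))),
            1e-6)
})

test_that("saturation vanishes when a50 dominates the dose", {
  # a50 = 10 a0 with k_a_max = a50 k_a: near-first-order over 12/k_a
  mm <- mm_fig1()
  fo <- first_order_params(ref_k, ref_a0)
  ts <- seq(0, 12 / ref_k, length.out = 100)
  m <- michaelis_menten_amount(mm, ts)
  f <- first_order_amount(fo, ts)
  # symmetric relative difference: the curves stay within 10% of each other
  expect_lt(max(abs(m - f) / pmax(m, f)), 0.10)
})

test_that("the dispatcher routes each case and refuses the implicit regime", {
  ts <- c(0, 1, 5)
  pc <- absorption_params(2 / 3, 75, 1, 0, 150)
  expect_identical(amount_closed_form(pc, ts), amount_case_c(pc, ts))
  pb <- case_b_bundle(2, 0.5)
  expect_identical(amount_closed_form(pb, ts), amount_case_b(pb, ts))
  pd <- case_d_bundle(2, 0.5)
  expect_identical(amount_closed_form(pd, ts), amount_case_d(pd, ts))
  pa <- absorption_params(1, 1, 2, 3, 150)
  expect_error(amount_closed_form(pa, 1), "CASE_A_IMPLICIT")
  # zero dose short-circuits every case, including A
  p0 <- absorption_params(1, 1, 2, 3, 0)
  expect_equal(amount_closed_form(p0, ts), c(0, 0, 0))
})

test_that("case evaluators reject bundles from other regimes", {
  pb <- case_b_bundle(1, 0.5)
  expect_error(amount_case_c(pb, 1), "CASE_C_FIRST_ORDER")
  expect_error(amount_case_d(pb, 1), "CASE_D_LAMBERT")
  expect_error(amount_power_law(pb, 1), "POWER_LAW")
  expect_error(amount_case_b(case_d_bundle(2, 0.5), 1), "CASE_B_LAMBERT")
})
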