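test_that("optimality switches from risky to cautious as collapse risk grows", {
  # no collapse risk and r_h > r_l: the risky policy wins
  expect_true(is_optimal("risky", tipping_model(0, 0.2, 0.5, r_l = 0.5)))
  # fully myopic agent: risky optimal iff (1 - delta) r_h >= r_l
  expect_true(is_optimal("cautious", tipping_model(0.6, 0.2, 0, r_l = 0.5)))
  expect_false(is_optimal("risky", tipping_model(0.6, 0.2, 0, r_l = 0.5)))
  expect_true(is_optimal("risky", tipping_model(0.4, 0.2, 0, r_l = 0.5)))
  # the critical collapse probability at rho = 0.2, r_l = 0.5, gamma = 0.9
  # solves (1 - d) 0.28 = 0.5 (0.28 + 0.9 d), i.e. d* = 0.14 / 0.73
  d_star <- 0.14 / 0.73
  expect_true(is_optimal("risky",
                         tipping_model(d_star - 1e-6, 0.2, 0.9, r_l = 0.5)))
  expect_true(is_optimal("cautious",
                         tipping_model(d_star + 1e-6, 0.2, 0.9, r_l = 0.5)))
  expect_error(is_optimal("trap_hh", tipping_model(0.1, 0.2, 0.9, r_l = 0.5)))
})

test_that("bisection locates the optimality boundary where values cross", {
  m <- tipping_model(0, 0.2, 0.9, r_l = 0.5)
  root <- boundary_root("optimality", m, "delta")
  expect_equal(root, 0.14 / 0.73, tolerance = 1e-10)
  m_root <- tipping_model(root, 0.2, 0.9, r_l = 0.5)
  expect_equal(value_risky(m_root)$v_p, value_cautious(m_root)$v_p,
               tolerance = 1e-10)
  # no sign change -> NA
  expect_true(is.na(boundary_root("cautious_acceptable_p",
                                  tipping_model(0.1, 0.2, 0.9, r_l = 0.5,
                                                r_min = 0.3), "delta")))
})

test_that("acceptability is the non-strict value threshold", {
  # boundary case r_l = r_min counts as acceptable
  m <- tipping_model(0.1, 0.2, 0.9, r_l = 0.5, r_min = 0.5)
  expect_true(is_acceptable("cautious", m, "prosperous"))
  expect_equal(boundary_residual("cautious_acceptable_p", m), 0)
  # without recovery the degraded state is worthless under the risky policy
  expect_false(is_acceptable("risky",
                             tipping_model(0.1, 0, 0.9, r_l = 0.5,
                                           r_min = 0.2), "degraded"))
  expect_true(is_acceptable("risky",
                            tipping_model(0.1, 0, 0.9, r_l = 0.5,
                                          r_min = 0), "degraded"))
  # v_d = 0.18/0.28 ~ 0.643 >= 0.6
  expect_true(is_acceptable("cautious",
                            tipping_model(0.1, 0.2, 0.9, r_l = 1,
                                          r_min = 0.6), "degraded"))
})

test_that("sustainability follows the visited-states rule", {
  # cautious: sustainable exactly when the prosperous state is acceptable
  rows <- random_models(200, seed = 71, gamma_max = 1)
  for (i in seq_len(nrow(rows))) {
    m <- model_from_row(rows[i, ])
    expect_identical(is_sustainable("cautious", m), m$r_l >= m$r_min)
    # risky: both states must be acceptable
    expect_identical(is_sustainable("risky", m),
                     is_acceptable("risky", m, "prosperous") &&
                       is_acceptable("risky", m, "degraded"))
  }
  # zero threshold makes everything acceptable
  expect_true(is_sustainable("risky",
                             tipping_model(0.9, 0.1, 0.5, r_l = 0.5,
                                           r_min = 0)))
  # farsighted agent, small collapse risk: even the degraded state is
  # acceptable under the risky policy
  m <- tipping_model(0.05, 0.2, 0.99, r_l = 0.5, r_min = 0.3)
  expect_true(is_sustainable("risky", m))
  expect_gt(boundary_residual("risky_acceptable_d", m), 0)
})

test_that("only the cautious policy is safe, for every parameter choice", {
  rows <- random_models(100, seed = 81, gamma_max = 1)
  for (i in seq_len(nrow(rows))) {
    m <- model_from_row(rows[i, ])
    expect_true(is_safe("cautious", m))
    expect_false(is_safe("risky", m))
  }
  # the blanket rule holds even at delta = 0, where the reachability-based
  # cross-check disagrees (the chain then never leaves the prosperous state)
  m0 <- tipping_model(0, 0.2, 0.9, r_l = 0.5)
  expect_false(is_safe("risky", m0))
  expect_true(reachability_safe("risky", m0))
  # for delta > 0 the cross-check agrees with the rule
  m1 <- tipping_model(0.2, 0.2, 0.9, r_l = 0.5)
  expect_identical(reachability_safe("risky", m1), is_safe("risky", m1))
  expect_identical(reachability_safe("cautious", m1),
                   is_safe("cautious", m1))
})

test_that("boundary residual signs match the predicates on random models", {
  rows <- random_models(400, seed = 91, gamma_max = 1)
  for (i in seq_len(nrow(rows))) {
    m <- model_from_row(rows[i, ])
    expect_identical(boundary_residual("optimality", m) >= 0,
                     is_optimal("risky", m))
    expect_identical(boundary_residual("risky_acceptable_p", m) >= 0,
                     is_acceptable("risky", m, "prosperous"))
    expect_identical(boundary_residual("risky_acceptable_d", m) >= 0,
                     is_acceptable("risky", m, "degraded"))
    expect_identical(boundary_residual("cautious_acceptable_p", m) >= 0,
                     is_acceptable("cautious", m, "prosperous"))
    expect_identical(boundary_residual("cautious_acceptable_d", m) >= 0,
                     is_acceptable("cautious", m, "degraded"))
  }
})

test_that("optimality does not depend on the state used for comparison", {
  rows <- random_models(300, seed = 101, gamma_max = 1)
  for (i in seq_len(nrow(rows))) {
    m <- model_from_row(rows[i, ])
    vr <- value_risky(m); vc <- value_cautious(m)
    if (vr$v_d != vc$v_d)
      expect_identical(vr$v_p >= vc$v_p, vr$v_d >= vc$v_d)
  }
})

test_that("classification composes the three predicates", {
  # cautious above the critical collapse probability: the sweet spot
  lab <- classify_policy("cautious",
                         tipping_model(0.3, 0.2, 0.9, r_l = 0.5,
                                       r_min = 0.3))
  expect_identical(lab$code, "OSF")
  # risky at low collapse risk: optimal but never safe
  lab <- classify_policy("risky",
                         tipping_model(0.05, 0.2, 0.9, r_l = 0.5,
                                       r_min = 0.3))
  expect_true(lab$optimal)
  expect_false(lab$safe)
  # threshold above r_l: the cautious policy is safe but not sustainable,
  # whatever delta, rho, gamma
  rows <- random_models(50, seed = 111, gamma_max = 1)
  for (i in seq_len(nrow(rows))) {
    m <- tipping_model(rows$delta[i], rows$rho[i], rows$gamma[i],
                       r_l = 0.5, r_min = 0.7)
    lab <- classify_policy("cautious", m)
    expect_false(lab$sustainable)
    expect_true(lab$safe)
  }
})

test_that("paradigm codes round-trip through decoding", {
  codes <- paradigm_codes()
  expect_length(unique(codes), 8L)
  d <- decode_paradigm(codes)
  expect_identical(paradigm_code(d$optimal, d$sustainable, d$safe), codes)
})

test_that("regime-map sweeps reproduce the known region structure", {
  base <- sweep_settings()$baseline
  vals <- seq(0, 1, length.out = 21)
  sw <- sweep_classification("delta", "gamma", vals, vals, fixed = base)
  expect_identical(names(sw),
                   c("axis1_name", "axis1", "axis2_name", "axis2",
                     "policy", "optimal", "sustainable", "safe"))
  expect_true(all(sw$safe[sw$policy == "cautious"]))
  expect_false(any(sw$safe[sw$policy == "risky"]))
  # with r_l >= r_min the cautious policy is sustainable everywhere
  expect_true(all(sw$sustainable[sw$policy == "cautious"]))
  # the classification survives absolute farsightedness: at gamma = 1 the
  # risky policy is still sustainable-but-not-safe somewhere, and with a
  # high threshold the optimal policy is still not sustainable somewhere
  top <- sw[sw$axis2 == 1 & sw$policy == "risky", ]
  expect_true(any(top$sustainable & !top$safe))
  hi <- sweep_classification("delta", "gamma", vals, vals,
                             fixed = sweep_settings()$high_threshold)
  top_hi <- hi[hi$axis2 == 1, ]
  expect_true(any(top_hi$optimal & !top_hi$sustainable))
  expect_error(sweep_classification("delta", "gamma", c(0, 1.5), vals),
               "\\[0, 1\\]")
  expect_error(sweep_classification("delta", "delta", vals, vals))
})

test_that("point classification and the vectorized sweep agree", {
  rows <- random_models(60, seed = 121, gamma_max = 1)
  for (i in seq_len(nrow(rows))) {
    m <- model_from_row(rows[i, ])
    sw <- sweep_classification("delta", "rho", m$delta, m$rho,
                               fixed = list(gamma = m$gamma, r_l = m$r_l,
                                            r_min = m$r_min))
    for (pol in c("risky", "cautious")) {
      lab <- classify_policy(pol, m)
      row <- sw[sw$policy == pol, ]
      expect_identical(row$optimal, lab$optimal)
      expect_identical(row$sustainable, lab$sustainable)
      expect_identical(row$safe, lab$safe)
    }
  }
})
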