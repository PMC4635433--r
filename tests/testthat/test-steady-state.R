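test_that("closed-form fixtures solve exactly", {
  f1 <- fixture_system("one_pool")
  X <- steady_state_pools(f1$sys, f1$xi, f1$U)
  expect_equal(unname(X), f1$U / diag(f1$sys$C))
  expect_equal(residence_time(f1$sys, f1$xi)$tau, f1$tau_expected)
  # zero influx gives zero pools
  expect_equal(unname(steady_state_pools(f1$sys, f1$xi, 0)), 0)

  f2 <- fixture_system("chain_2")
  expect_equal(residence_time(f2$sys, f2$xi)$tau, f2$tau_expected)
  f3 <- fixture_system("chain_3")
  expect_equal(residence_time(f3$sys, f3$xi)$tau, f3$tau_expected)
})

test_that("steady state matches forward integration on a 3-pool chain", {
  f <- fixture_system("chain_3")
  o <- ode_integrate_oracle(f$sys, f$xi, f$U, years = 1000, dt = 1 / 365)
  expect_lt(o$max_rel_gap, 1e-3)
  X <- steady_state_pools(f$sys, f$xi, f$U)
  expect_equal(unname(o$X), unname(X), tolerance = 1e-3)
})

test_that("residence time is internally consistent and U-independent", {
  for (seed in c(11, 12, 13, 14, 15)) {
    r <- random_system(seed)
    rt <- residence_time(r$sys, r$xi)
    expect_equal(sum(rt$per_pool), rt$tau)
    X <- steady_state_pools(r$sys, r$xi, r$U)
    # tau * U = total steady stock
    expect_equal(rt$tau * r$U, sum(X), tolerance = 1e-9)
    # linearity: doubling U doubles pools, leaves tau unchanged
    expect_equal(unname(steady_state_pools(r$sys, r$xi, 2 * r$U)),
                 unname(2 * X), tolerance = 1e-12)
    expect_true(all(X >= 0))
  }
})

test_that("baseline residence time equals the unscaled system's tau", {
  sys <- ebf_system()
  expect_identical(baseline_residence_time(sys)$tau,
                   residence_time(sys, diag(13))$tau)
  # identity scalar: residence time equals baseline exactly
  xi1 <- environmental_scalar_matrix(1, 1)
  expect_equal(residence_time(sys, xi1)$tau,
               baseline_residence_time(sys)$tau)
})

test_that("increasing wood allocation increases forest baseline tau", {
  p <- shipped_params[["EBF"]]
  taus <- vapply(c(0.30, 0.38, 0.46), function(bw) {
    b <- p$b
    b[-2] <- b[-2] * (1 - bw) / sum(b[-2])
    b[2] <- bw
    p2 <- biome_params(p$biome, b, p$LN, p$Lleaf, p$Lfroot, p$Lwood, p$c)
    baseline_residence_time(transfer_system(p2, loam))$tau
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("elementwise-larger environmental scalar never increases tau", {
  for (seed in c(21, 22, 23, 24)) {
    r <- random_system(seed)
    s <- diag(r$xi)[5]
    s_hi <- min(1, s * 1.5)
    xi_hi <- environmental_scalar_matrix(sqrt(s_hi), sqrt(s_hi))
    expect_lte(residence_time(r$sys, xi_hi)$tau,
               residence_time(r$sys, r$xi)$tau + 1e-12)
    # and tau never drops below the all-ones baseline
    expect_gte(residence_time(r$sys, r$xi)$tau,
               baseline_residence_time(r$sys)$tau - 1e-12)
  }
})

test_that("aggregate scalar exposes both product and ratio definitions", {
  sys <- ebf_system()
  agg1 <- aggregate_environmental_scalar(sys, 1, 1)
  expect_equal(agg1$product, 1)
  expect_equal(agg1$ratio, 1)
  agg <- aggregate_environmental_scalar(sys, 0.69, 0.53)
  expect_equal(agg$product, 0.3657)
  expect_equal(round(agg$product, 2), 0.37)
  # vegetation pools dilute the implied (ratio) limitation
  expect_gt(agg$ratio, agg$product)
  # subtracting vegetation contributions recovers the litter/soil scalar
  s <- 0.3657
  xi <- environmental_scalar_matrix(0.69, 0.53)
  pp <- residence_time(sys, xi)$per_pool
  pp0 <- baseline_residence_time(sys)$per_pool
  veg <- pool_indices(class = "vegetation")
  expect_equal((sum(pp0[-veg])) / (sum(pp[-veg])), s, tolerance = 1e-12)
})

test_that("storage capacity is the NPP x tau product with unit conversion", {
  cst <- carbon_storage_capacity(272.9, 69.1)
  expect_equal(cst$gC_m2, 272.9 * 69.1)
  expect_equal(round(cst$kgC_m2, 1), 18.9)
  expect_equal(carbon_storage_capacity(0, 50)$gC_m2, 0)
  expect_equal(carbon_storage_capacity(1000, 50)$gC_m2, 50000)
  expect_error(carbon_storage_capacity(-1, 50), "NPP")
  expect_error(carbon_storage_capacity(100, 0), "residence")
})

test_that("respired flux balances influx at steady state", {
  for (seed in c(31, 32, 33)) {
    r <- random_system(seed)
    X <- steady_state_pools(r$sys, r$xi, r$U)
    out_flux <- diag(r$xi) * diag(r$sys$C) * X      # exiting flux per pool
    respired <- sum(r$sys$respired * out_flux)
    expect_equal(respired, r$U, tolerance = 1e-6 * r$U)
  }
})

test_that("integration oracle behaves on trivial cases", {
  # 1-pool: X -> U/c within 0.1% after 200 yr
  sys1 <- as_transfer_system(matrix(1), 0.5, 1)
  o <- ode_integrate_oracle(sys1, diag(1), U = 10, years = 200, dt = 0.05)
  expect_equal(unname(o$X), 20, tolerance = 1e-3)
  # zero influx: monotone decay to zero from any start
  o0 <- ode_integrate_oracle(sys1, diag(1), U = 0, years = 50, dt = 0.05,
                             X0 = 7)
  expect_lt(unname(o0$X), 1e-8)
  traj <- o0$trajectory[, 1]
  expect_true(all(diff(traj) <= 0))
  # unstable step refused
  expect_error(ode_integrate_oracle(sys1, diag(1), U = 1, years = 1,
                                    dt = 3), "dt")
})

test_that("ill-conditioned systems are rejected with pool names", {
  sys <- as_transfer_system(diag(2), c(1, 1e-30), c(1, 0),
                            c("fast", "degenerate"))
  expect_error(steady_state_pools(sys, diag(2), U = 1, kappa_max = 1e12),
               "ill-conditioned.*degenerate")
})

test_that("trace_cell reproduces the decomposition identity", {
  res <- trace_cell(ebf_system(), 0.69, 0.53, npp = 1325.7)
  expect_identical(res$c_storage, res$npp * res$tau_E)
  expect_equal(sum(res$per_pool_tau), res$tau_E)
  expect_lte(res$tau_E, res$tau_E_baseline / res$xi_agg + 1e-9)
  expect_gte(res$tau_E, res$tau_E_baseline)
})
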