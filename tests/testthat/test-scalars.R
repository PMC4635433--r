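test_that("Lloyd-Taylor scalar is normalized, monotone and clamped", {
  expect_equal(lloyd_taylor_scalar(10), 1)  # reference temperature
  # frozen values from direct evaluation of the exponential
  expect_equal(lloyd_taylor_scalar(5), 0.5828697463795024, tolerance = 1e-12)
  expect_equal(lloyd_taylor_scalar(0), 0.30213599062220675,
               tolerance = 1e-12)
  expect_equal(lloyd_taylor_scalar(25), 1)  # raw 3.2006, clamped
  tt <- seq(-40, 9.5, by = 0.5)
  expect_true(all(diff(lloyd_taylor_scalar(tt)) > 0))
  expect_warning(v <- lloyd_taylor_scalar(-50), "singularity")
  expect_equal(v, 0)
})

test_that("Q10 scalar matches the closed form", {
  expect_equal(q10_scalar(10), 1)
  expect_equal(q10_scalar(0, Q10 = 2), 0.5)
  expect_equal(q10_scalar(5, Q10 = 2), 2^(-0.5))
  expect_error(q10_scalar(5, Q10 = 1), "Q10")
})

test_that("piecewise moisture scalar honours the 0.25 floor and peak", {
  expect_equal(beps_moisture_scalar(0, 0.45), 0.25)
  expect_equal(beps_moisture_scalar(0.75 * 0.45, 0.45), 1)
  k <- seq(0, 1, by = 0.001)
  v <- beps_moisture_scalar(k * 0.5, 0.5)
  expect_gte(min(v), 0.25)
  expect_lte(max(v), 1)
  # unimodal: rises to the optimum, declines after
  expect_true(all(diff(v[k <= 0.75]) > 0))
  expect_true(all(diff(v[k >= 0.75]) < 0))
  expect_warning(beps_moisture_scalar(0.6, 0.5), "clamp")
  expect_error(beps_moisture_scalar(0.1, 0), "porosity")
})

test_that("parabolic moisture scalar is one smooth function over the range", {
  expect_equal(cable_moisture_scalar(0.6), 1)
  th <- seq(0, 1, by = 0.001)
  v <- cable_moisture_scalar(th)
  expect_true(all(v >= 0 & v <= 1))
  expect_lt(max(abs(diff(v))), 1e-3)      # continuity sweep
  expect_lt(v[1], 1)                      # parabolic-type shape:
  expect_lt(v[length(v)], 1)              # both ends below the optimum
  expect_warning(cable_moisture_scalar(1.4), "clamp")
})

test_that("linear moisture scalar matches 0.25 + 0.75 W1", {
  expect_equal(lpj_moisture_scalar(0), 0.25)
  expect_equal(lpj_moisture_scalar(1), 1)
  expect_equal(lpj_moisture_scalar(0.4), 0.55)
})

test_that("all registered scalars map admissible inputs into [0, 1]", {
  set.seed(99)
  reg <- scalar_scheme_registry()
  tt <- runif(300, -40, 40)
  mm <- runif(300, 0, 1)
  for (s in reg) {
    xt <- s$temperature_fn(tt)
    xw <- s$moisture_fn(mm)
    expect_true(all(xt >= 0 & xt <= 1), info = s$name)
    expect_true(all(xw >= 0 & xw <= 1), info = s$name)
    # determinism
    expect_identical(s$moisture_fn(mm), xw, info = s$name)
  }
})

test_that("scheme registry round-trips by name with a moisture variable", {
  reg <- scalar_scheme_registry()
  expect_setequal(names(reg), c("beps", "cable", "casa", "intec", "ibis",
                                "lpj", "orchidee", "dlem", "century"))
  for (nm in names(reg)) {
    s <- scalar_scheme_registry(nm)
    expect_identical(s$name, nm)
    expect_true(s$moisture_variable %in%
                  c("k", "theta1", "theta", "p", "W1", "x"))
  }
  expect_error(scalar_scheme_registry("miami"), "unknown")
})

test_that("Lloyd-Taylor and Q10 curves converge as soil warms", {
  tt <- seq(0, 30, by = 1)
  gap <- abs(lloyd_taylor_scalar(tt) - q10_scalar(tt))
  expect_true(all(diff(gap) <= 1e-12))  # non-increasing over 0-30 C
  expect_true(all(diff(q10_scalar(seq(-20, 9, by = 1))) > 0))
})

test_that("environmental scalar matrix spares vegetation pools", {
  expect_equal(environmental_scalar_matrix(1, 1), diag(13),
               ignore_attr = TRUE)
  xi <- environmental_scalar_matrix(0.69, 0.53)
  d <- diag(xi)
  expect_equal(unname(d[1:4]), rep(1, 4))
  expect_equal(unname(d[5:13]), rep(0.3657, 9))
  # vegetation entries are 1 regardless of inputs
  expect_equal(unname(diag(environmental_scalar_matrix(0.01, 0.02))[1:4]),
               rep(1, 4))
  expect_error(environmental_scalar_matrix(1.2, 0.5), "0, 1")
})
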