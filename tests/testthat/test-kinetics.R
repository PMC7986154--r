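test_that("Smoluchowski reaction probability: limits and frozen value", {
  expect_equal(p_react_total(0.5, 0.5, 0.01, 1), 1)
  expect_equal(p_react_total(1.0, 0.5, 0.01, 1e18), 0.5, tolerance = 1e-6)
  expect_equal(p_react_total(1.0, 0.5, 0.01, 0), 0)
  # frozen 50-digit oracle: R=0.5 nm, r0=1 nm, D=1e-8 m2/s, t=1 ns
  expect_equal(p_react_total(1.0, 0.5, diffusion_to_internal(1e-8), 1000),
               0.455489646255317, tolerance = 1e-12)
  expect_error(p_react_total(0.4, 0.5, 0.01, 1), "contact")
  # monotone in t
  tg <- 10^seq(-2, 6, length.out = 200)
  expect_true(all(diff(p_react_total(1.2, 0.4, 0.005, tg)) >= 0))
})

test_that("effective distance: sign convention, limits, frozen value", {
  expect_equal(effective_distance(1.0, 0), 1.0)
  expect_equal(effective_distance(1.0, 1e-12), 1.0, tolerance = 1e-9)
  # frozen oracle rc = 0.71 (repulsive), d = 1.5
  expect_equal(effective_distance(1.5, 0.71), 1.17290153547269,
               tolerance = 1e-12)
  # repulsion contracts, attraction dilates
  expect_lt(effective_distance(1.5, 0.71), 1.5)
  expect_gt(effective_distance(1.5, -0.71), 1.5)
  # numeric large-d limit: deff - (d - rc/2) -> 0
  expect_equal(effective_distance(1e6, 0.71), 1e6 - 0.71 / 2, tolerance = 1e-6)
})

test_that("radiation-boundary probability: limits, stability, frozen value", {
  R <- 0.4; r0 <- 1.0; D <- 0.005
  kdif <- 4 * pi * R * D; kact <- kdif
  expect_equal(p_react_partial(r0, R, D, kdif, kact, 0), 0)
  # asymptote Reff/r0 with Reff = R kact/(kdif+kact)
  expect_equal(p_react_partial(r0, R, D, kdif, kact, 1e15),
               (R / r0) * kact / (kdif + kact), tolerance = 1e-5)
  # frozen oracle at t = 100 ps
  expect_equal(p_react_partial(r0, R, D, kdif, kact, 100),
               0.0865954151461718, tolerance = 1e-12)
  # the scaled-erfc formulation stays finite where exp(x^2) overflows
  expect_true(is.finite(p_react_partial(r0, R, D, kdif, kact, 1e12)))
  # monotone, bounded by P0
  tg <- 10^seq(-2, 10, length.out = 300)
  p <- p_react_partial(r0, R, D, kdif, kact, tg)
  expect_true(all(diff(p) >= -1e-12))
  expect_true(all(p <= (R / r0) * kact / (kdif + kact) + 1e-12))
})

test_that("charged radiation-boundary probability converges to neutral", {
  R <- 0.4; r0 <- 1.2; D <- 0.007
  kdif <- 4 * pi * R * D; kact <- 2 * kdif
  tg <- 10^seq(0, 6, length.out = 40)
  pn <- p_react_partial(r0, R, D, kdif, kact, tg)
  for (rc in c(1e-8, -1e-8)) {
    Rt <- effective_distance(R, rc)
    pc <- p_react_partial(r0, R, D, 4 * pi * Rt * D, kact, tg,
                          charged = TRUE, rc = rc)
    expect_equal(pc, pn, tolerance = 1e-6)
  }
})

test_that("inversion sampler matches the Smoluchowski distribution", {
  set.seed(101)
  r0 <- 1.5; R <- 0.5; D <- 0.008; n <- 2e5
  t <- sample_time_total(r0, R, D, n)
  frac <- mean(is.finite(t))
  expect_lt(abs(frac - R / r0), sigma3(R / r0, n))
  ks <- ks_distance(t, function(tt) erfc_vec((r0 - R) / sqrt(4 * D * tt)))
  expect_lt(ks, 0.005)
  # contact start reacts immediately
  expect_true(all(sample_time_total(0.5, 0.5, D, 10) == 0))
})

test_that("encounter-stage sampler matches the contact distribution", {
  set.seed(102)
  kd <- 0.05; ka <- 0.05; R <- 0.4; D <- 0.0098; n <- 2e5
  t <- sample_time_from_encounter(kd, ka, R, D, n)
  expect_lt(abs(mean(is.finite(t)) - 0.5), sigma3(0.5, n))
  ks <- ks_distance(t, function(tt) {
    x <- (kd + ka) * sqrt(D * tt) / (kd * R)
    1 - erfcx_vec(x)
  })
  expect_lt(ks, 0.005)
  expect_true(all(is.infinite(sample_time_from_encounter(kd, 0, R, D, 100))))
})

test_that("two-stage sampler matches the radiation-boundary distribution", {
  set.seed(103)
  rx <- reaction_lookup(tab_mixed, "H", "OH")
  r0 <- 1.0; n <- 2e5
  t <- sample_time_partial(r0, rx$R, rx$D, rx$kdif, rx$kact, n)
  P0 <- rx$Reff / r0
  expect_lt(abs(mean(is.finite(t)) - P0), sigma3(P0, n))
  ks <- ks_distance(t, function(tt) {
    p_react_partial(r0, rx$R, rx$D, rx$kdif, rx$kact, tt) / P0
  })
  expect_lt(ks, 0.01)
})

test_that("two-stage sampler reduces to the inversion sampler when kact -> Inf", {
  set.seed(104)
  r0 <- 1.2; R <- 0.4; D <- 0.006; n <- 1e5
  kdif <- 4 * pi * R * D
  t1 <- sample_time_partial(r0, R, D, kdif, Inf, n)
  ks <- ks_distance(t1, function(tt) erfc_vec((r0 - R) / sqrt(4 * D * tt)))
  expect_lt(ks, 0.01)
})

test_that("contact-reaction probability: limits and exact value", {
  expect_equal(contact_reaction_prob(0.5, 0.3, 1, Inf), 1)
  expect_equal(contact_reaction_prob(0.5, 0.3, 1, 0), 0)
  expect_equal(contact_reaction_prob(0.5, 0.3, 1, 1), 0.3 / 1.1,
               tolerance = 1e-12)
  # charged form reduces to the neutral form as rc -> 0
  pn <- contact_reaction_prob(0.5, 0.3, 1, 2)
  pc <- contact_reaction_prob(0.5, 0.3, 1, 2, rc = 1e-9, charged = TRUE)
  expect_equal(pc, pn, tolerance = 1e-6)
})

test_that("protection-domain step inverts the reaction probability", {
  set.seed(105)
  for (i in 1:8) {
    R <- runif(1, 0.2, 0.8); r0 <- R * runif(1, 1.3, 6); D <- runif(1, 2e-3, 1e-2)
    dt <- dynamic_time_step(r0, R, D, 0.95)
    if (is.finite(dt)) {
      expect_equal(p_react_total(r0, R, D, dt), 0.05, tolerance = 1e-10)
    } else {
      expect_lt(R / r0, 0.05 + 1e-12)
    }
  }
  # frozen bisection oracle: r0=2, R=0.5, D=5e-9 m2/s
  expect_equal(dynamic_time_step(2, 0.5, diffusion_to_internal(5e-9)),
               136.996776084993, tolerance = 1e-9)
  # confidence -> 1 shrinks the step monotonically toward zero
  cseq <- c(0.9, 0.95, 0.99, 0.999, 0.999999, 1 - 1e-12)
  dts <- vapply(cseq, function(cc) dynamic_time_step(2, 0.5, 0.005, cc), 1.0)
  expect_true(all(diff(dts) < 0))
  expect_lt(dts[length(dts)], dts[1] / 20)
  expect_error(dynamic_time_step(0.4, 0.5, 0.005), "exceed")
})

test_that("bridge probability: limits and pinned-path Monte Carlo oracle", {
  expect_equal(brownian_bridge_prob(0.5, 0.8, 0.5, 0.005, 1), 1)
  expect_lt(brownian_bridge_prob(0.8, 0.8, 0.5, 0.005, 1e-6), 1e-10)
  # short-step regime equals the reflection form
  expect_equal(brownian_bridge_prob(0.6, 0.7, 0.5, 0.005, 1),
               exp(-0.1 * 0.2 / 0.005), tolerance = 1e-4)
  # pinned 1-D bridge MC at d0 = d1 = 1.2 R, D dt = (d0-R)^2:
  # expected exp(-1); discrete monitoring bias bounded by the
  # Broadie-Glasserman barrier shift 0.5826 sigma_step (~0.004 here)
  set.seed(106)
  R <- 1; a <- 0.2; D <- 0.01; dt <- a^2 / D
  mc <- cpp_bridge_mc_shim(a, a, D, dt, 2e4, 2e4)
  expect_lt(abs(mc - exp(-1)), sigma3(exp(-1), 2e4) + 0.005)
})
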