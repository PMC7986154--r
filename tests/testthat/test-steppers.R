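test_that("empty and inert systems pass through unchanged", {
  empty <- tibble::tibble(history = integer(0), species = character(0),
                          x_nm = numeric(0), y_nm = numeric(0),
                          z_nm = numeric(0), t_ps = numeric(0))
  for (m in c("irt", "sbs")) {
    h <- run_chemistry(empty, tab_mixed, method = m, end_time = 100)
    expect_equal(nrow(h$events), 0)
  }
  # hydrogen peroxide molecules have no mutual reaction: pure diffusion
  inert <- tibble::tibble(history = 1L, species = rep("H2O2", 6),
                          x_nm = rnorm(6), y_nm = rnorm(6), z_nm = rnorm(6),
                          t_ps = 0)
  h <- run_irt(inert, tab_mixed, end_time = 1e4)
  expect_equal(nrow(h$events), 0)
  expect_equal(nrow(h$final), 6)
  expect_true(all(h$final$species == "H2O2"))
})

test_that("neutralization kills both ions and creates nothing", {
  snap <- tibble::tibble(history = 1L, species = c("H3O+", "OH-"),
                         x_nm = c(0, 0.3), y_nm = 0, z_nm = 0, t_ps = 0)
  set.seed(31)
  h <- run_irt(snap, tab_mixed, end_time = 1e5)
  expect_equal(sum(h$events$type == "reaction"), 1)
  expect_equal(nrow(h$final), 0)
})

test_that("IRT two-particle reaction fraction matches the asymptote", {
  set.seed(32)
  rx <- reaction_lookup(tab_tdc, "H", "OH")
  r0 <- 1.0; n <- 2e4
  h <- run_chemistry(pair_snapshot("H", "OH", r0, n), tab_tdc,
                     method = "irt", end_time = 1e6)
  frac <- sum(h$events$type == "reaction") / n
  expect_lt(abs(frac - rx$Reff / r0), sigma3(rx$Reff / r0, n))
})

test_that("SBS two-particle reaction fraction matches the Smoluchowski law", {
  set.seed(33)
  rx <- reaction_lookup(tab_tdc, "H", "OH")
  r0 <- 1.0; n <- 2e4; t_end <- 1e5
  p_th <- (rx$Reff / r0) * erfc_vec((r0 - rx$Reff) / sqrt(4 * rx$D * t_end))
  h <- run_chemistry(pair_snapshot("H", "OH", r0, n), tab_tdc,
                     method = "sbs", end_time = t_end,
                     schedule = schedule_fixed(0.1))
  frac <- sum(h$events$type == "reaction") / n
  expect_lt(abs(frac - p_th), sigma3(p_th, n))
})

test_that("disabling the Brownian bridge loses reactions", {
  set.seed(34)
  n <- 4000
  snap <- pair_snapshot("H", "OH", 1.0, n)
  on <- run_chemistry(snap, tab_tdc, method = "sbs", end_time = 1e4,
                      bridge = TRUE)
  off <- run_chemistry(snap, tab_tdc, method = "sbs", end_time = 1e4,
                       bridge = FALSE)
  expect_gt(sum(on$events$type == "reaction"),
            sum(off$events$type == "reaction"))
})

test_that("free diffusion produces Gaussian displacements of variance 2 D t", {
  set.seed(35)
  n <- 3e4; t_end <- 100
  snap <- tibble::tibble(history = seq_len(n), species = "H2O2",
                         x_nm = 0, y_nm = 0, z_nm = 0, t_ps = 0)
  h <- run_chemistry(snap, tab_mixed, method = "irt", end_time = t_end)
  D <- species_table(tab_mixed)$D[match("H2O2", species_table(tab_mixed)$name)]
  v <- c(var(h$final$x_nm), var(h$final$y_nm), var(h$final$z_nm))
  expect_true(all(abs(v / (2 * D * t_end) - 1) < 0.03))
  expect_gt(shapiro.test(h$final$x_nm[1:3000])$p.value, 1e-4)
})

test_that("the spin statistical factor gates reactions at the singlet weight", {
  set.seed(36)
  rx <- reaction_lookup(tab_mixed, "H", "eaq")
  n <- 1e4
  # at contact the reaction is certain when admissible, blocked otherwise
  h <- run_chemistry(pair_snapshot("H", "eaq", rx$R * 0.5, n), tab_mixed,
                     method = "irt", end_time = 1e4)
  frac <- sum(h$events$type == "reaction") / n
  expect_lt(abs(frac - 0.25), sigma3(0.25, n))
})

test_that("event logs replay to the final state", {
  set.seed(37)
  snap <- gen_electron_spurs(spur_model(), 5)
  h <- run_chemistry(snap, tab_mixed, method = "irt", end_time = 1e5)
  # times nondecreasing within each history
  for (hh in unique(h$events$history)) {
    tt <- h$events$time_ps[h$events$history == hh]
    expect_true(all(diff(tt) >= 0))
  }
  expect_true(all(h$events$reaction[h$events$type == "reaction"] %in%
                    paste(tab_mixed$a, "+", tab_mixed$b)))
  # replay: initial counts + event deltas == final counts, per species
  prods <- stats::setNames(tab_mixed$products,
                           paste(tab_mixed$a, "+", tab_mixed$b))
  species <- species_table(tab_mixed)$name
  cnt <- table(factor(snap$species, species))
  rx <- h$events[h$events$type == "reaction", ]
  cnt <- cnt - table(factor(rx$species_a, species)) -
    table(factor(rx$species_b, species)) +
    table(factor(unlist(prods[rx$reaction]), species))
  oth <- h$events[h$events$type != "reaction", ]
  cnt <- cnt - table(factor(oth$species_a, species))
  expect_equal(as.vector(cnt),
               as.vector(table(factor(h$final$species, species))))
})

test_that("product placement follows the diffusion-weighted rule", {
  expect_equal(place_products(c(0, 0, 0), c(1, 0, 0), 2, 2, 1),
               matrix(c(0.5, 0, 0), 1, 3))
  expect_equal(place_products(c(1, 2, 3), c(4, 5, 6), 1e-30, 2, 1),
               matrix(c(1, 2, 3), 1, 3), tolerance = 1e-9)
  two <- place_products(c(0, 0, 0), c(1, 0, 0), 1, 1, 2)
  expect_equal(two, rbind(c(0, 0, 0), c(1, 0, 0)))
  three <- place_products(c(0, 0, 0), c(1, 0, 0), 1, 1, 3)
  expect_equal(three[3, ], c(0.5, 0, 0))
  expect_error(place_products(c(0, 0, 0), c(1, 0, 0), 1, 1, 4), "three")
})

test_that("molecules leaving the voxel are discarded, only with geometry", {
  fib <- build_fiber()
  # far corner start drifts out quickly at 10 ns scale
  snap <- tibble::tibble(history = seq_len(50), species = "OH",
                         x_nm = 19.5, y_nm = 19.5, z_nm = 19.5, t_ps = 1)
  set.seed(38)
  h <- run_chemistry(snap, tab_mixed, method = "irt", geometry = fib,
                     end_time = 1e4)
  expect_gt(sum(h$events$type == "escape"), 0)
  expect_true(all(abs(h$final$x_nm) <= 20))
  # without geometry the same population never escapes
  h2 <- run_chemistry(snap, tab_mixed, method = "irt", end_time = 1e4)
  expect_equal(sum(h2$events$type == "escape"), 0)
})

test_that("each sink is damaged at most once and damage is bounded", {
  fib <- build_fiber()
  set.seed(39)
  tr <- gen_proton_track(track_model(), n_histories = 5)
  for (m in c("irt", "sbs")) {
    h <- run_chemistry(tr$snapshot, tab_mixed, method = m, geometry = fib,
                       end_time = 1e3)
    dmg <- h$events[h$events$type == "damage", ]
    per_hist <- split(dmg$sink, dmg$history)
    expect_true(all(vapply(per_hist, anyDuplicated, 1L) == 0))
    expect_lte(nrow(dmg), nrow(tr$snapshot))
    expect_true(all(h$damage$element %in% c("deoxyribose", "base")))
    expect_true(all(h$damage$agent %in% c("eaq", "OH", "H")))
  }
})

test_that("IRT and SBS agree on a radical cluster's survival", {
  set.seed(40)
  n <- 300; m <- 10
  snap <- tibble::tibble(
    history = rep(seq_len(n), each = m), species = "OH",
    x_nm = rnorm(n * m), y_nm = rnorm(n * m), z_nm = rnorm(n * m), t_ps = 0)
  hI <- run_chemistry(snap, tab_tdc, method = "irt", end_time = 1e4)
  hS <- run_chemistry(snap, tab_tdc, method = "sbs", end_time = 1e4,
                      schedule = schedule_fixed(0.1))
  sI <- nrow(hI$final[hI$final$species == "OH", ]) / (n * m)
  sS <- nrow(hS$final[hS$final$species == "OH", ]) / (n * m)
  # binomial-scale agreement between the two methods
  expect_lt(abs(sI - sS), 3 * sqrt(2 * sI * (1 - sI) / (n * m)) + 0.02)
})
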