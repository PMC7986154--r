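test_that("G-values are counts per 100 eV on the grid", {
  snap <- tibble::tibble(history = 1L, species = rep("OH", 10),
                         x_nm = 1:10 * 100, y_nm = 0, z_nm = 0, t_ps = 1)
  h <- run_irt(snap, tab_mixed, end_time = 1e4)
  gv <- g_value_series(h, E_dep = 1000, grid = log_time_grid(1, 1e4, 10))
  oh <- gv[gv$species == "OH", ]
  expect_true(all(oh$G == 1.0))  # 10 molecules / 1000 eV * 100
  expect_true(all(gv[gv$species == "H2O2", ]$G == 0))
})

test_that("G-value series is a right-continuous step function of events", {
  # an isolated ion pair reacts exactly once; G steps down at that time
  snap <- tibble::tibble(history = 1L, species = c("H3O+", "OH-"),
                         x_nm = c(0, 0.3), y_nm = 0, z_nm = 0, t_ps = 1)
  set.seed(51)
  h <- run_irt(snap, tab_mixed, end_time = 1e6)
  t_rxn <- h$events$time_ps[h$events$type == "reaction"]
  gv <- g_value_series(h, E_dep = 100)
  ion <- gv[gv$species == "H3O+", ]
  expect_true(all(ion$G[ion$time_ps < t_rxn] == 1))
  expect_true(all(ion$G[ion$time_ps >= t_rxn] == 0))
})

test_that("the water material balance is conserved by the full scheme", {
  set.seed(52)
  snap <- gen_electron_spurs(spur_model(), 5)
  h <- run_chemistry(snap, tab_mixed, method = "irt", end_time = 1e5)
  gv <- g_value_series(h)
  expect_lt(material_balance(gv), 1e-12)
  prof <- material_balance_profile(gv)
  expect_true(all(prof$reducing > 0))
  expect_equal(prof$reducing, prof$oxidizing, tolerance = 1e-12)
})

test_that("method comparison reports relative differences vs the reference", {
  g <- tibble::tibble(time_ps = rep(c(1, 10), 2),
                      species = rep(c("OH", "eaq"), each = 2),
                      G = c(2, 1, 4, 3))
  same <- compare_methods(g, g)
  expect_true(all(same$rel_diff == 0))
  twice <- g; twice$G <- 2 * g$G
  cmp <- compare_methods(twice, g)
  expect_true(all(cmp$rel_diff == 1))
  bad <- g; bad$time_ps <- bad$time_ps * 2
  expect_error(compare_methods(bad, g), "grid")
})

test_that("direct damage needs a strict supra-threshold per-primary sum", {
  fib <- build_fiber(list(n_nucleosomes = 1L, n_linkers = 0L))
  sug <- fib$sinks[fib$sinks$element == "deoxyribose", ][1, ]
  at <- c(sug$x, sug$y, sug$z)
  dep <- function(h, e) tibble::tibble(history = h, x_nm = at[1],
                                       y_nm = at[2], z_nm = at[3],
                                       energy_eV = e)
  # exactly at threshold: no record (strict >)
  expect_equal(nrow(score_direct(dep(1L, 17.5), fib)), 0)
  # cumulative 10 + 8 from one primary: one record
  two <- dplyr::bind_rows(dep(1L, 10), dep(1L, 8))
  rec <- score_direct(two, fib)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$nucleotide_index, sug$nucleotide_index)
  expect_equal(rec$mechanism, "direct")
  # the same energies split across primaries never sum
  split <- dplyr::bind_rows(dep(1L, 10), dep(2L, 8))
  expect_equal(nrow(score_direct(split, fib)), 0)
  # deposits in the hydration shell count towards the backbone group
  shell_hit <- dep(1L, 20)
  shell_hit$x_nm <- shell_hit$x_nm + sug$radius + 0.08
  expect_equal(nrow(score_direct(shell_hit, fib)), 1)
  # far-away deposits belong to no group
  faraway <- dep(1L, 100); faraway$x_nm <- 1e3
  expect_equal(nrow(score_direct(faraway, fib)), 0)
})

test_that("damage yields bin per primary with a cumulative prefix sum", {
  grid <- log_time_grid(1, 1e4, 5)
  none <- damage_yield_series(
    tibble::tibble(time_ps = numeric(0)), n_primaries = 5, grid = grid)
  expect_true(all(none$cumulative == 0))
  rec <- tibble::tibble(time_ps = runif(10, 1, 1e4))
  ds <- damage_yield_series(rec, n_primaries = 5, grid = grid)
  expect_equal(ds$cumulative[nrow(ds)], 2.0)
  expect_equal(ds$cumulative, cumsum(ds$per_bin))
  # direct records enter at the grid origin
  ds2 <- damage_yield_series(rec, direct = tibble::tibble(id = 1:5),
                             n_primaries = 5, grid = grid)
  expect_equal(ds2$per_bin[1] - ds$per_bin[1], 1.0)
})

test_that("tidiers and autoplot expose the history", {
  set.seed(53)
  snap <- gen_electron_spurs(spur_model(), 2)
  h <- run_chemistry(snap, tab_mixed, method = "irt", end_time = 1e3)
  td <- tidy(h)
  expect_s3_class(td, "tbl_df")
  g <- glance(h)
  expect_equal(g$n_histories, 2)
  expect_equal(g$n_reactions, sum(h$events$type == "reaction"))
  gv <- g_value_series(h)
  expect_s3_class(autoplot(gv), "ggplot")
  ds <- damage_yield_series(tibble::tibble(time_ps = c(2, 3)), n_primaries = 2)
  expect_s3_class(autoplot(ds), "ggplot")
})
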