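test_that("water scheme builds with the printed rate constants and types", {
  expect_s3_class(tab_mixed, "reaction_table")
  expect_equal(nrow(tab_mixed), 9)
  expect_equal(sort(tab_mixed$kobs) / 1e10,
               sort(c(2.5, 1.55, 0.503, 1.1, 2.11, 11.3, 2.95, 0.55, 0.636)))
  expect_equal(sum(tab_mixed$rtype == "partially"), 5)
  # spin statistical factor marks the hydrated-electron / H-atom encounters
  expect_equal(sum(tab_mixed$spin), 3)
  spin_pairs <- tab_mixed[tab_mixed$spin, c("a", "b")]
  expect_true(all(unlist(spin_pairs) %in% c("H", "eaq")))
})

test_that("empty and malformed schemes are handled", {
  empty <- build_reaction_table(list(species = list(
    list(name = "A", charge = 0, D = 1e-9)), reactions = list()))
  expect_equal(nrow(empty), 0)
  expect_null(reaction_lookup(empty, "A", "A"))

  dup <- list(
    species = list(list(name = "H", charge = 0, D = 7e-9),
                   list(name = "OH", charge = 0, D = 2.8e-9)),
    reactions = list(
      list(reactants = list("H", "OH"), products = list(), kobs = 1.55e10,
           type = "partially", radius = 0.4),
      list(reactants = list("OH", "H"), products = list(), kobs = 1e10,
           type = "partially", radius = 0.4)))
  expect_error(build_reaction_table(dup), "duplicate")

  unk <- list(species = list(list(name = "H", charge = 0, D = 7e-9)),
              reactions = list(list(reactants = list("H", "X"),
                                    products = list(), kobs = 1e10,
                                    type = "totally")))
  expect_error(build_reaction_table(unk), "unknown species")

  neg <- list(species = list(list(name = "H", charge = 0, D = 7e-9)),
              reactions = list(list(reactants = list("H", "H"),
                                    products = list(), kobs = -1,
                                    type = "totally")))
  expect_error(build_reaction_table(neg), "positive")
})

test_that("pair lookup is symmetric and keyed on unordered names", {
  for (i in seq_len(nrow(tab_mixed))) {
    a <- tab_mixed$a[i]; b <- tab_mixed$b[i]
    expect_identical(reaction_lookup(tab_mixed, a, b),
                     reaction_lookup(tab_mixed, b, a))
  }
  expect_null(reaction_lookup(tab_mixed, "H2", "H2O2"))
})

test_that("derived kinetics follow the rate decomposition", {
  # totally controlled: R = kobs / (4 pi D)
  rx <- reaction_lookup(tab_mixed, "H", "eaq")
  D <- diffusion_to_internal(7.0e-9 + 4.9e-9)
  expect_equal(rx$R, kobs_to_internal(2.5e10) / (4 * pi * D), tolerance = 1e-12)
  # charged totally controlled: Reff direct from kobs
  rx <- reaction_lookup(tab_mixed, "H3O+", "OH-")
  D <- diffusion_to_internal(9.0e-9 + 5.0e-9)
  expect_equal(rx$Reff, kobs_to_internal(11.3e10) / (4 * pi * D),
               tolerance = 1e-12)
  expect_lt(rx$rc, 0)  # unlike charges attract
  # partially controlled recomposition 1/kobs = 1/kdif + 1/kact
  p <- tab_mixed[tab_mixed$rtype == "partially", ]
  k <- kobs_to_internal(p$kobs)
  expect_equal(1 / (1 / p$kdif + 1 / p$kact), k, tolerance = 1e-9)
  # and Reff recomposes kobs = 4 pi Reff D for every reaction
  expect_equal(4 * pi * tab_mixed$Reff * tab_mixed$D,
               kobs_to_internal(tab_mixed$kobs), tolerance = 1e-9)
})

test_that("a fixed contact radius below the transport limit is rejected", {
  bad <- list(
    species = list(list(name = "A", charge = 0, D = 2.5e-9),
                   list(name = "B", charge = 0, D = 2.5e-9)),
    reactions = list(list(reactants = list("A", "B"), products = list(),
                          kobs = 1e11, type = "partially", radius = 0.2)))
  expect_error(build_reaction_table(bad), "transport rate")
})

test_that("kinetics scale continuously to zero rate", {
  mk <- function(k) build_reaction_table(list(
    species = list(list(name = "A", charge = 0, D = 2.5e-9),
                   list(name = "B", charge = 0, D = 2.5e-9)),
    reactions = list(list(reactants = list("A", "B"), products = list(),
                          kobs = k, type = "totally"))))
  expect_lt(mk(1e4)$R, 1e-6)
  expect_gt(mk(1e10)$R, 0.1)
})

test_that("unit conversions round-trip and hit known magnitudes", {
  k <- c(1e7, 5.5e9, 1.13e11)
  expect_equal(kobs_from_internal(kobs_to_internal(k)), k, tolerance = 1e-12)
  # 1e10 1/M/s is about 0.0166 nm^3/ps
  expect_equal(kobs_to_internal(1e10), 0.0166054, tolerance = 1e-4)
  expect_equal(diffusion_to_internal(4.9e-9), 4.9e-3)
})

test_that("Onsager radius reproduces the water value and scaling law", {
  expect_equal(round(onsager_radius(298.15, 78.4), 2), 0.71)
  expect_equal(onsager_radius(300, 160) * 2, onsager_radius(300, 80),
               tolerance = 1e-12)
  # frozen arbitrary-precision evaluation at T = 300 K, eps_r = 80
  expect_equal(onsager_radius(300, 80), 0.69625394540953, tolerance = 1e-12)
})

test_that("radical-DNA rates derive per-target reaction radii", {
  dt <- dna_reaction_table(tab_mixed)
  expect_equal(nrow(dt), 14)
  # no guanine + H row, H2O2 never reacts with DNA
  expect_false(any(dt$target == "guanine" & dt$species == "H"))
  expect_false("H2O2" %in% dt$species)
  g <- dt[dt$target == "guanine" & dt$species == "OH", ]
  D_OH <- diffusion_to_internal(2.8e-9)
  expect_equal(g$R, kobs_to_internal(9.2e9) / (4 * pi * D_OH),
               tolerance = 1e-12)
})
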