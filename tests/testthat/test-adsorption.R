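geom50 <- particle_geometry(core_radius = 50, gyration_radius = 9)

test_that("geometry derives volume and interacting areas from the radii", {
  g <- particle_geometry(50, 9, brush_height_on_particle = 8)
  expect_equal(g$effective_radius, 58)
  expect_equal(g$binding_volume, pi * 58^2 * 9)
  expect_equal(g$area_particle, 2 * pi * 50 * 9)
  expect_equal(g$area_surface, pi * (50^2 - 41^2))
  expect_lt(g$area_surface, pi * 50^2)
  expect_error(particle_geometry(4, 9), "2 \\* core_radius")
})

test_that("molar concentrations convert to nm^-3 number densities", {
  expect_equal(molar_to_number_density(1), 0.602214076, tolerance = 1e-9)
  expect_equal(molar_to_number_density(0), 0)
  expect_equal(molar_to_number_density(1e-9), 6.02214076e-10,
               tolerance = 1e-9)
})

test_that("grafting densities map linearly to mean interacting counts", {
  cts <- counts_from_densities(0, 0, geom50)
  expect_equal(cts$n_ligands, 0)
  cts <- counts_from_densities(1 / geom50$area_particle, 2e-4, geom50)
  expect_equal(cts$n_ligands, 1, tolerance = 1e-12)
  expect_equal(counts_from_densities(0.02, 2e-4, geom50)$n_receptors,
               2 * counts_from_densities(0.01, 1e-4, geom50)$n_receptors)
})

test_that("total free energy is an order-free sum", {
  expect_equal(total_free_energy(-5, 2, 1), -2)
  expect_equal(total_free_energy(0, 0, 0), 0)
  expect_equal(total_free_energy(-3, 0.5, 0.25),
               total_free_energy(0.25, 0.5, -3))
})

test_that("bound-state weight follows the q = v_bind exp(-F) convention", {
  expect_equal(bound_partition_function(geom50, 0), geom50$binding_volume)
  expect_equal(bound_partition_function(geom50,
                                        log(geom50$binding_volume)), 1,
               tolerance = 1e-12)
  q1 <- bound_partition_function(geom50, -2)
  expect_equal(q1 / bound_partition_function(geom50, -1), exp(1),
               tolerance = 1e-12)
  # log form agrees and survives strongly attractive systems
  expect_equal(log_bound_weight(geom50, -2),
               log(bound_partition_function(geom50, -2)), tolerance = 1e-12)
  expect_true(is.finite(log_bound_weight(geom50, -2000)))
})

test_that("Langmuir probability is bounded, saturating and stable", {
  expect_equal(adsorption_probability(2, 0.5), 0.5)
  expect_equal(adsorption_probability(0, 5), 0)
  expect_gt(adsorption_probability(1, 1e12), 1 - 1e-10)
  expect_lt(adsorption_probability(1, 1e12), 1)
  # monotone in both arguments
  expect_gt(adsorption_probability(2, 1), adsorption_probability(1, 1))
  expect_gt(adsorption_probability(1, 2), adsorption_probability(1, 1))
  # log form equals the direct form
  expect_equal(adsorption_probability(3, log_q = log(0.2)),
               adsorption_probability(3, 0.2), tolerance = 1e-12)
})

test_that("Poisson-averaged theta matches explicit enumeration", {
  z <- molar_to_number_density(1e-9)
  spec <- averaging_spec(receptor = "poisson", ligand = "none",
                         truncation_mass = 1 - 1e-13)
  got <- adsorption_theta(3, 3, -9, geom50, z, scenario = "radial_exact",
                          rep_receptor = 0.5, averaging = spec)
  want <- oracle_theta_poisson(3, 50, 3, -9, geom50, z, rep_receptor = 0.5)
  expect_equal(got, want, tolerance = 1e-12)
  # mean-field scenario against the same enumeration
  got_mf <- adsorption_theta(3, 3, -9, geom50, z,
                             scenario = "radial_meanfield",
                             rep_receptor = 0.5, averaging = spec)
  want_mf <- oracle_theta_poisson(3, 50, 3, -9, geom50, z,
                                  rep_receptor = 0.5,
                                  scenario = "radial_meanfield")
  expect_equal(got_mf, want_mf, tolerance = 1e-12)
})

test_that("degenerate averaging reduces to the pointwise evaluation", {
  z <- molar_to_number_density(1e-9)
  got <- adsorption_theta(3, 7, -9, geom50, z, scenario = "radial_exact",
                          averaging = no_averaging())
  expect_equal(got, oracle_theta_fixed(3, 7, -9, geom50, z),
               tolerance = 1e-12)
  # all Poisson mass at zero receptors: bare translational balance
  got0 <- adsorption_theta(3, 0, -9, geom50, z, rep_receptor = 2,
                           averaging = averaging_spec(receptor = "poisson"))
  zv <- z * geom50$binding_volume
  expect_equal(got0, zv / (1 + zv), tolerance = 1e-12)
})

test_that("averaging is a convex combination over the count support", {
  z <- molar_to_number_density(1e-9)
  thetas <- vapply(0:40, function(k) {
    oracle_theta_fixed(3, k, -9, geom50, z, rep_receptor = 0.5)
  }, numeric(1))
  avg <- adsorption_theta(3, 5, -9, geom50, z, scenario = "radial_exact",
                          rep_receptor = 0.5,
                          averaging = averaging_spec(receptor = "poisson"))
  expect_gte(avg, min(thetas))
  expect_lte(avg, max(thetas))
  # Gaussian averaging stays within the same envelope and near Poisson
  avg_g <- adsorption_theta(3, 5, -9, geom50, z, scenario = "radial_exact",
                            rep_receptor = 0.5,
                            averaging = averaging_spec(receptor = "gaussian"))
  expect_gte(avg_g, min(thetas))
  expect_lte(avg_g, max(thetas))
  expect_lt(abs(avg_g - avg) / avg, 0.5)
})

test_that("theta stays in [0,1] and increases with activity", {
  acts <- molar_to_number_density(10^seq(-12, -6, length.out = 7))
  th <- vapply(acts, function(z) {
    adsorption_theta(3, 20, -9, geom50, z, rep_receptor = 0.3)
  }, numeric(1))
  expect_true(all(th >= 0 & th <= 1))
  expect_true(all(diff(th) > 0))
})

test_that("receptor sweeps are range-selective with repulsion, saturating without", {
  z <- molar_to_number_density(1e-9)
  grid <- 10^seq(0, 5, length.out = 41)
  avg <- averaging_spec(receptor = "poisson")
  sel <- adsorption_curve(grid, "n_receptors", n_ligands = 3,
                          bond_energy = -9, geometry = geom50, activity = z,
                          rep_receptor = 0.85, averaging = avg)
  i_peak <- which.max(sel$theta)
  expect_gt(i_peak, 1)
  expect_lt(i_peak, nrow(sel))
  expect_gt(sel$theta[i_peak], sel$theta[1])
  expect_gt(sel$theta[i_peak], sel$theta[nrow(sel)])
  expect_lt(sel$theta[nrow(sel)], 0.01 * sel$theta[i_peak])
  # control: no repulsion anywhere, classical multivalent saturation
  ctrl <- adsorption_curve(grid, "n_receptors", n_ligands = 3,
                           bond_energy = -9, geometry = geom50,
                           activity = z, averaging = avg)
  # non-decreasing up to Poisson-truncation noise (~1e-10 of the mass)
  expect_true(all(diff(ctrl$theta) >= -1e-9))
  expect_true(all(ctrl$theta >= 0 & ctrl$theta <= 1))
  expect_equal(max(ctrl$theta_normalized), 1)
})

test_that("size polydispersity averaging is a weighted mix over geometries", {
  z <- molar_to_number_density(1e-9)
  avg <- averaging_spec(receptor = "poisson", ligand = "poisson",
                        size_mean = 26.6, size_sd = 10.9)
  th <- adsorption_theta(5, 0.5, -9, geom50, z, rep_ligand = 0.4,
                         averaging = avg)
  expect_true(th >= 0 && th <= 1)
  # degenerate spread: identical to single-size evaluation at the mean
  avg0 <- averaging_spec(receptor = "poisson", ligand = "poisson",
                         size_mean = 26.6, size_sd = 0)
  geom_ref <- particle_geometry(26.6, 9)
  th0 <- adsorption_theta(5, 0.5, -9, geom_ref, z, rep_ligand = 0.4,
                          averaging = avg0)
  th_direct <- adsorption_theta(5, 0.5, -9, geom_ref, z, rep_ligand = 0.4,
                                averaging = averaging_spec(
                                  receptor = "poisson", ligand = "poisson"))
  expect_equal(th0, th_direct, tolerance = 1e-12)
})

test_that("compiled forward row agrees with the pure-R averaging layer", {
  model <- forward_model()
  for (case in list(c(0, 26.6, 10.9), c(0.5, 10, 4.7), c(5, 19.3, 10.1))) {
    sl <- 2e-2 * case[1]
    geom_ref <- particle_geometry(case[2], model$gyration_radius,
                                  model$brush_height)
    cts <- counts_from_densities(sl, 2e-4, geom_ref)
    want <- adsorption_theta(
      cts$n_ligands, cts$n_receptors, model$bond_energy, geom_ref,
      model$activity, scenario = "radial_meanfield",
      rep_receptor = model$rep_receptor, rep_ligand = model$rep_ligand,
      averaging = averaging_spec(receptor = "poisson", ligand = "poisson",
                                 size_mean = case[2], size_sd = case[3])
    )
    got <- rangebind:::theta_forward_row(sl, 2e-4, model, case[2], case[3])
    expect_equal(got, want, tolerance = 1e-7)
  }
})
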