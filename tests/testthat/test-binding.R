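test_that("exact radial free energy matches direct enumeration", {
  # 1+chi with chi=1 at unit valence
  expect_equal(f_att_exact(1, 1, 0), -log(2), tolerance = 1e-12)
  # enumerated configurations at 2x2, chi=1: 1 + 4 + 2 = 7
  expect_equal(f_att_exact(2, 2, 0), -log(7), tolerance = 1e-12)
  # empty sum when a species is absent
  expect_identical(f_att_exact(5, 0, -3), 0)
  expect_identical(f_att_exact(0, 7, 2), 0)
  # brute-force oracle over a small grid
  for (nl in c(1, 3, 6)) {
    for (nr in c(1, 4, 8)) {
      for (dg in c(-6, -2, 0, 1)) {
        expect_equal(f_att_exact(nl, nr, dg), oracle_exact_radial(nl, nr, dg),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("exact radial rejects fractional counts but survives large ones", {
  expect_error(f_att_exact(2.5, 3, -1), "integer")
  # log-domain accumulation: terms at these counts overflow doubles
  val <- f_att_exact(800, 1000, -12)
  expect_true(is.finite(val))
  expect_lt(val, -800 * 12)  # at least the fully-bonded term
})

test_that("indifferent free energy uses the full logarithm", {
  expect_equal(f_att_indifferent(3, 5, -2), -log(1 + 15 * exp(2)),
               tolerance = 1e-12)
  expect_identical(f_att_indifferent(0, 10, -5), 0)
  expect_equal(f_att_indifferent(1, 1, 0), -log(2), tolerance = 1e-12)
  # coincides with exact radial at unit valence for any bond energy
  for (dg in c(-8, -1, 2)) {
    expect_equal(f_att_indifferent(1, 1, dg), f_att_exact(1, 1, dg),
                 tolerance = 1e-12)
  }
})

test_that("free energies are symmetric under ligand-receptor exchange", {
  for (case in list(c(2, 9), c(5, 5), c(1, 12))) {
    for (dg in c(-10, -3, 0)) {
      expect_equal(f_att_exact(case[1], case[2], dg),
                   f_att_exact(case[2], case[1], dg), tolerance = 1e-12)
      expect_equal(f_att_indifferent(case[1], case[2], dg),
                   f_att_indifferent(case[2], case[1], dg),
                   tolerance = 1e-12)
    }
  }
})

test_that("radial binding is at least as strong as indifferent binding", {
  for (nl in 1:12) {
    for (nr in 1:12) {
      for (dg in c(-8, -3, 0, 2)) {
        expect_lte(f_att_exact(nl, nr, dg),
                   f_att_indifferent(nl, nr, dg) + 1e-12)
      }
    }
  }
})

test_that("free energies are non-increasing in counts and bond strength", {
  for (f in list(f_att_exact, f_att_indifferent)) {
    vals_nr <- vapply(1:15, function(nr) f(4, nr, -4), numeric(1))
    expect_true(all(diff(vals_nr) <= 1e-12))
    vals_nl <- vapply(1:15, function(nl) f(nl, 6, -4), numeric(1))
    expect_true(all(diff(vals_nl) <= 1e-12))
  }
  # stronger bond (more negative energy) lowers all formulations
  for (dg in list(c(-5, -4), c(-1, 0), c(0, 1))) {
    expect_lte(f_att_exact(4, 7, dg[1]), f_att_exact(4, 7, dg[2]))
    expect_lte(f_att_mean_field(4, 7, dg[1]), f_att_mean_field(4, 7, dg[2]))
  }
})

test_that("mean-field closed form solves the self-consistency equations", {
  # symmetric unit case: golden-ratio root
  s <- solve_bonds(1, 1, 0)
  expect_equal(s$p_ligand, (sqrt(5) - 1) / 2, tolerance = 1e-12)
  expect_equal(s$p_receptor, s$p_ligand, tolerance = 1e-12)
  # residual of the coupled equations, across regimes including the
  # cancellation-prone small n*chi corner
  for (nl in c(1e-6, 0.5, 3, 50, 2000)) {
    for (nr in c(1e-4, 1, 20, 500)) {
      for (dg in c(-12, -3, 0, 5, 15)) {
        s <- solve_bonds(nl, nr, dg)
        chi <- exp(-dg)
        r1 <- abs(s$p_ligand + nr * s$p_ligand * s$p_receptor * chi - 1)
        r2 <- abs(s$p_receptor + nl * s$p_ligand * s$p_receptor * chi - 1)
        expect_lt(max(r1, r2), 1e-10)
        expect_true(s$p_ligand > 0 && s$p_ligand <= 1)
        expect_true(s$p_receptor > 0 && s$p_receptor <= 1)
      }
    }
  }
  # degenerate counts: no bonds, zero free energy
  s0 <- solve_bonds(0, 10, -5)
  expect_identical(s0$p_ligand, 1)
  expect_identical(s0$f_att, 0)
})

test_that("mean-field tracks the exact radial sum and is never stronger", {
  # the saddle-point estimate underestimates the attraction magnitude; the
  # gap stays below 1 kT for moderate bonds, and at full bond saturation on
  # the balanced diagonal approaches the fluctuation term 0.5*ln(2*pi*n)
  for (nl in 1:20) {
    for (nr in 1:20) {
      for (dg in c(-15, -10, -5, -2, 0)) {
        gap <- f_att_mean_field(nl, nr, dg) - f_att_exact(nl, nr, dg)
        expect_gte(gap, -1e-9)
        expect_lte(gap, 0.5 * log(2 * pi * min(nl, nr)) + 0.1)
        if (dg >= -2 || abs(nl - nr) >= 4) expect_lt(gap, 1)
      }
    }
  }
  saturated <- f_att_mean_field(20, 20, -15) - f_att_exact(20, 20, -15)
  expect_equal(saturated, 0.5 * log(2 * pi * 20), tolerance = 0.01)
})

test_that("general bipartite solver agrees with the radial closed form", {
  for (case in list(c(2, 3, 0.5), c(1, 1, 1), c(4, 7, 20))) {
    net <- solve_bonds_network(
      ligand_neighbours = rep(list(seq_len(case[2])), case[1]),
      n_receptors = case[2], bond_strength = case[3]
    )
    closed <- solve_bonds(case[1], case[2], -log(case[3]))
    expect_equal(unique(round(net$p_ligand, 10)),
                 round(closed$p_ligand, 10))
    expect_equal(net$f_att, closed$f_att, tolerance = 1e-9)
  }
  # isolated ligand: certainly unbound
  net <- solve_bonds_network(list(1L, integer(0)), 1, 2)
  expect_equal(net$p_ligand[2], 1, tolerance = 1e-12)
  # single pair at chi = 1: golden-ratio root again
  net <- solve_bonds_network(list(1L), 1, 1)
  expect_equal(net$p_ligand, (sqrt(5) - 1) / 2, tolerance = 1e-10)
})

test_that("limiting expressions hold in their regimes", {
  expect_equal(f_att_limiting(100, 1, 0, "low_receptor"), -log(101),
               tolerance = 1e-12)
  # symmetric forms coincide when counts match
  expect_equal(f_att_limiting(6, 6, -3, "low_receptor"),
               f_att_limiting(6, 6, -3, "high_receptor"), tolerance = 1e-12)
  # high-receptor asymptote within 5% of the mean-field value
  lim <- f_att_limiting(3, 1e4, -9, "high_receptor")
  mf <- f_att_mean_field(3, 1e4, -9)
  expect_lt(abs(lim - mf) / abs(mf), 0.05)
  expect_error(f_att_limiting(3, 5, -1, "sideways"))
})

test_that("high-receptor growth is logarithmic: gap to the asymptote levels off", {
  nr_grid <- c(1e3, 1e4, 1e5, 1e6)
  gaps <- vapply(nr_grid, function(nr) {
    f_att_mean_field(5, nr, -6) - (-5 * log1p(nr * exp(6)))
  }, numeric(1))
  expect_lt(abs(gaps[4] - gaps[3]), abs(gaps[2] - gaps[1]) + 1e-6)
  expect_lt(abs(gaps[4] - gaps[3]), 0.01)
})

test_that("binding parameter container enforces its invariants", {
  p <- binding_params(3, 5, bond_energy = -9)
  expect_equal(p$bond_strength, exp(9), tolerance = 1e-12)
  p2 <- binding_params(3, 5, bond_strength = 2)
  expect_equal(p2$bond_energy, -log(2), tolerance = 1e-12)
  expect_error(binding_params(3, 5), "exactly one")
  expect_error(binding_params(3, 5, bond_energy = -1, bond_strength = 2))
  expect_error(binding_params(-1, 5, bond_energy = 0))
  expect_error(binding_params(3, 5, bond_strength = -2), "positive")
})
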