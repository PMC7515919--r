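# Independent brute-force oracles, kept deliberately naive: direct-summation
# partition function (no log-domain tricks) and a hand-rolled Poisson
# average assembled from package primitives rather than the averaging layer.

oracle_exact_radial <- function(n_ligands, n_receptors, bond_energy) {
  chi <- exp(-bond_energy)
  k <- 0:min(n_ligands, n_receptors)
  -log(sum(choose(n_ligands, k) * choose(n_receptors, k) *
             factorial(k) * chi^k))
}

# theta at fixed integer counts assembled step by step from first principles
oracle_theta_fixed <- function(n_ligands, n_receptors, bond_energy, geometry,
                               activity, rep_receptor = 0, rep_ligand = 0,
                               scenario = "radial_exact") {
  f_att <- switch(scenario,
    radial_exact = oracle_exact_radial(n_ligands, n_receptors, bond_energy),
    radial_meanfield = f_att_mean_field(n_ligands, n_receptors, bond_energy),
    indifferent = -log(1 + n_ligands * n_receptors * exp(-bond_energy))
  )
  f_tot <- f_att + rep_receptor * n_receptors + rep_ligand * n_ligands
  q <- geometry$binding_volume * exp(-f_tot)
  activity * q / (1 + activity * q)
}

# explicit Poisson average over receptor count, support 0..n_max
oracle_theta_poisson <- function(mean_receptors, n_max, n_ligands,
                                 bond_energy, geometry, activity,
                                 rep_receptor = 0, rep_ligand = 0,
                                 scenario = "radial_exact") {
  n <- 0:n_max
  w <- dpois(n, mean_receptors)
  sum(w * vapply(n, function(k) {
    oracle_theta_fixed(n_ligands, k, bond_energy, geometry, activity,
                       rep_receptor, rep_ligand, scenario)
  }, numeric(1)))
}
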