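# Canonical demonstration parameter sets for the receptor-number sweeps:
# a ligand-coated particle (R_np = 50 nm, N_L = 3, z = 1 nM) whose brush
# (N = 150, a = 0.35 nm) repels receptors with coefficient A from the
# curved-brush insertion formula. Sweeps run over the mean receptor count
# on a log grid with no count averaging (the trends are
# averaging-independent); the radial mean-field scenario is the default.

demo_repulsion <- function(area_per_chain = 1.95, receptor_volume = 110,
                            insertion_ratio = 0.9, ligand_length = NULL,
                            n_brush = 150, monomer = 0.35, core = 50) {
  if (!is.null(ligand_length)) {
    h0 <- brush_height(n_brush, monomer, area_per_chain)
    insertion_ratio <- min(ligand_length / h0, 1)
  }
  repulsion_coefficient(brush_model(
    area_per_chain = area_per_chain,
    degree_of_polymerisation = n_brush,
    monomer_size = monomer,
    core_radius = core,
    receptor_volume = receptor_volume,
    insertion_ratio = insertion_ratio
  ))
}

demo_curve <- function(bond_energy = -9, area_per_chain = 1.95,
                        receptor_volume = 110, insertion_ratio = 0.9,
                        ligand_length = NULL, binding_range = 1.5,
                        scenario = "radial_meanfield",
                        grid = 10^seq(0, 6, length.out = 61),
                        averaging = no_averaging()) {
  if (!is.null(ligand_length)) binding_range <- ligand_length
  a_coef <- demo_repulsion(area_per_chain, receptor_volume,
                            insertion_ratio, ligand_length)
  geom <- particle_geometry(core_radius = 50,
                            gyration_radius = binding_range)
  adsorption_curve(grid, sweep = "n_receptors", n_ligands = 3,
                   bond_energy = bond_energy, geometry = geom,
                   activity = molar_to_number_density(1e-9),
                   scenario = scenario, rep_receptor = a_coef,
                   averaging = averaging)
}
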