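#' Ligand-receptor binding parameters
#'
#' Bundles the counts and single-bond strength of a multivalent
#' ligand-receptor system. `bond_energy` is the free energy of a single
#' ligand-receptor bond in thermal units (beta * Delta G); the derived
#' `bond_strength` chi = exp(-bond_energy) is the dimensionless single-bond
#' strength (large chi = strong bond).
#'
#' @param n_ligands Number of ligands in the contact region (N_L, >= 0).
#' @param n_receptors Number of receptors in the contact region (N_R, >= 0).
#' @param bond_energy Single-bond free energy in units of kT. Mutually
#'   exclusive with `bond_strength`.
#' @param bond_strength Single-bond strength chi = exp(-bond_energy).
#'
#' @return An object of class `binding_params`: a list with fields
#'   `n_ligands`, `n_receptors`, `bond_energy`, `bond_strength`.
#' @examples
#' binding_params(3, 5, bond_energy = -9)
#' @export
binding_params <- function(n_ligands, n_receptors, bond_energy = NULL,
                           bond_strength = NULL) {
  if (is.null(bond_energy) == is.null(bond_strength)) {
    stop("supply exactly one of `bond_energy` or `bond_strength`", call. = FALSE)
  }
  if (is.null(bond_energy)) {
    if (!is.numeric(bond_strength) || bond_strength <= 0 || !is.finite(bond_strength)) {
      stop("`bond_strength` must be a positive finite number", call. = FALSE)
    }
    bond_energy <- -log(bond_strength)
  }
  if (!is.numeric(n_ligands) || !is.numeric(n_receptors) ||
      n_ligands < 0 || n_receptors < 0) {
    stop("counts must be non-negative numbers", call. = FALSE)
  }
  structure(
    list(
      n_ligands = as.numeric(n_ligands),
      n_receptors = as.numeric(n_receptors),
      bond_energy = as.numeric(bond_energy),
      bond_strength = exp(-as.numeric(bond_energy))
    ),
    class = "binding_params"
  )
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf(
    "<binding_params> N_L = %g, N_R = %g, beta*dG = %g (chi = %g)\n",
    x$n_ligands, x$n_receptors, x$bond_energy, x$bond_strength
  ))
  invisible(x)
}

assert_count_integer <- function(n, name) {
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n < 0 ||
      abs(n - round(n)) > 1e-9) {
    stop(sprintf("`%s` must be a single non-negative integer", name),
         call. = FALSE)
  }
  as.integer(round(n))
}

#' Exact radial binding free energy
#'
#' Attractive free energy of the radial binding scenario, in which every
#' ligand may bind every receptor subject to the valence limit (one bond per
#' binder per configuration). The bound-state weight sums the avidity
#' entropy over all bond numbers:
#' \deqn{\beta F_{att} = -\ln \sum_{N_\phi=0}^{\min(N_L,N_R)}
#'   \binom{N_L}{N_\phi}\binom{N_R}{N_\phi} N_\phi!\, \chi^{N_\phi}.}
#' This is the strongest (most negative) attraction any binding topology can
#' produce. The sum is accumulated in the log domain so counts of order 10^3
#' do not overflow.
#'
#' @param n_ligands,n_receptors Non-negative integer counts.
#' @param bond_energy Single-bond free energy in kT units.
#' @return The dimensionless free energy beta*F_att (<= 0; 0 when either
#'   count is 0).
#' @examples
#' f_att_exact(1, 1, 0)   # -log(2)
#' f_att_exact(2, 2, 0)   # -log(7): configurations 1 + 4 + 2
#' @seealso [f_att_indifferent()], [solve_bonds()] for the mean-field
#'   approximation that avoids the combinatorial sum.
#' @export
f_att_exact <- function(n_ligands, n_receptors, bond_energy) {
  nl <- assert_count_integer(n_ligands, "n_ligands")
  nr <- assert_count_integer(n_receptors, "n_receptors")
  stopifnot(is.numeric(bond_energy), length(bond_energy) == 1L,
            is.finite(bond_energy))
  if (nl == 0L || nr == 0L) return(0)
  k <- 0:min(nl, nr)
  log_terms <- lchoose(nl, k) + lchoose(nr, k) + lfactorial(k) -
    k * bond_energy
  m <- max(log_terms)
  out <- -(m + log(sum(exp(log_terms - m))))
  if (!is.finite(out)) {
    stop("exact radial sum overflowed despite log-domain accumulation",
         call. = FALSE)
  }
  out
}

#' Indifferent binding free energy
#'
#' Attractive free energy of the indifferent binding scenario, in which at
#' most one ligand-receptor bond exists at any time (the weakest multivalent
#' attraction): \deqn{\beta F_{att} = -\ln[1 + N_R N_L \chi].}
#' The full logarithm is used rather than its large-argument expansion, so
#' zero-count systems give exactly 0.
#'
#' @inheritParams f_att_exact
#' @return Dimensionless beta*F_att (<= 0).
#' @examples
#' f_att_indifferent(3, 5, -2)  # -log(1 + 15 * exp(2))
#' @export
f_att_indifferent <- function(n_ligands, n_receptors, bond_energy) {
  stopifnot(is.numeric(n_ligands), is.numeric(n_receptors),
            n_ligands >= 0, n_receptors >= 0,
            is.numeric(bond_energy), is.finite(bond_energy))
  -log1p(n_ligands * n_receptors * exp(-bond_energy))
}

#' Limiting radial free energy
#'
#' Asymptotic forms of the radial attraction when one species vastly
#' outnumbers the other. In the low-receptor regime (N_R << N_L) receptors
#' bind independently and \eqn{\beta F_{att} = -N_R \ln[1 + N_L \chi]}; in
#' the high-receptor regime the roles swap. In the high-receptor regime the
#' attraction grows only logarithmically with N_R, which is what allows a
#' linearly growing repulsion to overtake it and suppress binding.
#'
#' @inheritParams f_att_exact
#' @param regime `"low_receptor"` (N_R << N_L) or `"high_receptor"`.
#' @return Dimensionless beta*F_att.
#' @export
f_att_limiting <- function(n_ligands, n_receptors, bond_energy,
                           regime = c("low_receptor", "high_receptor")) {
  regime <- match.arg(regime)
  stopifnot(n_ligands > 0, n_receptors > 0)
  chi <- exp(-bond_energy)
  switch(regime,
    low_receptor  = -n_receptors * log1p(n_ligands * chi),
    high_receptor = -n_ligands * log1p(n_receptors * chi)
  )
}

mean_field_p <- function(n_self, n_other, chi) {
  # root of p + n_other * p * p_other * chi = 1 after eliminating p_other;
  # u >= 0 branch uses the conjugate form to avoid cancellation at small
  # n_self * chi
  u <- 1 + (n_other - n_self) * chi
  s <- sqrt(u^2 + 4 * n_self * chi)
  if (u >= 0) 2 / (u + s) else (-u + s) / (2 * n_self * chi)
}

#' Self-consistent mean-field bond probabilities (radial scenario)
#'
#' Solves the two coupled saddle-point equations of the radial binding
#' scenario, \eqn{p_L + N_R p_L p_R \chi = 1} and
#' \eqn{p_R + N_L p_L p_R \chi = 1}, via the closed-form root, and evaluates
#' the mean-field attraction
#' \deqn{\beta F_{att} = \sum_{i \in \{L,R\}} N_i\left(\ln p_i +
#'   \frac{1-p_i}{2}\right).}
#' `p_ligand` (`p_receptor`) is the probability that a ligand (receptor) is
#' unbound. The mean-field value tracks the exact radial sum to within a
#' fraction of kT while admitting real-valued (averaged) counts.
#'
#' @param n_ligands,n_receptors Non-negative real counts (fractional means
#'   allowed).
#' @inheritParams f_att_exact
#' @return An object of class `bond_solution`: list with `p_ligand`,
#'   `p_receptor`, `f_att`, `residual` (max absolute violation of the
#'   self-consistency equations).
#' @examples
#' solve_bonds(1, 1, 0)$p_ligand  # (sqrt(5) - 1) / 2
#' @export
solve_bonds <- function(n_ligands, n_receptors, bond_energy) {
  stopifnot(is.numeric(n_ligands), n_ligands >= 0,
            is.numeric(n_receptors), n_receptors >= 0,
            is.numeric(bond_energy), is.finite(bond_energy))
  chi <- exp(-bond_energy)
  if (n_ligands == 0 || n_receptors == 0) {
    return(new_bond_solution(1, 1, 0, 0))
  }
  p_l <- mean_field_p(n_ligands, n_receptors, chi)
  p_r <- mean_field_p(n_receptors, n_ligands, chi)
  f <- n_ligands * (log(p_l) + (1 - p_l) / 2) +
    n_receptors * (log(p_r) + (1 - p_r) / 2)
  res <- max(
    abs(p_l + n_receptors * p_l * p_r * chi - 1),
    abs(p_r + n_ligands * p_l * p_r * chi - 1)
  )
  if (res > 1e-8) {
    stop(sprintf("mean-field closed form failed self-consistency (residual %g)",
                 res), call. = FALSE)
  }
  new_bond_solution(p_l, p_r, f, res)
}

new_bond_solution <- function(p_ligand, p_receptor, f_att, residual) {
  structure(
    list(p_ligand = p_ligand, p_receptor = p_receptor,
         f_att = f_att, residual = residual),
    class = "bond_solution"
  )
}

#' @export
print.bond_solution <- function(x, ...) {
  cat(sprintf(
    "<bond_solution> p_L = %.6g, p_R = %.6g, beta*F_att = %.6g (residual %.2e)\n",
    x$p_ligand, x$p_receptor, x$f_att, x$residual
  ))
  invisible(x)
}

#' Mean-field bond probabilities on an arbitrary bipartite topology
#'
#' Solves the full set of coupled equations \eqn{p_i + \sum_j p_i p_j \chi
#' = 1} (one per individual ligand and receptor, the sum running over the
#' binding partners of i) by damped fixed-point iteration. On the complete
#' bipartite topology this reproduces [solve_bonds()]; it exists so
#' non-uniform neighbourhoods (partial overlap, isolated binders) can be
#' treated with the same free-energy functional.
#'
#' @param ligand_neighbours List of integer vectors: receptor indices each
#'   ligand can reach (empty vector = isolated ligand).
#' @param n_receptors Number of receptors.
#' @param bond_strength Single-bond strength chi > 0.
#' @param damping Fixed-point damping factor in (0, 1].
#' @param tol Convergence tolerance on the equation residual.
#' @param max_iter Iteration cap.
#' @return A `bond_solution` whose `p_ligand` / `p_receptor` are vectors
#'   (one entry per binder).
#' @export
solve_bonds_network <- function(ligand_neighbours, n_receptors, bond_strength,
                                damping = 0.5, tol = 1e-12, max_iter = 1e5) {
  stopifnot(is.list(ligand_neighbours), bond_strength > 0,
            n_receptors >= 0)
  nl <- length(ligand_neighbours)
  receptor_neighbours <- vector("list", n_receptors)
  for (i in seq_len(nl)) {
    for (j in ligand_neighbours[[i]]) {
      if (j < 1 || j > n_receptors) stop("receptor index out of range")
      receptor_neighbours[[j]] <- c(receptor_neighbours[[j]], i)
    }
  }
  p_l <- rep(1, nl)
  p_r <- rep(1, n_receptors)
  chi <- bond_strength
  for (iter in seq_len(max_iter)) {
    new_l <- vapply(seq_len(nl), function(i) {
      1 / (1 + chi * sum(p_r[ligand_neighbours[[i]]]))
    }, numeric(1))
    new_r <- vapply(seq_len(n_receptors), function(j) {
      1 / (1 + chi * sum(p_l[receptor_neighbours[[j]]]))
    }, numeric(1))
    p_l <- damping * new_l + (1 - damping) * p_l
    p_r <- damping * new_r + (1 - damping) * p_r
    res <- max(0, abs(p_l * (1 + chi * vapply(
      seq_len(nl), function(i) sum(p_r[ligand_neighbours[[i]]]), numeric(1)
    )) - 1), if (n_receptors > 0) abs(p_r * (1 + chi * vapply(
      seq_len(n_receptors), function(j) sum(p_l[receptor_neighbours[[j]]]),
      numeric(1)
    )) - 1))
    if (res < tol) {
      f <- sum(log(p_l) + (1 - p_l) / 2) + sum(log(p_r) + (1 - p_r) / 2)
      return(new_bond_solution(p_l, p_r, f, res))
    }
  }
  stop(sprintf("mean-field network solver did not converge in %d iterations (residual %g)",
               as.integer(max_iter), res), call. = FALSE)
}

#' Mean-field radial attraction (free energy only)
#'
#' Convenience wrapper around [solve_bonds()] returning just beta*F_att;
#' used heavily inside averaging loops.
#'
#' @inheritParams solve_bonds
#' @return Dimensionless beta*F_att.
#' @export
f_att_mean_field <- function(n_ligands, n_receptors, bond_energy) {
  solve_bonds(n_ligands, n_receptors, bond_energy)$f_att
}
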