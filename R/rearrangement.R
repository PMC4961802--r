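#' Adhesion parameters
#'
#' Intercellular adhesion is classified binarily from the effective active
#' VEGFR2 level: high VEGFR2 activity drives VE-cadherin endocytosis, which
#' weakens junctions, so a cell with `k_ADH * Vhat >= eta` is WEAKLY adhesive
#' and below the threshold STRONGLY adhesive. The ATP modifier `k_ADH < 1`
#' (reduced glycolytic ATP, hence reduced endocytosis) shifts cells towards
#' strong adhesion. Adhesion classes enter the contact energies of the
#' rearrangement Hamiltonian through the bonuses `alpha_strong > alpha_weak`:
#' stronger adhesion means lower interfacial energy, i.e. contacts that are
#' harder to break.
#'
#' @param eta Calibrated threshold on the effective active VEGFR2 level.
#' @param k_ADH ATP modifier applied multiplicatively to `Vhat` before
#'   thresholding (1 = wild type).
#' @param alpha_strong,alpha_weak Contact-energy bonuses of the two classes.
#' @return An object of class `adhesion_params`.
#' @export
adhesion_params <- function(eta = 60, k_ADH = 1, alpha_strong = 2.4,
                            alpha_weak = 0.8) {
  stopifnot(eta > 0, k_ADH >= 0, alpha_strong > alpha_weak, alpha_weak >= 0)
  structure(list(eta = eta, k_ADH = k_ADH,
                 alpha_strong = alpha_strong, alpha_weak = alpha_weak),
            class = "adhesion_params")
}

#' Adhesion class codes: strongly (`ADHESION_STRONG = 1`) or weakly
#' (`ADHESION_WEAK = 2`) adhesive.
#' @rdname adhesion_classes
#' @export
ADHESION_STRONG <- 1L
#' @rdname adhesion_classes
#' @export
ADHESION_WEAK <- 2L

#' Classify cellular adhesive strength
#'
#' Binary classification against the calibrated threshold `eta`:
#' `WEAK` iff `k_ADH * Vhat >= eta` (boundary inclusive), else `STRONG`.
#'
#' @param Vhat Effective active VEGFR2 level(s).
#' @param params An [adhesion_params()].
#' @param k_ADH Optional per-cell override of the ATP modifier (vector
#'   recycled against `Vhat`); defaults to the value in `params`.
#' @return Integer vector of `ADHESION_STRONG` / `ADHESION_WEAK`.
#' @export
classify_adhesion <- function(Vhat, params, k_ADH = params$k_ADH) {
  ifelse(k_ADH * Vhat >= params$eta, ADHESION_WEAK, ADHESION_STRONG)
}

#' Potts / rearrangement parameters
#'
#' Junctional dynamics follow a modified Cellular Potts model: per timestep,
#' `n_attempts` random boundary copy-proposals are evaluated, protrusive
#' proposals (a cell expanding into a neighbour or the medium) are gated by
#' the cortical-protrusion probability, and every attempted proposal is
#' accepted with Metropolis probability `min(1, exp(-dH / T))`. Tension
#' homeostasis bypasses the gate in two symmetric situations: a cell
#' squeezed more than `spread_slack` sites below its target area re-spreads
#' passively, and a neighbour bloated more than `spread_slack` sites above
#' target yields its excess passively. Only expansion beyond the resting
#' footprint against a resting neighbour requires the Notch-gated
#' protrusion machinery; the bypass is what lets a motile cell worm past
#' neighbours instead of jamming the sprout. During the initial
#' `stabilization` timesteps no movement occurs, letting the
#' salt-and-pepper signalling pattern form first.
#'
#' @param lambda_mig Migratory capacity scaling the protrusive attempt rate.
#' @param k_COR ATP modifier of the cortex effector in `[0, 1]` (1 = wild
#'   type).
#' @param N_ref Notch reference scale: the effective active Notch level at
#'   which cortical protrusion formation is maximally suppressed.
#' @param notch_cap Ceiling on the normalised Notch suppression (1 = Notch
#'   can suppress protrusions completely).
#' @param cor_lat,cor_back Polarization of cortical protrusions: multipliers
#'   on the protrusion probability for lateral and rearward expansion
#'   proposals (forward, up the VEGF gradient, carries the full
#'   probability). Polarized junctional protrusions are what let an active
#'   cell migrate tip-ward through the sprout.
#' @param T Metropolis temperature.
#' @param lambda_A Area-constraint stiffness.
#' @param J0 Baseline cell-cell contact energy (before adhesion bonuses).
#' @param J_cm Cell-medium contact energy.
#' @param gamma Cortex tension: energy per unit cell perimeter, the lattice
#'   representation of the Hookean actin cortex.
#' @param beta_fil Filopodial traction: energy bonus for a protrusive
#'   expansion into a site held by one of the cell's own filopodia (the body
#'   following its protrusion).
#' @param n_attempts Boundary-move attempts per timestep.
#' @param stabilization Timesteps with movement disabled at run start.
#' @param min_area Hard floor on territory size (guards against annihilation;
#'   the soft area constraint does the real work).
#' @param spread_slack Area deviation (sites) beyond which the tension
#'   homeostasis bypass of the protrusion gate engages.
#' @return An object of class `potts_params`.
#' @export
potts_params <- function(lambda_mig = 1.2, k_COR = 1, N_ref = 30,
                         notch_cap = 1, cor_lat = 0.4, cor_back = 0.15,
                         T = 1.2,
                         lambda_A = 0.15, J0 = 6, J_cm = 3.5, gamma = 0.4,
                         beta_fil = 7, n_attempts = 60L,
                         stabilization = 1000L, min_area = 10L,
                         spread_slack = 8L) {
  stopifnot(T > 0, n_attempts >= 1, lambda_mig >= 0, k_COR >= 0, k_COR <= 1,
            N_ref > 0, notch_cap >= 0, notch_cap <= 1,
            cor_lat >= 0, cor_lat <= 1, cor_back >= 0, cor_back <= 1,
            lambda_A >= 0, gamma >= 0, beta_fil >= 0,
            stabilization >= 0, min_area >= 1, spread_slack >= 0)
  structure(list(lambda_mig = lambda_mig, k_COR = k_COR, N_ref = N_ref,
                 notch_cap = notch_cap, cor_lat = cor_lat,
                 cor_back = cor_back, T = T,
                 lambda_A = lambda_A, J0 = J0, J_cm = J_cm, gamma = gamma,
                 beta_fil = beta_fil, n_attempts = as.integer(n_attempts),
                 stabilization = as.integer(stabilization),
                 min_area = as.integer(min_area),
                 spread_slack = as.integer(spread_slack)),
            class = "potts_params")
}

#' Cortical protrusion probability
#'
#' `p = min(1, k_COR * lambda_mig * (1 - Nhat_norm))`: Notch signalling
#' suppresses junctional cortex protrusions, so a cell's probability of
#' attempting a protrusive move falls linearly with its effective active
#' Notch level, normalised to `[0, 1]` by the fixed reference scale `N_ref`
#' at which suppression is complete. The absolute scale matters: a sprout in
#' which every cell carries high Notch (e.g. saturating VEGF) is uniformly
#' non-protrusive, not rescaled back to full motility.
#'
#' @param Nhat Effective active Notch level(s).
#' @param params A [potts_params()].
#' @param k_COR Optional per-cell override of the ATP modifier.
#' @return Protrusion probability in `[0, 1]`.
#' @export
cortical_protrusion_probability <- function(Nhat, params,
                                            k_COR = params$k_COR) {
  norm <- pmin(params$notch_cap, Nhat / params$N_ref)
  pmin(1, k_COR * params$lambda_mig * (1 - norm))
}

# Effective contact energy between two site owners (0 = medium), given the
# per-cell adhesion bonuses; the cortex-tension term gamma*perimeter is
# absorbed into the pairwise energies (each heterotypic edge adds gamma per
# cell endpoint).
contact_energy <- function(o1, o2, alpha, potts) {
  if (o1 == o2) return(0)
  if (o1 == 0L || o2 == 0L) return(potts$J_cm + potts$gamma)
  potts$J0 - alpha[o1] - alpha[o2] + 2 * potts$gamma
}

# Full Hamiltonian of a mesh; the reference energy for hamiltonian_delta().
mesh_hamiltonian <- function(owner, alpha, potts, target_area) {
  L <- nrow(owner); C <- ncol(owner)
  H <- 0
  for (r in seq_len(L)) {
    for (cc in seq_len(C)) {
      o <- owner[r, cc]
      if (r < L) H <- H + contact_energy(o, owner[r + 1L, cc], alpha, potts)
      H <- H + contact_energy(o, owner[r, cc %% C + 1L], alpha, potts)
    }
  }
  areas <- tabulate(owner[owner > 0L], nbins = length(alpha))
  H + potts$lambda_A * sum((areas - target_area)^2)
}

#' Energy change of a boundary copy-proposal
#'
#' Computes the change in the rearrangement Hamiltonian when the owner of
#' site `a` is copied onto the 4-adjacent site `b`:
#' `dH = d(contact energy) + d(area penalty) + d(cortex tension)`, with
#' heterotypic cell-cell contact energy `J0 - (alpha_i + alpha_j)` for the two
#' cells' adhesion classes, cell-medium contact `J_cm`, quadratic area
#' penalty `lambda_A * (|territory| - target_area)^2` and cortex tension
#' `gamma * perimeter`. A proposal that would disconnect the invaded cell's
#' territory is flagged as rejected (`valid = FALSE`) without evaluation.
#'
#' @param mesh A `sprout_mesh`.
#' @param a,b Length-2 vectors `c(x, y)`, 0-based site coordinates; `a` is the
#'   source whose owner expands into target `b`.
#' @param adhesion_class Integer vector of per-cell adhesion classes
#'   ([classify_adhesion()]).
#' @param adh An [adhesion_params()].
#' @param potts A [potts_params()].
#' @return List with elements `dH` (numeric; `0` for a null proposal) and
#'   `valid` (logical; `FALSE` when the proposal is rejected by the
#'   connectivity guard).
#' @export
hamiltonian_delta <- function(mesh, a, b, adhesion_class, adh, potts) {
  owner <- mesh$owner
  L <- nrow(owner); C <- ncol(owner)
  ra <- a[1] + 1L; ca <- a[2] + 1L
  rb <- b[1] + 1L; cb <- b[2] + 1L
  src <- owner[ra, ca]; tgt <- owner[rb, cb]
  if (src == tgt) return(list(dH = 0, valid = TRUE))
  alpha <- ifelse(adhesion_class == ADHESION_WEAK,
                  adh$alpha_weak, adh$alpha_strong)
  if (tgt > 0L) {
    trial <- owner
    trial[rb, cb] <- src
    if (!territory_connected(trial, tgt)) {
      return(list(dH = NA_real_, valid = FALSE))
    }
  }
  nb <- list(c(rb - 1L, cb), c(rb + 1L, cb),
             c(rb, cb %% C + 1L), c(rb, (cb - 2L + C) %% C + 1L))
  dH <- 0
  for (p in nb) {
    if (p[1] < 1L || p[1] > L) next
    o <- owner[p[1], p[2]]
    dH <- dH + contact_energy(src, o, alpha, potts) -
      contact_energy(tgt, o, alpha, potts)
  }
  A <- mesh$config$target_area
  if (tgt > 0L) {
    at <- sum(owner == tgt)
    dH <- dH + potts$lambda_A * ((at - 1 - A)^2 - (at - A)^2)
  }
  if (src > 0L) {
    as_ <- sum(owner == src)
    dH <- dH + potts$lambda_A * ((as_ + 1 - A)^2 - (as_ - A)^2)
  }
  list(dH = dH, valid = TRUE)
}
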