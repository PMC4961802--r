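#' Signalling parameters
#'
#' Parameters of the discrete-time VEGF -> VEGFR2 -> Dll4 -> Notch
#' lateral-inhibition dynamics. One timestep corresponds to 30 s of real time.
#'
#' The functional forms are deliberately simple and every gain is exposed:
#' per-site VEGFR2 activation saturates with local VEGF
#' (`min(1, m * vegf / (K_sat * su_fold))`), Dll4 production and VEGFR2
#' downregulation act after a shared expression delay `tau`, and "effective"
#' activity levels are trailing moving averages over `W` timesteps. Defaults
#' are fixed by the patterning calibration criterion: a resting 10-cell sprout
#' at normal VEGF must settle into a stable salt-and-pepper configuration with
#' exactly 3 active, pairwise non-adjacent cells within the 1,000-timestep
#' stabilization window.
#'
#' @param V_max Maximal VEGFR2 capacity per cell (arbitrary units).
#' @param K_sat VEGF saturation constant (same units as the VEGF field).
#' @param V0,g Intercept and axial slope of the linear VEGF gradient.
#' @param m VEGF multiplier (1 = normal; the elevated-VEGF scenarios use
#'   1.44, 2 and 10).
#' @param delta_D Dll4 production gain (Dll4 per unit active VEGFR2).
#' @param D_max Dll4 cap.
#' @param sigma Notch -> VEGFR2 inhibition gain.
#' @param tau Expression delay in timesteps (default 8, i.e. 4 min at 30
#'   s/timestep), shared by Dll4 production and VEGFR2 downregulation;
#'   bounded above by the requirement that the salt-and-pepper pattern
#'   establishes within the 1,000-timestep stabilization window.
#' @param rho_D,rho_R First-order expression kinetics: per-step relaxation
#'   rates with which Dll4 and VEGFR2 capacity approach their delayed
#'   production/downregulation targets (finite synthesis and turnover;
#'   instantaneous jumps after the delay would synchronize the whole sprout
#'   into relaxation oscillations and no salt-and-pepper pattern could form).
#' @param W Smoothing window for the effective activity levels, timesteps.
#' @param theta_D,theta_V Activation thresholds on Dll4 and active VEGFR2
#'   (inclusive). `theta_D` also gates Dll4 presentation: only cells whose
#'   Dll4 is at least `theta_D` productively activate Notch on their
#'   neighbours (sub-threshold ligand does not cluster into signalling
#'   competence), so a weakly activated cell cannot silence a niche it
#'   cannot itself fill.
#' @param R_floor Basal VEGFR2 capacity that Notch-driven downregulation
#'   cannot remove. At saturating VEGF even maximally inhibited cells then
#'   reach threshold activity, which homogenizes the sprout (every cell
#'   active) and destroys the salt-and-pepper alternation - the high-VEGF
#'   disorganization phenotype.
#' @param dapt Logical; `TRUE` removes Notch signalling between all cells
#'   (gamma-secretase inhibition).
#' @param su_fold VEGFR2-signalling reduction factor `f >= 1` (VEGFR2 kinase
#'   inhibition; `1` = untreated). See [apply_su5416()].
#' @param init_spread Relative half-width of the seed-determined initial
#'   heterogeneity of receptor capacities (breaks the symmetry between
#'   geometrically equivalent cells).
#' @return An object of class `signalling_params`.
#' @export
signalling_params <- function(V_max = 100, K_sat = 5, V0 = 0.5, g = 0.05,
                              m = 1, delta_D = 1.35, D_max = 120,
                              sigma = 12, tau = 8L, W = 60L,
                              rho_D = 0.12, rho_R = 0.12,
                              theta_D = 40, theta_V = 30, R_floor = 32,
                              dapt = FALSE, su_fold = 1,
                              init_spread = 0.05) {
  stopifnot(V_max > 0, K_sat > 0, m >= 0, delta_D >= 0, D_max >= 0,
            sigma >= 0, tau >= 1, W >= 1, theta_D > 0, theta_V > 0,
            rho_D > 0, rho_D <= 1, rho_R > 0, rho_R <= 1,
            R_floor >= 0, R_floor <= V_max,
            is.logical(dapt), su_fold >= 1,
            init_spread >= 0, init_spread < 1)
  structure(list(V_max = V_max, K_sat = K_sat, V0 = V0, g = g, m = m,
                 delta_D = delta_D, D_max = D_max, sigma = sigma,
                 tau = as.integer(tau), W = as.integer(W),
                 rho_D = rho_D, rho_R = rho_R,
                 theta_D = theta_D, theta_V = theta_V, R_floor = R_floor,
                 dapt = isTRUE(dapt), su_fold = su_fold,
                 init_spread = init_spread),
            class = "signalling_params")
}

#' VEGF concentration at an axial position
#'
#' Linear axial gradient `m * (V0 + g * x)`, clipped at zero. The gradient
#' rises towards the sprout front, so protrusions reaching ahead of the cell
#' body sense more VEGF.
#'
#' @param x Axial coordinate(s), site units, `x >= 0`.
#' @param params A [signalling_params()].
#' @return VEGF concentration(s), same length as `x`.
#' @examples
#' vegf_at(0:5, signalling_params())
#' @export
vegf_at <- function(x, params) {
  pmax(0, params$m * (params$V0 + params$g * x))
}

# Saturated per-site VEGFR2 activation input in [0, 1]. VEGFR2 kinase
# inhibition (su_fold) divides the input to the saturating cascade, so in the
# unsaturated regime activation is exactly 1/su_fold of untreated.
site_activation <- function(x, params) {
  pmin(1, vegf_at(x, params) / (params$K_sat * params$su_fold))
}

#' Model VEGFR2 kinase inhibition (SU5416)
#'
#' Returns a parameter set in which VEGFR2 signalling activity is reduced
#' `fold`-fold: per-site receptor activation is divided by `fold` upstream of
#' saturation, so unsaturated activation is exactly `1/fold` of untreated and
#' activation under inhibition is monotonically non-increasing in `fold`.
#'
#' @param params A [signalling_params()].
#' @param fold Reduction factor `f >= 1`.
#' @return The modified `signalling_params`.
#' @export
apply_su5416 <- function(params, fold) {
  if (!is.numeric(fold) || length(fold) != 1L || fold < 1) {
    stop("parameter error: `fold` must be a single number >= 1")
  }
  params$su_fold <- fold
  params
}

#' Initialise per-cell signalling state
#'
#' Receptor capacities start at `V_max` scaled by a small seed-determined
#' heterogeneity (uniform on `1 +/- init_spread`, clamped to `[0, V_max]`),
#' which breaks the symmetry between geometrically equivalent cells; all other
#' levels and the delay ring-buffers start at zero.
#'
#' @param n_cells Number of cells.
#' @param params A [signalling_params()].
#' @param seed Integer seed for the initial heterogeneity.
#' @param init_spread Relative half-width of the initial capacity spread.
#' @return An object of class `signalling_state`.
#' @export
init_signalling_state <- function(n_cells, params, seed = 1L,
                                  init_spread = params$init_spread) {
  u <- seeded_uniforms(n_cells, seed)
  R0 <- pmin(params$V_max, pmax(0, params$V_max * (1 - init_spread + 2 * init_spread * u)))
  structure(list(
    t = 0L,
    R = R0, R0 = R0,
    Vp = numeric(n_cells), D = numeric(n_cells), Np = numeric(n_cells),
    Vhat = numeric(n_cells), Nhat = numeric(n_cells),
    D_buf = matrix(0, params$tau, n_cells),
    R_buf = matrix(0, params$tau, n_cells),
    Vp_hist = matrix(0, params$W, n_cells),
    Np_hist = matrix(0, params$W, n_cells)),
    class = "signalling_state")
}

# Deterministic uniforms from the same 64-bit generator as the compiled core,
# so R- and C++-side initial states agree bitwise.
seeded_uniforms <- function(n, seed) {
  rng_uniforms_cpp(as.integer(n), as.integer(seed))
}

#' One timestep of the signalling dynamics
#'
#' Advances the lateral-inhibition network by one timestep on a fixed mesh:
#'
#' 1. per-memAgent activation `V'_m = (R_c / M_tot) * min(1, vegf(x) / (K_sat
#'    * f))`, summed over the cell's memAgents (filopodium sites included, the
#'    positive feedback of VEGF-sensing protrusions) to the active VEGFR2
#'    level `Vp_c`;
#' 2. delayed Dll4 production: the target `min(D_max, delta_D * Vp_c(t))`
#'    takes effect from `t + tau` and is approached with first-order
#'    kinetics at rate `rho_D`;
#' 3. Notch activation `Np_c` as the junction-length-weighted mean of the
#'    suprathreshold (`D >= theta_D`) Dll4 of neighbouring cells (zero under
#'    DAPT);
#' 4. delayed receptor downregulation: the target `clamp(V_max - sigma *
#'    Np_c(t), R_floor, V_max)` takes effect from `t + tau`, approached at
#'    rate `rho_R`;
#' 5. effective levels `Vhat`, `Nhat` as trailing `W`-step moving averages.
#'
#' This R implementation is the reference semantics for one update; the
#' simulation engine applies the identical update inside its compiled loop.
#'
#' @param mesh A `sprout_mesh`.
#' @param state A `signalling_state`.
#' @param params A [signalling_params()].
#' @return The advanced `signalling_state`.
#' @export
update_signalling <- function(mesh, state, params) {
  n <- mesh$config$n_cells
  tau <- params$tau
  W <- params$W
  slot <- state$t %% tau + 1L

  # (0) delayed production targets arriving this step, applied with
  # first-order relaxation
  if (state$t >= tau) {
    target_D <- state$D_buf[slot, ]
    target_R <- state$R_buf[slot, ]
  } else {
    target_D <- rep(0, n)
    target_R <- state$R0
  }
  state$D <- state$D + params$rho_D * (target_D - state$D)
  state$R <- state$R + params$rho_R * (target_R - state$R)

  # (1) active VEGFR2 from per-memAgent saturated activation
  sbar <- vapply(seq_len(n), function(cell) {
    ma <- memagents(mesh, cell)
    mean(site_activation(ma[, "x"], params))
  }, numeric(1))
  state$Vp <- state$R * sbar

  # (2) buffer Dll4 production for t + tau
  state$D_buf[slot, ] <- pmin(params$D_max, params$delta_D * state$Vp)

  # (3) Notch from neighbours' Dll4, weighted by shared junction fraction
  state$Np <- rep(0, n)
  if (!params$dapt) {
    ji <- junction_interfaces(mesh)
    if (nrow(ji)) {
      tot <- numeric(n)
      for (k in seq_len(nrow(ji))) {
        tot[ji$cell_i[k]] <- tot[ji$cell_i[k]] + ji$length[k]
        tot[ji$cell_j[k]] <- tot[ji$cell_j[k]] + ji$length[k]
      }
      Deff <- ifelse(state$D >= params$theta_D, state$D, 0)
      for (k in seq_len(nrow(ji))) {
        i <- ji$cell_i[k]; j <- ji$cell_j[k]; len <- ji$length[k]
        state$Np[i] <- state$Np[i] + Deff[j] * len / tot[i]
        state$Np[j] <- state$Np[j] + Deff[i] * len / tot[j]
      }
    }
  }

  # (4) buffer receptor downregulation for t + tau (basal capacity retained)
  state$R_buf[slot, ] <- pmin(params$V_max,
                              pmax(params$R_floor,
                                   params$V_max - params$sigma * state$Np))

  # (5) effective (windowed) levels
  wslot <- state$t %% W + 1L
  state$Vp_hist[wslot, ] <- state$Vp
  state$Np_hist[wslot, ] <- state$Np
  denom <- min(state$t + 1L, W)
  state$Vhat <- colSums(state$Vp_hist) / denom
  state$Nhat <- colSums(state$Np_hist) / denom

  state$t <- state$t + 1L
  state
}

#' Classify a cell as signalling-active
#'
#' A cell is signal-active when both its Dll4 level and its active VEGFR2
#' level meet their activation thresholds (boundary inclusive). The
#' classification depends only on the signalling levels, never on the actin
#' pool; the salt-and-pepper scorer layers its actin test on top of this one.
#'
#' @param D,Vp Dll4 and active VEGFR2 level(s).
#' @param theta_D,theta_V Activation thresholds.
#' @return Logical vector.
#' @export
classify_signal_active <- function(D, Vp, theta_D, theta_V) {
  D >= theta_D & Vp >= theta_V
}
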