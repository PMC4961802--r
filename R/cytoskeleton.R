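#' Filopodia / actin-pool parameters
#'
#' Each cell carries a fixed actin pool of `A_max` units; every filopodium
#' site holds one deployed unit, returned to the free pool on retraction
#' (actin is conserved: `deployed + free = A_max` at all times). Filopodia are
#' one-site-wide axial chains growing from front-edge membrane sites into
#' empty lattice sites ahead of the cell, the planar surrogate of filopodia
#' extending up the VEGF gradient. Filopodium sites count as memAgents and
#' carry a receptor share (amplifying VEGF sensing) but are not cell-body
#' occupancy for the tip rule.
#'
#' @param A_max Actin units per cell (1 unit per filopodium site).
#' @param C Strength of the VEGFR2-to-actin activation signal.
#' @param L_max Maximal filopodium length, sites.
#' @param p_ret Per-step spontaneous tip-retraction probability.
#' @param v_ret Deterministic retraction threshold on the tip's relative local
#'   activation (`R_c * sat(x) / V_max`); tips below it retract.
#' @param fil_over Multiplier on the extension probability when the next site
#'   is covered by another cell's body: filopodia are not volume-exclusive
#'   and may reach over neighbouring cells towards the VEGF gradient, but
#'   crawling along a cell surface is slower than extension into free space.
#' @param k_FIL ATP modifier of the filopodia effector, in `[0, 1]`
#'   (1 = wild type, smaller = less glycolytic ATP).
#' @return An object of class `filopodia_params`.
#' @export
filopodia_params <- function(A_max = 100L, C = 0.8, L_max = 20L,
                             p_ret = 0.05, v_ret = 0.1, fil_over = 1,
                             k_FIL = 1) {
  stopifnot(A_max >= 0, C >= 0, L_max >= 1,
            p_ret >= 0, p_ret <= 1, v_ret >= 0,
            fil_over >= 0, fil_over <= 1, k_FIL >= 0, k_FIL <= 1)
  structure(list(A_max = as.integer(A_max), C = C, L_max = as.integer(L_max),
                 p_ret = p_ret, v_ret = v_ret, fil_over = fil_over,
                 k_FIL = k_FIL),
            class = "filopodia_params")
}

#' Filopodia extension probability at a membrane site
#'
#' `p = min(1, k_FIL * C * V'_m / (V_max / M_tot))`: the probability that an
#' eligible membrane site (a front-edge body site or a filopodium tip)
#' extends, proportional to its active VEGFR2 relative to the per-memAgent
#' receptor capacity, scaled by the actin activation strength `C` and the ATP
#' modifier `k_FIL`. Since `V'_m = (R_c / M_tot) * sat(x)`, the ratio reduces
#' to `k_FIL * C * R_c * sat(x) / V_max`, independent of `M_tot`. A cell with
#' no free actin cannot extend (`p = 0`).
#'
#' @param Vp_m Per-memAgent active VEGFR2 `V'_m`.
#' @param M_tot Current memAgent count of the cell.
#' @param V_max Maximal VEGFR2 capacity.
#' @param params A [filopodia_params()].
#' @param free_actin Free actin units of the cell.
#' @return Extension probability in `[0, 1]`.
#' @examples
#' p <- filopodia_params(C = 0.1)
#' filopodia_extension_probability(100 / 60, 60, 100, p)  # k*C at full drive
#' @export
filopodia_extension_probability <- function(Vp_m, M_tot, V_max, params,
                                            free_actin = Inf) {
  if (free_actin < 1) return(0)
  min(1, params$k_FIL * params$C * Vp_m / (V_max / M_tot))
}

#' Filopodia statistics of a cell
#'
#' @param mesh A `sprout_mesh`.
#' @param cell Cell id.
#' @return Named numeric vector `c(count = , mean_length = )`; a cell without
#'   filopodia reports `c(0, 0)`.
#' @export
filopodia_stats <- function(mesh, cell) {
  fil <- mesh$filopodia
  cols <- which(fil$cell == cell & fil$hi >= fil$lo)
  if (!length(cols)) return(c(count = 0, mean_length = 0))
  lens <- fil$hi[cols] - fil$lo[cols] + 1L
  c(count = length(cols), mean_length = mean(lens))
}

#' Deployed actin of a cell
#'
#' Total actin units currently bound in the cell's filopodium sites.
#' @inheritParams filopodia_stats
#' @return Integer count of deployed units.
#' @export
deployed_actin <- function(mesh, cell) {
  fil <- mesh$filopodia
  cols <- which(fil$cell == cell & fil$hi >= fil$lo)
  if (!length(cols)) return(0L)
  sum(fil$hi[cols] - fil$lo[cols] + 1L)
}
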