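#' Registry of named in silico experiments
#'
#' Ready-made scenario configurations for the study's experiments:
#'
#' * `competition_1to1` / `competition_9to1`: mosaic knockdown:wild-type
#'   competition with the calibrated filopodia-effector constant.
#' * `control_1to1` / `control_9to1`: labelled isWT:isWT controls (all
#'   `k` = 1); expected tip fractions ~50% and ~90%.
#' * `dapt_mosaic`: 1:1 mosaic under Notch removal between all cells.
#' * `vegf_1.44x`, `vegf_2x`, `vegf_10x`: wild-type sprouts at elevated VEGF
#'   (choroidal-neovascularization-like and tumour-like levels).
#' * `vegf_2x_pi_fil`, `vegf_2x_pi_fil_adh`, `vegf_2x_pi_fil_cor`:
#'   pharmacological glycolysis inhibition (all cells modified) at 2x VEGF.
#' * `su5416_f1` .. `su5416_f6`: VEGFR2-signalling reduction sweep at
#'   10x VEGF.
#' * `combo_rescue_10x`: combined glycolysis (FIL/ADH) and sixfold VEGFR2
#'   blockade at 10x VEGF.
#'
#' @param k Calibrated effector constants, as [calibrated_k()].
#' @return Named list of [scenario_config()] objects.
#' @export
named_experiments <- function(k = calibrated_k()) {
  base <- scenario_config()
  with_m <- function(cfg, m) {
    cfg$signalling$m <- m
    cfg
  }
  pi_cfg <- function(mech, kval, m) {
    # non-mosaic pharmacological inhibition: the drug reaches every cell
    cfg <- with_m(base, m)
    cfg$ratio <- c(0L, 1L)
    cfg$effectors <- effector_config(mech, k_FIL = kval, k_COR = kval,
                                     k_ADH = kval, mode = "PHARMACOLOGICAL")
    cfg
  }
  out <- list()

  cfg <- base
  cfg$effectors <- effector_config("FIL", k_FIL = k$FIL)
  cfg$n_replicates <- 150L
  out$competition_1to1 <- cfg
  cfg$ratio <- c(9L, 1L)
  out$competition_9to1 <- cfg

  cfg <- base
  cfg$n_replicates <- 150L
  out$control_1to1 <- cfg
  cfg$ratio <- c(9L, 1L)
  out$control_9to1 <- cfg

  cfg <- base
  cfg$signalling$dapt <- TRUE
  cfg$effectors <- effector_config("FIL", k_FIL = k$FIL)
  out$dapt_mosaic <- cfg

  out$vegf_1.44x <- with_m(base, 1.44)
  out$vegf_1.44x$ratio <- c(0L, 1L)
  out$vegf_2x <- with_m(base, 2)
  out$vegf_2x$ratio <- c(0L, 1L)
  out$vegf_10x <- with_m(base, 10)
  out$vegf_10x$ratio <- c(0L, 1L)

  out$vegf_2x_pi_fil <- pi_cfg("FIL", k$FIL, 2)
  out$vegf_2x_pi_fil_adh <- pi_cfg(c("FIL", "ADH"), k$FIL_ADH, 2)
  out$vegf_2x_pi_fil_cor <- pi_cfg(c("FIL", "COR"), k$FIL_COR, 2)

  for (f in 1:6) {
    cfg <- with_m(base, 10)
    cfg$ratio <- c(0L, 1L)
    cfg$signalling <- apply_su5416(cfg$signalling, f)
    out[[paste0("su5416_f", f)]] <- cfg
  }

  cfg <- with_m(base, 10)
  cfg$ratio <- c(0L, 1L)
  cfg$signalling <- apply_su5416(cfg$signalling, 6)
  cfg$effectors <- effector_config(c("FIL", "ADH"), k_FIL = k$FIL_ADH,
                                   k_ADH = k$FIL_ADH,
                                   mode = "PHARMACOLOGICAL")
  out$combo_rescue_10x <- cfg

  out
}
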