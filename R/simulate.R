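#' Effector configuration
#'
#' Selects which ATP-dependent effectors a scenario modifies and how. The
#' three effectors are `FIL` (filopodia extension probability), `COR`
#' (junctional cortex protrusion probability) and `ADH` (binary intercellular
#' adhesion); the seven legal non-empty mechanisms are their non-empty
#' subsets. `k` values attached to effectors outside the mechanism are forced
#' to 1 (wild-type behaviour). In `MOSAIC_KD` mode the modifiers apply only
#' to knockdown-genotype cells; in `PHARMACOLOGICAL` mode (a blood-borne drug
#' reaching every cell indiscriminately) they apply to all cells.
#'
#' @param mechanism Character subset of `c("FIL", "COR", "ADH")`; empty for a
#'   pure wild-type scenario.
#' @param k_FIL,k_COR,k_ADH Effector modifiers (1 = wild type).
#' @param mode `"MOSAIC_KD"` or `"PHARMACOLOGICAL"`.
#' @return An object of class `effector_config`.
#' @export
effector_config <- function(mechanism = character(), k_FIL = 1, k_COR = 1,
                            k_ADH = 1, mode = c("MOSAIC_KD", "PHARMACOLOGICAL")) {
  mode <- match.arg(mode)
  mechanism <- toupper(as.character(mechanism))
  if (!all(mechanism %in% c("FIL", "COR", "ADH"))) {
    stop("configuration error: unknown effector in mechanism: ",
         paste(setdiff(mechanism, c("FIL", "COR", "ADH")), collapse = ", "))
  }
  if (!("FIL" %in% mechanism)) k_FIL <- 1
  if (!("COR" %in% mechanism)) k_COR <- 1
  if (!("ADH" %in% mechanism)) k_ADH <- 1
  stopifnot(k_FIL >= 0, k_COR >= 0, k_ADH >= 0)
  structure(list(mechanism = mechanism, k_FIL = k_FIL, k_COR = k_COR,
                 k_ADH = k_ADH, mode = mode),
            class = "effector_config")
}

#' Scenario configuration
#'
#' Bundles everything one simulation run needs: lattice geometry, signalling
#' parameters, filopodia and rearrangement parameters, the effector mechanism
#' and the mosaic genotype ratio. The default endpoint is 15,000 timesteps
#' (125 h at 30 s/timestep) with a 1,000-timestep movement-free stabilization
#' period; the alternative 24-h endpoint is 2,880 timesteps.
#'
#' @param lattice A [lattice_config()].
#' @param signalling A [signalling_params()].
#' @param filopodia A [filopodia_params()].
#' @param adhesion An [adhesion_params()].
#' @param potts A [potts_params()].
#' @param effectors An [effector_config()].
#' @param ratio Mosaic KD:WT genotype ratio, length-2 integer vector.
#' @param total_timesteps Run length in timesteps.
#' @param n_replicates Default replicate count for [run_replicates()].
#' @param base_seed Default first seed for replicate sets.
#' @param movement Disable to freeze all rearrangement (signalling-only run).
#' @param filopodia_on Disable to suppress all filopodia dynamics.
#' @param record_from First recorded timestep (defaults to the end of the
#'   stabilization period).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(lattice = lattice_config(),
                            signalling = signalling_params(),
                            filopodia = filopodia_params(),
                            adhesion = adhesion_params(),
                            potts = potts_params(),
                            effectors = effector_config(),
                            ratio = c(1L, 1L),
                            total_timesteps = 15000L,
                            n_replicates = 50L,
                            base_seed = 1L,
                            movement = TRUE,
                            filopodia_on = TRUE,
                            record_from = NULL) {
  total_timesteps <- as.integer(total_timesteps)
  if (total_timesteps <= potts$stabilization) {
    stop("configuration error: `total_timesteps` (", total_timesteps,
         ") must exceed the stabilization period (", potts$stabilization, ")")
  }
  if (is.null(record_from)) record_from <- potts$stabilization
  structure(list(lattice = lattice, signalling = signalling,
                 filopodia = filopodia, adhesion = adhesion, potts = potts,
                 effectors = effectors, ratio = as.integer(ratio),
                 total_timesteps = total_timesteps,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed),
                 movement = isTRUE(movement),
                 filopodia_on = isTRUE(filopodia_on),
                 record_from = as.integer(record_from)),
            class = "scenario_config")
}

#' Hours/timesteps conversion at 30 s per timestep
#'
#' @param hours Duration in hours.
#' @return Number of timesteps (`hours_to_timesteps`) or hours
#'   (`timesteps_to_hours`).
#' @examples
#' hours_to_timesteps(24)   # 2880
#' hours_to_timesteps(125)  # 15000
#' @export
hours_to_timesteps <- function(hours) as.integer(round(hours * 3600 / 30))

#' @rdname hours_to_timesteps
#' @param timesteps Number of timesteps.
#' @export
timesteps_to_hours <- function(timesteps) timesteps * 30 / 3600

# Per-cell effector modifiers from genotype + effector config.
percell_k <- function(effectors, genotype) {
  n <- length(genotype)
  if (effectors$mode == "PHARMACOLOGICAL") {
    list(k_FIL = rep(effectors$k_FIL, n),
         k_COR = rep(effectors$k_COR, n),
         k_ADH = rep(effectors$k_ADH, n))
  } else {
    kd <- genotype == GENOTYPE_KD
    list(k_FIL = ifelse(kd, effectors$k_FIL, 1),
         k_COR = ifelse(kd, effectors$k_COR, 1),
         k_ADH = ifelse(kd, effectors$k_ADH, 1))
  }
}

flat_params <- function(config) {
  s <- config$signalling; f <- config$filopodia
  a <- config$adhesion; p <- config$potts
  list(V_max = s$V_max, K_sat = s$K_sat, V0 = s$V0, g = s$g, m = s$m,
       delta_D = s$delta_D, D_max = s$D_max, sigma = s$sigma, tau = s$tau,
       W = s$W, rho_D = s$rho_D, rho_R = s$rho_R, R_floor = s$R_floor,
       theta_D = s$theta_D, theta_V = s$theta_V, dapt = s$dapt,
       su_fold = s$su_fold,
       A_max = f$A_max, L_max = f$L_max, C = f$C, p_ret = f$p_ret,
       v_ret = f$v_ret, fil_over = f$fil_over,
       eta = a$eta, alpha_strong = a$alpha_strong, alpha_weak = a$alpha_weak,
       lambda_mig = p$lambda_mig, N_ref = p$N_ref, notch_cap = p$notch_cap,
       cor_lat = p$cor_lat, cor_back = p$cor_back, T = p$T,
       lambda_A = p$lambda_A, J0 = p$J0,
       J_cm = p$J_cm, gamma = p$gamma, beta_fil = p$beta_fil,
       n_attempts = p$n_attempts, stabilization = p$stabilization,
       min_area = p$min_area, spread_slack = p$spread_slack,
       movement = config$movement, filopodia_on = config$filopodia_on,
       total_timesteps = config$total_timesteps,
       record_from = config$record_from,
       init_spread = s$init_spread)
}

#' Run one sprout simulation
#'
#' Builds the sprout, assigns genotypes by the seed, runs the stabilization
#' period (signalling and filopodia only, no cell movement) and then the full
#' dynamics to `total_timesteps`, recording the per-timestep, per-cell
#' trajectory from `record_from` onwards. The same `(config, seed)` pair
#' yields bit-identical output.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; determines the genotype placement and all
#'   stochastic dynamics.
#' @return An object of class `sprout_trajectory`: per-timestep matrices
#'   (`com_x`, `com_y`, `Vp`, `D`, `Np`, `R`, `Vhat`, `Nhat`, `adhesion`,
#'   `active`, `actin`, `filo_count`, `filo_len`), the per-timestep `tip`
#'   cell id, the packed pairwise `adjacency` matrix, the recorded
#'   `timestep` vector, per-cell `genotype`, the final mesh and the scenario
#'   `config`.
#' @export
run_scenario <- function(config, seed) {
  stopifnot(inherits(config, "scenario_config"))
  mesh <- build_sprout(config$lattice)
  mesh <- assign_genotypes(mesh, config$ratio, seed)
  k <- percell_k(config$effectors, mesh$genotype)
  res <- run_sprout_cpp(mesh$owner, mesh$genotype,
                        k$k_FIL, k$k_COR, k$k_ADH,
                        flat_params(config), config$lattice$target_area,
                        as.integer(seed))
  final_mesh <- mesh
  final_mesh$owner <- res$owner_final
  final_mesh$filopodia <- list(cell = res$chain_cell,
                               lo = res$chain_lo, hi = res$chain_hi)
  structure(list(
    timestep = seq.int(config$record_from, config$total_timesteps - 1L),
    genotype = mesh$genotype,
    com_x = res$com_x, com_y = res$com_y,
    Vp = res$Vp, D = res$D, Np = res$Np, R = res$R,
    Vhat = res$Vhat, Nhat = res$Nhat,
    adhesion = res$adhesion, active = res$active, actin = res$actin,
    filo_count = res$filo_count, filo_len = res$filo_len,
    tip = res$tip, adjacency = res$adjacency,
    final_mesh = final_mesh, final_Vp = res$Vp[nrow(res$Vp), ],
    move_stats = res$move_stats,
    areas = res$areas, seed = as.integer(seed), config = config),
    class = "sprout_trajectory")
}

#' @export
print.sprout_trajectory <- function(x, ...) {
  cat("<sprout_trajectory> ", length(x$genotype), " cells, timesteps ",
      x$timestep[1], "-", x$timestep[length(x$timestep)],
      ", tip at endpoint: cell ", x$tip[length(x$tip)], " (",
      c("WT", "KD")[x$genotype[x$tip[length(x$tip)]]], ")\n", sep = "")
  invisible(x)
}

#' Run a seeded replicate set
#'
#' Runs `n` simulations with seeds `base_seed .. base_seed + n - 1` (each
#' seed determines the initial genotype placement and the stochastic
#' dynamics) and aggregates the per-run summaries.
#'
#' @param config A [scenario_config()].
#' @param n Number of replicates (at least 50 for the in silico experiments;
#'   150 for tip-competition quantification).
#' @param base_seed First seed.
#' @param summarise Function applied to each trajectory; the default records
#'   the endpoint tip cell and its genotype, overtakes, migration, pattern
#'   scores and adhesion fractions.
#' @return An object of class `replicate_set`: list with `runs` (per-run
#'   summary data frame), `tip` ([tip_contribution()] on the endpoint tips),
#'   and the aggregate means of the scalar per-run metrics.
#' @export
run_replicates <- function(config, n = config$n_replicates,
                           base_seed = config$base_seed,
                           summarise = summarise_run) {
  stopifnot(n >= 1)
  seeds <- base_seed + seq_len(n) - 1L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    traj <- tryCatch(run_scenario(config, seeds[i]), error = function(e) {
      stop("replicate with seed ", seeds[i], " failed: ",
           conditionMessage(e))
    })
    rows[[i]] <- summarise(traj)
  }
  runs <- do.call(rbind, rows)
  tip <- tip_contribution(runs$tip_genotype, n_runs = n)
  agg <- colMeans(runs[vapply(runs, is.numeric, logical(1))])
  structure(list(runs = runs, tip = tip, aggregate = as.list(agg),
                 seeds = seeds, config = config),
            class = "replicate_set")
}

#' Single-run summary used by [run_replicates()]
#'
#' @param traj A `sprout_trajectory`.
#' @return One-row data frame of endpoint and whole-run metrics.
#' @export
summarise_run <- function(traj) {
  endpoint_tip <- traj$tip[length(traj$tip)]
  sp <- score_sp_patterns(traj)
  adh <- adhesion_strength_summary(traj)
  kd <- traj$genotype == GENOTYPE_KD
  fc <- colMeans(traj$filo_count)
  fl <- colSums(traj$filo_len) / pmax(1, colSums(traj$filo_count))
  mig <- migrated_distance(traj)
  data.frame(
    tip_cell = endpoint_tip,
    tip_genotype = traj$genotype[endpoint_tip],
    overtakes = count_overtakes(traj),
    avg_pattern_time = sp$avg_pattern_time,
    max_pattern_time = sp$max_pattern_time,
    avg_stabilizing_time = sp$avg_stabilizing_time,
    n_patterns = sp$n_patterns,
    strong_fraction = adh$overall_strong_fraction,
    strong_fraction_wt = adh$by_genotype["WT"],
    strong_fraction_kd = adh$by_genotype["KD"],
    filo_count_wt = mean(fc[!kd]),
    filo_count_kd = if (any(kd)) mean(fc[kd]) else NA_real_,
    filo_len_wt = mean(fl[!kd]),
    filo_len_kd = if (any(kd)) mean(fl[kd]) else NA_real_,
    migration_wt = mean(mig[!kd]),
    migration_kd = if (any(kd)) mean(mig[kd]) else NA_real_,
    row.names = NULL)
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("<replicate_set> ", nrow(x$runs), " runs\n", sep = "")
  cat("  KD tip fraction: ", round(100 * x$tip$fraction["KD"], 1), "% (",
      x$tip$counts["KD"], "/", x$tip$n_runs, ")\n", sep = "")
  cat("  mean overtakes: ", round(x$aggregate$overtakes, 2),
      "; mean S&P pattern time: ", round(x$aggregate$avg_pattern_time, 1),
      " ts\n", sep = "")
  invisible(x)
}
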