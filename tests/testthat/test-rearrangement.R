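test_that("adhesion classification is binary with an inclusive threshold", {
  ap <- adhesion_params(eta = 60)
  expect_equal(classify_adhesion(0, ap), ADHESION_STRONG)
  expect_equal(classify_adhesion(60, ap), ADHESION_WEAK)   # boundary -> weak
  expect_equal(classify_adhesion(59.999, ap), ADHESION_STRONG)
  out <- classify_adhesion(seq(0, 120, by = 5), ap)
  expect_true(all(out %in% c(ADHESION_STRONG, ADHESION_WEAK)))
  # reduced ATP (k_ADH < 1) shifts cells towards strong adhesion
  expect_equal(classify_adhesion(80, ap, k_ADH = 0.5), ADHESION_STRONG)
  expect_equal(classify_adhesion(80, ap, k_ADH = 1), ADHESION_WEAK)
})

test_that("cortical protrusion probability is Notch-suppressed", {
  pp <- potts_params(lambda_mig = 1.2, N_ref = 30)
  expect_equal(cortical_protrusion_probability(0, pp, k_COR = 0), 0)
  expect_equal(cortical_protrusion_probability(30, pp), 0)  # fully inhibited
  expect_equal(cortical_protrusion_probability(0, pp), 1)   # clipped at 1
  p_half <- cortical_protrusion_probability(15, pp)
  expect_equal(p_half, min(1, 1.2 * 0.5))
  # monotone decreasing in Nhat
  p_seq <- cortical_protrusion_probability(seq(0, 40, by = 5), pp)
  expect_true(all(diff(p_seq) <= 0))
})

test_that("hamiltonian delta matches a brute-force full Hamiltonian", {
  pp <- potts_params()
  ap <- adhesion_params()
  alpha_of <- function(class) ifelse(class == ADHESION_WEAK,
                                     ap$alpha_weak, ap$alpha_strong)
  set.seed(99)
  n_checked <- 0L
  for (i in 1:40) {
    owner <- random_two_cell_owner()
    mesh <- mesh_from_owner(owner, 2)
    target_area <- mesh$config$target_area
    classes <- sample(c(ADHESION_STRONG, ADHESION_WEAK), 2, replace = TRUE)
    alpha <- alpha_of(classes)
    # random boundary proposal
    cand <- which(owner > 0L, arr.ind = TRUE)
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      r <- cand[j, 1]; cc <- cand[j, 2]
      dirs <- list(c(-1, 0), c(1, 0), c(0, 1), c(0, -1))
      d <- dirs[[sample.int(4, 1)]]
      rb <- r + d[1]; cb <- (cc - 1 + d[2]) %% ncol(owner) + 1
      if (rb < 1 || rb > nrow(owner)) next
      if (owner[rb, cb] == owner[r, cc]) next
      res <- hamiltonian_delta(mesh, a = c(r - 1, cc - 1), b = c(rb - 1, cb - 1),
                               adhesion_class = classes, adh = ap, potts = pp)
      res_cpp <- delta_h_cpp(owner, c(r - 1L, cc - 1L), c(rb - 1L, cb - 1L),
                             alpha, pp, target_area, 1L)
      if (!res$valid) {
        expect_false(res_cpp$valid)
        break
      }
      H0 <- oracle_hamiltonian(owner, alpha, pp$J0, pp$J_cm, pp$gamma,
                               pp$lambda_A, target_area)
      owner2 <- owner
      owner2[rb, cb] <- owner[r, cc]
      H1 <- oracle_hamiltonian(owner2, alpha, pp$J0, pp$J_cm, pp$gamma,
                               pp$lambda_A, target_area)
      expect_equal(res$dH, H1 - H0, tolerance = 1e-12)
      expect_equal(res_cpp$dH, H1 - H0, tolerance = 1e-12)
      n_checked <- n_checked + 1L
      break
    }
  }
  expect_gte(n_checked, 25L)
})

test_that("a null proposal has zero energy and reverses antisymmetrically", {
  mesh <- two_cell_mesh()
  pp <- potts_params(); ap <- adhesion_params()
  classes <- c(ADHESION_STRONG, ADHESION_WEAK)
  # null: both sites owned by the same cell
  expect_equal(hamiltonian_delta(mesh, c(0, 0), c(1, 0), classes, ap, pp)$dH, 0)
  # forward then exact reverse move sum to zero
  fwd <- hamiltonian_delta(mesh, c(5, 4), c(5, 5), classes, ap, pp)
  expect_true(fwd$valid)
  mesh2 <- mesh
  mesh2$owner[6, 6] <- mesh$owner[6, 5]
  rev <- hamiltonian_delta(mesh2, c(5, 6), c(5, 5), classes, ap, pp)
  expect_equal(fwd$dH + rev$dH, 0, tolerance = 1e-12)
})

test_that("the connectivity guard rejects territory-splitting proposals", {
  # cell 2 is a 1-wide bridge; invading its middle would split it
  owner <- matrix(0L, 6, 6)
  owner[2, 2:4] <- 2L
  owner[3, 2:4] <- 1L
  mesh <- mesh_from_owner(owner, 2)
  res <- hamiltonian_delta(mesh, a = c(2, 2), b = c(1, 2),
                           adhesion_class = c(1L, 1L),
                           adh = adhesion_params(), potts = potts_params())
  expect_false(res$valid)
  expect_true(is.na(res$dH))
})

test_that("Metropolis acceptance frequency follows exp(-dH/T)", {
  T <- 1.2
  for (dH in c(0.5, 1.5, 3)) {
    acc <- metropolis_accept_cpp(dH, T, 10000L, 77L)
    p <- exp(-dH / T)
    expect_lt(abs(acc / 10000 - p), 3.5 * sqrt(p * (1 - p) / 10000))
  }
  expect_equal(metropolis_accept_cpp(-1, T, 1000L, 1L), 1000L)
})

test_that("ownership stays a partition and territories stay connected", {
  for (s in 1:4) {
    traj <- run_scenario(short_config(4000L), seed = s)
    expect_true(validate_mesh(traj$final_mesh))
    counts <- tabulate(traj$final_mesh$owner[traj$final_mesh$owner > 0L], 10)
    expect_equal(sum(counts), sum(traj$areas))
  }
})

test_that("territory areas stay near the target over long runs", {
  cfg <- scenario_config()
  for (s in 1:3) {
    traj <- run_scenario(cfg, seed = s)
    expect_true(all(traj$areas >= 0.6 * cfg$lattice$target_area))
    expect_true(all(traj$areas <= 1.4 * cfg$lattice$target_area))
  }
})

test_that("weakly adhesive cells are the motile ones", {
  dx_by_class <- c(STRONG = 0, WEAK = 0); n <- c(STRONG = 0, WEAK = 0)
  for (s in 1:6) {
    traj <- run_scenario(short_config(6000L), seed = s)
    step_dx <- abs(diff(traj$com_x))
    weak <- traj$adhesion[-1, ] == ADHESION_WEAK
    dx_by_class["WEAK"] <- dx_by_class["WEAK"] + sum(step_dx[weak])
    dx_by_class["STRONG"] <- dx_by_class["STRONG"] + sum(step_dx[!weak])
    n["WEAK"] <- n["WEAK"] + sum(weak)
    n["STRONG"] <- n["STRONG"] + sum(!weak)
  }
  expect_gt(dx_by_class["WEAK"] / n["WEAK"],
            dx_by_class["STRONG"] / n["STRONG"])
})

test_that("without the cortex effector the sprout front never advances", {
  cfg <- short_config(4000L, effectors = effector_config(
    "COR", k_COR = 0, mode = "PHARMACOLOGICAL"))
  for (s in 1:2) {
    traj <- run_scenario(cfg, seed = s)
    front <- apply(traj$com_x, 1, max)
    # no protrusive expansion: the front can only recede or hold
    expect_lte(max(front), front[1] + 0.5)
  }
})
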