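#' Identify the tip cell of a sprout snapshot
#'
#' Applies the front-grid-site rule: the `circumference` sites of the
#' front-most occupied axial row form the tip-scoring window; the cell with
#' the most cell-body memAgents among those sites is the tip cell. An exact
#' tie is broken by the higher active VEGFR2 level, a double tie by the lower
#' cell id. Filopodium sites are excluded: the tip is decided by the relative
#' position of cell bodies, not cytoskeletal protrusions. Should a front row
#' contain no cell-body site the rule walks back one axial row and retries.
#'
#' @param mesh A `sprout_mesh`.
#' @param Vp Per-cell active VEGFR2 levels used for the tie-break.
#' @return The tip cell id.
#' @export
identify_tip <- function(mesh, Vp) {
  own <- mesh$owner
  n <- mesh$config$n_cells
  rows <- which(apply(own > 0L, 1, any))
  if (!length(rows)) stop("invariant violation: empty sprout")
  r <- max(rows)
  repeat {
    counts <- tabulate(own[r, own[r, ] > 0L], nbins = n)
    if (any(counts > 0L)) break
    r <- r - 1L  # walk back one axial row
  }
  best <- which(counts == max(counts))
  if (length(best) > 1L) {
    best <- best[Vp[best] == max(Vp[best])]
  }
  min(best)
}

#' Tip-cell contribution over a replicate set
#'
#' Counts, per genotype, in how many replicate runs a cell of that genotype
#' occupied the tip at the analysis endpoint, mirroring the manual in vitro
#' spheroid scoring of red/green tip cells.
#'
#' @param tip_genotype Integer vector of per-run endpoint tip genotypes
#'   (`GENOTYPE_WT` / `GENOTYPE_KD`).
#' @param n_runs Number of runs (defaults to `length(tip_genotype)`).
#' @return List with `counts` and `fraction` (named `WT`, `KD`) and `n_runs`.
#' @export
tip_contribution <- function(tip_genotype, n_runs = length(tip_genotype)) {
  if (n_runs == 0L) stop("tip_contribution requires at least one run")
  counts <- c(WT = sum(tip_genotype == GENOTYPE_WT),
              KD = sum(tip_genotype == GENOTYPE_KD))
  list(counts = counts, fraction = counts / n_runs, n_runs = n_runs)
}

#' Count cell-cell overtakes in a trajectory
#'
#' An overtake is a persistent inversion of the axial centre-of-mass rank
#' order of a cell pair: the pair's `COM_x` ordering flips and the new
#' ordering persists for at least `debounce` consecutive timesteps.
#' Transient flips reverted within the debounce window are not counted.
#'
#' @param traj A `sprout_trajectory`.
#' @param debounce Persistence requirement in timesteps (10 = 5 min).
#' @return Total number of overtake events across all cell pairs.
#' @export
count_overtakes <- function(traj, debounce = 10L) {
  cx <- traj$com_x
  n <- ncol(cx)
  total <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sign(cx[, i] - cx[, j])
      # ties inherit the preceding ordering (leading ties are dropped)
      if (any(s == 0)) {
        nz <- which(s != 0)
        if (!length(nz)) next
        s <- s[nz[1]:length(s)]
        s <- s[cummax(ifelse(s != 0, seq_along(s), 0L))]
      }
      r <- rle(as.vector(s))
      keep <- r$lengths >= debounce
      confirmed <- r$values[keep]
      if (length(confirmed) > 1L) {
        total <- total + sum(diff(confirmed) != 0)
      }
    }
  }
  total
}

#' Total migrated axial distance per cell
#'
#' The absolute difference in a cell's `COM_x` between two subsequent
#' timesteps, accumulated over the analysed window; purely circumferential
#' motion does not contribute.
#'
#' @param traj A `sprout_trajectory`.
#' @param cell Optional cell id; all cells when omitted.
#' @return Named numeric vector of migrated distances in site units.
#' @export
migrated_distance <- function(traj, cell = NULL) {
  cx <- traj$com_x
  out <- colSums(abs(diff(cx)))
  names(out) <- seq_len(ncol(cx))
  if (is.null(cell)) out else out[[cell]]
}

#' Time at tip by initial axial rank
#'
#' Links tip occupancy to each cell's starting position: cells are ranked by
#' their initial `COM_x` (rank 1 = front-most at the first recorded
#' timestep), and for each rank the total time its cell held the tip and
#' whether it ever reached the tip are reported. Occupancy times sum to the
#' analysed window length.
#'
#' @param traj A `sprout_trajectory`.
#' @return Data frame with columns `initial_rank`, `cell`, `time_at_tip`,
#'   `reached_tip`.
#' @export
time_at_tip_by_initial_rank <- function(traj) {
  n <- ncol(traj$com_x)
  ord <- order(traj$com_x[1, ], decreasing = TRUE)  # rank 1 = front
  occ <- tabulate(traj$tip, nbins = n)
  data.frame(initial_rank = seq_len(n),
             cell = ord,
             time_at_tip = occ[ord],
             reached_tip = occ[ord] > 0L)
}

#' Adhesive-strength summary of a trajectory
#'
#' Fraction of cell-timesteps classified strongly adhesive, per genotype and
#' overall, plus the mean number of strongly adhesive cells per timestep;
#' links the binary adhesion classification to cell genotype for comparisons
#' across conditions.
#'
#' @param traj A `sprout_trajectory`.
#' @return List with `by_genotype` (named fractions), the
#'   `overall_strong_fraction`, and `mean_strong_per_timestep`.
#' @export
adhesion_strength_summary <- function(traj) {
  strong <- traj$adhesion == ADHESION_STRONG
  kd <- traj$genotype == GENOTYPE_KD
  by_g <- c(WT = if (any(!kd)) mean(strong[, !kd, drop = FALSE]) else NA_real_,
            KD = if (any(kd)) mean(strong[, kd, drop = FALSE]) else NA_real_)
  list(by_genotype = by_g,
       overall_strong_fraction = mean(strong),
       mean_strong_per_timestep = mean(rowSums(strong)))
}

#' Score salt-and-pepper patterns
#'
#' At every analysed timestep each cell is tested for three properties: its
#' Dll4 level, its active VEGFR2 level (together the signal-activity
#' classification recorded in the trajectory) and the status of its actin
#' pool. Signal-active cells with at least `theta_A` deployed actin units are
#' "sprout active"; signal-active cells below the actin threshold are
#' "stunted active". A timestep carries a stable salt-and-pepper pattern when
#' the number of active cells (sprout active + stunted active) equals
#' `n_ideal` and no two active cells are adjacent. Contiguous stable runs
#' give the pattern times; the intermittent gaps preceding each newly formed
#' pattern give the stabilizing times (the stabilizing counter does not run
#' during a stable pattern and resets when a new pattern forms).
#'
#' @param traj A `sprout_trajectory` (simulated or fixture).
#' @param theta_A Actin threshold, deployed units.
#' @param n_ideal Active-cell count of an ideal pattern (3 for the 10-cell
#'   sprout).
#' @return An object of class `sp_stats`: `avg_pattern_time`,
#'   `max_pattern_time`, `avg_stabilizing_time`, `n_patterns`,
#'   `stable` (per-timestep logical), `n_active` (per-timestep count),
#'   `n_sprout_active`, `n_stunted_active`.
#' @export
score_sp_patterns <- function(traj, theta_A = 1L, n_ideal = 3L) {
  if (n_ideal <= 0L) stop("parameter error: `n_ideal` must be positive")
  active <- traj$active > 0L
  sprout_active <- active & traj$actin >= theta_A
  stunted <- active & traj$actin < theta_A
  n_active <- rowSums(active)
  T_len <- nrow(active)
  n <- ncol(active)
  pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(2:n, function(i) seq.int(i, n)))
  # adjacency of two active cells at the same timestep
  act_i <- active[, pair_i, drop = FALSE]
  act_j <- active[, pair_j, drop = FALSE]
  adjacent_actives <- rowSums(traj$adjacency & act_i & act_j) > 0L
  stable <- n_active == n_ideal & !adjacent_actives
  r <- rle(as.vector(stable))
  pat <- r$lengths[r$values]
  gaps <- integer(0)
  if (length(r$lengths) > 1L) {
    followed <- which(!r$values & seq_along(r$values) < length(r$values))
    gaps <- r$lengths[followed]
  }
  structure(list(
    avg_pattern_time = if (length(pat)) mean(pat) else 0,
    max_pattern_time = if (length(pat)) max(pat) else 0,
    avg_stabilizing_time = if (!length(pat)) T_len
                           else if (length(gaps)) mean(gaps) else 0,
    n_patterns = length(pat),
    stable = stable,
    n_active = n_active,
    n_sprout_active = rowSums(sprout_active),
    n_stunted_active = rowSums(stunted)),
    class = "sp_stats")
}

#' @export
print.sp_stats <- function(x, ...) {
  cat("<sp_stats> ", x$n_patterns, " stable pattern(s); avg ",
      round(x$avg_pattern_time, 1), " ts, max ", x$max_pattern_time,
      " ts; avg stabilizing ", round(x$avg_stabilizing_time, 1), " ts\n",
      sep = "")
  invisible(x)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided exact test used for tip-cell competition counts (genotype at
#' tip versus expectation): the p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (within a relative tolerance
#' of 1e-7 for floating-point ties).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(5, 5, 5, 5), 2))   # 1
#' fisher_exact(matrix(c(10, 0, 0, 10), 2)) # 2 / choose(20, 10)
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0), all(tab == round(tab)))
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  if (r1 == 0L || c1 == 0L || r1 == N || c1 == N) {
    if (N == 0L || min(r1, N - r1) == 0L || min(c1, N - c1) == 0L) {
      stop("fisher_exact: a table margin is zero")
    }
  }
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
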