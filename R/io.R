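#' Write / read a trajectory
#'
#' The trajectory CSV holds one row per timestep and cell with the columns
#' `timestep, cell, genotype, com_x, com_y, R, Vp, D, Np, Vhat, Nhat,
#' signal_active, adhesion, actin, filo_count, filo_len, is_tip`; the
#' per-timestep cell adjacency needed by the pattern scorer is written next
#' to it as `<path>.adjacency.csv` (`timestep, cell_i, cell_j`, contacting
#' pairs only).
#'
#' @param traj A `sprout_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  T_len <- length(traj$timestep)
  n <- length(traj$genotype)
  df <- data.frame(
    timestep = rep(traj$timestep, n),
    cell = rep(seq_len(n), each = T_len),
    genotype = rep(traj$genotype, each = T_len),
    com_x = as.vector(traj$com_x), com_y = as.vector(traj$com_y),
    R = as.vector(traj$R), Vp = as.vector(traj$Vp), D = as.vector(traj$D),
    Np = as.vector(traj$Np), Vhat = as.vector(traj$Vhat),
    Nhat = as.vector(traj$Nhat),
    signal_active = as.vector(traj$active),
    adhesion = as.vector(traj$adhesion),
    actin = as.vector(traj$actin),
    filo_count = as.vector(traj$filo_count),
    filo_len = as.vector(traj$filo_len),
    is_tip = as.integer(traj$tip[rep(seq_len(T_len), n)] ==
                          rep(seq_len(n), each = T_len)))
  df <- df[order(df$timestep, df$cell), ]
  utils::write.csv(df, path, row.names = FALSE)
  pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(2:n, function(i) seq.int(i, n)))
  hits <- which(traj$adjacency, arr.ind = TRUE)
  adj <- data.frame(timestep = traj$timestep[hits[, 1]],
                    cell_i = pair_i[hits[, 2]],
                    cell_j = pair_j[hits[, 2]])
  adj <- adj[order(adj$timestep, adj$cell_i, adj$cell_j), ]
  utils::write.csv(adj, paste0(path, ".adjacency.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  ts <- sort(unique(df$timestep))
  cells <- sort(unique(df$cell))
  T_len <- length(ts); n <- length(cells)
  df <- df[order(df$cell, df$timestep), ]
  shape <- function(col) matrix(df[[col]], T_len, n)
  tip <- integer(T_len)
  tip_rows <- df[df$is_tip == 1L, ]
  tip[match(tip_rows$timestep, ts)] <- tip_rows$cell
  n_pairs <- (n * (n - 1L)) %/% 2L
  adjacency <- matrix(FALSE, T_len, n_pairs)
  adj_path <- paste0(path, ".adjacency.csv")
  if (file.exists(adj_path)) {
    adj <- utils::read.csv(adj_path)
    if (nrow(adj)) {
      pair_index <- function(i, j) {
        (i - 1L) * n - (i * (i - 1L)) %/% 2L + (j - i)
      }
      adjacency[cbind(match(adj$timestep, ts),
                      pair_index(adj$cell_i, adj$cell_j))] <- TRUE
    }
  }
  structure(list(
    timestep = ts,
    genotype = df$genotype[match(cells, df$cell)],
    com_x = shape("com_x"), com_y = shape("com_y"),
    Vp = shape("Vp"), D = shape("D"), Np = shape("Np"), R = shape("R"),
    Vhat = shape("Vhat"), Nhat = shape("Nhat"),
    adhesion = shape("adhesion"), active = shape("signal_active"),
    actin = shape("actin"), filo_count = shape("filo_count"),
    filo_len = shape("filo_len"),
    tip = tip, adjacency = adjacency,
    final_mesh = NULL, seed = NA_integer_, config = NULL),
    class = "sprout_trajectory")
}

#' Write a replicate-set summary as JSON
#'
#' Per-genotype tip counts and fractions, the Fisher exact p-value of the
#' tip counts against a null expectation, and the aggregate per-run metric
#' means.
#'
#' @param rs A `replicate_set`.
#' @param path Output JSON path.
#' @param null_fraction Expected KD tip fraction under the null (e.g. 0.5
#'   for a 1:1 mosaic).
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(rs, path, null_fraction = NULL) {
  out <- list(n_runs = rs$tip$n_runs,
              tip_counts = as.list(rs$tip$counts),
              tip_fraction = as.list(rs$tip$fraction),
              aggregate = rs$aggregate)
  if (!is.null(null_fraction)) {
    n <- rs$tip$n_runs
    expected_kd <- round(null_fraction * n)
    tab <- matrix(c(rs$tip$counts["KD"], n - rs$tip$counts["KD"],
                    expected_kd, n - expected_kd), 2, byrow = TRUE)
    out$fisher_p_vs_expected <- fisher_exact(tab)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
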