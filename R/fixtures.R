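#' Build a trajectory fixture from handwritten per-timestep states
#'
#' Constructs a `sprout_trajectory` with exactly the schema the simulator
#' emits, from explicitly specified per-timestep matrices, so the metric
#' algorithms can be exercised (and unit-tested) without running the
#' simulator. Unspecified fields default to inert values (zero signalling,
#' strong adhesion, no filopodia, no adjacency).
#'
#' @param com_x Timesteps x cells matrix of axial centres of mass (required).
#' @param active Optional logical/0-1 matrix of signal-activity flags.
#' @param actin Optional matrix of deployed actin units.
#' @param adjacency Optional timesteps x pairs logical matrix (pair order
#'   `(1,2), (1,3), ..., (n-1,n)`), or a single logical vector applied to
#'   every timestep.
#' @param tip Optional per-timestep tip cell id (defaults to the cell with
#'   the highest `com_x`).
#' @param adhesion Optional matrix of adhesion classes.
#' @param genotype Optional per-cell genotype vector.
#' @param com_y,Vp,D,Np,R,Vhat,Nhat Optional matrices, zero when omitted.
#' @param timestep Optional timestep labels.
#' @return A `sprout_trajectory`.
#' @export
generate_fixture_trajectory <- function(com_x, active = NULL, actin = NULL,
                                        adjacency = NULL, tip = NULL,
                                        adhesion = NULL, genotype = NULL,
                                        com_y = NULL, Vp = NULL, D = NULL,
                                        Np = NULL, R = NULL, Vhat = NULL,
                                        Nhat = NULL, timestep = NULL) {
  com_x <- as.matrix(com_x)
  T_len <- nrow(com_x)
  n <- ncol(com_x)
  n_pairs <- (n * (n - 1L)) %/% 2L
  zero <- function(x) if (is.null(x)) matrix(0, T_len, n) else as.matrix(x)
  if (is.null(active)) {
    active <- matrix(0L, T_len, n)
  } else {
    active <- as.matrix(active)
    storage.mode(active) <- "integer"
  }
  actin <- if (is.null(actin)) matrix(0L, T_len, n) else as.matrix(actin)
  adhesion <- if (is.null(adhesion)) matrix(ADHESION_STRONG, T_len, n) else
    as.matrix(adhesion)
  if (is.null(adjacency)) {
    adjacency <- matrix(FALSE, T_len, n_pairs)
  } else if (is.vector(adjacency) || nrow(as.matrix(adjacency)) == 1L) {
    adjacency <- matrix(as.logical(adjacency), T_len, n_pairs, byrow = TRUE)
  } else {
    adjacency <- as.matrix(adjacency)
  }
  if (is.null(tip)) tip <- max.col(com_x, ties.method = "first")
  if (is.null(genotype)) genotype <- rep(GENOTYPE_WT, n)
  bad <- character()
  check_dim <- function(x, nm, rows = T_len, cols = n) {
    if (nrow(x) != rows || ncol(x) != cols) {
      bad <<- c(bad, sprintf("%s must be %d x %d, got %d x %d",
                             nm, rows, cols, nrow(x), ncol(x)))
    }
  }
  check_dim(active, "active"); check_dim(actin, "actin")
  check_dim(adhesion, "adhesion")
  check_dim(adjacency, "adjacency", cols = n_pairs)
  if (length(tip) != T_len) {
    bad <- c(bad, sprintf("tip must have %d entries, got %d",
                          T_len, length(tip)))
  }
  if (length(genotype) != n) {
    bad <- c(bad, sprintf("genotype must have %d entries, got %d",
                          n, length(genotype)))
  }
  if (length(bad)) {
    stop("fixture validation error:\n  ", paste(bad, collapse = "\n  "))
  }
  structure(list(
    timestep = if (is.null(timestep)) seq_len(T_len) - 1L else timestep,
    genotype = as.integer(genotype),
    com_x = com_x, com_y = zero(com_y),
    Vp = zero(Vp), D = zero(D), Np = zero(Np), R = zero(R),
    Vhat = zero(Vhat), Nhat = zero(Nhat),
    adhesion = adhesion, active = active, actin = actin,
    filo_count = matrix(0L, T_len, n), filo_len = matrix(0L, T_len, n),
    tip = as.integer(tip), adjacency = adjacency,
    final_mesh = NULL, seed = NA_integer_, config = NULL),
    class = "sprout_trajectory")
}
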