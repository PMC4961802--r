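#' Lattice configuration for a sprout
#'
#' Defines the discrete geometry of the simulated vessel sprout: a 2-D lattice
#' on the unrolled cylindrical vessel wall, periodic in the circumferential
#' (`y`) direction, with the axial coordinate `x` increasing towards the sprout
#' front. Cells are initialised as rectangular territories tiling axial bands,
#' `cells_per_cross_section` cells per band.
#'
#' @param circumference Number of circumferential sites (default 10, so the
#'   front row of the sprout is exactly the 10-site tip-scoring window).
#' @param axial_length Number of axial sites (default 120), leaving free space
#'   ahead of the initial sprout front.
#' @param cells_per_cross_section Cells sharing one cross-sectional band
#'   (default 2).
#' @param n_cells Total number of cells (default 10).
#' @param band_length Axial extent of one band of cells, in sites (default 10).
#' @return An object of class `lattice_config`.
#' @examples
#' cfg <- lattice_config()
#' cfg$target_area  # 50 sites per cell
#' @export
lattice_config <- function(circumference = 10L, axial_length = 120L,
                           cells_per_cross_section = 2L, n_cells = 10L,
                           band_length = 10L) {
  circumference <- as.integer(circumference)
  axial_length <- as.integer(axial_length)
  cells_per_cross_section <- as.integer(cells_per_cross_section)
  n_cells <- as.integer(n_cells)
  band_length <- as.integer(band_length)
  if (circumference %% cells_per_cross_section != 0L) {
    stop("configuration error: `circumference` (", circumference,
         ") must be divisible by `cells_per_cross_section` (",
         cells_per_cross_section, ")")
  }
  if (n_cells %% cells_per_cross_section != 0L) {
    stop("configuration error: `n_cells` (", n_cells,
         ") must be divisible by `cells_per_cross_section` (",
         cells_per_cross_section, ")")
  }
  n_bands <- n_cells %/% cells_per_cross_section
  if (axial_length <= n_bands * band_length) {
    stop("configuration error: `axial_length` (", axial_length,
         ") must exceed the initial sprout extent (", n_bands * band_length,
         " sites) to leave room ahead of the front")
  }
  structure(
    list(circumference = circumference,
         axial_length = axial_length,
         cells_per_cross_section = cells_per_cross_section,
         n_cells = n_cells,
         band_length = band_length,
         n_bands = n_bands,
         target_area = band_length * circumference %/% cells_per_cross_section),
    class = "lattice_config")
}

#' Build the initial sprout mesh
#'
#' Tiles the lattice with `n_cells` rectangular territories
#' (`cells_per_cross_section` per axial band); all remaining sites are empty
#' medium. Site ownership is stored as an `axial_length x circumference`
#' integer matrix with 0 marking empty sites and cell ids `1..n_cells`
#' otherwise; cell 1 sits at the sprout rear, the highest ids at the front.
#'
#' @param config A [lattice_config()].
#' @return An object of class `sprout_mesh`: a list with elements `owner`
#'   (ownership matrix), `config`, `genotype` (integer vector, all
#'   `GENOTYPE_WT` until [assign_genotypes()] is called) and `filopodia`
#'   (per-column chain table, initially empty).
#' @examples
#' mesh <- build_sprout(lattice_config())
#' table(mesh$owner[mesh$owner > 0])  # 50 sites per cell
#' @export
build_sprout <- function(config) {
  stopifnot(inherits(config, "lattice_config"))
  owner <- matrix(0L, nrow = config$axial_length, ncol = config$circumference)
  sector <- config$circumference %/% config$cells_per_cross_section
  for (b in seq_len(config$n_bands) - 1L) {
    rows <- b * config$band_length + seq_len(config$band_length)
    for (s in seq_len(config$cells_per_cross_section) - 1L) {
      cols <- s * sector + seq_len(sector)
      owner[rows, cols] <- b * config$cells_per_cross_section + s + 1L
    }
  }
  structure(
    list(owner = owner,
         config = config,
         genotype = rep(GENOTYPE_WT, config$n_cells),
         filopodia = empty_filopodia(config)),
    class = "sprout_mesh")
}

empty_filopodia <- function(config) {
  # one potential chain per circumferential column: owner cell, lo..hi axial range
  list(cell = rep(0L, config$circumference),
       lo = rep(-1L, config$circumference),
       hi = rep(-1L, config$circumference))
}

#' @export
print.sprout_mesh <- function(x, ...) {
  cfg <- x$config
  cat("<sprout_mesh> ", cfg$n_cells, " cells (",
      sum(x$genotype == GENOTYPE_KD), " KD), ",
      cfg$axial_length, "x", cfg$circumference, " lattice, ",
      sum(x$owner > 0L), " occupied sites\n", sep = "")
  invisible(x)
}

#' Genotype codes
#'
#' Integer codes used for cell genotypes throughout the package: wild-type
#' (`GENOTYPE_WT = 1`) and glycolysis-attenuated knockdown
#' (`GENOTYPE_KD = 2`).
#' @rdname genotypes
#' @export
GENOTYPE_WT <- 1L
#' @rdname genotypes
#' @export
GENOTYPE_KD <- 2L

#' Randomly assign genotypes to a mosaic sprout
#'
#' Labels cells as knockdown (KD) or wild-type (WT) in the exact proportion
#' given by `ratio`, by a seed-determined random permutation of cell ids. The
#' seed determines the initial positioning of the two genotypes in the sprout;
#' replicate simulations differ only in this seed (and in the downstream
#' stochastic dynamics it drives).
#'
#' @param mesh A [build_sprout()] mesh.
#' @param ratio Length-2 integer vector `c(kd, wt)`; `kd + wt` must divide
#'   `n_cells` exactly after scaling (e.g. `c(1, 1)` or `c(9, 1)` for 10
#'   cells).
#' @param seed Integer seed controlling the placement.
#' @return The mesh with its `genotype` vector filled in.
#' @examples
#' mesh <- assign_genotypes(build_sprout(lattice_config()), c(1, 1), seed = 1)
#' table(mesh$genotype)
#' @export
assign_genotypes <- function(mesh, ratio, seed) {
  stopifnot(inherits(mesh, "sprout_mesh"), length(ratio) == 2L)
  ratio <- as.integer(ratio)
  n <- mesh$config$n_cells
  if (any(ratio < 0L) || sum(ratio) <= 0L || n %% sum(ratio) != 0L) {
    stop("configuration error: ratio ", ratio[1], ":", ratio[2],
         " is not realizable with ", n, " cells")
  }
  n_kd <- ratio[1] * (n %/% sum(ratio))
  kd_ids <- sample_ids(n, n_kd, seed)
  mesh$genotype <- rep(GENOTYPE_WT, n)
  mesh$genotype[kd_ids] <- GENOTYPE_KD
  mesh
}

# Seeded sampling without disturbing the caller's RNG state.
sample_ids <- function(n, k, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(n, k)
}

#' Sites on a cell's membrane (memAgents)
#'
#' A cell's memAgents are its territory sites with at least one 4-neighbour
#' (circumferential wrap) belonging to a different owner or to the medium,
#' plus all of its filopodium sites. Coordinates are 0-based, `x` axial,
#' `y` circumferential.
#'
#' @param mesh A `sprout_mesh`.
#' @param cell Cell id.
#' @return Two-column integer matrix of `(x, y)` site coordinates.
#' @export
memagents <- function(mesh, cell) {
  own <- mesh$owner
  idx <- which(own == cell, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("invariant violation: cell ", cell, " owns no sites")
  }
  L <- nrow(own); C <- ncol(own)
  boundary <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; cc <- idx[i, 2]
    up <- if (r > 1L) own[r - 1L, cc] else -1L
    dn <- if (r < L) own[r + 1L, cc] else -1L
    lf <- own[r, if (cc == 1L) C else cc - 1L]
    rt <- own[r, if (cc == C) 1L else cc + 1L]
    boundary[i] <- any(c(up, dn, lf, rt) != cell)
  }
  body <- cbind(x = idx[boundary, 1] - 1L, y = idx[boundary, 2] - 1L)
  fil <- mesh$filopodia
  cols <- which(fil$cell == cell & fil$hi >= fil$lo)
  if (length(cols)) {
    extra <- do.call(rbind, lapply(cols, function(j) {
      cbind(x = fil$lo[j]:fil$hi[j], y = j - 1L)
    }))
    body <- rbind(body, extra)
  }
  body
}

#' Centre of mass of a cell
#'
#' Arithmetic mean of the cell's memAgent coordinates. The axial coordinate
#' `COM_x` is a plain mean; the circumferential coordinate `COM_y` uses the
#' circular-mean convention (the lattice wraps in `y`), mapped back to
#' `[0, circumference)`.
#'
#' The per-timestep positions recorded in simulation trajectories (used for
#' migration and overtake metrics) are the cell-body centres of mass
#' (`include_filopodia = FALSE`): positional metrics follow the relative
#' position of cell bodies, not of transient cytoskeletal protrusions.
#'
#' @inheritParams memagents
#' @param include_filopodia Include filopodium sites in the average (the
#'   full memAgent set), or cell-body boundary sites only.
#' @return Named numeric vector `c(x = , y = )` in site units.
#' @examples
#' mesh <- build_sprout(lattice_config())
#' center_of_mass(mesh, 1)
#' @export
center_of_mass <- function(mesh, cell, include_filopodia = TRUE) {
  m <- if (include_filopodia) {
    memagents(mesh, cell)
  } else {
    mesh2 <- mesh
    mesh2$filopodia <- empty_filopodia(mesh$config)
    memagents(mesh2, cell)
  }
  C <- mesh$config$circumference
  ang <- 2 * pi * m[, "y"] / C
  my <- atan2(mean(sin(ang)), mean(cos(ang))) * C / (2 * pi)
  if (my < 0) my <- my + C
  c(x = mean(m[, "x"]), y = my)
}

#' Junction interfaces between cells
#'
#' Enumerates every unordered pair of cells in contact, with the length of the
#' shared boundary counted as the number of 4-adjacent site pairs (with
#' circumferential wrap) having the two distinct owners. Filopodium sites do
#' not form junctions.
#'
#' @param mesh A `sprout_mesh`.
#' @return A data frame with columns `cell_i`, `cell_j` (`cell_i < cell_j`)
#'   and `length`; zero rows if no two cells touch.
#' @export
junction_interfaces <- function(mesh) {
  own <- mesh$owner
  L <- nrow(own); C <- ncol(own)
  a <- own[-L, , drop = FALSE]; b <- own[-1, , drop = FALSE]
  pairs_x <- cbind(as.vector(a), as.vector(b))
  left <- own; right <- own[, c(2:C, 1L), drop = FALSE]
  pairs_y <- cbind(as.vector(left), as.vector(right))
  all_pairs <- rbind(pairs_x, pairs_y)
  keep <- all_pairs[, 1] != all_pairs[, 2] & all_pairs[, 1] > 0L & all_pairs[, 2] > 0L
  all_pairs <- all_pairs[keep, , drop = FALSE]
  if (nrow(all_pairs) == 0L) {
    return(data.frame(cell_i = integer(), cell_j = integer(),
                      length = integer()))
  }
  lo <- pmin(all_pairs[, 1], all_pairs[, 2])
  hi <- pmax(all_pairs[, 1], all_pairs[, 2])
  tab <- table(paste(lo, hi))
  key <- do.call(rbind, strsplit(names(tab), " "))
  out <- data.frame(cell_i = as.integer(key[, 1]),
                    cell_j = as.integer(key[, 2]),
                    length = as.integer(tab))
  out[order(out$cell_i, out$cell_j), , drop = FALSE]
}

#' Write / read a mesh ownership snapshot
#'
#' Serialises the site-ownership map to CSV (columns `x`, `y`, `owner`,
#' 0-based coordinates, occupied sites only) next to a JSON header echoing the
#' lattice configuration, genotypes and timestep.
#'
#' @param mesh A `sprout_mesh`.
#' @param path CSV path; the header is written to `paste0(path, ".json")`.
#' @param timestep Timestep tag stored in the header.
#' @return `path`, invisibly.
#' @export
write_mesh_snapshot <- function(mesh, path, timestep = 0L) {
  occ <- which(mesh$owner > 0L, arr.ind = TRUE)
  df <- data.frame(x = occ[, 1] - 1L, y = occ[, 2] - 1L,
                   owner = mesh$owner[occ])
  utils::write.csv(df[order(df$x, df$y), ], path, row.names = FALSE)
  hdr <- list(timestep = timestep,
              genotype = mesh$genotype,
              config = unclass(mesh$config))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mesh_snapshot
#' @param config The [lattice_config()] of the stored mesh (re-read from the
#'   JSON header when omitted).
#' @export
read_mesh_snapshot <- function(path, config = NULL) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(config)) {
    config <- do.call(lattice_config, hdr$config[c(
      "circumference", "axial_length", "cells_per_cross_section",
      "n_cells", "band_length")])
  }
  df <- utils::read.csv(path)
  owner <- matrix(0L, config$axial_length, config$circumference)
  owner[cbind(df$x + 1L, df$y + 1L)] <- as.integer(df$owner)
  structure(list(owner = owner, config = config,
                 genotype = as.integer(hdr$genotype),
                 filopodia = empty_filopodia(config)),
            class = "sprout_mesh")
}

# Validate the ownership-partition and connectivity invariants; used by tests
# and by run_scenario() on its final state.
validate_mesh <- function(mesh) {
  own <- mesh$owner
  counts <- tabulate(own[own > 0L], nbins = mesh$config$n_cells)
  if (any(counts == 0L)) {
    stop("invariant violation: cell(s) ",
         paste(which(counts == 0L), collapse = ", "), " own no sites")
  }
  for (cell in seq_len(mesh$config$n_cells)) {
    if (!territory_connected(own, cell)) {
      stop("invariant violation: territory of cell ", cell,
           " is not 4-connected")
    }
  }
  invisible(TRUE)
}

territory_connected <- function(owner, cell) {
  idx <- which(owner == cell)
  if (length(idx) <= 1L) return(length(idx) == 1L)
  L <- nrow(owner); C <- ncol(owner)
  seen <- logical(length(idx))
  pos <- setNames(seq_along(idx), idx)
  queue <- idx[1]; seen[1] <- TRUE
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    r <- (p - 1L) %% L + 1L; cc <- (p - 1L) %/% L + 1L
    nb <- c(if (r > 1L) p - 1L, if (r < L) p + 1L,
            (cc %% C) * L + r,                    # right with wrap
            ((cc - 2L + C) %% C) * L + r)         # left with wrap
    for (q in nb) {
      j <- pos[as.character(q)]
      if (!is.na(j) && !seen[j]) {
        seen[j] <- TRUE
        queue <- c(queue, q)
      }
    }
  }
  all(seen)
}
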