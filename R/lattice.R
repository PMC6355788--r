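#' Tumour profile: the clinically meaningful feature triple
#'
#' The tumour profile is the interface between the clinical and the
#' mathematical description of a tumour: the growth fraction GF (percent of
#' living cells that are proliferating), the hypoxic fraction HF (percent
#' of all tumour cells that are dormant/hypoxic) and the dead fraction DF
#' (percent of all tumour cells that are dead).  Together with a cisplatin
#' cell-kill rate and a volume doubling time (or grid of doubling times) a
#' profile selects a family of compatible parameter sets.
#'
#' @param gf Growth fraction (%), in `[0, 100]`.
#' @param hf Hypoxic fraction (%), in `[0, 100]`.
#' @param df Dead fraction (%), in `[0, 100]`.
#' @param ckr Optional cisplatin kill-rate value(s) attached to the
#'   profile.
#' @param td Optional doubling-time value(s) (days) attached to the
#'   profile.
#'
#' @return An object of class `cv_profile`.
#' @export
#' @examples
#' tumour_profile(60, 30, 5)   # the high-proliferative study profile
#' tumour_profile(10, 30, 5)   # the low-proliferative study profile
tumour_profile <- function(gf, hf, df, ckr = NULL, td = NULL) {
  stopifnot(gf >= 0, gf <= 100, hf >= 0, hf <= 100, df >= 0, df <= 100)
  if (df + hf > 100)
    stop("infeasible profile: dead (DF) plus hypoxic (HF) fractions exceed 100% (hypoxic cells are living)")
  structure(list(gf = gf, hf = hf, df = df, ckr = ckr, td = td),
            class = "cv_profile")
}

#' @export
print.cv_profile <- function(x, ...) {
  cat(sprintf("Tumour profile: GF = %g%%, HF = %g%%, DF = %g%%", x$gf, x$hf,
              x$df))
  if (!is.null(x$ckr)) cat(sprintf(", CKR = {%s}", paste(x$ckr, collapse = ", ")))
  if (!is.null(x$td)) cat(sprintf(", Td = {%s} d", paste(x$td, collapse = ", ")))
  cat("\n")
  invisible(x)
}

# Per-GC compartment composition (cells, length n_compartments) realising a
# profile at the given capacity.  The class-level pools (proliferating,
# dormant, differentiated, dead, stem share) follow the profile exactly;
# *within* each class the cells are spread over phases and LIMP generations
# proportionally to the dominant eigenvector of the hourly transition
# operator, so a freely growing tumour starts close to its asymptotic
# internal composition instead of traversing a months-long ladder
# transient.  Falls back to phase-duration/uniform weights when the
# eigenvector is degenerate.
profile_composition <- function(profile, params, capacity) {
  gf <- profile$gf / 100; hf <- profile$hf / 100; df <- profile$df / 100
  nl <- params$n_limp
  dead <- df * capacity
  living <- capacity - dead
  g0 <- hf * capacity
  cycling <- gf * living
  diff <- living - cycling - g0
  if (diff < -1e-9 * capacity)
    stop(sprintf(paste0(
      "infeasible profile: GF = %g%%, HF = %g%%, DF = %g%% leaves a negative",
      " differentiated pool (living - proliferating - dormant = %.3g%% of",
      " capacity); requires HF <= (100-DF)(100-GF)/100"),
      profile$gf, profile$hf, profile$df, 100 * diff / capacity))
  diff <- max(diff, 0)
  stem_tot <- params$stem_frac * living
  pool <- cycling + g0
  if (stem_tot > pool + 1e-9 * capacity)
    stop("infeasible profile: stem fraction exceeds the proliferating plus dormant pool")
  s <- if (pool > 0) stem_tot / pool else 0

  idx <- state_idx(nl)
  ev <- .growth_eigenvector(params)
  spread <- function(weights, fallback) {
    w <- weights
    if (!all(is.finite(w)) || sum(w) <= 0) w <- fallback
    w / sum(w)
  }
  ph_w <- params$phase_frac / sum(params$phase_frac)
  stem_cyc <- 1:4
  limp_cyc <- setdiff(idx$cycling, stem_cyc)
  v <- setNames(numeric(n_compartments(nl)), state_compartments(nl))
  v[stem_cyc] <- s * cycling * spread(ev[stem_cyc], ph_w)
  v[5] <- s * g0
  v[limp_cyc] <- (1 - s) * cycling *
    spread(ev[limp_cyc], rep(ph_w / nl, nl))
  limp_g0 <- setdiff(idx$g0, 5L)
  v[limp_g0] <- (1 - s) * g0 * spread(ev[limp_g0], rep(1 / nl, nl))
  v[idx$diff] <- diff
  v[idx$necrotic] <- dead   # initial dead pool is necrotic (no/minimal
                            # necrotic core in the modelled tumours; the
                            # dead fraction is an MRI-derived estimate)
  v
}

# Dominant (Perron) eigenvector of the living block of the hourly operator
# at full crowding, normalised and made non-negative.
.growth_eigenvector <- function(params) {
  A <- cyto_operator(params, crowding = 1)
  idx <- state_idx(params$n_limp)
  Al <- A[idx$living, idx$living, drop = FALSE]
  e <- eigen(Al)
  v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
  out <- numeric(nrow(A))
  out[idx$living] <- v
  out
}

#' Initialize a tumour lattice from a voxel mask and a tumour profile
#'
#' Superimposes the discretization mesh on a binary region-of-interest mask
#' and populates every tumour GC to capacity with a cell census realising
#' the profile exactly: `DF`% of cells dead (necrotic pool), `HF`% dormant
#' in G0, `GF`% of living cells proliferating (spread over G1/S/G2/M
#' proportionally to the phase durations and uniformly over LIMP
#' generations), stem cells making up `params$stem_frac` of living cells
#' (split between cycling and dormant pools proportionally), and the
#' remaining living cells terminally differentiated.
#'
#' @param mask 3-D array (0/1 or logical) marking tumour voxels, or an
#'   object read by [read_voxel_volume()].
#' @param profile A [tumour_profile()].
#' @param params A [parameter_set()].
#' @param gc_edge Edge length of a geometrical cell (mm).
#' @param density Cell density (cells/cm^3); the default 1e9 is the typical
#'   density used when no tumour-specific estimate exists.
#'
#' @return An object of class `cv_lattice`.
#' @export
#' @examples
#' mask <- array(0, c(8, 8, 8)); mask[3:6, 3:6, 3:6] <- 1
#' lat <- init_tumour(mask, tumour_profile(60, 30, 5),
#'                    parameter_set(n_limp = 4))
#' tumour_volume(lat)
init_tumour <- function(mask, profile, params, gc_edge = 1,
                        density = 1e9) {
  stopifnot(inherits(profile, "cv_profile"), inherits(params, "cv_params"))
  mask <- as.array(mask)
  if (length(dim(mask)) != 3) stop("mask must be a 3-D array")
  bad <- !(mask %in% c(0, 1))
  if (any(bad)) stop(sprintf("mask is not binary: %d voxel(s) outside {0,1}",
                             sum(bad)))
  vox <- which(mask == 1, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("empty mask: no tumour voxels")
  capacity <- density * (gc_edge / 10)^3
  comp <- profile_composition(profile, params, capacity)
  n0 <- nrow(vox)
  alloc <- n0 + max(256L, ceiling(n0 / 2))
  states <- matrix(0, nrow = length(comp), ncol = alloc,
                   dimnames = list(names(comp), NULL))
  states[, seq_len(n0)] <- comp
  coords <- matrix(0L, nrow = alloc, ncol = 3)
  coords[seq_len(n0), ] <- vox
  index <- array(0L, dim(mask))
  index[vox] <- seq_len(n0)
  active <- c(rep(TRUE, n0), rep(FALSE, alloc - n0))
  structure(list(dim = dim(mask), gc_edge = gc_edge, density = density,
                 capacity = capacity, n_limp = params$n_limp,
                 states = states, coords = coords, index = index,
                 active = active),
            class = "cv_lattice")
}

#' @export
print.cv_lattice <- function(x, ...) {
  vol <- tumour_volume(x)
  cat(sprintf(
    "Tumour lattice: %d x %d x %d grid, %d tumour GCs of %g mm, %.4g cells (%.3g cm^3)\n",
    x$dim[1], x$dim[2], x$dim[3], sum(x$active), x$gc_edge,
    vol["cells"], vol["volume_cm3"]))
  invisible(x)
}

#' Tumour volume readouts of a lattice
#'
#' Two readouts are returned: the primary one converts the total cell
#' census (living plus not-yet-cleared dead cells, which imaging cannot
#' distinguish from living tissue) to a volume through the cell density;
#' the alternative counts tumour-labelled GCs times the GC volume.
#'
#' @param lattice A [cv_lattice][init_tumour()].
#' @return Named vector: `cells`, `volume_cm3` (census-based, primary),
#'   `volume_gc_cm3` (label-based), `n_gc`.
#' @export
tumour_volume <- function(lattice) {
  act <- which(lattice$active)
  cells <- if (length(act)) sum(col_totals_cpp(lattice$states, act)) else 0
  gc_vol <- (lattice$gc_edge / 10)^3
  c(cells = cells, volume_cm3 = cells / lattice$density,
    volume_gc_cm3 = length(act) * gc_vol, n_gc = length(act))
}

# Extend the column storage of a lattice with `extra` inactive slots.
.grow_lattice <- function(lat, extra = max(256L, ncol(lat$states) %/% 2L)) {
  lat$states <- cbind(lat$states, matrix(0, nrow(lat$states), extra))
  lat$coords <- rbind(lat$coords, matrix(0L, extra, 3))
  lat$active <- c(lat$active, rep(FALSE, extra))
  lat
}

#' Spatial rebalancing scan of the tumour lattice
#'
#' The second of the two hourly mesh scans: it governs the movement of
#' cells through the tumour region so that the tumour shrinks or grows
#' coherently.  Under-populated GCs (occupancy below `floor_frac` of
#' capacity) are dissolved into their most occupied neighbour, boundary
#' GCs first, so the tumour contracts inward; over-full GCs spill their
#' surplus into their least occupied neighbour, annexing an adjacent
#' non-tumour voxel when every neighbour is full.  Total cell count is
#' conserved exactly (cells are only moved, never created or destroyed).
#'
#' @param lattice A [cv_lattice][init_tumour()].
#' @param seed Integer seed entering the deterministic tie-break hash.
#' @param hour Simulation hour (enters the tie-break hash so ties are not
#'   broken identically every step).
#' @param floor_frac Occupancy floor as a fraction of capacity.
#' @return The updated lattice.
#' @export
spatial_step <- function(lattice, seed = 1L, hour = 0L, floor_frac = 0.1) {
  lat <- .dup_lattice(lattice)
  .spatial_step_(lat, seed, hour, floor_frac)
}

# Force private copies of every array the compiled kernels mutate.
.dup_lattice <- function(lat) {
  lat$states <- lat$states + 0
  lat$index <- array(as.integer(lat$index), dim(lat$index))
  lat$coords <- lat$coords + 0L
  lat$active <- lat$active | FALSE
  lat
}

# In-place variant: assumes every array of `lat` is privately owned by the
# caller (see .dup_lattice).  The heavy lifting lives in spatial_scan_cpp:
# a spill scan (surplus pushed to the least occupied neighbour, annexing an
# adjacent non-tumour voxel when every neighbour is full) followed by a
# dissolution scan (under-populated GCs hand their contents to their most
# occupied neighbours, filling each only up to capacity, boundary GCs
# first).  Cells are only ever moved, never created or destroyed.
.spatial_step_ <- function(lat, seed = 1L, hour = 0L, floor_frac = 0.1,
                           max_passes = 30L) {
  if (!any(lat$active)) return(lat)
  free <- which(!lat$active)
  if (length(free) < 64L) {
    lat <- .grow_lattice(lat)
    free <- which(!lat$active)
  }
  res <- spatial_scan_cpp(lat$states, lat$index, lat$coords, lat$active,
                          as.integer(lat$dim), lat$capacity, floor_frac,
                          as.integer(seed), as.integer(hour),
                          as.integer(free), as.integer(max_passes))
  if (isTRUE(res$out_of_slots)) {
    lat <- .grow_lattice(lat)
    lat <- .spatial_step_(lat, seed, hour, floor_frac, max_passes)
  }
  lat
}
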