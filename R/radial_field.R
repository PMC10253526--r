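#' Uniform radial grid on a cylindrical target
#'
#' The track axis is z; fields live on annular bins of width `bw`
#' between radius 0 and `r_max`, with bin centres used as the spatial
#' partition of the finite-difference scheme.
#'
#' @param bw bin width in nm (default 20).
#' @param r_max outer radius in nm (default 5000, i.e. 5 um). Must be an
#'   integer multiple of `bw`.
#' @param h track (cylinder) length in nm (default 10000; use 1000-2000
#'   for high-LET ions).
#' @return Object of class `radial_grid` with bin edges, centres and
#'   annulus volumes in litres.
#' @export
radial_grid <- function(bw = 20, r_max = 5000, h = 10000) {
  stopifnot(bw > 0, r_max > 0, h > 0)
  J <- as.integer(round(r_max / bw))
  if (abs(J * bw - r_max) > 1e-9 * r_max)
    stop("`r_max` must be an integer multiple of `bw`")
  if (J < 3) stop("grid needs at least 3 bins")
  edges <- seq(0, r_max, length.out = J + 1)
  centers <- (edges[-1] + edges[-(J + 1)]) / 2
  volumes <- pi * (edges[-1]^2 - edges[-(J + 1)]^2) * h / .NM3_PER_L
  structure(list(bw = bw, r_max = r_max, h = h, J = J,
                 edges = edges, centers = centers, volumes_L = volumes),
            class = "radial_grid")
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf("<radial_grid> %d bins of %g nm to r_max = %g nm, h = %g nm\n",
              x$J, x$bw, x$r_max, x$h))
  invisible(x)
}

#' System state: all concentration fields on a shared grid
#'
#' @param grid a [radial_grid()].
#' @param species character vector of species names.
#' @param conc J x n_species matrix of molarities (default all zero).
#' @param time time in ns.
#' @param n_tracks number of tracks averaged into the state.
#' @param flattened named logical; a flattened field is spatially
#'   constant and is skipped by the diffusion step.
#' @return Object of class `system_state`.
#' @export
system_state <- function(grid, species, conc = NULL, time = 0,
                         n_tracks = 1L, flattened = NULL) {
  if (is.null(conc))
    conc <- matrix(0, grid$J, length(species))
  conc <- as.matrix(conc)
  stopifnot(nrow(conc) == grid$J, ncol(conc) == length(species))
  dimnames(conc) <- list(NULL, species)
  if (is.null(flattened))
    flattened <- setNames(rep(FALSE, length(species)), species)
  if (any(conc < 0)) stop("concentrations must be non-negative")
  structure(list(time = time, grid = grid, conc = conc,
                 n_tracks = n_tracks, flattened = flattened),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> t = %g ns, %d species on %d bins (%d flat)\n",
              x$time, ncol(x$conc), x$grid$J, sum(x$flattened)))
  invisible(x)
}

#' Beam / irradiation geometry specification
#'
#' Dose, fluence and LET are tied together by
#' `D[Gy] = 1.6e-9 * LET[keV/um] * Phi[1/cm2] / rho[g/cm3]`.
#'
#' @param let LET in keV/um.
#' @param fluence particle fluence in 1/cm^2 (optional).
#' @param dose dose in Gy (optional).
#' @param rho density in g/cm^3 (water: 1).
#' @return Object of class `beam_spec`. Missing one of dose/fluence is
#'   filled in from the other when possible.
#' @export
beam_spec <- function(let, fluence = NULL, dose = NULL, rho = 1) {
  stopifnot(let > 0, rho > 0)
  if (is.null(fluence) && !is.null(dose))
    fluence <- dose * rho / (1.6e-9 * let)
  if (is.null(dose) && !is.null(fluence))
    dose <- 1.6e-9 * let * fluence / rho
  structure(list(let = let, fluence = fluence, dose = dose, rho = rho),
            class = "beam_spec")
}

#' Dose from fluence and LET
#'
#' @param beam a [beam_spec()] with `let` and `fluence` set.
#' @return Dose in Gy.
#' @export
dose_from_fluence <- function(beam) {
  if (is.null(beam$fluence) || beam$fluence <= 0)
    stop("beam fluence must be positive")
  1.6e-9 * beam$let * beam$fluence / beam$rho
}

#' Average surface per track, and the equivalent track-cell radius
#'
#' The mean surface around one particle track is `S = 1/Phi`; the
#' equivalent cylindrical cell radius is `sqrt(S/pi)`. This is the
#' dose-rate-dependent prescription for choosing `r_max` when inter-track
#' spacing matters.
#'
#' @param beam a [beam_spec()] with fluence (or dose + LET) set.
#' @return List with `S_cm2` and `r_max_nm`.
#' @export
surface_from_fluence <- function(beam) {
  if (is.null(beam$fluence) || beam$fluence <= 0)
    stop("beam fluence must be positive")
  S <- 1 / beam$fluence                    # cm^2
  r_cm <- sqrt(S / pi)
  list(S_cm2 = S, r_max_nm = r_cm * 1e7)
}

#' Bin discrete species positions into a radial concentration state
#'
#' Converts per-molecule coordinates around the track axis (z) into
#' per-species radial concentration histograms, averaging over
#' `n_tracks` superimposed tracks:
#' `conc[j] = count[j] / (N_A * V_j * n_tracks)` with `V_j` the annulus
#' volume in litres. Bins are half-open `[e_j, e_{j+1})`; positions at or
#' beyond `r_max`, or with z outside `[0, h]`, are discarded and counted.
#'
#' @param positions `data.frame` with columns `species`, `x_nm`, `y_nm`,
#'   `z_nm`.
#' @param grid a [radial_grid()].
#' @param species character vector fixing field order (defaults to the
#'   species present).
#' @param n_tracks number of tracks the positions accumulate.
#' @param time time stamp for the state, ns.
#' @return A [system_state()]; attribute `discarded` counts rejected
#'   positions.
#' @export
bin_positions <- function(positions, grid, species = NULL, n_tracks = 1L,
                          time = 0) {
  stopifnot(n_tracks >= 1)
  if (is.null(species))
    species <- sort(unique(as.character(positions$species)))
  conc <- matrix(0, grid$J, length(species), dimnames = list(NULL, species))
  discarded <- 0L
  if (nrow(positions)) {
    r <- sqrt(positions$x_nm^2 + positions$y_nm^2)
    ok <- r < grid$r_max & positions$z_nm >= 0 & positions$z_nm <= grid$h &
      as.character(positions$species) %in% species
    discarded <- sum(!ok)
    if (any(ok)) {
      bin <- findInterval(r[ok], grid$edges, rightmost.closed = FALSE)
      tab <- table(factor(as.character(positions$species[ok]), levels = species),
                   factor(bin, levels = seq_len(grid$J)))
      counts <- t(unclass(tab))
      conc <- counts / (.AVOGADRO * grid$volumes_L * n_tracks)
      dimnames(conc) <- list(NULL, species)
    }
  }
  st <- system_state(grid, species, conc, time = time,
                     n_tracks = as.integer(n_tracks))
  attr(st, "discarded") <- discarded
  st
}

#' Total number of molecules per track in one field
#'
#' Exact inverse of the binning conversion:
#' `sum_j conc[j] * N_A * V_j` (molecules per track).
#'
#' @param values numeric vector of bin molarities.
#' @param grid a [radial_grid()].
#' @return Molecules per track.
#' @export
total_amount <- function(values, grid) {
  sum(values * grid$volumes_L) * .AVOGADRO
}

#' Per-species total amounts of a state
#'
#' @param state a [system_state()].
#' @return Named vector, molecules per track.
#' @export
state_totals <- function(state) {
  colSums(state$conc * state$grid$volumes_L) * .AVOGADRO
}

#' Radiation-chemical yields (G-values)
#'
#' G = 100 * N / E_dep with N the per-track molecule total and
#' `E_dep = LET[keV/um] * h[um] * 1000` eV the energy one track deposits
#' along the cylinder. G is intensive: independent of h at fixed
#' concentrations.
#'
#' @param state a [system_state()].
#' @param beam a [beam_spec()] providing the LET.
#' @return Named vector of molecules per 100 eV; attribute `time_ns`.
#' @export
gvalues <- function(state, beam) {
  e_dep <- beam$let * (state$grid$h / 1000) * 1000  # eV per track
  if (e_dep <= 0) stop("deposited energy is zero; check LET and h")
  g <- 100 * state_totals(state) / e_dep
  attr(g, "time_ns") <- state$time
  g
}

#' Category sums of the standard species groups
#'
#' @param state a [system_state()] containing the standard species.
#' @return J x 3 matrix with columns `i`, `ii`, `iii`.
#' @export
category_sums <- function(state) {
  out <- sapply(species_categories, function(members) {
    members <- intersect(members, colnames(state$conc))
    if (!length(members)) return(rep(0, state$grid$J))
    rowSums(state$conc[, members, drop = FALSE])
  })
  colnames(out) <- names(species_categories)
  out
}

#' Relative deviation in per-species totals between two states
#'
#' `(N_a - N_b) / N_b` per species; species with a zero reference total
#' are reported as `NA` and flagged in the `skipped` attribute.
#'
#' @param state_a,state_b [system_state()] objects on identical species
#'   sets (grids may differ).
#' @return Named vector of relative differences.
#' @export
deviation <- function(state_a, state_b) {
  if (!setequal(colnames(state_a$conc), colnames(state_b$conc)))
    stop("states track different species sets")
  na <- state_totals(state_a)
  nb <- state_totals(state_b)[names(na)]
  out <- ifelse(nb > 0, (na - nb) / nb, NA_real_)
  names(out) <- names(na)
  attr(out, "skipped") <- names(out)[is.na(out)]
  out
}
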