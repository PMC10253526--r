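#' Synthetic track model
#'
#' Parametric stand-in for a Monte Carlo track-chemistry snapshot at the
#' hand-over time: per-species expected molecule counts per track and
#' 2-D Gaussian radial scales, approximately homogeneous along the
#' axis. Radial profiles may optionally be a two-component core +
#' penumbra mixture, emulating the delta-ray halo of ion tracks. These
#' are fixtures with tunable parameters, not reproductions of any
#' particular Monte Carlo output.
#'
#' @param yields named numeric, expected molecules per track per species.
#' @param sigma named numeric, radial Gaussian scale per species (nm).
#' @param let LET in keV/um.
#' @param h track length in nm.
#' @param t_in snapshot time in ns (default 500).
#' @param penumbra_fraction fraction of each species' molecules placed in
#'   the broad penumbra component (default 0: single Gaussian).
#' @param penumbra_sigma radial scale of the penumbra component (nm).
#' @param seed default random seed used by the sampler.
#' @return Object of class `track_model`.
#' @export
track_model <- function(yields, sigma, let, h, t_in = 500,
                        penumbra_fraction = 0, penumbra_sigma = NA,
                        seed = NULL) {
  stopifnot(all(yields >= 0), all(sigma > 0), let > 0, h > 0,
            penumbra_fraction >= 0, penumbra_fraction < 1)
  if (penumbra_fraction > 0 && (is.na(penumbra_sigma) || penumbra_sigma <= 0))
    stop("penumbra_sigma required when penumbra_fraction > 0")
  if (!setequal(names(yields), names(sigma)))
    stop("yields and sigma must name the same species")
  structure(list(yields = yields, sigma = sigma[names(yields)], let = let,
                 h = h, t_in = t_in, penumbra_fraction = penumbra_fraction,
                 penumbra_sigma = penumbra_sigma, seed = seed),
            class = "track_model")
}

#' Sample discrete molecule positions for synthetic tracks
#'
#' Per species, the molecule count is Poisson around
#' `n_tracks * yield`; radial positions are drawn from a 2-D Gaussian of
#' the species' scale (optionally mixed with a penumbra component) and z
#' uniformly along the track. Reproducible for a fixed seed.
#'
#' @param model a [track_model()].
#' @param n_tracks number of independent tracks to superimpose.
#' @param seed random seed; defaults to the model's.
#' @return `data.frame` with columns `species`, `x_nm`, `y_nm`, `z_nm`.
#' @export
sample_track_positions <- function(model, n_tracks = 1L, seed = model$seed) {
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(names(model$yields), function(s) {
    n <- rpois(1L, n_tracks * model$yields[[s]])
    if (n == 0L) return(NULL)
    sg <- rep(model$sigma[[s]], n)
    if (model$penumbra_fraction > 0) {
      pen <- runif(n) < model$penumbra_fraction
      sg[pen] <- model$penumbra_sigma
    }
    data.frame(species = rep(s, n),
               x_nm = rnorm(n, 0, sg),
               y_nm = rnorm(n, 0, sg),
               z_nm = runif(n, 0, model$h),
               stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts))
    return(data.frame(species = character(), x_nm = numeric(),
                      y_nm = numeric(), z_nm = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, parts)
}

#' Bin a synthetic track model into an initial radial state
#'
#' Convenience wrapper: samples `n_tracks` tracks, bins them on `grid`
#' with per-track averaging, and stamps the model's hand-over time.
#'
#' @param model a [track_model()].
#' @param grid a [radial_grid()] (its `h` should match the model's).
#' @param species field order, defaulting to the standard ten species.
#' @param n_tracks tracks to average.
#' @param seed random seed; defaults to the model's.
#' @return A [system_state()] at `t = model$t_in`.
#' @export
synthetic_initial_state <- function(model, grid, species = NULL,
                                    n_tracks = 1000L, seed = model$seed) {
  if (is.null(species))
    species <- unlist(species_categories, use.names = FALSE)
  pos <- sample_track_positions(model, n_tracks = n_tracks, seed = seed)
  bin_positions(pos, grid, species = species, n_tracks = n_tracks,
                time = model$t_in)
}

## Radial scale at the snapshot time: initial spur width plus free
## diffusion, sigma^2 = sigma0^2 + 2 D t_in (2-D Gaussian per axis).
.sigma_at <- function(D, t_in, sigma0 = 10) {
  sqrt(sigma0^2 + 2 * D * t_in)
}

.preset_model <- function(gv, let, h, t_in, po2, henry,
                          penumbra_fraction, penumbra_sigma, seed) {
  net <- build_default_network()
  Dmap <- setNames(net$species$D, net$species$name)
  e_dep <- let * (h / 1000) * 1000            # eV per track
  yields <- gv * e_dep / 100
  if (po2 > 0) {
    ## Emulate an oxygenated Monte Carlo snapshot: during [0, t_in] the
    ## scavenging reactions eaq- + O2 and H + O2 convert most of the
    ## reducing radicals; partition the yields by the exponential
    ## survival factor exp(-k [O2] t_in).
    o2 <- o2_concentration_from_po2(po2, henry)
    k_e <- net$reactions$k[match("R13", net$reactions$id)] * 1e-9
    k_h <- net$reactions$k[match("R14", net$reactions$id)] * 1e-9
    f_e <- exp(-k_e * o2 * t_in)
    f_h <- exp(-k_h * o2 * t_in)
    yields[["O2-"]] <- yields[["O2-"]] + yields[["eaq-"]] * (1 - f_e)
    yields[["HO2"]] <- yields[["HO2"]] + yields[["H"]] * (1 - f_h)
    yields[["eaq-"]] <- yields[["eaq-"]] * f_e
    yields[["H"]] <- yields[["H"]] * f_h
  }
  sigma <- vapply(names(yields), function(s) .sigma_at(Dmap[[s]], t_in), 0)
  track_model(yields, sigma, let = let, h = h, t_in = t_in,
              penumbra_fraction = penumbra_fraction,
              penumbra_sigma = penumbra_sigma, seed = seed)
}

#' Dilute low-LET (electron-like) track preset
#'
#' Emulates a 500 keV electron track (~0.2 keV/um) at the hand-over
#' time: standard scavenger-free escape yields for the primary species,
#' radial scales set by free diffusion since track formation, no
#' penumbra. With `po2 > 0` the eaq-/H yields are pre-partitioned into
#' O2-/HO2 according to the oxygen-scavenging survival factor at
#' `t_in`, as an oxygenated Monte Carlo snapshot would show.
#'
#' @param po2 oxygen partial pressure (fraction of 1 atm) the snapshot
#'   was generated under (default 0).
#' @param t_in snapshot time, ns.
#' @param seed default sampler seed.
#' @param henry_M_per_atm Henry constant used for the partitioning.
#' @return A [track_model()].
#' @export
low_let_preset <- function(po2 = 0, t_in = 500, seed = NULL,
                           henry_M_per_atm = 1.3e-3) {
  gv <- c("OH" = 2.70, "H3O+" = 3.30, "H" = 0.58, "eaq-" = 2.62,
          "H2" = 0.45, "H2O2" = 0.68, "OH-" = 0.50,
          "HO2" = 0, "O2-" = 0, "HO2-" = 0)
  .preset_model(gv, let = 0.2, h = 10000, t_in = t_in, po2 = po2,
                henry = henry_M_per_atm,
                penumbra_fraction = 0, penumbra_sigma = NA, seed = seed)
}

#' Dense high-LET (carbon-like) track preset
#'
#' Emulates a carbon-ion track (~160 keV/um) at the hand-over time:
#' lower per-100-eV yields with a larger intra-track molecular fraction,
#' a shorter target (2 um) and a delta-ray penumbra carrying 35% of the
#' molecules out to ~1 um.
#'
#' @inheritParams low_let_preset
#' @param let LET in keV/um (default 160; pass e.g. 50 for a 40 MeV/u
#'   carbon-like track).
#' @return A [track_model()].
#' @export
high_let_preset <- function(po2 = 0, t_in = 500, seed = NULL,
                            henry_M_per_atm = 1.3e-3, let = 160) {
  gv <- c("OH" = 1.10, "H3O+" = 1.35, "H" = 0.35, "eaq-" = 1.05,
          "H2" = 0.80, "H2O2" = 0.85, "OH-" = 0.25,
          "HO2" = 0, "O2-" = 0, "HO2-" = 0)
  .preset_model(gv, let = let, h = 2000, t_in = t_in, po2 = po2,
                henry = henry_M_per_atm,
                penumbra_fraction = 0.35, penumbra_sigma = 1000, seed = seed)
}

#' Uniform random well-mixed state
#'
#' Assigns each species one concentration drawn log-uniformly from
#' `conc_range`, constant across bins and immediately flagged flat: the
#' "dummy" fully homogeneous scenario used to cross-check the radial
#' solver against well-mixed kinetics.
#'
#' @param grid a [radial_grid()].
#' @param species character vector of species names.
#' @param conc_range two molarities bounding the log-uniform draw.
#' @param seed random seed.
#' @param time state time stamp, ns (default 1000: the homogeneous-stage
#'   hand-over point).
#' @return A [system_state()] with all fields flattened.
#' @export
uniform_random_state <- function(grid, species, conc_range = c(1e-9, 1e-6),
                                 seed = NULL, time = 1000) {
  stopifnot(length(conc_range) == 2, all(conc_range > 0))
  if (!is.null(seed)) set.seed(seed)
  cvals <- if (conc_range[1] == conc_range[2]) rep(conc_range[1], length(species))
  else exp(runif(length(species), log(conc_range[1]), log(conc_range[2])))
  conc <- matrix(rep(cvals, each = grid$J), grid$J, length(species))
  system_state(grid, species, conc, time = time,
               flattened = setNames(rep(TRUE, length(species)), species))
}
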