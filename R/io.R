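## CSV dialects and the JSON config/manifest. All floating output is
## written at 9 significant digits.

.fmt <- function(x) sprintf("%.9g", x)

#' Write / read a positions CSV (`species,x_nm,y_nm,z_nm`)
#'
#' @param positions `data.frame` with columns `species`, `x_nm`, `y_nm`,
#'   `z_nm`.
#' @param path file path.
#' @return `write_positions_csv` returns `path` invisibly;
#'   `read_positions_csv` returns the `data.frame`.
#' @export
write_positions_csv <- function(positions, path) {
  df <- data.frame(species = positions$species,
                   x_nm = .fmt(positions$x_nm),
                   y_nm = .fmt(positions$y_nm),
                   z_nm = .fmt(positions$z_nm))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_positions_csv
#' @export
read_positions_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("species", "x_nm", "y_nm", "z_nm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("positions file lacks column(s): ", paste(miss, collapse = ", "))
  df[need]
}

#' Write / read a binned radial state CSV
#'
#' Format `species,bin_index,concentration_M` (bin_index is 0-based),
#' with the grid and time stamp echoed in `#`-prefixed header lines so
#' a state round-trips through its own reader.
#'
#' @param state a [system_state()].
#' @param path file path.
#' @param grid grid used to rebuild the state (defaults to the header).
#' @return The path (writer, invisibly) or a [system_state()] (reader).
#' @export
write_state_csv <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  g <- state$grid
  writeLines(sprintf("# time_ns=%s bw_nm=%s r_max_nm=%s h_nm=%s n_tracks=%d",
                     .fmt(state$time), .fmt(g$bw), .fmt(g$r_max), .fmt(g$h),
                     state$n_tracks), con)
  writeLines(sprintf("# flattened=%s",
                     paste(colnames(state$conc)[state$flattened],
                           collapse = ",")), con)
  writeLines("species,bin_index,concentration_M", con)
  for (s in colnames(state$conc)) {
    writeLines(sprintf("%s,%d,%s", s, seq_len(g$J) - 1L,
                       .fmt(state$conc[, s])), con)
  }
  invisible(path)
}

#' @rdname write_state_csv
#' @export
read_state_csv <- function(path, grid = NULL) {
  hdr <- readLines(path, n = 2L)
  meta <- regmatches(hdr[1], gregexpr("[a-z_]+=[^ ]+", hdr[1]))[[1]]
  kv <- strsplit(meta, "=")
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  if (is.null(grid))
    grid <- radial_grid(bw = as.numeric(vals[["bw_nm"]]),
                        r_max = as.numeric(vals[["r_max_nm"]]),
                        h = as.numeric(vals[["h_nm"]]))
  flat_field <- sub("^# flattened=", "", hdr[2])
  flat_names <- if (nzchar(flat_field)) strsplit(flat_field, ",")[[1]] else character()
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  species <- unique(df$species)
  conc <- matrix(0, grid$J, length(species), dimnames = list(NULL, species))
  for (s in species) {
    rows <- df[df$species == s, ]
    conc[rows$bin_index + 1L, s] <- rows$concentration_M
  }
  system_state(grid, species, conc,
               time = as.numeric(vals[["time_ns"]]),
               n_tracks = as.integer(vals[["n_tracks"]]),
               flattened = setNames(species %in% flat_names, species))
}

#' Write G-value records (`time_ns,species,g_per_100eV`)
#'
#' @param run a `radchem_run` with G-values recorded.
#' @param path file path.
#' @export
write_gvalues_csv <- function(run, path) {
  if (is.null(run$gvalues)) stop("run has no G-values (no beam given)")
  long <- data.frame(
    time_ns = rep(run$times, ncol(run$gvalues)),
    species = rep(colnames(run$gvalues), each = nrow(run$gvalues)),
    g_per_100eV = .fmt(as.vector(run$gvalues)))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gvalues_csv
#' @export
read_gvalues_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Write the run manifest
#'
#' Echoes the configuration, the clamp counter (which must be zero for
#' a trustworthy run), per-species flatten times and the package
#' version, as JSON.
#'
#' @param run a `radchem_run`.
#' @param path file path.
#' @export
write_manifest <- function(run, path) {
  m <- run$manifest
  m$schedule <- as.list(m$schedule)
  m$version <- as.character(utils::packageVersion("radchemxt"))
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Load a full run configuration
#'
#' Reads a JSON configuration and returns validated objects with all
#' defaults filled in (bw = 20 nm, r_max = 5 um, staged schedule,
#' flatten threshold 5%, t_in = 500 ns). Recognised blocks:
#' `po2`, `henry_M_per_atm`, `network` (override block passed to
#' [build_default_network()]), `grid` (`bw_nm`, `r_max_nm`, `h_nm`),
#' `solver` (`t_in_ns`, `t_end_ns`, `flatten_threshold`,
#' `record_times_ns`, `schedule` as a list of
#' `{t_start,t_end,dt}`), `beam` (`let_kev_um`, `fluence_per_cm2`,
#' `dose_gy`, `rho`), `track` (`preset` = "low"/"high" plus `seed`,
#' `n_tracks`, or explicit `yields`/`sigma_nm`/`let_kev_um`/`h_nm`).
#'
#' @param path JSON file path.
#' @return List with elements `net`, `config`, `grid`, `beam`, `model`,
#'   `n_tracks`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("po2", "henry_M_per_atm", "network", "grid", "solver",
             "beam", "track")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  po2 <- if (!is.null(cfg$po2)) cfg$po2 else 0
  if (po2 < 0 || po2 > 1) stop("config field `po2` must be in [0, 1]")
  henry <- if (!is.null(cfg$henry_M_per_atm)) cfg$henry_M_per_atm else 1.3e-3
  ov <- if (!is.null(cfg$network)) as.list(cfg$network) else list()
  ov$po2 <- po2
  ov$henry_M_per_atm <- henry
  net <- build_default_network(ov)

  g <- cfg$grid
  grid <- radial_grid(
    bw = if (!is.null(g$bw_nm)) g$bw_nm else 20,
    r_max = if (!is.null(g$r_max_nm)) g$r_max_nm else 5000,
    h = if (!is.null(g$h_nm)) g$h_nm else 10000)

  s <- cfg$solver
  t_in <- if (!is.null(s$t_in_ns)) s$t_in_ns else 500
  t_end <- if (!is.null(s$t_end_ns)) s$t_end_ns else 1e6
  schedule <- if (!is.null(s$schedule)) as.data.frame(s$schedule) else NULL
  config <- solver_config(
    t_in = t_in, t_end = t_end, schedule = schedule,
    flatten_threshold = if (!is.null(s$flatten_threshold))
      s$flatten_threshold else 0.05,
    record_times = s$record_times_ns)

  beam <- NULL
  if (!is.null(cfg$beam)) {
    b <- cfg$beam
    if (is.null(b$let_kev_um)) stop("config field `beam.let_kev_um` missing")
    beam <- beam_spec(let = b$let_kev_um, fluence = b$fluence_per_cm2,
                      dose = b$dose_gy,
                      rho = if (!is.null(b$rho)) b$rho else 1)
  }

  model <- NULL
  n_tracks <- 1000L
  if (!is.null(cfg$track)) {
    tr <- cfg$track
    if (!is.null(tr$n_tracks)) n_tracks <- as.integer(tr$n_tracks)
    seed <- tr$seed
    if (!is.null(tr$preset)) {
      model <- switch(tr$preset,
        low = low_let_preset(po2 = po2, t_in = t_in, seed = seed,
                             henry_M_per_atm = henry),
        high = high_let_preset(po2 = po2, t_in = t_in, seed = seed,
                               henry_M_per_atm = henry),
        stop("unknown track preset: ", tr$preset))
    } else if (!is.null(tr$yields)) {
      model <- track_model(
        yields = unlist(tr$yields), sigma = unlist(tr$sigma_nm),
        let = tr$let_kev_um, h = tr$h_nm, t_in = t_in,
        penumbra_fraction = if (!is.null(tr$penumbra_fraction))
          tr$penumbra_fraction else 0,
        penumbra_sigma = if (!is.null(tr$penumbra_sigma_nm))
          tr$penumbra_sigma_nm else NA,
        seed = seed)
    }
  }
  list(net = net, config = config, grid = grid, beam = beam,
       model = model, n_tracks = n_tracks, po2 = po2)
}

#' Save a configuration list back to JSON
#'
#' @param cfg a plain configuration list in the [load_config()] schema.
#' @param path output path.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
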