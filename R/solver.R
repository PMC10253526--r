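#' Staged time-step schedule
#'
#' The default schedule grows the step from 0.5 ns just after hand-over
#' to 10 ns beyond 1 ms:
#' \tabular{ll}{
#'   t_in - 1 us \tab 0.5 ns \cr
#'   1 - 10 us   \tab 1 ns   \cr
#'   10 - 100 us \tab 2.5 ns \cr
#'   100 us - 1 ms \tab 5 ns \cr
#'   >= 1 ms     \tab 10 ns  \cr
#' }
#'
#' @param t_in hand-over (start) time in ns.
#' @param t_end final time in ns.
#' @return `data.frame` with columns `t_start`, `t_end`, `dt` (ns),
#'   contiguous and covering `[t_in, t_end]`.
#' @export
default_schedule <- function(t_in = 500, t_end = 1e6) {
  breaks <- c(0, 1e3, 1e4, 1e5, 1e6, Inf)
  dts <- c(0.5, 0.5, 1, 2.5, 5, 10)  # dts[i+1] applies on [breaks[i], breaks[i+1])
  starts <- pmax(breaks[-length(breaks)], t_in)
  ends <- pmin(breaks[-1], t_end)
  keep <- starts < ends
  data.frame(t_start = starts[keep], t_end = ends[keep],
             dt = dts[-1][keep])
}

.validate_schedule <- function(schedule, t_in, t_end) {
  if (!all(c("t_start", "t_end", "dt") %in% names(schedule)))
    stop("schedule needs columns t_start, t_end, dt")
  s <- schedule[order(schedule$t_start), , drop = FALSE]
  if (any(s$dt <= 0)) stop("schedule dt values must be positive")
  if (s$t_start[1] > t_in || s$t_end[nrow(s)] < t_end)
    stop("schedule does not cover [t_in, t_end]")
  if (nrow(s) > 1 && any(abs(s$t_start[-1] - s$t_end[-nrow(s)]) > 1e-9))
    stop("schedule intervals must be contiguous (gap or overlap found)")
  s
}

#' Solver configuration
#'
#' @param t_in start (hand-over) time in ns, default 500.
#' @param t_end final time in ns.
#' @param schedule time-step schedule `data.frame`; defaults to
#'   [default_schedule()].
#' @param flatten_threshold relative-standard-deviation threshold below
#'   which a distribution is collapsed to its flat value (default 0.05).
#' @param record_times times (ns) at which snapshots and G-values are
#'   recorded; defaults to ~40 log-spaced points. Flattening is checked
#'   at these times.
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(t_in = 500, t_end = 1e6, schedule = NULL,
                          flatten_threshold = 0.05, record_times = NULL) {
  stopifnot(t_in < t_end, flatten_threshold > 0, flatten_threshold < 1)
  if (is.null(schedule)) schedule <- default_schedule(t_in, t_end)
  schedule <- .validate_schedule(schedule, t_in, t_end)
  if (is.null(record_times)) {
    record_times <- if (t_in > 0)
      unique(c(exp(seq(log(t_in), log(t_end), length.out = 40)), t_end))
    else seq(t_in, t_end, length.out = 40)
  }
  record_times <- sort(unique(pmin(pmax(record_times, t_in), t_end)))
  structure(list(t_in = t_in, t_end = t_end, schedule = schedule,
                 flatten_threshold = flatten_threshold,
                 record_times = record_times),
            class = "solver_config")
}

#' Assemble Crank-Nicolson matrices for cylindrical diffusion
#'
#' Discretises `d[A]/dt = D (d2/dr2 + (1/r) d/dr) [A]` at the bin
#' centres with the Crank-Nicolson average of current and next states,
#' giving the tridiagonal system `M a(n+1) = N a(n)`. Virtual points
#' outside the domain are eliminated by mirror conditions `a(-1) = a(0)`
#' (smoothness at the axis) and `a(J) = a(J-1)` (zero net flux at
#' `r_max`, the neighbouring-track symmetry condition), so a flat field
#' is an exact fixed point.
#'
#' @param D diffusion coefficient, nm^2/ns.
#' @param dt time step, ns.
#' @param grid a [radial_grid()] (uniform).
#' @return List with tridiagonal `M` and `N`, each a list
#'   `(lower, diag, upper)` of length J-1, J, J-1.
#' @export
assemble_cn_matrices <- function(D, dt, grid) {
  stopifnot(D >= 0, dt > 0)
  if (max(abs(diff(diff(grid$edges)))) > 1e-9 * grid$bw)
    stop("grid must be uniform")
  J <- grid$J
  r <- grid$centers
  bw <- grid$bw
  lam <- D * dt / (2 * bw^2)
  mu <- D * dt / (4 * bw * r)           # per-bin advective-like term
  lo <- -(lam - mu[-1])                 # coefficient of a[j-1], rows 2..J
  up <- -(lam + mu[-J])                 # coefficient of a[j+1], rows 1..J-1
  dg <- rep(1 + 2 * lam, J)
  # mirror eliminations: a(-1) = a(0) folds into row 1, a(J) = a(J-1) into row J
  dg[1] <- dg[1] - (lam - mu[1])
  dg[J] <- dg[J] - (lam + mu[J])
  M <- list(lower = lo, diag = dg, upper = up)
  N <- list(lower = -lo, diag = 2 - dg, upper = -up)
  list(M = M, N = N)
}

#' Solve a tridiagonal system (Thomas algorithm)
#'
#' @param M tridiagonal matrix as a list `(lower, diag, upper)`.
#' @param rhs right-hand-side vector.
#' @return Solution vector of `M x = rhs`.
#' @export
tridiagonal_solve <- function(M, rhs) {
  thomas_solve_cpp(M$lower, M$diag, M$upper, rhs)
}

#' Apply a tridiagonal matrix to a vector
#'
#' @param M tridiagonal matrix as a list `(lower, diag, upper)`.
#' @param x vector.
#' @return `M %*% x`.
#' @export
tridiagonal_apply <- function(M, x) {
  J <- length(x)
  M$diag * x + c(M$upper * x[-1], 0) + c(0, M$lower * x[-J])
}

#' Dense matrix form of a tridiagonal operator
#'
#' Convenience for validating the tridiagonal path against dense linear
#' algebra.
#'
#' @param M tridiagonal matrix as a list `(lower, diag, upper)`.
#' @return Dense square matrix.
#' @export
tridiag_as_matrix <- function(M) {
  J <- length(M$diag)
  m <- diag(M$diag, J)
  m[cbind(1:(J - 1), 2:J)] <- M$upper
  m[cbind(2:J, 1:(J - 1))] <- M$lower
  m
}

.cn_cache <- function(net, grid, dt) {
  lapply(setNames(net$species$D, net$species$name),
         function(D) assemble_cn_matrices(D, dt, grid))
}

#' One diffusion half-step (Crank-Nicolson) for all fields
#'
#' Advances every non-flattened field by its species' diffusion
#' coefficient; flattened fields are exact fixed points and are skipped.
#' Negative values produced by round-off are clamped to zero and counted
#' in the `clamped` attribute.
#'
#' @param state a [system_state()].
#' @param net a [reaction_network()].
#' @param dt time step, ns.
#' @param cache optional precomputed matrices from an internal cache.
#' @return Updated state (time unchanged; [advance()] owns the clock).
#' @export
diffusion_step <- function(state, net, dt, cache = NULL) {
  if (is.null(cache)) cache <- .cn_cache(net, state$grid, dt)
  clamped <- 0L
  for (s in colnames(state$conc)) {
    if (isTRUE(state$flattened[[s]])) next
    mats <- cache[[s]]
    a <- cn_step_cpp(mats$M$lower, mats$M$diag, mats$M$upper,
                     mats$N$lower, mats$N$diag, mats$N$upper,
                     state$conc[, s])
    neg <- a < 0
    if (any(neg)) {
      clamped <- clamped + sum(neg)
      a[neg] <- 0
    }
    state$conc[, s] <- a
  }
  attr(state, "clamped") <- clamped
  state
}

#' Bin-wise reaction increments (forward Euler)
#'
#' For every bin independently, sums the mass-action contributions of
#' all reactions consuming and producing each species over one explicit
#' step: `delta_A(r) = sum_reactions nu_A * k * [R1](r) * [R2](r) * dt`.
#' Continuum solutes (O2) enter with their fixed concentration;
#' same-species reactions consume two molecules per event.
#'
#' @param state a [system_state()].
#' @param net a [reaction_network()].
#' @param dt time step, ns.
#' @param compiled optional result of an internal network compilation.
#' @return J x n_species matrix of concentration increments (M).
#' @export
reaction_increments <- function(state, net, dt, compiled = NULL) {
  if (is.null(compiled)) compiled <- compile_network(net)
  J <- state$grid$J
  caug <- cbind(state$conc[, compiled$species, drop = FALSE],
                matrix(rep(compiled$continuum, each = J), nrow = J),
                rep(1, J))
  rates <- caug[, compiled$i1, drop = FALSE] * caug[, compiled$i2, drop = FALSE]
  (rates %*% compiled$KS) * dt
}

#' One reaction step (simultaneous explicit update)
#'
#' Increments are computed from the pre-step state only, then all fields
#' are updated at once. Updates that would drive a bin negative are
#' clamped to zero; the clamp count is reported (and must stay zero with
#' the default schedule).
#'
#' @inheritParams reaction_increments
#' @return Updated state with attribute `clamped`.
#' @export
reaction_step <- function(state, net, dt, compiled = NULL) {
  incr <- reaction_increments(state, net, dt, compiled)
  newc <- state$conc + incr
  neg <- newc < 0
  clamped <- sum(neg)
  if (clamped) newc[neg] <- 0
  state$conc <- newc
  attr(state, "clamped") <- clamped
  state
}

#' One operator-split step: diffusion then reactions
#'
#' Lie splitting with the diffusion sub-step first, both sub-steps using
#' the same `dt` taken from the schedule at the current time.
#'
#' @param state a [system_state()].
#' @param net a [reaction_network()].
#' @param config a [solver_config()] (supplies the schedule).
#' @param dt optional explicit step; defaults to the scheduled step at
#'   `state$time`, clipped so interval boundaries are hit exactly.
#' @return State advanced by `dt` with attribute `clamped` (total of
#'   both sub-steps).
#' @export
advance <- function(state, net, config, dt = NULL) {
  if (is.null(dt)) dt <- schedule_dt(config$schedule, state$time)
  st <- diffusion_step(state, net, dt)
  c1 <- attr(st, "clamped")
  st <- reaction_step(st, net, dt)
  c2 <- attr(st, "clamped")
  st$time <- state$time + dt
  attr(st, "clamped") <- c1 + c2
  st
}

#' Scheduled time step at a given time
#'
#' @param schedule schedule `data.frame`.
#' @param t current time, ns.
#' @return dt in ns, clipped so the step does not overrun the interval.
#' @export
schedule_dt <- function(schedule, t) {
  row <- which(schedule$t_start - 1e-9 <= t & t < schedule$t_end - 1e-9)
  if (!length(row)) stop("time ", t, " ns not covered by the schedule")
  row <- row[1]
  min(schedule$dt[row], schedule$t_end[row] - t)
}

.rel_sd <- function(v) {
  m <- mean(v)
  if (m == 0) return(0)
  sqrt(mean((v - m)^2)) / m   # population sd, unweighted over bins
}

#' Collapse nearly-flat distributions to their well-mixed value
#'
#' A field whose unweighted relative standard deviation over bins falls
#' below `threshold` is recast to the single mass-conserving value
#' `total_amount / (N_A * pi * r_max^2 * h)`; thereafter diffusion is
#' skipped for that field. A field with zero mean is flat at zero. Once
#' every field is flat the integrator is effectively a homogeneous
#' well-mixed kinetics solver ("phase III").
#'
#' @param state a [system_state()].
#' @param threshold relative standard deviation threshold (default 0.05).
#' @return State with updated fields and `flattened` flags.
#' @export
check_and_flatten <- function(state, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 1)
  vtot <- sum(state$grid$volumes_L)
  for (s in colnames(state$conc)) {
    if (isTRUE(state$flattened[[s]])) next
    v <- state$conc[, s]
    if (.rel_sd(v) < threshold) {
      flat <- total_amount(v, state$grid) / (.AVOGADRO * vtot)
      state$conc[, s] <- flat
      state$flattened[[s]] <- TRUE
    }
  }
  state
}

#' Run a full reaction-diffusion simulation
#'
#' Advances an initial radial state from `config$t_in` to `config$t_end`
#' under the staged schedule, alternating Crank-Nicolson diffusion and
#' explicit reaction sub-steps, checking the flattening criterion at
#' every recording time, and recording snapshots plus (if a beam is
#' given) G-values. Fully deterministic given its inputs.
#'
#' @param initial a [system_state()] with `time == config$t_in`.
#' @param net a [reaction_network()].
#' @param config a [solver_config()].
#' @param beam optional [beam_spec()] enabling G-value records.
#' @param snapshots logical: keep full state snapshots at record times
#'   (default TRUE; totals and G-values are always kept).
#' @return Object of class `radchem_run`: list with `times`, `states`
#'   (list of snapshots or NULL), `totals` (matrix, molecules/track),
#'   `gvalues` (matrix or NULL), and `manifest` (clamp counter,
#'   per-species flatten times, config echo).
#' @export
run_simulation <- function(initial, net, config, beam = NULL,
                           snapshots = TRUE) {
  if (abs(initial$time - config$t_in) > 1e-6)
    stop("initial state time must equal config$t_in")
  viol <- validate_network(net)
  if (length(viol)) stop("invalid network: ", paste(viol, collapse = "; "))
  compiled <- compile_network(net)
  spn <- colnames(initial$conc)
  state <- check_and_flatten(initial, config$flatten_threshold)
  rec <- config$record_times
  n_rec <- length(rec)
  states <- if (snapshots) vector("list", n_rec) else NULL
  totals <- matrix(NA_real_, n_rec, length(spn), dimnames = list(NULL, spn))
  gv <- if (!is.null(beam)) totals else NULL
  times <- numeric(n_rec)
  flat_times <- setNames(rep(NA_real_, length(spn)), spn)
  flat_times[state$flattened] <- state$time
  clamp_total <- 0L
  cache <- NULL
  cache_dt <- NA_real_

  record <- function(i, state) {
    times[i] <<- state$time
    totals[i, ] <<- state_totals(state)
    if (!is.null(beam)) gv[i, ] <<- gvalues(state, beam)
    if (snapshots) states[[i]] <<- state
  }

  i_rec <- 1L
  while (i_rec <= n_rec && rec[i_rec] <= state$time + 1e-9) {
    record(i_rec, state)
    i_rec <- i_rec + 1L
  }
  while (state$time < config$t_end - 1e-9) {
    dt <- schedule_dt(config$schedule, state$time)
    if (i_rec <= n_rec) dt <- min(dt, rec[i_rec] - state$time)
    all_flat <- all(state$flattened)
    if (!all_flat) {
      if (!identical(dt, cache_dt)) {
        cache <- .cn_cache(net, state$grid, dt)
        cache_dt <- dt
      }
      state <- diffusion_step(state, net, dt, cache)
      clamp_total <- clamp_total + attr(state, "clamped")
    }
    state <- reaction_step(state, net, dt, compiled)
    clamp_total <- clamp_total + attr(state, "clamped")
    state$time <- state$time + dt
    if (i_rec <= n_rec && state$time >= rec[i_rec] - 1e-9) {
      was_flat <- state$flattened
      state <- check_and_flatten(state, config$flatten_threshold)
      newly <- state$flattened & !was_flat
      flat_times[newly] <- state$time
      record(i_rec, state)
      i_rec <- i_rec + 1L
    }
  }
  structure(list(
    times = times, states = states, totals = totals, gvalues = gv,
    manifest = list(
      t_in = config$t_in, t_end = config$t_end,
      flatten_threshold = config$flatten_threshold,
      schedule = config$schedule,
      clamped = clamp_total,
      flatten_times_ns = flat_times,
      species = spn,
      po2 = if (!is.null(net$po2)) net$po2 else NA_real_,
      n_tracks = initial$n_tracks)),
    class = "radchem_run")
}

#' @export
print.radchem_run <- function(x, ...) {
  cat(sprintf("<radchem_run> %d records from %g to %g ns; clamped = %d\n",
              length(x$times), min(x$times), max(x$times),
              x$manifest$clamped))
  invisible(x)
}
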