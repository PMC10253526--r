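## Independent well-mixed kinetics engines. These deliberately share no
## code with the radial solver: the mass-action derivative is a plain
## per-reaction loop and the deterministic integrator is an adaptive
## embedded Runge-Kutta pair, not Crank-Nicolson/forward Euler.

.mass_action_deriv <- function(conc, net) {
  d <- setNames(rep(0, length(conc)), names(conc))
  for (i in seq_len(nrow(net$reactions))) {
    rx <- net$reactions[i, ]
    k <- rx$k * 1e-9                      # lab units -> per ns
    r1 <- rx$r1
    r2 <- rx$r2
    c1 <- if (r1 %in% names(conc)) conc[[r1]] else net$continuum[[r1]]
    rate <- k * c1
    if (!is.na(r2)) {
      c2 <- if (r2 %in% names(conc)) conc[[r2]] else net$continuum[[r2]]
      rate <- rate * c2
    }
    if (rate == 0) next
    if (r1 %in% names(d)) d[[r1]] <- d[[r1]] - rate
    if (!is.na(r2) && r2 %in% names(d)) d[[r2]] <- d[[r2]] - rate
    for (p in rx$products[[1]]) if (p %in% names(d)) d[[p]] <- d[[p]] + rate
  }
  d
}

## Cash-Karp embedded RK5(4) tableau.
.CK <- list(
  a = c(1 / 5, 3 / 10, 3 / 5, 1, 7 / 8),
  b = list(c(1 / 5),
           c(3 / 40, 9 / 40),
           c(3 / 10, -9 / 10, 6 / 5),
           c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
           c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592, 253 / 4096)),
  c5 = c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771),
  c4 = c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4))

#' Deterministic well-mixed kinetics (adaptive Runge-Kutta oracle)
#'
#' Integrates the mass-action rate equations of a network with an
#' embedded Cash-Karp Runge-Kutta 5(4) pair and proportional step-size
#' control. Serves as an independent reference for the radial solver's
#' homogeneous limit.
#'
#' @param conc0 named molarities at `t0`.
#' @param net a [reaction_network()].
#' @param t_end final time, ns.
#' @param t0 start time, ns (default 0).
#' @param record_times output times (ns); defaults to 50 points.
#' @param rtol,atol relative/absolute error tolerances.
#' @return `data.frame` with column `time_ns` and one column per species.
#' @export
ode_wellmixed <- function(conc0, net, t_end, t0 = 0, record_times = NULL,
                          rtol = 1e-8, atol = 1e-16) {
  stopifnot(rtol > 0, atol > 0, t_end > t0)
  if (is.null(record_times))
    record_times <- seq(t0, t_end, length.out = 50)
  record_times <- sort(unique(pmin(pmax(record_times, t0), t_end)))
  y <- conc0
  t <- t0
  out <- matrix(NA_real_, length(record_times), length(y),
                dimnames = list(NULL, names(y)))
  i_rec <- 1L
  while (i_rec <= length(record_times) && record_times[i_rec] <= t) {
    out[i_rec, ] <- y
    i_rec <- i_rec + 1L
  }
  h <- (t_end - t0) / 1e4
  k <- vector("list", 6)
  n_reject <- 0L
  while (t < t_end - 1e-12) {
    h <- min(h, t_end - t)
    if (i_rec <= length(record_times))
      h <- min(h, record_times[i_rec] - t)
    k[[1]] <- .mass_action_deriv(y, net)
    for (s in 1:5) {
      yy <- y
      for (j in seq_len(s)) yy <- yy + h * .CK$b[[s]][j] * k[[j]]
      k[[s + 1]] <- .mass_action_deriv(yy, net)
    }
    y5 <- y
    y4 <- y
    for (j in 1:6) {
      y5 <- y5 + h * .CK$c5[j] * k[[j]]
      y4 <- y4 + h * .CK$c4[j] * k[[j]]
    }
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (is.na(err)) stop("well-mixed integration failed (non-finite state)")
    if (err <= 1) {
      t <- t + h
      y <- pmax(y5, 0)
      while (i_rec <= length(record_times) &&
             record_times[i_rec] <= t + 1e-12) {
        out[i_rec, ] <- y
        i_rec <- i_rec + 1L
      }
    } else {
      n_reject <- n_reject + 1L
      if (n_reject > 1e6) stop("well-mixed integration failed to converge")
    }
    fac <- if (err > 0) 0.9 * err^(-0.2) else 5
    h <- h * min(5, max(0.2, fac))
    if (h <= 0 || !is.finite(h)) stop("step size collapsed in ode_wellmixed")
  }
  data.frame(time_ns = record_times, out, check.names = FALSE)
}

#' Exact stochastic well-mixed kinetics (Gillespie direct method)
#'
#' Propensities follow the network's conventions: for distinct
#' bimolecular reactants `k/(N_A V) n1 n2`, for same-species reactions
#' `k/(N_A V) nA (nA - 1)` (each event consumes two molecules), for a
#' continuum partner `k [X] n1`, and `k n1` for unimolecular channels.
#'
#' @param counts0 named integer molecule counts.
#' @param volume_L system volume in litres.
#' @param net a [reaction_network()].
#' @param t_end final time, ns.
#' @param seed random seed.
#' @param record_times output grid (ns); the state is piecewise constant
#'   between events.
#' @return `data.frame` with `time_ns` and per-species counts.
#' @export
ssa_wellmixed <- function(counts0, volume_L, net, t_end, seed = NULL,
                          record_times = NULL) {
  stopifnot(volume_L > 0, all(counts0 >= 0))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(record_times))
    record_times <- seq(0, t_end, length.out = 50)
  record_times <- sort(unique(pmin(record_times, t_end)))
  n <- counts0
  t <- 0
  nav <- .AVOGADRO * volume_L
  nR <- nrow(net$reactions)
  rx <- net$reactions
  kns <- rx$k * 1e-9
  out <- matrix(NA_real_, length(record_times), length(n),
                dimnames = list(NULL, names(n)))
  i_rec <- 1L
  flush <- function(upto) {
    while (i_rec <= length(record_times) && record_times[i_rec] <= upto) {
      out[i_rec, ] <<- n
      i_rec <<- i_rec + 1L
    }
  }
  repeat {
    a <- numeric(nR)
    for (i in seq_len(nR)) {
      r1 <- rx$r1[i]; r2 <- rx$r2[i]
      if (is.na(r2)) {
        a[i] <- kns[i] * n[[r1]]
      } else if (!(r2 %in% names(n))) {
        a[i] <- kns[i] * net$continuum[[r2]] * n[[r1]]
      } else if (!(r1 %in% names(n))) {
        a[i] <- kns[i] * net$continuum[[r1]] * n[[r2]]
      } else if (r1 == r2) {
        a[i] <- kns[i] / nav * n[[r1]] * (n[[r1]] - 1)
      } else {
        a[i] <- kns[i] / nav * n[[r1]] * n[[r2]]
      }
    }
    a0 <- sum(a)
    if (a0 <= 0) break
    tau <- rexp(1, a0)
    if (t + tau > t_end) break
    flush(t + tau)
    t <- t + tau
    i <- sample.int(nR, 1L, prob = a)
    for (s in c(rx$r1[i], rx$r2[i]))
      if (!is.na(s) && s %in% names(n)) n[[s]] <- n[[s]] - 1
    for (p in rx$products[[i]])
      if (p %in% names(n)) n[[p]] <- n[[p]] + 1
    if (any(n < 0)) { # same-species channel fired with n = 1; undo guard
      n[n < 0] <- 0
    }
  }
  flush(t_end)
  data.frame(time_ns = record_times, out, check.names = FALSE)
}

#' Well-mixed comparison volume from fluence
#'
#' The average volume per track is the per-track surface `S = 1/Phi`
#' times the target height: `V = h / Phi`.
#'
#' @param beam a [beam_spec()] with fluence set.
#' @param h target height in nm.
#' @return Volume in litres.
#' @export
volume_from_fluence <- function(beam, h) {
  s <- surface_from_fluence(beam)          # cm^2
  v_cm3 <- s$S_cm2 * (h * 1e-7)            # nm -> cm
  v_cm3 / 1000
}
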