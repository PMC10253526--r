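test_that("default schedule reproduces the staged dt table exactly", {
  s <- default_schedule(t_in = 500, t_end = 2e6)
  expect_equal(s$t_start, c(500, 1e3, 1e4, 1e5, 1e6))
  expect_equal(s$t_end,   c(1e3, 1e4, 1e5, 1e6, 2e6))
  expect_equal(s$dt,      c(0.5, 1, 2.5, 5, 10))
  # truncation to shorter windows keeps the same intervals
  s2 <- default_schedule(t_in = 600, t_end = 5e4)
  expect_equal(s2$dt, c(0.5, 1, 2.5))
  expect_equal(s2$t_start[1], 600)
  expect_equal(s2$t_end[3], 5e4)
  expect_equal(schedule_dt(s, 500), 0.5)
  expect_equal(schedule_dt(s, 5e4), 2.5)
  expect_equal(schedule_dt(s, 999.9), 0.1)  # clipped to land on the boundary
  expect_error(schedule_dt(s, 3e6), "not covered")
})

test_that("Crank-Nicolson matrices: degenerate and fixed-point structure", {
  g <- small_grid(bw = 50, r_max = 400, h = 1000)
  m0 <- assemble_cn_matrices(0, 0.5, g)
  expect_equal(m0$M$diag, rep(1, g$J))
  expect_true(all(m0$M$lower == 0) && all(m0$M$upper == 0))
  expect_equal(m0$N$diag, rep(1, g$J))

  m <- assemble_cn_matrices(3.3, 0.7, g)
  a <- rep(2.4e-7, g$J)
  # flat field: N a = M a, so the update is the identity
  expect_equal(tridiagonal_apply(m$N, a), tridiagonal_apply(m$M, a))
  expect_equal(tridiagonal_solve(m$M, tridiagonal_apply(m$N, a)), a,
               tolerance = 1e-13)
})

test_that("tridiagonal path matches dense linear algebra", {
  # full CN update vs dense inversion oracle on a small grid
  g <- small_grid(bw = 50, r_max = 400, h = 1000)
  m <- assemble_cn_matrices(2.1, 0.9, g)
  dense <- solve(tridiag_as_matrix(m$M)) %*% tridiag_as_matrix(m$N)
  for (j in c(1, 4, 8)) {
    e <- replace(rep(0, g$J), j, 1)
    expect_equal(tridiagonal_solve(m$M, tridiagonal_apply(m$N, e)),
                 as.vector(dense %*% e), tolerance = 1e-12)
  }

  # known 3x3 system
  M3 <- list(lower = c(1, 2), diag = c(4, 5, 6), upper = c(1, 1))
  rhs <- c(7, 8, 9)
  expect_equal(tridiagonal_solve(M3, rhs),
               solve(tridiag_as_matrix(M3), rhs), tolerance = 1e-12)

  # random diagonally dominant systems up to the production size
  set.seed(1)
  for (J in c(100, 250)) {
    M <- list(lower = runif(J - 1, -1, 1), diag = runif(J, 3, 4),
              upper = runif(J - 1, -1, 1))
    rhs <- rnorm(J)
    expect_lt(max(abs(tridiagonal_solve(M, rhs) -
                      solve(tridiag_as_matrix(M), rhs))), 1e-10)
  }

  id_rhs <- c(7, 8, 9)
  expect_equal(tridiagonal_solve(list(lower = c(0, 0), diag = rep(1, 3),
                                      upper = c(0, 0)), id_rhs), id_rhs)
})

test_that("diffusion: moment growth, mass conservation, flat fixed point", {
  net <- net_ab_c(D = c(A = 2.8, B = 1, C = 1))
  g <- radial_grid(bw = 20, r_max = 5000, h = 10000)
  st <- gaussian_state(g, "A", peak = 1e-6, sigma = 100)
  st$conc <- cbind(st$conc, B = 0, C = 0)
  st$flattened <- setNames(rep(FALSE, 3), c("A", "B", "C"))
  colnames(st$conc) <- c("A", "B", "C")

  w <- st$conc[, "A"] * g$volumes_L
  m2_0 <- sum(w * g$centers^2) / sum(w)
  n0 <- state_totals(st)["A"]
  st1 <- diffusion_step(st, net, 0.5)
  w <- st1$conc[, "A"] * g$volumes_L
  m2_1 <- sum(w * g$centers^2) / sum(w)
  expect_equal(m2_1 - m2_0, 4 * 2.8 * 0.5, tolerance = 1e-2)

  stk <- st
  for (i in 1:1000) stk <- diffusion_step(stk, net, 0.5)
  expect_lt(abs(state_totals(stk)["A"] / n0 - 1), 1e-3)

  # flat fields are exact fixed points and flattened fields are skipped
  flat <- flat_state(small_grid(), list(A = 1e-7, B = 2e-7, C = 0))
  out <- diffusion_step(flat, net, 5)
  expect_equal(out$conc, flat$conc)
})

test_that("free diffusion matches the 2-D heat kernel at second order in bw", {
  D <- 2; sigma0 <- 200; T_end <- 2000; dt <- 2
  kernel_err <- function(bw) {
    g <- radial_grid(bw = bw, r_max = 3200, h = 1000)
    net <- net_diffusion_only("A", D)
    st <- gaussian_state(g, "A", peak = 1e-6, sigma = sigma0)
    for (i in seq_len(T_end / dt)) st <- diffusion_step(st, net, dt)
    s2 <- sigma0^2 + 2 * D * T_end
    exact <- 1e-6 * sigma0^2 / s2 * exp(-g$centers^2 / (2 * s2))
    sqrt(sum((st$conc[, 1] - exact)^2 * g$volumes_L) /
         sum(exact^2 * g$volumes_L))
  }
  errs <- vapply(c(80, 40, 20), kernel_err, 0)
  expect_lt(errs[3], 2e-3)                 # resolved limit is accurate
  expect_gt(errs[1] / errs[2], 2.5)        # ~4 expected for O(bw^2)
  expect_gt(errs[2] / errs[3], 2.5)
  expect_lt(errs[1] / errs[2], 6)
  expect_lt(errs[2] / errs[3], 6)
})

test_that("reaction increments follow bin-wise mass action", {
  g <- small_grid()
  net <- net_ab_c(k = 1e10)
  st <- flat_state(g, list(A = 0, B = 0, C = 0))
  st$conc[3, c("A", "B")] <- 1e-6
  incr <- reaction_increments(st, net, 0.5)
  # k = 1e10 /M/s = 10 /M/ns; dA = -k [A][B] dt = -5e-12 in that bin only
  expect_equal(unname(incr[3, "A"]), -5e-12)
  expect_equal(unname(incr[3, "B"]), -5e-12)
  expect_equal(unname(incr[3, "C"]), +5e-12)
  expect_true(all(incr[-3, ] == 0))

  expect_true(all(reaction_increments(flat_state(g, list(A = 0, B = 0, C = 0)),
                                      net, 0.5) == 0))

  # continuum partner enters at its fixed concentration
  netc <- reaction_network(toy_species(c("A", "P")),
                           toy_reactions("A", "X", list("P"), 1e10),
                           continuum = c(X = 1e-4))
  stc <- flat_state(g, list(A = 1e-6, P = 0))
  ic <- reaction_increments(stc, netc, 1)
  expect_equal(unname(ic[1, "A"]), -10 * 1e-6 * 1e-4 * 1)
  expect_equal(ic[, "P"], -ic[, "A"])
})

test_that("explicit kinetics reproduce closed-form solutions", {
  g <- small_grid()
  # A + B -> C from equal concentrations: 1/[A](t) = 1/c0 + k t
  k_lab <- 1e10; k <- k_lab * 1e-9; c0 <- 1e-4; T_end <- 5000; dt <- 0.5
  net <- net_ab_c(k = k_lab)
  st <- flat_state(g, list(A = c0, B = c0, C = 0))
  for (i in seq_len(T_end / dt)) st <- reaction_step(st, net, dt)
  expect_equal(unname(st$conc[1, "A"]), 1 / (1 / c0 + k * T_end), tolerance = 1e-3)
  expect_equal(unname(st$conc[1, "C"]), unname(c0 - st$conc[1, "A"]), tolerance = 1e-9)

  # A + A -> B: 1/[A] slope is 2k (two molecules consumed per event)
  net2 <- net_aa_b(k = k_lab)
  st2 <- flat_state(g, list(A = c0, B = 0))
  for (i in seq_len(T_end / dt)) st2 <- reaction_step(st2, net2, dt)
  slope <- (1 / st2$conc[1, "A"] - 1 / c0) / T_end
  expect_equal(unname(slope), 2 * k, tolerance = 1e-3)
  # stoichiometry: two A per B produced
  expect_equal(unname(c0 - st2$conc[1, "A"]), unname(2 * st2$conc[1, "B"]), tolerance = 1e-9)

  # zero rate constant is the identity
  net0 <- net_ab_c(k = 0)
  st0 <- flat_state(g, list(A = c0, B = c0, C = 0))
  expect_equal(reaction_step(st0, net0, 10)$conc, st0$conc)
})

test_that("operator splitting degenerates and converges as expected", {
  g <- small_grid()
  cfg <- solver_config(t_in = 0, t_end = 100,
                       schedule = fixed_schedule(0, 100, 10))

  # no reactions + flat field: advance is the identity
  netn <- net_diffusion_only("A", 1)
  flat <- flat_state(g, list(A = 1e-7))
  adv <- advance(flat, netn, cfg)
  expect_equal(adv$conc, flat$conc, tolerance = 1e-13)
  expect_equal(adv$time, 10)

  # D = 0: splitting equals pure reaction evolution
  net0 <- net_ab_c(k = 1e10, D = c(A = 0, B = 0, C = 0))
  st <- flat_state(g, list(A = 1e-4, B = 1e-4, C = 0))
  a <- advance(st, net0, cfg)
  r <- reaction_step(st, net0, 10)
  expect_equal(a$conc, r$conc)

  # Richardson: halving dt shrinks the splitting error (first-order Lie)
  netd <- net_ab_c(k = 5e10, D = c(A = 2, B = 1, C = 0.5))
  init <- gaussian_state(g, "A", peak = 5e-5, sigma = 120)
  init$conc <- cbind(init$conc, B = 5e-5 * exp(-g$centers^2 / (2 * 180^2)),
                     C = 0)
  colnames(init$conc) <- c("A", "B", "C")
  init$flattened <- setNames(rep(FALSE, 3), c("A", "B", "C"))
  run_dt <- function(dt) {
    st <- init
    for (i in seq_len(400 / dt)) st <- advance(st, netd, cfg, dt = dt)
    st$conc
  }
  ref <- run_dt(1.25)
  err10 <- max(abs(run_dt(10) - ref))
  err5 <- max(abs(run_dt(5) - ref))
  expect_lt(err5, 0.75 * err10)
})

test_that("flattening control collapses near-uniform fields conservatively", {
  g <- small_grid(bw = 50, r_max = 200, h = 1000)  # J = 4
  st <- system_state(g, "A", matrix(c(1, 1, 1, 2) * 1e-7, ncol = 1))
  # relative std of (1,1,1,2) is 0.346: far above a 5% threshold
  out <- check_and_flatten(st, 0.05)
  expect_false(out$flattened[["A"]])
  expect_equal(out$conc, st$conc)
  # but a 40% threshold collapses it, conserving the total amount
  out2 <- check_and_flatten(st, 0.4)
  expect_true(out2$flattened[["A"]])
  expect_equal(state_totals(out2), state_totals(st), tolerance = 1e-12)
  expect_equal(var(out2$conc[, 1]), 0)

  # exactly constant field: flattened with the value preserved
  stc <- flat_state(g, list(A = 3e-8))
  outc <- check_and_flatten(stc, 0.05)
  expect_true(outc$flattened[["A"]])
  expect_equal(outc$conc[, 1], rep(3e-8, g$J))

  # zero field counts as flat at zero
  stz <- flat_state(g, list(A = 0))
  expect_true(check_and_flatten(stz, 0.05)$flattened[["A"]])
})

test_that("run_simulation: bookkeeping, determinism and degenerate inputs", {
  net <- build_default_network()
  g <- small_grid()
  cfg <- solver_config(t_in = 500, t_end = 2000,
                       record_times = c(1000, 2000))
  zero <- system_state(g, STANDARD_SPECIES, time = 500)
  run <- run_simulation(zero, net, cfg)
  expect_equal(run$times, c(1000, 2000))
  expect_true(all(run$totals == 0))
  expect_identical(run$manifest$clamped, 0L)

  # deterministic: identical inputs give identical outputs
  st <- flat_state(g, setNames(as.list(runif(10, 1e-8, 1e-7)),
                               STANDARD_SPECIES), time = 500)
  r1 <- run_simulation(st, net, cfg, snapshots = FALSE)
  r2 <- run_simulation(st, net, cfg, snapshots = FALSE)
  expect_identical(r1$totals, r2$totals)

  # time mismatch and schedule gaps are configuration errors
  expect_error(run_simulation(system_state(g, STANDARD_SPECIES, time = 0),
                              net, cfg), "t_in")
  gap <- data.frame(t_start = c(500, 1200), t_end = c(1000, 2000),
                    dt = c(0.5, 1))
  expect_error(solver_config(t_in = 500, t_end = 2000, schedule = gap),
               "contiguous")
  expect_error(solver_config(t_in = 500, t_end = 2000,
                             schedule = fixed_schedule(600, 2000, 1)),
               "cover")
})
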