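# Brute-force time-driven two-body integrator: the independent oracle for
# event times and impulse outcomes. Crossings are located by stepping the
# (exactly linear) inter-particle distance on a fine grid and bisecting;
# no quadratic root formula is shared with the engine.

# boundaries: ascending surface distances; energy: per-region potential,
# length(boundaries) + 1, innermost first (use Inf for forbidden cores).
oracle_two_body <- function(state, mass, boundaries, energy, tmax,
                            dt = 5e-4, iters = 200) {
  pos <- state$pos; vel <- state$vel; L <- state$box
  rdist <- function(p) {
    d <- p[1, ] - p[2, ]
    d <- d - L * round(d / L)
    sqrt(sum(d^2))
  }
  region_of <- function(r) findInterval(r, boundaries) + 1L
  t <- 0
  reg <- region_of(rdist(pos))
  ev_t <- numeric(0); ev_vel <- list()
  while (t < tmax) {
    step <- min(dt, tmax - t)
    r_new <- rdist(pos + vel * step)
    reg_new <- region_of(r_new)
    if (reg_new == reg) {
      pos <- pos + vel * step
      t <- t + step
      next
    }
    bidx <- if (reg_new < reg) reg - 1L else reg
    d <- boundaries[bidx]
    f0 <- rdist(pos) - d
    lo <- 0; hi <- step
    for (it in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (((rdist(pos + vel * mid) - d) > 0) == (f0 > 0)) lo <- mid else hi <- mid
    }
    s <- (lo + hi) / 2
    pos <- pos + vel * s
    t <- t + s
    dvec <- pos[1, ] - pos[2, ]
    dvec <- dvec - L * round(dvec / L)
    nh <- dvec / sqrt(sum(dvec^2))
    vr <- sum((vel[1, ] - vel[2, ]) * nh)
    mu <- mass[1] * mass[2] / sum(mass)
    target <- if (vr < 0) reg - 1L else reg + 1L
    du <- energy[target] - energy[reg]
    if (!is.finite(du) || 0.5 * mu * vr^2 <= du) {
      vr2 <- -vr
    } else {
      vr2 <- sign(vr) * sqrt(vr^2 - 2 * du / mu)
      reg <- target
    }
    dp <- mu * (vr2 - vr)
    vel[1, ] <- vel[1, ] + dp * nh / mass[1]
    vel[2, ] <- vel[2, ] - dp * nh / mass[2]
    ev_t <- c(ev_t, t)
    ev_vel[[length(ev_vel) + 1]] <- vel
  }
  list(times = ev_t, velocities = ev_vel)
}
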