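# Shared fixtures: one force field per suite, small state constructors,
# and synthetic chain-shape geometries.

FF <- load_forcefield()
FF_ORIG <- load_forcefield(hbond_mode = "original", salt_bridge_enhanced = FALSE)

make_state <- function(pos, vel = pos * 0, box = 100, time = 0, tstar = NULL) {
  structure(list(pos = pos, vel = vel, box = box, time = time, tstar = tstar),
            class = "prime_state")
}

total_kinetic <- function(state, mass) {
  sum(0.5 * mass * rowSums(state$vel^2))
}

# Synthetic CaH traces with prescribed turn patterns for the 26-residue
# Abeta fragment; other spheres are placed in fixed small offsets around
# CaH (the classifier uses CaH and side spheres only).
synthetic_shape_positions <- function(topology, shape, strand_sep = 5,
                                      step = 3.5) {
  nres <- topology$n_residues
  stopifnot(topology$n_chains == 1, nres == 26)
  ca <- matrix(0, nres, 3)
  walk <- function(from, idx, dir) {
    for (q in seq_along(idx)) ca[idx[q], ] <<- from + q * dir * step
    ca[idx[length(idx)], ]
  }
  if (shape == "extended") {
    ca[, 1] <- seq_len(nres) * step
  } else if (shape == "U") {
    # strand out (1..7), central turn (8..10, Abeta 24..26), strand back
    ca[1:7, 1] <- (1:7) * step
    ca[8, ] <- c(7 * step + 2.5, 1.8, 0)
    ca[9, ] <- c(7 * step + 3.3, strand_sep / 2, 0)
    ca[10, ] <- c(7 * step + 2.5, strand_sep - 1.8, 0)
    ca[11:26, 1] <- (7:(-8)) * step
    ca[11:26, 2] <- strand_sep
  } else if (shape == "S") {
    ca[1:7, 1] <- (1:7) * step
    ca[8, ] <- c(7 * step + 2.5, 1.8, 0)
    ca[9, ] <- c(7 * step + 3.3, strand_sep / 2, 0)
    ca[10, ] <- c(7 * step + 2.5, strand_sep - 1.8, 0)
    ca[11:20, 1] <- (7 - (1:10)) * step
    ca[11:20, 2] <- strand_sep
    # second turn at 21..22 (Abeta 37..38), C-terminal strand leaves the core
    ca[21, ] <- c(ca[20, 1] - 2.5, strand_sep + 1.8, 0)
    ca[22, ] <- c(ca[20, 1] - 3.3, 1.5 * strand_sep, 0)
    ca[23:26, 1] <- ca[20, 1] - 2.5 + (1:4) * step
    ca[23:26, 2] <- 2 * strand_sep
  } else if (shape == "triangular") {
    ca[1:7, 1] <- (1:7) * step
    ca[8, ] <- c(7 * step + 2.5, 1.8, 0)
    ca[9, ] <- c(7 * step + 3.3, strand_sep / 2, 0)
    ca[10, ] <- c(7 * step + 2.5, strand_sep - 1.8, 0)
    ca[11:16, 1] <- (7 - (1:6)) * step
    ca[11:16, 2] <- strand_sep
    # extra turn near residue 17 (Abeta 33): third leg turns back by 130
    # degrees, closing the triangle
    th <- 130 * pi / 180
    dir3 <- c(-cos(th), -sin(th), 0)  # incoming direction is -x
    for (q in 1:10) ca[16 + q, ] <- ca[16, ] + q * step * dir3
  } else stop("unknown shape")
  rsi <- residue_sphere_index(topology)
  pos <- matrix(0, nrow(topology$spheres), 3)
  for (g in seq_len(nres)) {
    pos[rsi[g, "CA"], ] <- ca[g, ]
    pos[rsi[g, "NH"], ] <- ca[g, ] + c(-0.9, 0, 1.0)
    pos[rsi[g, "CO"], ] <- ca[g, ] + c(0.9, 0, 1.0)
    if (!is.na(rsi[g, "R"])) pos[rsi[g, "R"], ] <- ca[g, ] + c(0, 0, -1.6)
  }
  pos
}
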