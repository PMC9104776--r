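# Independent brute-force oracles: plain double loops, no shared code
# with the package's estimators.

oracle_min_image <- function(d, box) d - box * round(d / box)

# O(N^2) pair-distance histogram between index sets (unordered pairs)
oracle_pair_counts <- function(coords_list, box, ia, ib, nbins, dx,
                               excl = NULL) {
  counts <- numeric(nbins)
  is_excl <- function(i, j) {
    if (is.null(excl) || nrow(excl) == 0L) return(FALSE)
    any((excl[, 1] == i & excl[, 2] == j) | (excl[, 1] == j & excl[, 2] == i))
  }
  same <- setequal(ia, ib)
  for (pos in coords_list) {
    for (p in seq_along(ia)) {
      qs <- if (same) seq_along(ib)[-seq_len(p)] else seq_along(ib)
      for (q in qs) {
        i <- ia[p]; j <- ib[q]
        if (i == j || is_excl(i, j)) next
        d <- oracle_min_image(pos[i, ] - pos[j, ], box)
        r <- sqrt(sum(d^2))
        bin <- floor(r / dx) + 1L
        if (bin >= 1L && bin <= nbins) counts[bin] <- counts[bin] + 1
      }
    }
  }
  counts
}

oracle_bond_hist <- function(coords_list, box, pairs, nbins, dx) {
  counts <- numeric(nbins)
  for (pos in coords_list) {
    for (b in seq_len(nrow(pairs))) {
      d <- oracle_min_image(pos[pairs[b, 1], ] - pos[pairs[b, 2], ], box)
      bin <- floor(sqrt(sum(d^2)) / dx) + 1L
      if (bin >= 1L && bin <= nbins) counts[bin] <- counts[bin] + 1
    }
  }
  counts
}

oracle_angle_hist <- function(coords_list, box, triples, nbins, dtheta) {
  counts <- numeric(nbins)
  for (pos in coords_list) {
    for (a in seq_len(nrow(triples))) {
      u <- oracle_min_image(pos[triples[a, 1], ] - pos[triples[a, 2], ], box)
      v <- oracle_min_image(pos[triples[a, 3], ] - pos[triples[a, 2], ], box)
      ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      th <- acos(max(-1, min(1, ct))) * 180 / pi
      bin <- min(nbins, floor(th / dtheta) + 1L)
      counts[bin] <- counts[bin] + 1
    }
  }
  counts
}

# numerical gradient of the total potential energy w.r.t. one coordinate
oracle_num_force <- function(system, i, d, h = 1e-6, r_cut = 1.0) {
  perturb <- function(s) {
    ep <- compute_forces(s, r_cut)$epot
    ep
  }
  sp <- system; sp$positions[i, d] <- sp$positions[i, d] + h
  sm <- system; sm$positions[i, d] <- sm$positions[i, d] - h
  -(perturb(sp) - perturb(sm)) / (2 * h)
}

# list-of-matrices view of a cg_traj for the oracles
traj_frames <- function(traj) {
  nf <- dim(traj$coords)[1]
  lapply(seq_len(nf), function(f) traj$coords[f, , , drop = TRUE])
}

# a small deterministic 3-type toy system used across simulator tests
toy_pair_system <- function(r = 0.5, eps = 1.0, sigma = 0.34, box = 3) {
  tab <- lj_table(eps, sigma, x0 = 0.005, dx = 0.005, n = 240, r_cut = 1.0)
  cg_system(rbind(c(1, 1, 1), c(1 + r, 1, 1)), c(72, 72), c("LJ", "LJ"),
            rep(box, 3), nonbonded = list("LJ-LJ" = tab))
}
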