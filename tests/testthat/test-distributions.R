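test_that("RDF matches the brute-force pair-counting oracle bin-exactly", {
  set.seed(21)
  box <- c(10, 10, 10)
  n <- 40
  frames <- lapply(1:3, function(i) {
    cg_frame(matrix(runif(3 * n, 0, 10), n, 3), rep(1, n),
             rep(c("A", "B"), each = n / 2), box)
  })
  traj <- cg_traj(frames)
  dx <- 0.5; r_max <- 5
  nbins <- floor(r_max / dx)
  for (case in list(list(a = "A", b = "B"), list(a = "A", b = "A"))) {
    g <- radial_distribution(traj, case$a, case$b, r_max, dx)
    ia <- which(traj$types %in% case$a); ib <- which(traj$types %in% case$b)
    counts <- oracle_pair_counts(traj_frames(traj), box, ia, ib, nbins, dx)
    r_mid <- (seq_len(nbins) - 0.5) * dx
    npair <- if (case$a == case$b) length(ia) * (length(ia) - 1) / 2 else
      length(ia) * length(ib)
    ideal <- 3 * npair * 4 * pi * r_mid^2 * dx / prod(box)
    expect_equal(g$values, counts / ideal, tolerance = 1e-12)
  }
})

test_that("RDF of an ideal gas is 1 within sampling noise", {
  set.seed(5)
  n <- 200
  frames <- lapply(1:40, function(i)
    cg_frame(matrix(runif(3 * n, 0, 4), n, 3), rep(1, n), rep("I", n),
             c(4, 4, 4)))
  g <- radial_distribution(cg_traj(frames), "I", "I", 2, 0.05)
  x <- tab_grid(g)
  expect_lt(max(abs(g$values[x > 0.5] - 1)), 0.1)
  # long-range limit: mean over the last 20% of the range near 1
  expect_lt(abs(mean(g$values[x > 1.6]) - 1), 0.05)
})

test_that("RDF is frame-average idempotent and symmetric in the type pair", {
  set.seed(6)
  n <- 30
  frames <- lapply(1:4, function(i)
    cg_frame(matrix(runif(3 * n, 0, 6), n, 3), rep(1, n),
             rep(c("A", "B"), n / 2), c(6, 6, 6)))
  traj <- cg_traj(frames)
  doubled <- cg_traj(c(frames, frames))
  g1 <- radial_distribution(traj, "A", "B", 3, 0.1)
  expect_equal(radial_distribution(doubled, "A", "B", 3, 0.1)$values,
               g1$values)
  expect_equal(radial_distribution(traj, "B", "A", 3, 0.1)$values, g1$values)
})

test_that("exclusions remove exactly the excluded pair contributions", {
  set.seed(7)
  n <- 20
  frames <- lapply(1:3, function(i)
    cg_frame(matrix(runif(3 * n, 0, 6), n, 3), rep(1, n), rep("A", n),
             c(6, 6, 6)))
  traj <- cg_traj(frames)
  excl <- rbind(c(1L, 2L), c(3L, 4L))
  g_ex <- radial_distribution(traj, "A", "A", 3, 0.1, exclusions = excl)
  counts <- oracle_pair_counts(traj_frames(traj), c(6, 6, 6), 1:n, 1:n,
                               30L, 0.1, excl = excl)
  r_mid <- (1:30 - 0.5) * 0.1
  ideal <- 3 * (n * (n - 1) / 2) * 4 * pi * r_mid^2 * 0.1 / 216
  expect_equal(g_ex$values, counts / ideal, tolerance = 1e-12)
})

test_that("RDF rejects bad geometry and empty type sets", {
  fr <- cg_frame(matrix(runif(9, 0, 2), 3, 3), rep(1, 3), c("A", "A", "B"),
                 c(2, 2, 2))
  expect_error(radial_distribution(fr, "A", "A", 1.5, 0.1), "half")
  expect_error(radial_distribution(fr, "Z", "A", 0.9, 0.1), "no beads")
})

test_that("bond distribution is normalized and matches its oracle", {
  set.seed(8)
  n <- 10
  frames <- lapply(1:5, function(i)
    cg_frame(matrix(runif(3 * n, 0, 4), n, 3), rep(1, n), rep("A", n),
             c(4, 4, 4)))
  traj <- cg_traj(frames)
  pairs <- rbind(c(1L, 2L), c(3L, 4L), c(5L, 6L))
  P <- bond_distribution(traj, pairs, l_max = 4, dx = 0.1)
  counts <- oracle_bond_hist(traj_frames(traj), c(4, 4, 4), pairs, 40L, 0.1)
  expect_equal(P$values / sum(P$values), counts / sum(counts),
               tolerance = 1e-12)
  expect_equal(tab_integral(P), 1, tolerance = 1e-6)
  # delta case: identical bond lengths occupy a single bin
  fr <- cg_frame(rbind(c(0, 0, 0), c(0.5, 0, 0), c(2, 0, 0), c(2, 0.5, 0)),
                 rep(1, 4), rep("A", 4), c(4, 4, 4))
  Pd <- bond_distribution(fr, rbind(c(1L, 2L), c(3L, 4L)), 1, dx = 0.1)
  expect_equal(sum(Pd$values > 0), 1L)
  expect_error(bond_distribution(fr, matrix(integer(0), 0, 2), 1), "empty")
})

test_that("angle distribution reproduces printed geometries and its oracle", {
  fr <- cg_frame(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                       c(2, 2, 2), c(2.5, 2, 2), c(3, 2, 2)),
                 rep(1, 6), rep("A", 6), c(8, 8, 8))
  P <- angle_distribution(fr, rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)), dtheta = 1)
  x <- tab_grid(P)
  occupied <- x[P$values > 0]
  expect_equal(occupied, c(90.5, 179.5))  # right angle and collinear
  set.seed(9)
  n <- 12
  frames <- lapply(1:4, function(i)
    cg_frame(matrix(runif(3 * n, 0, 5), n, 3), rep(1, n), rep("A", n),
             c(5, 5, 5)))
  traj <- cg_traj(frames)
  triples <- rbind(c(1L, 2L, 3L), c(4L, 5L, 6L), c(7L, 8L, 9L))
  Pr <- angle_distribution(traj, triples, dtheta = 5)
  counts <- oracle_angle_hist(traj_frames(traj), c(5, 5, 5), triples, 36L, 5)
  expect_equal(Pr$values / sum(Pr$values), counts / sum(counts),
               tolerance = 1e-12)
  expect_equal(tab_integral(Pr), 1, tolerance = 1e-6)
})

test_that("smoothing is a fixed point on constants and reduces roughness", {
  const <- tab_fn(0, 0.1, rep(2.5, 30), "rdf")
  expect_equal(smooth_table(const, window = 5)$values, const$values)
  set.seed(10)
  noisy <- tab_fn(0, 0.1, pmax(0, 1 + rnorm(50, 0, 0.3)), "rdf")
  sm <- smooth_table(noisy, window = 5)
  rough <- function(v) sum(diff(diff(v))^2)
  expect_lt(rough(sm$values), rough(noisy$values))
  expect_true(all(sm$values >= 0))
  # endpoints preserved
  expect_equal(sm$values[c(1, 50)], noisy$values[c(1, 50)])
  expect_error(smooth_table(noisy, window = 51), "window")
  expect_error(smooth_table(noisy, window = 4), "odd")
})
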