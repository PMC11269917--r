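test_that("phyllotaxis plan counts, SI spokes and unit norms", {
  plan <- phyllotaxis_directions(n_segments = 50, trs_per_segment = 13)
  expect_equal(nrow(plan$dir), 50 * 13)
  expect_equal(sum(plan$is_si), 50)
  expect_true(all(plan$pos_in_segment[plan$is_si] == 1))
  expect_lt(max(abs(sqrt(rowSums(plan$dir^2)) - 1)), 1e-9)
  expect_true(all(plan$dir[plan$is_si, 3] == 1))

  single <- phyllotaxis_directions(1, 1)
  expect_equal(single$dir, matrix(c(0, 0, 1), 1))

  expect_error(phyllotaxis_directions(0, 13), ">= 1")
})

test_that("direction multiset is invariant to segment interleaving", {
  a <- phyllotaxis_directions(n_segments = 30, trs_per_segment = 5)
  b <- phyllotaxis_directions(n_segments = 30, trs_per_segment = 5)
  key <- function(p) {
    d <- round(p$dir[!p$is_si, ], 12)
    d[order(d[, 1], d[, 2], d[, 3]), ]
  }
  expect_equal(key(a), key(b))
  # reordering segments permutes rows but not the set of directions
  perm <- sample(30)
  reord <- a
  ord <- order(match(a$segment, perm), a$pos_in_segment)
  reord$dir <- a$dir[ord, ]; reord$is_si <- a$is_si[ord]
  expect_equal(key(reord), key(a))
})

test_that("spoke directions cover the hemisphere near-uniformly", {
  plan <- phyllotaxis_directions(n_segments = 40, trs_per_segment = 9)
  d <- plan$dir[!plan$is_si, ]
  n <- nrow(d)
  # nearest-neighbor angular distance vs uniform-coverage spacing
  cosang <- d %*% t(d)
  diag(cosang) <- -1
  nn <- acos(pmin(pmax(apply(cosang, 1, max), -1), 1))
  expect_equal(mean(nn), sqrt(2 * pi / n), tolerance = 0.2)
})

test_that("readout gradients put echo centers on the scheme timing", {
  for (nm in c("bipolar3T", "monopolar3T")) {
    sch <- scheme_preset(nm)
    ro <- build_readout(readout_design(), sch)
    centers_ms <- (attr(ro, "echo_center_idx") - 1) * ro$dt * 1e3
    expect_lt(max(abs(centers_ms - echo_times(sch, "ms"))), ro$dt * 1e3)
    # k = 0 crossing at every echo center
    traj <- integrate_trajectory(ro, fov_m = 0.22)
    expect_lt(max(abs(traj$k[attr(ro, "echo_center_idx"), 1])), 0.05)
    # amplitude and slew within hardware limits
    expect_lt(max(abs(ro$G)), readout_design()$g_max_mt_m)
    expect_lt(max(abs(diff(ro$G[, 1]))) / ro$dt * 1e-3,
              readout_design()$slew_max_t_m_s * 1.01)
  }
})

test_that("monopolar flybacks rewind k between echoes", {
  ro <- build_readout(readout_design(), scheme_preset("monopolar3T"))
  traj <- integrate_trajectory(ro, fov_m = 0.22)
  es <- attr(ro, "echo_samples")
  st <- attr(ro, "sample_times_s")
  k_at <- function(idx) approx(traj$t_s, traj$k[, 1], xout = st[idx])$y
  starts <- vapply(es, function(ix) k_at(ix[1]), numeric(1))
  # every echo starts at the same -kmax edge (net area of lobe+rewind = 0)
  expect_lt(max(abs(starts - starts[1])), 1e-6)
})

test_that("infeasible echo timing raises a named constraint error", {
  tight <- echo_scheme("bipolar", 4, 1.12, 0.5, 15)
  expect_error(build_readout(readout_design(), tight), "echo spacing")
})

test_that("spoke k-space respects direction, GIRF and parity structure", {
  ro <- build_readout(readout_design(), scheme_preset("bipolar3T"))
  plan <- phyllotaxis_directions(4, 3)
  ks <- spoke_kspace(plan, ro, spokes = c(2, 5))
  # nominal samples are collinear with the spoke direction
  d <- plan$dir[2, ]
  k1 <- ks$k[, , 1]
  cross_norm <- max(abs(k1[, 1] * d[2] - k1[, 2] * d[1]),
                    abs(k1[, 2] * d[3] - k1[, 3] * d[2]))
  expect_lt(cross_norm, 1e-9)

  idg <- synth_gradient_system(delay_per_axis_s = c(x = 0, y = 0, z = 0),
                               resonance_freqs_hz = numeric(0),
                               lowpass_cutoff_hz = Inf)
  ks_id <- spoke_kspace(plan, ro, girf = idg, spokes = c(2, 5))
  expect_equal(ks_id$k, ks$k, tolerance = 1e-6)

  # asymmetric delays produce parity-split shifts (consumed downstream)
  sys_g <- synth_gradient_system()
  ks_d <- spoke_kspace(plan, ro, girf = sys_g, spokes = 2)
  as_traj <- function(kk) structure(
    list(k = kk$k[, , 1], t_s = kk$sample_times_s,
         echo_samples = kk$echo_samples, echo_parity = kk$echo_parity,
         fov_m = 0.22, axes = c("x", "y", "z")), class = "k_trajectory")
  ps <- echo_parity_shift(as_traj(spoke_kspace(plan, ro, spokes = 2)),
                          as_traj(ks_d))
  expect_gt(abs(ps["even"]), abs(ps["odd"]))
  expect_gt(abs(ps["even"]), 0.1)
})
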