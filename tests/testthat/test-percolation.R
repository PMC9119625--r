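test_that("bond probabilities follow the site-fraction definition", {
  expect_equal(bond_probabilities(c(FpFm = 9, Fp = 1))$theta_pm, 0.9)

  th <- bond_probabilities(c(FcLFc = 2, FcBFm = 1, Fc = 5))
  expect_equal(th$theta_cc, 0.4) # 4 / (4 + 1 + 5)
  expect_equal(th$theta_cm, 0.1)

  # empty network: all zero, no division errors
  th0 <- bond_probabilities(setNames(numeric(13),
                                     names(initial_state(fix_comp()))))
  expect_true(all(unlist(th0) == 0))

  # minus-site denominator counts brancher-capped ends
  th2 <- bond_probabilities(c(FpFm = 6, FcBFm = 2, Fm = 2))
  expect_equal(th2$theta_mp, 0.6)
  expect_equal(th2$theta_mc, 0.2)
})

test_that("linker_only removes motor/brancher bonds but keeps occupancy", {
  st <- c(FcLFc = 2, FcMFc = 3, FcBFm = 1, Fc = 5, FpFm = 4, Fp = 1, Fm = 1)
  all_th <- bond_probabilities(st, "all")
  lnk <- bond_probabilities(st, "linker_only")
  # same denominator: occupied sites still occupy
  expect_equal(lnk$theta_ccL, all_th$theta_ccL)
  expect_equal(lnk$theta_ccM, 0)
  expect_equal(lnk$theta_cm, 0)
  expect_equal(lnk$theta_mc, 0)
  expect_equal(lnk$theta_pm, all_th$theta_pm) # backbone unaffected
  # optional: brancher junctions still connect
  lnk_b <- bond_probabilities(st, "linker_only",
                              branchers_connect_linker_only = TRUE)
  expect_equal(lnk_b$theta_cm, all_th$theta_cm)
})

test_that("fixed point solves hand-checked cases", {
  # no bonds: everything finite
  f0 <- finite_cluster_probability(list(theta_pm = 0))
  expect_equal(f0$Ps, 1)
  expect_false(f0$gel)

  # only c-c bonds: dimers, still finite
  f1 <- finite_cluster_probability(list(theta_cc = 1))
  expect_equal(f1$Ps, 1)

  # symmetric three-site toy at t = 0.75: v = 1/9, B = 1/3, Ps = 1/27
  f2 <- finite_cluster_probability(
    list(theta_pm = 0.75, theta_mp = 0.75, theta_cc = 0.75))
  expect_equal(f2$Ps, 1 / 27, tolerance = 1e-10)
  expect_equal(unname(f2$B), rep(1 / 3, 3), tolerance = 1e-10)

  # fully bonded backbone: infinite chains
  f3 <- finite_cluster_probability(list(theta_pm = 1, theta_mp = 1))
  expect_equal(f3$Ps, 0)
  expect_true(f3$gel)
})

test_that("spectral criterion and fixed point agree on random draws", {
  set.seed(101)
  for (i in 1:1000) {
    th <- draw_theta()
    fit <- finite_cluster_probability(th)
    if (fit$spectral_radius <= 1) {
      expect_equal(fit$Ps, 1)
    } else {
      expect_lt(fit$Ps, 1)
    }
  }
})

test_that("iteration from zero is monotone and bounded", {
  th <- list(theta_pm = 0.9, theta_mp = 0.8, theta_ccL = 0.5,
             theta_ccM = 0.2, theta_cm = 0.1, theta_mc = 0.15)
  # replicate the iteration explicitly
  v <- c(p = 0, m = 0, c = 0)
  prev <- v
  for (k in 1:200) {
    B <- c(1 - th$theta_pm * (1 - v[["m"]]),
           1 - th$theta_mp * (1 - v[["p"]]) - th$theta_mc * (1 - v[["c"]]),
           1 - (th$theta_ccL + th$theta_ccM) * (1 - v[["c"]]) -
             th$theta_cm * (1 - v[["m"]]))
    v <- c(p = B[2] * B[3], m = B[1] * B[3], c = B[1] * B[2])
    expect_true(all(v >= prev - 1e-15))
    expect_true(all(v <= 1))
    prev <- v
  }
  fit <- finite_cluster_probability(th)
  expect_equal(unname(fit$v), unname(v), tolerance = 1e-8)
})

test_that("classical three-functional threshold sits at one half", {
  gel_at <- function(t) {
    finite_cluster_probability(
      list(theta_pm = t, theta_mp = t, theta_cc = t))$gel
  }
  lo <- 0.3; hi <- 0.7
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (gel_at(mid)) hi <- mid else lo <- mid
  }
  expect_equal((lo + hi) / 2, 0.5, tolerance = 1e-6)
})

test_that("Ps time series starts at one and finds a gel time", {
  comp <- fix_comp(L_total = 1)
  traj0 <- simulate_kinetics(initial_state(comp), abp_rates(),
                             times = c(0, 1, 2))
  ps0 <- ps_timeseries(traj0)
  expect_equal(ps0$Ps, rep(1, 3)) # dilute finite seeds, no kinetics

  r <- default_rates()
  traj <- simulate_kinetics(initial_state(comp), r,
                            times = seq(0, 300, by = 5))
  ps <- ps_timeseries(traj)
  expect_equal(ps$Ps[1], 1)
  expect_false(ps$gel[1])
  expect_true(any(ps$gel)) # 1 uM linker gels this system
  tg <- gel_time(traj)
  expect_true(is.finite(tg))
  expect_gt(tg, 0)
  # linker-only edge set gels no earlier than the full edge set
  ps_l <- ps_timeseries(traj, edge_set = "linker_only")
  expect_true(all(ps_l$Ps >= ps$Ps - 1e-12))

  # without any crosslinker the chains stay finite at all finite times
  traj_nox <- simulate_kinetics(initial_state(fix_comp()), r,
                                times = seq(0, 300, by = 10))
  ps_nox <- ps_timeseries(traj_nox)
  expect_true(all(ps_nox$Ps == 1))
  expect_true(is.na(gel_time(traj_nox)))
})

test_that("regime classification is well ordered", {
  r <- default_rates()
  prov <- steady_state_provider(fix_comp(), r)
  expect_equal(classify_regime(prov(1e-4, 1e-4)), 1L) # sol
  expect_equal(classify_regime(prov(1e-4, 0.5)), 2L)  # motors needed
  expect_equal(classify_regime(prov(1, 1e-4)), 3L)    # linkers alone
  # linker-only gel implies full gel by edge-subset inclusion
  sc <- regime_scan(c(1e-4, 0.03, 1), c(1e-4, 0.5), prov)
  expect_true(all(!sc$gel_linker | sc$gel_all))
  expect_true(all(sc$Ps_linker >= sc$Ps_all - 1e-12))
})

test_that("gel boundary is found by bisection and shifts with composition", {
  r <- default_rates()
  xg <- exp(seq(log(1e-4), log(10), length.out = 9))

  # boundary moves to lower linker when motors help (additive crosslinking)
  prov <- steady_state_provider(fix_comp(), r)
  bd <- gel_boundary(xg, c(1e-4, 0.01), prov)
  expect_equal(nrow(bd), 2)
  expect_lt(bd$x[2], bd$x[1])

  # brancher lowers the linker requirement everywhere on the line
  prov_b <- steady_state_provider(fix_comp(B_total = 0.5), r)
  bd_b <- gel_boundary(xg, c(1e-4, 0.01), prov_b)
  expect_true(all(bd_b$x < bd$x))

  # a line with no transition yields no boundary points
  prov0 <- steady_state_provider(fix_comp(), abp_rates())
  expect_equal(nrow(gel_boundary(xg, 1e-4, prov0)), 0)
})
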