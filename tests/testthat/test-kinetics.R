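test_that("initial_state does the seed-filament bookkeeping", {
  # a 10-mer seed: one plus end, one minus end, 9 backbone bonds, 10 sites
  st <- initial_state(fix_comp(n_seed = 0.1, len_seed = 10))
  expect_equal(st$Fp, 0.1)
  expect_equal(st$Fm, 0.1)
  expect_equal(st$FpFm, 0.9)
  expect_equal(st$Fc, 1.0)
  expect_equal(st$G, 24.0)

  # no seeds: everything monomeric
  st0 <- initial_state(fix_comp(n_seed = 0))
  expect_equal(st0$G, 25)
  expect_equal(unlist(st0[c("Fp", "Fm", "Fc", "FpFm")]),
               c(Fp = 0, Fm = 0, Fc = 0, FpFm = 0))

  # monomeric seeds carry no backbone bonds
  st1 <- initial_state(fix_comp(n_seed = 0.5, len_seed = 1))
  expect_equal(st1$FpFm, 0)
  expect_equal(st1$Fp, 0.5)
  expect_equal(st1$Fc, 0.5)

  expect_error(abp_composition(G_total = 1, n_seed = 1, len_seed = 5),
               "exceeds")
})

test_that("derivatives implement the reaction stoichiometry", {
  zero <- derivatives(initial_state(fix_comp(L_total = 2, M_total = 1)),
                      abp_rates())
  expect_true(all(unlist(zero) == 0))

  # termolecular linker flux: 1 * 2 * 3^2 = 18
  d <- derivatives(c(Fc = 3, L_free = 2), abp_rates(kC_plus = 1))
  expect_equal(d$FcLFc, 18)
  expect_equal(d$Fc, -36)
  expect_equal(d$L_free, -18)

  # branching: daughter contributes a fresh plus end and binding site
  d2 <- derivatives(c(Fc = 1, B_free = 1, G = 1), abp_rates(kB_plus = 1))
  expect_equal(d2$Fp, 1)
  expect_equal(d2$Fc, 0)
  expect_equal(d2$G, -1)
  expect_equal(d2$FcBFm, 1)

  expect_error(derivatives(c(Fc = -1), abp_rates()), "negative")
  expect_error(derivatives(c(Fc = 1), abp_rates(), mode = "bogus"))
})

test_that("free minus ends are conserved by every reaction", {
  # elongation moves the end, branching caps the daughter's minus end
  set.seed(4)
  for (i in 1:20) {
    y <- setNames(runif(13, 0, 5), names(initial_state(fix_comp())))
    r <- abp_rates(kp_plus = runif(1), kp_minus = runif(1),
                   km_plus = runif(1), km_minus = runif(1),
                   kB_plus = runif(1), kB_minus = runif(1),
                   kC_plus = runif(1), kC_minus = runif(1),
                   kM_plus = runif(1), kM_minus = runif(1))
    for (mode in c("termolecular", "two_step")) {
      expect_equal(derivatives(y, r, mode)$Fm, 0)
    }
  }
})

test_that("conservation identities have zero analytic time derivative", {
  set.seed(11)
  for (i in 1:20) {
    y <- setNames(runif(13, 0, 5), names(initial_state(fix_comp())))
    r <- abp_rates(kp_plus = runif(1), kp_minus = runif(1),
                   km_plus = runif(1), km_minus = runif(1),
                   kB_plus = runif(1), kB_minus = runif(1),
                   kC_plus = runif(1), kC_minus = runif(1),
                   kM_plus = runif(1), kM_minus = runif(1))
    for (mode in c("termolecular", "two_step")) {
      d <- derivatives(y, r, mode)
      expect_equal(d$G + d$Fp + d$FpFm, 0) # actin via plus-site count
      expect_equal(d$L_free + d$FcL + d$FcLFc, 0)
      expect_equal(d$M_free + d$FcM + d$FcMFc, 0)
      expect_equal(d$B_free + d$FcBFm, 0)
      # the three site-bookkeeping identities move together
      expect_equal(d$Fp + d$FpFm, d$Fm + d$FpFm + d$FcBFm)
      expect_equal(d$Fp + d$FpFm,
                   d$Fc + d$FcL + d$FcM + 2 * d$FcLFc + 2 * d$FcMFc + d$FcBFm)
    }
  }
})

test_that("integration conserves totals and handles edge cases", {
  expect_error(simulate_kinetics(initial_state(fix_comp()), abp_rates(),
                                 times = c(1, 1)), "increasing")

  # all rates zero: constant trajectory
  comp <- fix_comp(L_total = 2)
  traj0 <- simulate_kinetics(initial_state(comp), abp_rates(),
                             times = c(0, 5, 10))
  expect_equal(traj0$G, rep(24, 3))
  expect_equal(traj0$L_free, rep(2, 3))

  # full model, both modes: conservation to 1e-8 relative
  r <- default_rates()
  for (mode in c("termolecular", "two_step")) {
    comp <- fix_comp(L_total = 1, M_total = 0.3, B_total = 0.5)
    traj <- simulate_kinetics(initial_state(comp), r,
                              times = seq(0, 500, by = 10), mode = mode)
    expect_conservation(traj, comp)
    expect_true(all(traj$Fm == traj$Fm[1]))
  }
})

test_that("irreversible polymerization exhausts G monotonically", {
  comp <- fix_comp()
  traj <- simulate_kinetics(initial_state(comp), abp_rates(kp_plus = 1),
                            times = seq(0, 400, by = 4))
  expect_true(all(diff(traj$G) <= 1e-10))
  expect_true(all(diff(traj$FpFm + traj$Fc) >= -1e-10))
  expect_lt(tail(traj$G, 1), 1e-6)
})

test_that("isolated reversible linker reaction reaches mass-action equilibrium", {
  comp <- fix_saturated_comp(L_total = 5)
  r <- abp_rates(kC_plus = 2, kC_minus = 0.5)
  st <- steady_state(initial_state(comp), r, mode = "termolecular")
  K <- st$FcLFc / (st$L_free * st$Fc^2)
  expect_equal(K, 2 / 0.5, tolerance = 1e-6)
})

test_that("steady_state trivial and exhaustion cases", {
  comp <- fix_comp(L_total = 1)
  st0 <- steady_state(initial_state(comp), abp_rates())
  expect_equal(as.numeric(unlist(st0)),
               as.numeric(unlist(initial_state(comp))))

  st <- steady_state(initial_state(fix_comp()), abp_rates(kp_plus = 1))
  expect_lt(st$G, 1e-8)

  expect_error(
    steady_state(initial_state(fix_comp()), abp_rates(kp_plus = 1),
                 t_max = 1e-3),
    "plateau")
})

test_that("two-step steady state matches the closed-form equilibrium", {
  comp <- fix_saturated_comp(L_total = 13)
  r <- abp_rates(kC_plus = 1, kC_minus = 1)
  st <- steady_state(initial_state(comp), r, mode = "two_step")
  eq <- equilibrium_fractions(Fc_total = 25, L_total = 13, K1 = 1, K2 = 1)
  expect_equal(st$Fc, eq$Fc_free, tolerance = 1e-6)
  expect_equal(st$FcL, eq$FcL, tolerance = 1e-6)
  expect_equal(st$FcLFc, eq$FcLFc, tolerance = 1e-6)
  expect_equal(st$L_free, eq$L_free, tolerance = 1e-6)
})

test_that("two-step with fast second step converges to termolecular limit", {
  # matched overall affinity K1 * K2 = kC_plus / kC_minus = 1 uM^-2, with a
  # weak first step so the singly-bound intermediate is negligible
  comp <- fix_saturated_comp(L_total = 8)
  st_term <- steady_state(initial_state(comp),
                          abp_rates(kC_plus = 1, kC_minus = 1))
  st_two <- steady_state(initial_state(comp),
                         abp_rates(kC1_plus = 0.01, kC1_minus = 1,
                                   kC2_plus = 100, kC2_minus = 1),
                         mode = "two_step")
  expect_equal(st_two$FcLFc, st_term$FcLFc, tolerance = 5e-3)
  expect_lt(st_two$FcL, 0.05 * st_two$FcLFc)
})
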