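# Shared fixtures: compositions, rate sets and random theta draws used
# across the module tests. Everything is generated in code.

fix_comp <- function(...) {
  args <- modifyList(list(G_total = 25, L_total = 0, M_total = 0,
                          B_total = 0, n_seed = 0.1, len_seed = 10),
                     list(...))
  do.call(abp_composition, args)
}

# composition whose seeds already hold all actin: no polymerization needed,
# binding sites total exactly G_total
fix_saturated_comp <- function(L_total = 0, M_total = 0, B_total = 0,
                               G_total = 25, len_seed = 5) {
  abp_composition(G_total = G_total, L_total = L_total, M_total = M_total,
                  B_total = B_total, n_seed = G_total / len_seed,
                  len_seed = len_seed)
}

# draw a valid random theta configuration; site sums kept within [0,1]
draw_theta <- function() {
  mp <- runif(1)
  mc <- runif(1, 0, 1 - mp)
  ccL <- runif(1)
  ccM <- runif(1, 0, 1 - ccL)
  cm <- runif(1, 0, 1 - ccL - ccM)
  list(theta_pm = runif(1), theta_mp = mp, theta_mc = mc,
       theta_ccL = ccL, theta_ccM = ccM, theta_cm = cm)
}

# rejection-sample a theta draw in the requested criticality class,
# keeping a margin away from the threshold so Monte-Carlo comparisons at a
# finite cap are meaningful
draw_theta_class <- function(supercritical, margin = 0.05, max_tries = 1e4) {
  for (i in seq_len(max_tries)) {
    th <- draw_theta()
    sr <- finite_cluster_probability(th)$spectral_radius
    if (supercritical && sr > 1 + margin) return(th)
    if (!supercritical && sr < 1 - margin) return(th)
  }
  stop("could not draw a theta configuration in the requested class")
}

expect_conservation <- function(traj, comp, tol = 1e-8) {
  cq <- conserved_quantities(traj)
  rel <- function(x, target) {
    if (target == 0) max(abs(x)) else max(abs(x - target) / target)
  }
  expect_lt(rel(cq$actin_total, comp$G_total), tol)
  expect_lt(rel(cq$linker_total, comp$L_total), tol)
  expect_lt(rel(cq$motor_total, comp$M_total), tol)
  expect_lt(rel(cq$brancher_total, comp$B_total), tol)
  expect_lt(max(cq$site_consistency), tol)
}
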