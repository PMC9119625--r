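test_that("degenerate clusters have exact sizes", {
  th0 <- list(theta_pm = 0)
  expect_equal(sample_branching_cluster(th0, seed = 1), 1)
  # pure c-c bonds make dimers only
  th2 <- list(theta_cc = 1)
  sizes <- vapply(1:50, function(s) sample_branching_cluster(th2, seed = s),
                  numeric(1))
  expect_true(all(sizes == 2))
  e <- empirical_ps(th0, n_roots = 1000, seed = 3)
  expect_equal(e$ps_hat, 1)
  expect_equal(e$se, 0)
})

test_that("sampling is reproducible under a fixed seed", {
  th <- list(theta_pm = 0.7, theta_mp = 0.6, theta_ccL = 0.3)
  a <- empirical_ps(th, n_roots = 2000, cap = 1e4, seed = 99)
  b <- empirical_ps(th, n_roots = 2000, cap = 1e4, seed = 99)
  expect_identical(a, b)
  n1 <- sample_network(th, cap = 200, seed = 7)
  n2 <- sample_network(th, cap = 200, seed = 7)
  expect_identical(n1$edges, n2$edges)
})

test_that("sampled edges respect the site-compatibility matrix", {
  set.seed(5)
  for (i in 1:20) {
    th <- draw_theta()
    net <- sample_network(th, cap = 500)
    ed <- net$edges
    if (nrow(ed) == 0) next
    # endpoint site types match the bond type
    expect_true(all(ed$from_site[ed$type == "pm"] %in% c("p", "m")))
    expect_true(all(ed$to_site[ed$type == "pm"] %in% c("p", "m")))
    expect_true(all(ed$from_site[ed$type == "pm"] != ed$to_site[ed$type == "pm"]))
    expect_true(all(ed$from_site[ed$type %in% c("cLc", "cMc")] == "c"))
    expect_true(all(ed$to_site[ed$type %in% c("cLc", "cMc")] == "c"))
    expect_true(all((ed$from_site == "c" & ed$to_site == "m") |
                      (ed$from_site == "m" & ed$to_site == "c") |
                      ed$type != "cBm"))
    # acyclic: every non-root monomer has exactly one incoming edge
    expect_equal(sort(unique(ed$to)), sort(ed$to))
    # each monomer uses each site at most once
    usage <- rbind(data.frame(id = ed$from, site = ed$from_site),
                   data.frame(id = ed$to, site = ed$to_site))
    expect_false(any(duplicated(usage)))
  }
})

test_that("empirical Ps matches the analytic fixed point", {
  # hand-solved symmetric case: Ps = 1/27
  th <- list(theta_pm = 0.75, theta_mp = 0.75, theta_ccL = 0.75)
  e <- empirical_ps(th, n_roots = 1e5, cap = 1e4, seed = 13)
  expect_lt(abs(e$ps_hat - 1 / 27), 3 * e$se)

  # supercritical chain with crosslinks
  th2 <- list(theta_pm = 0.9, theta_mp = 0.9, theta_ccL = 0.4)
  fit2 <- finite_cluster_probability(th2)
  e2 <- empirical_ps(th2, n_roots = 5e4, cap = 1e4, seed = 17)
  expect_lt(abs(e2$ps_hat - fit2$Ps), 3 * e2$se)

  # subcritical draw: nearly everything finite, small truncation bias
  th3 <- list(theta_pm = 0.6, theta_mp = 0.6, theta_ccL = 0.2)
  fit3 <- finite_cluster_probability(th3)
  expect_equal(fit3$Ps, 1)
  e3 <- empirical_ps(th3, n_roots = 2e4, cap = 1e4, seed = 19)
  expect_gte(e3$ps_hat, 1 - max(3 * e3$se, e3$bias_bound))
})

test_that("empirical Maxwell count validates the analytic weights", {
  fx <- flexibility_map(b_pm = 6, b_cm = 4, b_cLc = 2, b_cMc = 5)

  # rigid chain: 6n - 6(n-1) = 6 floppy modes total, 0 per monomer
  th_chain <- list(theta_pm = 1, theta_mp = 1)
  em <- empirical_maxwell(th_chain, flexibility_map(), n_roots = 2000,
                          cap = 1e3, seed = 23)
  expect_equal(em$f_hat, 0, tolerance = 1e-9)

  # all b = 0: nothing constrains
  em0 <- empirical_maxwell(th_chain,
                           flexibility_map(b_pm = 0, b_cm = 0, b_cLc = 0,
                                           b_cMc = 0),
                           n_roots = 2000, cap = 1e3, seed = 23)
  expect_equal(em0$f_hat, 6)

  # mixed bond types against the analytic count
  th <- list(theta_pm = 0.9, theta_mp = 0.85, theta_ccL = 0.3,
             theta_ccM = 0.2, theta_cm = 0.05, theta_mc = 0.1)
  fit <- finite_cluster_probability(th)
  fm <- floppy_modes(th, fit, fx)
  em2 <- empirical_maxwell(th, fx, n_roots = 5e4, cap = 5e3, seed = 29)
  expect_lt(abs(em2$f_hat - fm$f), 3 * em2$se)

  # subcritical input is a domain error
  expect_error(
    empirical_maxwell(list(theta_pm = 0.3), fx, n_roots = 2000, seed = 1),
    "supercritical")
})
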