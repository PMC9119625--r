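#' Bond probabilities from a kinetic state
#'
#' Converts species concentrations into the per-site bond probabilities of
#' the generalized Flory-Stockmayer theory: each theta is the fraction of
#' sites of a class that are engaged in a given bond type,
#' `theta = [bound] / [total sites of that class]`.
#'
#' * `theta_pm = FpFm / (FpFm + Fp)` — plus site bound to a minus site;
#' * `theta_mp = FpFm / (FpFm + FcBFm + Fm)` — minus site bound to a plus;
#' * `theta_cc = (2 FcLFc + 2 FcMFc) / D_c` — binding site crosslinked to
#'   another binding site (linker or motor), with
#'   `D_c = 2 FcLFc + 2 FcMFc + FcBFm + Fc + FcL + FcM`;
#' * `theta_cm = FcBFm / D_c` — binding site holding a brancher junction;
#' * `theta_mc = FcBFm / (FpFm + FcBFm + Fm)` — minus site capped by a
#'   brancher.
#'
#' Under `edge_set = "linker_only"` only linker crosslinks count as
#' connections: the motor contribution is removed from the `theta_cc`
#' numerator (and, by default, brancher junction bonds are removed from
#' `theta_cm`/`theta_mc`), while every occupied site remains in the
#' denominators — occupancy is physical even when the bond does not
#' propagate connectivity.
#'
#' @param state A kinetic state (one-row tibble or named vector of uM
#'   concentrations).
#' @param edge_set `"all"` or `"linker_only"`.
#' @param branchers_connect_linker_only Logical: whether brancher junctions
#'   still count as connections under `"linker_only"` (default `FALSE`).
#' @return A one-row tibble of class `bond_probs` with columns `theta_pm`,
#'   `theta_mp`, `theta_cc`, `theta_ccL`, `theta_ccM`, `theta_cm`,
#'   `theta_mc` (`theta_cc = theta_ccL + theta_ccM`). Classes of sites that
#'   do not exist give theta = 0.
#' @examples
#' bond_probabilities(c(FpFm = 9, Fp = 1))
#' @export
bond_probabilities <- function(state, edge_set = c("all", "linker_only"),
                               branchers_connect_linker_only = FALSE) {
  edge_set <- match.arg(edge_set)
  y <- .state_vec(state)
  if (any(y < 0)) abort("negative input concentration")
  den_p <- y[["FpFm"]] + y[["Fp"]]
  den_m <- y[["FpFm"]] + y[["FcBFm"]] + y[["Fm"]]
  den_c <- 2 * y[["FcLFc"]] + 2 * y[["FcMFc"]] + y[["FcBFm"]] +
    y[["Fc"]] + y[["FcL"]] + y[["FcM"]]
  sdiv <- function(num, den) if (den > 0) num / den else 0
  ccL <- sdiv(2 * y[["FcLFc"]], den_c)
  ccM <- sdiv(2 * y[["FcMFc"]], den_c)
  cm <- sdiv(y[["FcBFm"]], den_c)
  mc <- sdiv(y[["FcBFm"]], den_m)
  if (edge_set == "linker_only") {
    ccM <- 0
    if (!branchers_connect_linker_only) {
      cm <- 0
      mc <- 0
    }
  }
  out <- tibble(
    theta_pm = sdiv(y[["FpFm"]], den_p),
    theta_mp = sdiv(y[["FpFm"]], den_m),
    theta_cc = ccL + ccM,
    theta_ccL = ccL,
    theta_ccM = ccM,
    theta_cm = cm,
    theta_mc = mc
  )
  class(out) <- c("bond_probs", class(out))
  attr(out, "edge_set") <- edge_set
  out
}

# Accept a bond_probs row, named list/vector, or plain list; return a named
# list with all seven theta fields, deriving the ccL/ccM split when absent
# (all theta_cc attributed to linkers).
.theta_list <- function(theta) {
  if (is.data.frame(theta)) {
    stopifnot(nrow(theta) == 1)
    theta <- as.list(theta)
  } else {
    theta <- as.list(theta)
  }
  th <- list(theta_pm = 0, theta_mp = 0, theta_cc = NULL, theta_ccL = NULL,
             theta_ccM = 0, theta_cm = 0, theta_mc = 0)
  th[intersect(names(theta), names(th))] <-
    theta[intersect(names(theta), names(th))]
  if (is.null(th$theta_ccL)) {
    th$theta_ccL <- (th$theta_cc %||% 0) - th$theta_ccM
  }
  if (is.null(th$theta_cc)) th$theta_cc <- th$theta_ccL + th$theta_ccM
  th <- lapply(th, as.numeric)
  vals <- unlist(th)
  # tolerate integration-level round-off; reject genuine violations
  if (any(vals < -1e-6) || any(vals > 1 + 1e-6)) {
    abort("bond probabilities must lie in [0, 1]")
  }
  th <- lapply(th, function(x) min(1, max(0, x)))
  s_m <- th$theta_mp + th$theta_mc
  s_c <- th$theta_cc + th$theta_cm
  if (s_m > 1 + 1e-6 || s_c > 1 + 1e-6) {
    abort("site bond probabilities exceed 1 (theta_mp + theta_mc or theta_cc + theta_cm)")
  }
  if (s_m > 1) {
    th$theta_mp <- th$theta_mp / s_m
    th$theta_mc <- th$theta_mc / s_m
  }
  if (s_c > 1) {
    sc_l <- th$theta_ccL / s_c
    th$theta_ccL <- sc_l
    th$theta_ccM <- th$theta_ccM / s_c
    th$theta_cm <- th$theta_cm / s_c
    th$theta_cc <- th$theta_ccL + th$theta_ccM
  }
  th
}

# Jacobian of the branch-finiteness map at v = 1; its spectral radius
# decides sub- vs supercriticality of the multi-type branching process.
.branching_jacobian <- function(th) {
  matrix(c(
    th$theta_mp, th$theta_cm, th$theta_mc + th$theta_cc,
    0,           th$theta_pm + th$theta_cm, th$theta_cc,
    th$theta_mp, th$theta_pm, th$theta_mc
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("p", "m", "c"), c("p", "m", "c")))
}

#' Finite-cluster probability of the generalized Flory-Stockmayer theory
#'
#' Solves the multi-type branching-process fixed point on the three-site
#' monomer (Bethe lattice, no loops). `v_s` is the probability that the
#' subtree entered through a bond arriving at site `s` is finite; `B_s` is
#' the probability that site `s` of a monomer does not lead to an infinite
#' branch:
#' \deqn{B_p = 1 - \theta_{pm}(1 - v_m),\quad
#'       B_m = 1 - \theta_{mp}(1 - v_p) - \theta_{mc}(1 - v_c),\quad
#'       B_c = 1 - \theta_{cc}(1 - v_c) - \theta_{cm}(1 - v_m)}
#' with \eqn{v_p = B_m B_c}, \eqn{v_m = B_p B_c}, \eqn{v_c = B_p B_m}
#' (a bond entering a site continues through the monomer's other two
#' sites; brancher junction bonds enter the daughter via its minus site and
#' the mother via its binding site). The fraction of monomers in finite
#' clusters is \eqn{P_s = B_p B_m B_c}; the system is a gel when
#' \eqn{P_s < 1}.
#'
#' Subcriticality is decided first from the spectral radius of the
#' branching Jacobian at `v = 1` (radius <= 1 gives `Ps = 1` exactly);
#' otherwise the smallest fixed point is reached by monotone iteration from
#' `v = 0`.
#'
#' @param theta Bond probabilities ([bond_probabilities()] output or a
#'   named list/vector of thetas).
#' @param tol Fixed-point iteration tolerance.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return An object of class `percolation_fit`: a list with `v`, `B`
#'   (named length-3 vectors), `Ps`, `gel`, `spectral_radius`,
#'   `iterations`, `theta`. `gel` is `Ps < 1 - 1e-9`, with ties at the
#'   threshold resolved by the spectral criterion.
#' @examples
#' th <- list(theta_pm = 0.75, theta_mp = 0.75, theta_cc = 0.75)
#' finite_cluster_probability(th)$Ps # 1/27
#' @export
finite_cluster_probability <- function(theta, tol = 1e-12, max_iter = 1e6) {
  th <- .theta_list(theta)
  J <- .branching_jacobian(th)
  sr <- max(abs(eigen(J, only.values = TRUE)$values))
  # strictly subcritical: the all-ones point is the unique fixed point.
  # At sr = 1 exactly a degenerate (deterministic-offspring) process can
  # still be infinite, so the boundary case falls through to the iteration.
  if (sr < 1) {
    res <- list(v = c(p = 1, m = 1, c = 1), B = c(p = 1, m = 1, c = 1),
                Ps = 1, gel = FALSE, spectral_radius = sr, iterations = 0L,
                theta = th)
    class(res) <- "percolation_fit"
    return(res)
  }
  bmap <- function(v) c(
    p = 1 - th$theta_pm * (1 - v[["m"]]),
    m = 1 - th$theta_mp * (1 - v[["p"]]) - th$theta_mc * (1 - v[["c"]]),
    c = 1 - th$theta_cc * (1 - v[["c"]]) - th$theta_cm * (1 - v[["m"]])
  )
  fmap <- function(v) {
    B <- bmap(v)
    c(p = B[["m"]] * B[["c"]], m = B[["p"]] * B[["c"]],
      c = B[["p"]] * B[["m"]])
  }
  jac <- function(v) {
    B <- bmap(v)
    matrix(c(
      th$theta_mp * B[["c"]], th$theta_cm * B[["m"]],
      th$theta_mc * B[["c"]] + th$theta_cc * B[["m"]],
      0, th$theta_pm * B[["c"]] + th$theta_cm * B[["p"]],
      th$theta_cc * B[["p"]],
      th$theta_mp * B[["p"]], th$theta_pm * B[["m"]],
      th$theta_mc * B[["p"]]
    ), nrow = 3, byrow = TRUE)
  }
  v <- c(p = 0, m = 0, c = 0)
  it <- 0L
  repeat {
    v_new <- fmap(v)
    it <- it + 1L
    delta <- max(abs(v_new - v))
    v <- v_new
    if (delta < tol) break
    # near the threshold the linear rate approaches 1; polish the monotone
    # iterate with damped Newton (the smallest fixed point is the nearest
    # root from below, where J - I is nonsingular)
    if (it %% 512L == 0L) {
      vn <- v
      ok <- TRUE
      for (k in 1:60) {
        res <- fmap(vn) - vn
        if (max(abs(res)) < tol) break
        step <- tryCatch(solve(jac(vn) - diag(3), -res),
                         error = function(e) NULL)
        if (is.null(step) || any(!is.finite(step))) { ok <- FALSE; break }
        vn <- pmin(pmax(vn + step, 0), 1)
      }
      # accept only the stable (smallest) fixed point: its Jacobian radius
      # is <= 1, while the supercritical all-ones root has radius > 1
      if (ok && max(abs(fmap(vn) - vn)) < tol &&
          max(abs(eigen(jac(vn), only.values = TRUE)$values)) <= 1 + 1e-9) {
        v <- setNames(vn, c("p", "m", "c"))
        break
      }
    }
    if (it >= max_iter) {
      abort(sprintf(
        "fixed-point iteration did not converge in %d iterations (residual %.3g)",
        it, delta))
    }
  }
  B <- bmap(v)
  Ps <- prod(B)
  res <- list(v = v, B = B, Ps = Ps, gel = Ps < 1 - 1e-9,
              spectral_radius = sr, iterations = it, theta = th)
  class(res) <- "percolation_fit"
  res
}

#' @export
print.percolation_fit <- function(x, ...) {
  cat(sprintf("<percolation_fit> Ps = %.6g (%s), spectral radius %.4g\n",
              x$Ps, if (x$gel) "gel" else "sol", x$spectral_radius))
  invisible(x)
}

#' Fraction of monomers in finite clusters along a trajectory
#'
#' @param trajectory An `abp_trajectory` (output of [simulate_kinetics()]).
#' @param edge_set Passed to [bond_probabilities()].
#' @param ... Passed to [bond_probabilities()].
#' @return A tibble: `time`, `Ps`, `gel`.
#' @export
ps_timeseries <- function(trajectory, edge_set = "all", ...) {
  stopifnot(is.data.frame(trajectory), "time" %in% names(trajectory))
  rows <- purrr::map(seq_len(nrow(trajectory)), function(i) {
    th <- bond_probabilities(trajectory[i, setdiff(names(trajectory), "time")],
                             edge_set = edge_set, ...)
    fit <- finite_cluster_probability(th)
    tibble(time = trajectory$time[i], Ps = fit$Ps, gel = fit$gel)
  })
  dplyr::bind_rows(rows)
}

#' First time the system is a gel
#'
#' @inheritParams ps_timeseries
#' @return The midpoint of the pair of output times bracketing the first
#'   `Ps < 1` crossing (resolution is limited by the time grid; the bracket
#'   is attached as attribute `"bracket"`), or `NA` if the system never
#'   gels on the grid.
#' @export
gel_time <- function(trajectory, edge_set = "all", ...) {
  ps <- ps_timeseries(trajectory, edge_set = edge_set, ...)
  idx <- which(ps$gel)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  if (i == 1) {
    return(structure(ps$time[1], bracket = c(NA, ps$time[1])))
  }
  structure((ps$time[i - 1] + ps$time[i]) / 2,
            bracket = c(ps$time[i - 1], ps$time[i]))
}

#' Trace a connectivity (gel) boundary along scan lines
#'
#' For each value of the slow axis, evaluates the gel predicate on the fast
#' axis grid and refines every sign change by bisection.
#'
#' @param x_grid Fast-axis concentrations (uM), increasing; boundary points
#'   are located between consecutive grid values.
#' @param y_grid Slow-axis concentrations (uM).
#' @param state_provider `function(x, y)` returning a kinetic state (e.g. a
#'   memoised wrapper around [steady_state()]).
#' @param edge_set Passed to [bond_probabilities()].
#' @param predicate Optional replacement predicate `function(state)`
#'   returning `TRUE`/`FALSE`; defaults to the gel flag of
#'   [finite_cluster_probability()]. Used by [rigidity_boundary()].
#' @param rel_tol Relative bisection tolerance on the fast axis.
#' @return A tibble: `y`, `x` (boundary location), `direction` (`+1` when
#'   the predicate turns on with increasing x, `-1` when it turns off).
#'   Lines on which the predicate is constant contribute no rows.
#' @export
gel_boundary <- function(x_grid, y_grid, state_provider, edge_set = "all",
                         predicate = NULL, rel_tol = 1e-3) {
  stopifnot(length(x_grid) >= 2, all(diff(x_grid) > 0))
  pred <- predicate %||% function(state) {
    finite_cluster_probability(bond_probabilities(state, edge_set = edge_set))$gel
  }
  rows <- purrr::map(y_grid, function(y) {
    flags <- vapply(x_grid, function(x) isTRUE(pred(state_provider(x, y))),
                    logical(1))
    ch <- which(diff(flags) != 0)
    if (length(ch) == 0) return(NULL)
    pts <- purrr::map(ch, function(i) {
      lo <- x_grid[i]; hi <- x_grid[i + 1]
      f_lo <- flags[i]
      while ((hi - lo) > rel_tol * max(hi, 1e-12)) {
        mid <- sqrt(max(lo, 1e-300) * hi) # geometric bisection: log axes
        if (isTRUE(pred(state_provider(mid, y))) == f_lo) lo <- mid else hi <- mid
      }
      tibble(y = y, x = (lo + hi) / 2,
             direction = if (f_lo) -1 else 1)
    })
    dplyr::bind_rows(pts)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- tibble(y = numeric(), x = numeric(),
                                    direction = numeric())
  out
}

#' Classify the connectivity regime of a steady state
#'
#' * regime 1 (sol): no gel even counting motor and linker crosslinks;
#' * regime 2: gel with all connections but not by linkers alone — motors
#'   are required to connect the network (contractile regime);
#' * regime 3: gel by linker connections alone (rigid, structural gel).
#'
#' @param state A steady-state kinetic state.
#' @param ... Passed to [bond_probabilities()] (e.g.
#'   `branchers_connect_linker_only`).
#' @return Integer 1, 2, or 3.
#' @export
classify_regime <- function(state, ...) {
  gel_all <- finite_cluster_probability(
    bond_probabilities(state, edge_set = "all", ...))$gel
  gel_lnk <- finite_cluster_probability(
    bond_probabilities(state, edge_set = "linker_only", ...))$gel
  if (gel_lnk) 3L else if (gel_all) 2L else 1L
}

#' Steady-state scan over a concentration grid
#'
#' Convenience wrapper: computes the steady state, finite-cluster
#' probability under both edge sets, and the regime label over an
#' (x, y) grid of total concentrations.
#'
#' @param x_grid,y_grid Concentration grids (uM).
#' @param state_provider `function(x, y)` returning a steady-state kinetic
#'   state.
#' @return A tibble of class `regime_scan`: `x`, `y`, `Ps_all`,
#'   `Ps_linker`, `gel_all`, `gel_linker`, `regime`.
#' @export
regime_scan <- function(x_grid, y_grid, state_provider) {
  grid <- tidyr::expand_grid(y = y_grid, x = x_grid)
  rows <- purrr::map2(grid$x, grid$y, function(x, y) {
    st <- state_provider(x, y)
    fa <- finite_cluster_probability(bond_probabilities(st, "all"))
    fl <- finite_cluster_probability(bond_probabilities(st, "linker_only"))
    tibble(Ps_all = fa$Ps, Ps_linker = fl$Ps,
           gel_all = fa$gel, gel_linker = fl$gel,
           regime = if (fl$gel) 3L else if (fa$gel) 2L else 1L)
  })
  out <- dplyr::bind_cols(grid[, c("x", "y")], dplyr::bind_rows(rows))
  class(out) <- c("regime_scan", class(out))
  out
}

#' Memoised steady-state provider over two composition axes
#'
#' Returns a `function(x, y)` that builds a composition with the two named
#' fields set to `(x, y)`, computes its steady state, and caches results.
#'
#' @param base A base [abp_composition()]; the scanned fields are
#'   overwritten.
#' @param rates An [abp_rates()] object.
#' @param x_field,y_field Composition field names bound to the two axes
#'   (e.g. `"L_total"`, `"M_total"`).
#' @param mode,... Passed to [steady_state()].
#' @return A memoising `function(x, y)` returning a kinetic state.
#' @export
steady_state_provider <- function(base, rates, x_field = "L_total",
                                  y_field = "M_total",
                                  mode = "termolecular", ...) {
  stopifnot(inherits(base, "abp_composition"),
            x_field %in% names(base), y_field %in% names(base))
  cache <- new.env(parent = emptyenv())
  dots <- list(...)
  function(x, y) {
    key <- sprintf("%.12g_%.12g", x, y)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cm <- unclass(base)
    cm[[x_field]] <- x
    cm[[y_field]] <- y
    cm <- do.call(abp_composition, cm)
    st <- do.call(steady_state,
                  c(list(initial_state(cm), rates, mode = mode), dots))
    cache[[key]] <- st
    st
  }
}
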