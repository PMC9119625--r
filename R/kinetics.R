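#' Initial kinetic state from a system composition
#'
#' The system starts with `n_seed` uM of seed filaments of `len_seed`
#' monomers each (the nucleators), the remaining actin as G-actin, and all
#' binding proteins free. A seed filament of length n contributes one free
#' plus end, one free minus end, n-1 backbone bonds, and n free binding
#' sites.
#'
#' @param composition An [abp_composition()] object.
#' @return A one-row tibble with one column per species (uM), of class
#'   `kinetic_state`.
#' @examples
#' initial_state(abp_composition(G_total = 25, n_seed = 0.1, len_seed = 10))
#' @export
initial_state <- function(composition) {
  stopifnot(inherits(composition, "abp_composition"))
  cm <- composition
  seeded <- cm$n_seed * cm$len_seed
  st <- tibble(
    G = cm$G_total - seeded,
    Fp = cm$n_seed,
    Fm = cm$n_seed,
    Fc = seeded,
    FpFm = cm$n_seed * (cm$len_seed - 1),
    FcLFc = 0, FcMFc = 0, FcBFm = 0,
    L_free = cm$L_total, M_free = cm$M_total, B_free = cm$B_total,
    FcL = 0, FcM = 0
  )
  class(st) <- c("kinetic_state", class(st))
  attr(st, "composition") <- cm
  st
}

# Coerce a kinetic state (one-row tibble / data.frame / named vector) to a
# named numeric vector in canonical species order, with absent auxiliary
# species defaulting to 0.
.state_vec <- function(state) {
  if (is.data.frame(state)) {
    stopifnot(nrow(state) == 1)
    state <- unlist(state[intersect(names(state), .species)])
  }
  out <- setNames(numeric(length(.species)), .species)
  common <- intersect(names(state), .species)
  if (length(common) == 0) abort("state contains no recognized species")
  out[common] <- as.numeric(state[common])
  out
}

# Mass-action fluxes and species derivatives. y is a named vector in
# canonical order. Returns the derivative vector in the same order.
.derivs <- function(y, rates, mode) {
  r <- rates
  G <- y[["G"]]; Fp <- y[["Fp"]]; Fm <- y[["Fm"]]; Fc <- y[["Fc"]]
  FpFm <- y[["FpFm"]]; FcLFc <- y[["FcLFc"]]; FcMFc <- y[["FcMFc"]]
  FcBFm <- y[["FcBFm"]]; L <- y[["L_free"]]; M <- y[["M_free"]]
  B <- y[["B_free"]]; FcL <- y[["FcL"]]

  # Elongation: the end stays an end, so Fp/Fm are unchanged; each added
  # monomer contributes one backbone bond and one fresh binding site.
  # Depolymerization is first order in ends and reverses that stoichiometry.
  el_p <- r$kp_plus * Fp * G - r$kp_minus * Fp
  el_m <- r$km_plus * Fm * G - r$km_minus * Fm

  # Branching consumes a mother binding site, a brancher, and one G-actin;
  # the daughter monomer arrives with a free plus end and a free binding
  # site (so Fc is net unchanged) and a brancher-capped minus end.
  br <- r$kB_plus * Fc * B * G - r$kB_minus * FcBFm

  # Motors always crosslink via a single three-body reaction.
  mo <- r$kM_plus * M * Fc^2 - r$kM_minus * FcMFc

  if (mode == "termolecular") {
    li1 <- r$kC_plus * L * Fc^2 - r$kC_minus * FcLFc
    li2 <- 0
    dFcL <- 0
    dFcLFc <- li1
    dL <- -li1
    dFc_link <- -2 * li1
  } else { # two_step
    li1 <- r$kC1_plus * L * Fc - r$kC1_minus * FcL
    li2 <- r$kC2_plus * FcL * Fc - r$kC2_minus * FcLFc
    dFcL <- li1 - li2
    dFcLFc <- li2
    dL <- -li1
    dFc_link <- -li1 - li2
  }

  c(
    G = -el_p - el_m - br,
    Fp = br,
    Fm = 0,
    Fc = el_p + el_m + dFc_link - 2 * mo,
    FpFm = el_p + el_m,
    FcLFc = dFcLFc,
    FcMFc = mo,
    FcBFm = br,
    L_free = dL,
    M_free = -mo,
    B_free = -br,
    FcL = dFcL,
    FcM = 0
  )
}

#' Time derivatives of every kinetic species
#'
#' Evaluates the mass-action right-hand side for the five reaction families:
#' plus/minus-end (de)polymerization, Arp2/3 branching, and linker/motor
#' crosslinking, in either termolecular or two-step linker-binding mode.
#' All conservation identities (actin, linker, motor, brancher totals and
#' the three per-site bookkeeping identities) have exactly zero time
#' derivative by construction.
#'
#' @param state A kinetic state (one-row tibble or named vector, uM).
#' @param rates An [abp_rates()] object.
#' @param mode `"termolecular"` (single three-body crosslinking reaction) or
#'   `"two_step"` (sequential binding of the two linker heads).
#' @return A one-row tibble of d/dt values (uM/s), one column per species.
#' @examples
#' st <- initial_state(abp_composition(G_total = 25, L_total = 2))
#' derivatives(st, default_rates())
#' @export
derivatives <- function(state, rates, mode = c("termolecular", "two_step")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rates, "abp_rates"))
  y <- .state_vec(state)
  if (any(y < 0)) abort("negative input concentration")
  as_tibble(as.list(.derivs(y, rates, mode)))
}

#' Integrate the kinetic model
#'
#' Solves the mass-action ODE system with a stiff-capable integrator
#' (`deSolve::lsoda`).
#'
#' @inheritParams derivatives
#' @param state0 Initial kinetic state (see [initial_state()]).
#' @param times Strictly increasing output times (s); the first entry is the
#'   initial time.
#' @param rtol,atol Integrator tolerances.
#' @return A tibble of class `abp_trajectory`: column `time` plus one column
#'   per species.
#' @examples
#' comp <- abp_composition(G_total = 25, L_total = 1, n_seed = 0.1)
#' traj <- simulate_kinetics(initial_state(comp), default_rates(),
#'                           times = seq(0, 50, by = 1))
#' @export
simulate_kinetics <- function(state0, rates, times,
                              mode = c("termolecular", "two_step"),
                              rtol = 1e-8, atol = 1e-12) {
  mode <- match.arg(mode)
  stopifnot(inherits(rates, "abp_rates"))
  if (length(times) < 2 || any(diff(times) <= 0)) {
    abort("times must be strictly increasing with at least two points")
  }
  y0 <- .state_vec(state0)
  fn <- function(t, y, parms) list(.derivs(y, rates, mode))
  sol <- deSolve::lsoda(y0, times, fn, parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort(sprintf("ODE integration failed near t = %g", max(sol[, "time"])))
  }
  out <- as_tibble(as.data.frame(unclass(sol)))
  # tiny negative round-off only, within integration tolerance
  num <- names(out)[-1]
  floor_tol <- -1e-9 * max(abs(y0), 1)
  if (any(vapply(out[num], min, numeric(1)) < floor_tol)) {
    warn("trajectory has negative concentrations beyond tolerance")
  }
  out[num] <- lapply(out[num], function(x) pmax(x, 0))
  class(out) <- c("abp_trajectory", class(out))
  attr(out, "rates") <- rates
  attr(out, "mode") <- mode
  attr(out, "composition") <- attr(state0, "composition")
  out
}

#' Steady state of the kinetic model
#'
#' Integrates over geometrically growing horizons until the relative flux
#' criterion `max_i |dy_i/dt| * t / scale_i < tol` is met, where `scale_i`
#' is the larger of the species concentration and the dominant total
#' concentration.
#'
#' @inheritParams simulate_kinetics
#' @param tol Plateau tolerance (dimensionless; default 1e-9).
#' @param t0 First integration horizon (s).
#' @param t_max Maximum horizon (s); non-convergence raises an error.
#' @return A one-row tibble (class `kinetic_state`) with attributes
#'   `t_steady` (the horizon reached) and `mode`.
#' @examples
#' comp <- abp_composition(G_total = 25, L_total = 1, n_seed = 0.1)
#' steady_state(initial_state(comp), default_rates())
#' @export
steady_state <- function(state0, rates, mode = c("termolecular", "two_step"),
                         tol = 1e-9, t0 = 10, t_max = 1e7,
                         rtol = 1e-10, atol = 1e-14) {
  mode <- match.arg(mode)
  stopifnot(inherits(rates, "abp_rates"))
  y <- .state_vec(state0)
  if (all(unlist(rates) == 0) ||
      max(abs(.derivs(y, rates, mode))) == 0) {
    st <- as_tibble(as.list(y))
    class(st) <- c("kinetic_state", class(st))
    attr(st, "t_steady") <- 0
    attr(st, "mode") <- mode
    return(st)
  }
  scale0 <- max(y, 1e-12)
  fn <- function(t, yy, parms) list(.derivs(yy, rates, mode))
  t_cur <- 0
  horizon <- t0
  while (t_cur < t_max) {
    t_next <- min(t_cur + horizon, t_max)
    sol <- deSolve::lsoda(y, c(t_cur, t_next), fn, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      abort(sprintf("steady-state integration failed near t = %g", t_next))
    }
    y <- pmax(sol[nrow(sol), -1], 0)
    t_cur <- t_next
    dy <- .derivs(y, rates, mode)
    crit <- max(abs(dy) * t_cur / pmax(y, scale0))
    if (crit < tol) {
      st <- as_tibble(as.list(y))
      class(st) <- c("kinetic_state", class(st))
      attr(st, "t_steady") <- t_cur
      attr(st, "mode") <- mode
      return(st)
    }
    horizon <- horizon * 2
  }
  abort(sprintf("no steady-state plateau within t_max = %g s", t_max))
}

#' Conservation identities of a kinetic state or trajectory
#'
#' Computes the conserved totals implied by the reaction stoichiometry:
#' total actin `G + N_F`, linker, motor and brancher balances, and the three
#' per-site bookkeeping identities on the polymerized monomer count
#' `N_F = Fp + FpFm = Fm + FpFm + FcBFm
#'      = Fc + FcL + FcM + 2 FcLFc + 2 FcMFc + FcBFm`.
#'
#' @param x A kinetic state or trajectory (any data frame with species
#'   columns).
#' @return A tibble with one row per input row: the conserved totals and
#'   the maximum relative spread of the three `N_F` bookkeeping identities
#'   (`site_consistency`).
#' @export
conserved_quantities <- function(x) {
  stopifnot(is.data.frame(x))
  need <- setdiff(.species, names(x))
  for (nm in need) x[[nm]] <- 0
  nf_p <- x$Fp + x$FpFm
  nf_m <- x$Fm + x$FpFm + x$FcBFm
  nf_c <- x$Fc + x$FcL + x$FcM + 2 * x$FcLFc + 2 * x$FcMFc + x$FcBFm
  nf <- (nf_p + nf_m + nf_c) / 3
  spread <- pmax(abs(nf_p - nf), abs(nf_m - nf), abs(nf_c - nf))
  tibble(
    actin_total = x$G + nf_p,
    linker_total = x$L_free + x$FcL + x$FcLFc,
    motor_total = x$M_free + x$FcM + x$FcMFc,
    brancher_total = x$B_free + x$FcBFm,
    site_consistency = spread / pmax(nf, 1e-300)
  )
}
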