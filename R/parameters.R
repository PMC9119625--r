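#' Rate constants for the five reaction families
#'
#' Builds the set of forward/backward rate constants for the mass-action
#' kinetic model: actin polymerization and depolymerization at the plus and
#' minus ends, Arp2/3 branching, and linker / motor crosslinking.
#'
#' Crosslinking can be treated either as a single termolecular reaction
#' (`Fc + L + Fc <-> FcLFc`, forward constant in uM^-2 s^-1) or as two
#' sequential bimolecular steps (`Fc + L <-> FcL`, `FcL + Fc <-> FcLFc`,
#' per-step constants in uM^-1 s^-1). The two-step constants default to the
#' same value for both steps (non-cooperative, equal-affinity heads); pass
#' `kC1_*` / `kC2_*` explicitly for distinct steps.
#'
#' @param kp_plus,kp_minus Plus-end polymerization (uM^-1 s^-1) and
#'   depolymerization (s^-1) constants.
#' @param km_plus,km_minus Minus-end polymerization and depolymerization
#'   constants.
#' @param kB_plus,kB_minus Brancher (Arp2/3) binding (uM^-2 s^-1) and
#'   unbinding (s^-1) constants.
#' @param kC_plus,kC_minus Linker crosslinking constants. In termolecular
#'   mode these are used directly; in two-step mode they are the per-head
#'   bimolecular constants unless `kC1_*`/`kC2_*` are given.
#' @param kM_plus,kM_minus Motor crosslinking constants (termolecular).
#' @param kC1_plus,kC1_minus,kC2_plus,kC2_minus Optional distinct two-step
#'   linker constants; default to `kC_plus`/`kC_minus`.
#' @return An object of class `abp_rates` (a named list).
#' @examples
#' abp_rates(kC_plus = 1, kC_minus = 1)
#' @export
abp_rates <- function(kp_plus = 0, kp_minus = 0,
                      km_plus = 0, km_minus = 0,
                      kB_plus = 0, kB_minus = 0,
                      kC_plus = 0, kC_minus = 0,
                      kM_plus = 0, kM_minus = 0,
                      kC1_plus = NULL, kC1_minus = NULL,
                      kC2_plus = NULL, kC2_minus = NULL) {
  r <- list(
    kp_plus = kp_plus, kp_minus = kp_minus,
    km_plus = km_plus, km_minus = km_minus,
    kB_plus = kB_plus, kB_minus = kB_minus,
    kC_plus = kC_plus, kC_minus = kC_minus,
    kM_plus = kM_plus, kM_minus = kM_minus,
    kC1_plus = kC1_plus %||% kC_plus,
    kC1_minus = kC1_minus %||% kC_minus,
    kC2_plus = kC2_plus %||% kC_plus,
    kC2_minus = kC2_minus %||% kC_minus
  )
  bad <- names(r)[!vapply(r, function(x) is.numeric(x) && length(x) == 1 &&
                            is.finite(x) && x >= 0, logical(1))]
  if (length(bad)) {
    abort(paste0("rate constants must be single non-negative numbers; bad: ",
                 paste(bad, collapse = ", ")))
  }
  structure(r, class = "abp_rates")
}

#' Default rate constants
#'
#' A documented set of literature-style rate constants for exploratory runs:
#' barbed-end actin kinetics (11.6 uM^-1 s^-1 on, 1.4 s^-1 off), slower
#' pointed-end kinetics, alpha-actinin-like linker constants, slow motor
#' minifilament unbinding, and a moderate Arp2/3 branching rate. These are
#' defaults for the package's own study conditions, not fitted values; runs
#' against a specific experimental system should supply an explicit
#' configuration.
#'
#' @return An `abp_rates` object.
#' @export
default_rates <- function() {
  abp_rates(
    kp_plus = 11.6, kp_minus = 1.4,
    km_plus = 1.3, km_minus = 0.8,
    kB_plus = 0.1, kB_minus = 0.001,
    kC_plus = 0.7, kC_minus = 0.3,
    kM_plus = 0.2, kM_minus = 0.017
  )
}

#' System composition (total concentrations and seed filaments)
#'
#' @param G_total Total actin (uM).
#' @param L_total Total linker (alpha-actinin) concentration (uM).
#' @param M_total Total motor concentration (uM, minifilament units; one unit
#'   is [myosin_per_minifilament] myosin molecules).
#' @param B_total Total brancher (Arp2/3) concentration (uM).
#' @param n_seed Seed filament number concentration (uM).
#' @param len_seed Monomers per seed filament (integer >= 1).
#' @return An object of class `abp_composition`.
#' @examples
#' abp_composition(G_total = 25, L_total = 1, n_seed = 0.1, len_seed = 10)
#' @export
abp_composition <- function(G_total = 25, L_total = 0, M_total = 0,
                            B_total = 0, n_seed = 0.1, len_seed = 10) {
  vals <- c(G_total = G_total, L_total = L_total, M_total = M_total,
            B_total = B_total, n_seed = n_seed)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("all concentrations must be finite and non-negative")
  }
  if (!is.finite(len_seed) || len_seed < 1 || len_seed != round(len_seed)) {
    abort("len_seed must be an integer >= 1")
  }
  if (n_seed * len_seed > G_total + 1e-12) {
    abort("seed actin (n_seed * len_seed) exceeds G_total")
  }
  structure(list(G_total = G_total, L_total = L_total, M_total = M_total,
                 B_total = B_total, n_seed = n_seed,
                 len_seed = as.integer(len_seed)),
            class = "abp_composition")
}

#' Per-bond-type flexibility (constraint counts) for Maxwell counting
#'
#' Each bond type removes `b` degrees of freedom from the pair it joins;
#' `b = 6` is a fully rigid connection, smaller values describe flexible
#' connections (a freely rotating distance constraint removes only 1).
#'
#' @param b_pm Backbone (plus-to-minus polymerization) bond.
#' @param b_cm Brancher (Arp2/3 junction) bond.
#' @param b_cLc Linker crosslink.
#' @param b_cMc Motor crosslink.
#' @return An object of class `flexibility_map`.
#' @examples
#' flexibility_map(b_cLc = 1) # flexible alpha-actinin-like crosslinks
#' @export
flexibility_map <- function(b_pm = 6, b_cm = 6, b_cLc = 6, b_cMc = 6) {
  b <- c(b_pm = b_pm, b_cm = b_cm, b_cLc = b_cLc, b_cMc = b_cMc)
  if (any(!is.finite(b)) || any(b < 0) || any(b > 6)) {
    abort("flexibility values must lie in [0, 6]")
  }
  structure(as.list(b), class = "flexibility_map")
}

#' @export
print.abp_rates <- function(x, ...) {
  cat("<abp_rates>\n")
  for (nm in names(x)) cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.abp_composition <- function(x, ...) {
  cat("<abp_composition> (uM)\n")
  for (nm in names(x)) cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.flexibility_map <- function(x, ...) {
  cat("<flexibility_map> constraints per bond (0-6)\n")
  for (nm in names(x)) cat(sprintf("  %-6s %g\n", nm, x[[nm]]))
  invisible(x)
}
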