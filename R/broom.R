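#' Tidy a percolation fit
#'
#' @param x A `percolation_fit`.
#' @param ... Unused.
#' @return A tibble with one row per monomer site: `site`, `v` (probability
#'   the subtree entered through a bond arriving at that site is finite)
#'   and `B` (probability the site does not lead to an infinite branch).
#' @export
tidy.percolation_fit <- function(x, ...) {
  tibble(site = names(x$v), v = unname(x$v), B = unname(x$B))
}

#' Glance at a percolation fit
#'
#' @inheritParams tidy.percolation_fit
#' @return One-row tibble: `Ps`, `gel`, `spectral_radius`, `iterations`.
#' @export
glance.percolation_fit <- function(x, ...) {
  tibble(Ps = x$Ps, gel = x$gel, spectral_radius = x$spectral_radius,
         iterations = x$iterations)
}

#' Tidy a rigidity fit
#'
#' @param x A `rigidity_fit`.
#' @param ... Unused.
#' @return A tibble with one row per bond type: `bond_type`, `b`
#'   (constraints per bond), `bonds_per_monomer` (expected bonds per gel
#'   monomer) and `constraints` (their product).
#' @export
tidy.rigidity_fit <- function(x, ...) {
  b <- c(pm = x$flexibility$b_pm, cLc = x$flexibility$b_cLc,
         cMc = x$flexibility$b_cMc, cm = x$flexibility$b_cm)
  nd <- x$bond_density[names(b)]
  tibble(bond_type = names(b), b = unname(b),
         bonds_per_monomer = unname(nd),
         constraints = unname(b * nd))
}

#' Glance at a rigidity fit
#'
#' @inheritParams tidy.rigidity_fit
#' @return One-row tibble: `f`, `rigid`, `constraints`, `Ps`.
#' @export
glance.rigidity_fit <- function(x, ...) {
  tibble(f = x$f, rigid = x$rigid, constraints = x$constraints, Ps = x$Ps)
}
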