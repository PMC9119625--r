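#' Maxwell floppy-mode count on the infinite cluster
#'
#' Each F-actin monomer carries g = 6 degrees of freedom (3 translations,
#' 3 rotations); a bond of type `a->b` removes `b_{a->b}` of them from the
#' pair it joins. Counting within the infinite (gel) cluster, the floppy
#' modes per monomer are
#' \deqn{f = 6 - \tfrac12 \sum_{a\to b} b_{a\to b}\, \theta_{a\to b}\,
#'       w_{a\to b}, \qquad
#'       w_{a\to b} = \frac{1 - v_a v_b}{1 - P_s},}
#' where the sum runs over directed bond types seen from a monomer
#' (`p->m`, `m->p`, `c->c` split into linker and motor crosslinks, `c->m`,
#' `m->c`), `v` are the branch-finiteness probabilities of
#' [finite_cluster_probability()], and the factor 1/2 corrects the double
#' counting of undirected bonds. `w` is the probability that a bond at that
#' site exists-and-belongs to the infinite cluster, conditioned on the
#' monomer being in the infinite cluster; it tends to 1 deep in the gel and
#' to 4/3 at the symmetric threshold, which makes the `b = 6` rigidity
#' threshold coincide exactly with the connectivity threshold.
#'
#' @param theta Bond probabilities ([bond_probabilities()] output; the
#'   linker/motor split `theta_ccL`/`theta_ccM` is used when present,
#'   otherwise `theta_cc` is attributed to linkers).
#' @param percolation_result A `percolation_fit` for the same thetas; must
#'   be a gel (`Ps < 1`), otherwise an error is raised.
#' @param flexibility A [flexibility_map()].
#' @return An object of class `rigidity_fit`: `f` (floppy modes per gel
#'   monomer), `rigid` (`f <= 0`), and `bond_density` — expected
#'   constrained bonds per gel monomer by type.
#' @examples
#' th <- list(theta_pm = 0.9, theta_mp = 0.9, theta_cc = 0.3)
#' fit <- finite_cluster_probability(th)
#' floppy_modes(th, fit, flexibility_map())
#' @export
floppy_modes <- function(theta, percolation_result, flexibility) {
  stopifnot(inherits(percolation_result, "percolation_fit"),
            inherits(flexibility, "flexibility_map"))
  th <- .theta_list(theta)
  pr <- percolation_result
  if (!pr$gel) {
    abort("floppy_modes is defined only in the gel phase (Ps < 1)")
  }
  v <- pr$v
  one_m_ps <- 1 - pr$Ps
  w_pm <- (1 - v[["p"]] * v[["m"]]) / one_m_ps
  w_cc <- (1 - v[["c"]]^2) / one_m_ps
  w_cm <- (1 - v[["c"]] * v[["m"]]) / one_m_ps
  # bonds per gel monomer, by undirected type (each direction contributes
  # half a bond to the monomer it is seen from)
  n_pm <- 0.5 * (th$theta_pm + th$theta_mp) * w_pm
  n_cLc <- 0.5 * th$theta_ccL * w_cc
  n_cMc <- 0.5 * th$theta_ccM * w_cc
  n_cm <- 0.5 * (th$theta_cm + th$theta_mc) * w_cm
  fx <- flexibility
  constraints <- fx$b_pm * n_pm + fx$b_cLc * n_cLc + fx$b_cMc * n_cMc +
    fx$b_cm * n_cm
  f <- 6 - constraints
  res <- list(
    f = f,
    rigid = f <= 1e-12,
    bond_density = c(pm = n_pm, cLc = n_cLc, cMc = n_cMc, cm = n_cm),
    constraints = constraints,
    flexibility = fx,
    theta = th,
    Ps = pr$Ps
  )
  class(res) <- "rigidity_fit"
  res
}

#' @export
print.rigidity_fit <- function(x, ...) {
  cat(sprintf("<rigidity_fit> f = %.6g per gel monomer (%s)\n",
              x$f, if (x$rigid) "rigid" else "floppy"))
  invisible(x)
}

#' Trace a rigidity-percolation boundary along scan lines
#'
#' Bisects, along each scan line, the predicate "the system is a gel and
#' its infinite cluster has no floppy modes (f <= 0)". With all `b = 6`
#' this boundary coincides with the connectivity boundary; smaller `b_cLc`
#' pushes the boundary to higher linker concentrations.
#'
#' @inheritParams gel_boundary
#' @param flexibility A [flexibility_map()].
#' @return As [gel_boundary()]; empty when no rigid region is crossed.
#' @export
rigidity_boundary <- function(x_grid, y_grid, state_provider, flexibility,
                              edge_set = "all", rel_tol = 1e-3) {
  pred <- function(state) {
    th <- bond_probabilities(state, edge_set = edge_set)
    fit <- finite_cluster_probability(th)
    if (!fit$gel) return(FALSE)
    floppy_modes(th, fit, flexibility)$rigid
  }
  gel_boundary(x_grid, y_grid, state_provider, edge_set = edge_set,
               predicate = pred, rel_tol = rel_tol)
}
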