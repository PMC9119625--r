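#' Equilibrium of the isolated two-step linker-binding system
#'
#' Both linker heads bind actin binding sites independently (non-cooperative
#' binding): `Fc + L <-> FcL` with association constant `K1` and
#' `FcL + Fc <-> FcLFc` with `K2` (both uM^-1). At equilibrium
#' `FcL = K1 * Fc * L_free` and `FcLFc = K2 * Fc * FcL`. The solver reduces
#' the two mass balances to a single strictly monotone function of the free
#' binding-site concentration and bisects it, so the returned root is the
#' unique non-negative equilibrium.
#'
#' @param Fc_total Total binding-site concentration (uM).
#' @param L_total Total linker concentration (uM).
#' @param K1,K2 Association constants for the first and second head
#'   (uM^-1); with the default convention both heads share `K_c`.
#' @param tol Relative residual tolerance on the mass balances.
#' @return A one-row tibble: concentrations `Fc_free`, `FcL`, `FcLFc`,
#'   `L_free` (uM) and the site-state fractions `frac_free`, `frac_single`,
#'   `frac_crosslinked` (fractions of total binding sites; a crosslink
#'   occupies two sites).
#' @examples
#' equilibrium_fractions(Fc_total = 25, L_total = 13, K1 = 1, K2 = 1)
#' @export
equilibrium_fractions <- function(Fc_total, L_total, K1, K2 = K1,
                                  tol = 1e-10) {
  stopifnot(Fc_total >= 0, L_total >= 0, K1 >= 0, K2 >= 0)
  if (Fc_total == 0 || L_total == 0 || K1 == 0) {
    # K1 = 0 blocks the first step, hence also crosslinks
    out <- tibble(Fc_free = Fc_total, FcL = 0, FcLFc = 0, L_free = L_total)
  } else {
    # Given free sites x, the linker balance gives L_free explicitly;
    # the site balance residual s(x) is strictly increasing in x.
    lfree <- function(x) L_total / (1 + K1 * x + K1 * K2 * x^2)
    site_res <- function(x) {
      L <- lfree(x)
      x + K1 * x * L + 2 * K1 * K2 * x^2 * L - Fc_total
    }
    x <- uniroot(site_res, c(0, Fc_total), tol = .Machine$double.eps^0.75,
                 extendInt = "no")$root
    # polish by bisection to machine precision (uniroot tol is on x)
    lo <- max(0, x * (1 - 1e-6)); hi <- min(Fc_total, x * (1 + 1e-6) + 1e-300)
    if (site_res(lo) > 0) lo <- 0
    if (site_res(hi) < 0) hi <- Fc_total
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (site_res(mid) <= 0) lo <- mid else hi <- mid
      if (hi - lo <= .Machine$double.eps * max(hi, 1)) break
    }
    x <- (lo + hi) / 2
    L <- lfree(x)
    out <- tibble(Fc_free = x, FcL = K1 * x * L, FcLFc = K1 * K2 * x^2 * L,
                  L_free = L)
    res_site <- abs(out$Fc_free + out$FcL + 2 * out$FcLFc - Fc_total) /
      max(Fc_total, 1e-300)
    res_link <- abs(out$L_free + out$FcL + out$FcLFc - L_total) /
      max(L_total, 1e-300)
    if (max(res_site, res_link) > tol) {
      abort("equilibrium solver failed to meet residual tolerance")
    }
  }
  denom <- max(Fc_total, 1e-300)
  out$frac_free <- out$Fc_free / denom
  out$frac_single <- out$FcL / denom
  out$frac_crosslinked <- 2 * out$FcLFc / denom
  out
}

#' Crosslink fraction over a (linker, affinity) grid
#'
#' Applies [equilibrium_fractions()] element-wise over grids of total linker
#' concentration and association constant, reporting the proportion of
#' binding sites engaged in crosslinks, `2 FcLFc / Fc_total` (bounded by
#' 1; the pair concentration `FcLFc/Fc_total` is bounded by 0.5).
#'
#' @inheritParams equilibrium_fractions
#' @param L_grid,K_grid Positive numeric grids (typically log-spaced).
#' @return A long tibble of class `crosslink_surface`: `K`, `L`,
#'   the equilibrium concentrations and fractions, and
#'   `crosslink_pairs = FcLFc / Fc_total`.
#' @export
crosslink_surface <- function(Fc_total, L_grid, K_grid) {
  stopifnot(all(L_grid >= 0), all(K_grid >= 0), length(L_grid) > 0,
            length(K_grid) > 0)
  grid <- tidyr::expand_grid(K = K_grid, L = L_grid)
  eq <- purrr::map2(grid$K, grid$L,
                    ~ equilibrium_fractions(Fc_total, .y, K1 = .x))
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(eq))
  out$crosslink_pairs <- out$FcLFc / max(Fc_total, 1e-300)
  class(out) <- c("crosslink_surface", class(out))
  attr(out, "Fc_total") <- Fc_total
  out
}

#' Linker concentration maximizing the crosslink concentration
#'
#' At fixed affinity the crosslink concentration `FcLFc` is unimodal in the
#' total linker concentration: it rises while linkers are scarce and decays
#' once singly-bound linkers saturate the binding sites. The interior
#' maximizer is located by golden-section search on a log-linker axis.
#'
#' @inheritParams equilibrium_fractions
#' @param K Association constant `K_c` (uM^-1), used for both heads.
#' @param L_range Search bracket for the total linker concentration (uM);
#'   defaults to `Fc_total * c(1e-4, 1e4)`.
#' @return A one-row tibble: `L_star` (uM), `FcLFc_max` (uM) and
#'   `crosslink_pairs_max`. If `K` is so small that the curve is flat
#'   (peak below `1e-12 * Fc_total`), `L_star` is `NA`.
#' @examples
#' argmax_linker(Fc_total = 25, K = 1)
#' @export
argmax_linker <- function(Fc_total, K, L_range = NULL) {
  stopifnot(Fc_total > 0, K >= 0)
  L_range <- L_range %||% (Fc_total * c(1e-4, 1e4))
  f <- function(logL) {
    equilibrium_fractions(Fc_total, exp(logL), K1 = K)$FcLFc
  }
  opt <- optimize(f, log(L_range), maximum = TRUE,
                  tol = .Machine$double.eps^0.5)
  peak <- opt$objective
  L_star <- exp(opt$maximum)
  if (peak < 1e-12 * Fc_total) L_star <- NA_real_
  tibble(L_star = L_star, FcLFc_max = peak,
         crosslink_pairs_max = peak / Fc_total)
}

#' Sol-gel boundary of the two-step linker system for finite chains
#'
#' For chains of `N` binding sites the classical Flory-Stockmayer
#' vulcanization threshold is a per-site crosslink probability
#' `p_c(N) = 1/(N - 1)`. For each affinity on the grid this returns the
#' total linker concentrations where `p = 2 FcLFc / Fc_total` crosses the
#' threshold. Because `p(L)` is unimodal there are either zero crossings
#' (never gels at this affinity) or two: a low-linker gelation and a
#' high-linker re-entry into the sol (the two sol-gel transitions).
#'
#' @inheritParams argmax_linker
#' @param filament_len_N Number of binding sites per chain (>= 2).
#' @param K_grid Association-constant grid (uM^-1).
#' @return A tibble with one row per affinity that gels: `K`, `L_lower`,
#'   `L_upper` (uM), and `p_max`. Affinities whose peak never reaches the
#'   threshold are absent.
#' @export
percolation_curve <- function(filament_len_N, Fc_total, K_grid,
                              L_range = NULL) {
  stopifnot(filament_len_N >= 2, Fc_total > 0, all(K_grid >= 0))
  p_c <- 1 / (filament_len_N - 1)
  L_range <- L_range %||% (Fc_total * c(1e-4, 1e4))
  rows <- purrr::map(K_grid, function(K) {
    pk <- argmax_linker(Fc_total, K, L_range)
    p_max <- 2 * pk$crosslink_pairs_max
    if (!is.finite(pk$L_star) || p_max <= p_c) return(NULL)
    pfun <- function(L) {
      2 * equilibrium_fractions(Fc_total, L, K1 = K)$FcLFc / Fc_total - p_c
    }
    lo <- uniroot(pfun, c(L_range[1], pk$L_star),
                  tol = .Machine$double.eps^0.6)$root
    hi <- uniroot(pfun, c(pk$L_star, L_range[2]),
                  tol = .Machine$double.eps^0.6)$root
    tibble(K = K, L_lower = lo, L_upper = hi, p_max = p_max)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(K = numeric(), L_lower = numeric(), L_upper = numeric(),
                  p_max = numeric())
  }
  attr(out, "p_c") <- p_c
  out
}
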