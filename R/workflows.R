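#' Run a named analysis workflow
#'
#' Reproduces the package's standard analyses end to end and writes tidy
#' CSVs (long format, metadata header). Available workflows:
#'
#' * `fig1c` / `fig1d`: kinetic time course and the fraction of monomers in
#'   finite clusters `Ps(t)` for the default composition without
#'   (`B_total = 0`) / with (`B_total = 0.5` uM) brancher.
#' * `fig2`: two-step linker-binding site-state fractions against total
#'   linker concentration at `Fc_total = 25` uM, `K_c = 1` uM^-1.
#' * `fig3`: crosslink-fraction heatmap over normalized `(L, K)` grids.
#' * `fig5`: steady-state `Ps` over the (linker, motor) plane, without and
#'   with 0.5 uM brancher, plus connectivity boundary polylines.
#' * `fig6`: steady-state `Ps` over the (brancher, linker) plane.
#' * `fig7`: `Ps` over the (linker, motor) plane under the full edge set
#'   and under linker-only connections.
#' * `fig8`: regime classification (sol / motor+linker gel / linker gel)
#'   over the (linker, motor) plane.
#' * `fig9`: connectivity boundary plus rigidity boundaries for linker
#'   flexibilities `b_cLc = 1..6` (both edge sets).
#'
#' @param name Workflow name (see above).
#' @param config A configuration list or `abp_config`; `NULL` uses the
#'   defaults of [validate_config()]. Kinetics-based workflows fall back to
#'   [default_rates()] only with a recorded `rates_defaulted` flag.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of written files, invisibly; the main
#'   result tibble(s) as attribute `"results"`.
#' @export
run_figure_workflow <- function(name, config = NULL, out_dir = ".") {
  valid <- c("fig1c", "fig1d", "fig2", "fig3", "fig5", "fig6", "fig7",
             "fig8", "fig9")
  if (!is.character(name) || length(name) != 1 || !name %in% valid) {
    abort(paste0("unknown workflow name; valid names: ",
                 paste(valid, collapse = ", ")))
  }
  cfg <- if (inherits(config, "abp_config")) config else validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(cfg$seed)
  out <- switch(
    name,
    fig1c = .wf_timecourse(cfg, B_total = 0, tag = name, out_dir),
    fig1d = .wf_timecourse(cfg, B_total = 0.5, tag = name, out_dir),
    fig2 = .wf_twostep_curves(cfg, out_dir),
    fig3 = .wf_crosslink_surface(cfg, out_dir),
    fig5 = .wf_ps_grid_arp_pair(cfg, out_dir),
    fig6 = .wf_arp_linker_grid(cfg, out_dir),
    fig7 = .wf_edge_set_pair(cfg, out_dir),
    fig8 = .wf_regimes(cfg, out_dir),
    fig9 = .wf_rigidity(cfg, out_dir)
  )
  invisible(out)
}

.wf_finish <- function(results, files) {
  attr(files, "results") <- results
  files
}

.wf_timecourse <- function(cfg, B_total, tag, out_dir) {
  cm <- unclass(cfg$composition)
  cm$B_total <- B_total
  cm <- do.call(abp_composition, cm)
  traj <- simulate_kinetics(initial_state(cm), cfg$rates, cfg$times,
                            mode = cfg$mode, rtol = cfg$solver$rtol,
                            atol = cfg$solver$atol)
  ps <- ps_timeseries(traj, edge_set = cfg$edge_set)
  res <- dplyr::left_join(as_tibble(traj), ps, by = "time")
  f <- file.path(out_dir, paste0(tag, "_timecourse.csv"))
  write_result_csv(res, f, cfg)
  .wf_finish(list(timecourse = res), c(timecourse = f))
}

.wf_twostep_curves <- function(cfg, out_dir) {
  Fc_total <- 25
  K <- 1
  L_grid <- exp(seq(log(1e-2), log(1e4), length.out = 200))
  rows <- purrr::map(L_grid, ~ equilibrium_fractions(Fc_total, .x, K1 = K))
  res <- dplyr::bind_cols(tibble(L_total = L_grid), dplyr::bind_rows(rows))
  long <- tidyr::pivot_longer(
    res[, c("L_total", "frac_free", "frac_single", "frac_crosslinked")],
    -"L_total", names_to = "site_state", values_to = "fraction")
  f <- file.path(out_dir, "fig2_twostep_fractions.csv")
  write_result_csv(long, f, cfg)
  .wf_finish(list(fractions = res), c(fractions = f))
}

.wf_crosslink_surface <- function(cfg, out_dir) {
  Fc_total <- 25
  L_grid <- Fc_total * exp(seq(log(1e-2), log(1e2), length.out = 41))
  K_grid <- exp(seq(log(1e-2), log(1e2), length.out = 41)) / Fc_total
  surf <- crosslink_surface(Fc_total, L_grid, K_grid)
  f <- file.path(out_dir, "fig3_crosslink_surface.csv")
  write_result_csv(as_tibble(surf), f, cfg)
  .wf_finish(list(surface = surf), c(surface = f))
}

.wf_require_rates <- function(cfg) {
  # kinetics workflows need rate constants; defaults are allowed but the
  # provenance flag must be present so outputs record it
  if (is.null(cfg$rates)) abort("configuration supplies no rate constants")
}

.wf_ps_grid_arp_pair <- function(cfg, out_dir) {
  .wf_require_rates(cfg)
  grids <- purrr::map(c(no_arp = 0, with_arp = 0.5), function(B) {
    cm <- unclass(cfg$composition)
    cm$B_total <- B
    prov <- steady_state_provider(do.call(abp_composition, cm), cfg$rates,
                                  "L_total", "M_total", mode = cfg$mode)
    sc <- regime_scan(cfg$scan$x, cfg$scan$y, prov)
    bd <- gel_boundary(cfg$scan$x, cfg$scan$y, prov, edge_set = cfg$edge_set)
    list(scan = sc, boundary = bd)
  })
  res <- dplyr::bind_rows(
    dplyr::mutate(grids$no_arp$scan, B_total = 0),
    dplyr::mutate(grids$with_arp$scan, B_total = 0.5))
  bnd <- dplyr::bind_rows(
    dplyr::mutate(grids$no_arp$boundary, B_total = 0),
    dplyr::mutate(grids$with_arp$boundary, B_total = 0.5))
  f1 <- file.path(out_dir, "fig5_ps_grid.csv")
  f2 <- file.path(out_dir, "fig5_boundary.csv")
  write_result_csv(res, f1, cfg)
  write_result_csv(bnd, f2, cfg)
  .wf_finish(list(scan = res, boundary = bnd), c(grid = f1, boundary = f2))
}

.wf_arp_linker_grid <- function(cfg, out_dir) {
  .wf_require_rates(cfg)
  cm <- cfg$composition
  prov <- steady_state_provider(cm, cfg$rates, "L_total", "B_total",
                                mode = cfg$mode)
  B_grid <- cfg$scan$y
  sc <- regime_scan(cfg$scan$x, B_grid, prov)
  names(sc)[names(sc) == "y"] <- "B_total"
  names(sc)[names(sc) == "x"] <- "L_total"
  f <- file.path(out_dir, "fig6_arp_grid.csv")
  write_result_csv(sc, f, cfg)
  .wf_finish(list(scan = sc), c(grid = f))
}

.wf_edge_set_pair <- function(cfg, out_dir) {
  .wf_require_rates(cfg)
  prov <- steady_state_provider(cfg$composition, cfg$rates,
                                "L_total", "M_total", mode = cfg$mode)
  sc <- regime_scan(cfg$scan$x, cfg$scan$y, prov)
  long <- tidyr::pivot_longer(sc, c("Ps_all", "Ps_linker"),
                              names_to = "edge_set", values_to = "Ps")
  long$edge_set <- ifelse(long$edge_set == "Ps_all", "all", "linker_only")
  f <- file.path(out_dir, "fig7_edge_sets.csv")
  write_result_csv(long, f, cfg)
  .wf_finish(list(scan = sc), c(grid = f))
}

.wf_regimes <- function(cfg, out_dir) {
  .wf_require_rates(cfg)
  prov <- steady_state_provider(cfg$composition, cfg$rates,
                                "L_total", "M_total", mode = cfg$mode)
  sc <- regime_scan(cfg$scan$x, cfg$scan$y, prov)
  f <- file.path(out_dir, "fig8_regimes.csv")
  write_result_csv(sc, f, cfg)
  .wf_finish(list(scan = sc), c(grid = f))
}

.wf_rigidity <- function(cfg, out_dir) {
  .wf_require_rates(cfg)
  prov <- steady_state_provider(cfg$composition, cfg$rates,
                                "L_total", "M_total", mode = cfg$mode)
  conn <- dplyr::mutate(
    gel_boundary(cfg$scan$x, cfg$scan$y, prov, edge_set = cfg$edge_set),
    b_cLc = NA_real_, kind = "connectivity")
  rig <- purrr::map(6:1, function(b) {
    fx <- flexibility_map(b_cLc = b)
    dplyr::mutate(
      rigidity_boundary(cfg$scan$x, cfg$scan$y, prov, fx,
                        edge_set = cfg$edge_set),
      b_cLc = b, kind = "rigidity")
  })
  res <- dplyr::bind_rows(c(list(conn), rig))
  f <- file.path(out_dir, "fig9_rigidity_boundaries.csv")
  write_result_csv(res, f, cfg)
  .wf_finish(list(boundaries = res), c(boundaries = f))
}
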