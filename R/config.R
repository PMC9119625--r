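#' Read a run configuration (YAML or JSON)
#'
#' @param path File path; format chosen by extension (`.yml`/`.yaml` or
#'   `.json`).
#' @return The parsed configuration list (not yet validated; see
#'   [validate_config()]).
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    abort("config must be a .yaml/.yml or .json file")
  }
}

#' Validate and normalize a run configuration
#'
#' Fills defaults, converts units, and reports every problem at once.
#' Recognized top-level fields:
#' * `composition`: fields of [abp_composition()] (uM);
#' * `motor_units`: `"minifilament"` (default) or `"molecules"` — the
#'   latter divides `M_total` by 22.5 myosin molecules per minifilament;
#' * `rates`: fields of [abp_rates()]; missing means [default_rates()]
#'   with `rates_defaulted = TRUE` recorded;
#' * `mode`: `"termolecular"` (default) or `"two_step"`;
#' * `edge_set`: `"all"` (default) or `"linker_only"`;
#' * `flexibility`: fields of [flexibility_map()];
#' * `solver`: `rtol`, `atol`, `tol` (all > 0);
#' * `times`: output time grid for kinetics runs (s);
#' * `seed`: integer RNG seed;
#' * `scan`: `x_field`, `y_field` (composition field names), `x`, `y`
#'   (explicit grids) or `*_min`/`*_max`/`*_n`/`*_log`.
#'
#' @param config A configuration list (e.g. from [read_config()]); `NULL`
#'   gives the full default configuration.
#' @return The normalized configuration (class `abp_config`) or an error
#'   listing every offending field.
#' @export
validate_config <- function(config = NULL) {
  config <- config %||% list()
  if (!is.list(config)) abort("config must be a list")
  errs <- character()
  note <- function(msg) errs <<- c(errs, msg)

  comp_in <- config$composition %||% list()
  if (identical(config$motor_units %||% "minifilament", "molecules") &&
      !is.null(comp_in$M_total)) {
    comp_in$M_total <- comp_in$M_total / myosin_per_minifilament
  } else if (!(config$motor_units %||% "minifilament") %in%
             c("minifilament", "molecules")) {
    note("motor_units must be 'minifilament' or 'molecules'")
  }
  extra <- setdiff(names(comp_in),
                   c("G_total", "L_total", "M_total", "B_total",
                     "n_seed", "len_seed"))
  if (length(extra)) note(paste0("unknown composition fields: ",
                                 paste(extra, collapse = ", ")))
  comp <- tryCatch(
    do.call(abp_composition, comp_in[setdiff(names(comp_in), extra)]),
    error = function(e) { note(paste0("composition: ", conditionMessage(e))); NULL })

  rates_defaulted <- is.null(config$rates)
  rates <- if (rates_defaulted) default_rates() else tryCatch(
    do.call(abp_rates, as.list(config$rates)),
    error = function(e) { note(paste0("rates: ", conditionMessage(e))); NULL })

  mode <- config$mode %||% "termolecular"
  if (!mode %in% c("termolecular", "two_step")) {
    note("mode must be 'termolecular' or 'two_step'")
  }
  edge_set <- config$edge_set %||% "all"
  if (!edge_set %in% c("all", "linker_only")) {
    note("edge_set must be 'all' or 'linker_only'")
  }

  flex <- tryCatch(do.call(flexibility_map,
                           as.list(config$flexibility %||% list())),
                   error = function(e) {
                     note(paste0("flexibility: ", conditionMessage(e))); NULL })

  solver <- modifyList(list(rtol = 1e-8, atol = 1e-12, tol = 1e-9),
                       as.list(config$solver %||% list()))
  if (any(unlist(solver) <= 0)) note("solver tolerances must be > 0")

  times <- config$times %||% seq(0, 2000, by = 10)
  if (length(times) < 2 || any(diff(times) <= 0)) {
    note("times must be strictly increasing with >= 2 points")
  }

  seed <- config$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1) note("seed must be one integer")

  scan <- as.list(config$scan %||% list())
  scan$x_field <- scan$x_field %||% "L_total"
  scan$y_field <- scan$y_field %||% "M_total"
  comp_fields <- c("G_total", "L_total", "M_total", "B_total", "n_seed")
  if (!scan$x_field %in% comp_fields || !scan$y_field %in% comp_fields) {
    note(paste0("scan axes must be composition fields (",
                paste(comp_fields, collapse = ", "), ")"))
  }
  axis_grid <- function(axis) {
    if (!is.null(scan[[axis]])) return(as.numeric(scan[[axis]]))
    lo <- scan[[paste0(axis, "_min")]] %||% 1e-3
    hi <- scan[[paste0(axis, "_max")]] %||% 10
    n <- scan[[paste0(axis, "_n")]] %||% 9
    logax <- scan[[paste0(axis, "_log")]] %||% TRUE
    if (n < 1 || hi <= lo || (logax && lo <= 0)) {
      note(paste0("invalid scan grid for axis ", axis)); return(NULL)
    }
    if (logax) exp(seq(log(lo), log(hi), length.out = n))
    else seq(lo, hi, length.out = n)
  }
  scan$x <- axis_grid("x")
  scan$y <- axis_grid("y")
  if (!is.null(scan$x) && length(scan$x) == 0) note("scan x grid is empty")
  if (!is.null(scan$y) && length(scan$y) == 0) note("scan y grid is empty")

  if (length(errs)) {
    abort(paste0("invalid configuration:\n- ",
                 paste(errs, collapse = "\n- ")))
  }
  structure(list(
    composition = comp, rates = rates, rates_defaulted = rates_defaulted,
    mode = mode, edge_set = edge_set, flexibility = flex, solver = solver,
    times = as.numeric(times), seed = as.integer(seed), scan = scan
  ), class = "abp_config")
}

#' Emit a normalized configuration as a plain list
#'
#' Round-trip companion of [validate_config()]:
#' `validate_config(emit_config(cfg))` reproduces `cfg`.
#'
#' @param config An `abp_config`.
#' @return A plain list suitable for [yaml::write_yaml()] or
#'   [jsonlite::write_json()].
#' @export
emit_config <- function(config) {
  stopifnot(inherits(config, "abp_config"))
  out <- list(
    composition = unclass(config$composition),
    mode = config$mode,
    edge_set = config$edge_set,
    flexibility = unclass(config$flexibility),
    solver = config$solver,
    times = config$times,
    seed = config$seed,
    scan = config$scan[c("x_field", "y_field", "x", "y")]
  )
  if (!config$rates_defaulted) out$rates <- unclass(config$rates)
  out
}

# Header block written at the top of every output CSV: full normalized
# config + package version, as commented JSON.
.metadata_header <- function(config) {
  meta <- list(
    package = "actogel",
    version = as.character(utils::packageVersion("actogel")),
    config = emit_config(config)
  )
  paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
}

#' Write a tibble as CSV with an embedded metadata header
#'
#' @param x A data frame.
#' @param path Output path.
#' @param config The normalized `abp_config` of the run.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path, config) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(.metadata_header(config), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}
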