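# Configuration files, experiment orchestration, and plain-text serialization.

config_defaults <- list(
  grid = list(nq = 161L, np = 161L, s_bar = 5, ds_store = 0.01),
  solver = list(tol = 1e-6, max_sweeps = 2000L, u_max = NULL, cfl = 0.9),
  # "n_paths" rather than "n": a bare `n` is a YAML 1.1 boolean
  simulation = list(dt = 1e-3, n_paths = 10000L, seed = 1L, t_max = 200,
                    x0 = list(c(0.26, 0.665)), s_bar = list(5),
                    fallback = "dstar"))

#' Load an experiment configuration
#'
#' Reads a YAML experiment configuration with blocks `model` (a `tag` of
#' `"egt"`, `"sr"` or `"toy"` plus named parameter fields passed to the
#' matching constructor), `grid`, `solver`, `simulation` and `output`.
#' Missing fields get package defaults; unknown blocks or fields are
#' rejected with their path. The provenance of every resolved field
#' (`"user"` or `"default"`) is recorded in the `provenance` attribute, and
#' parameter invariants are enforced by the parameter constructors.
#'
#' @param path path to a YAML file.
#' @return A list of class `tx_config` with elements `params`, `grid`,
#'   `solver`, `simulation`, `output`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- c("model", "grid", "solver", "simulation", "output")
  bad <- setdiff(names(raw), known)
  if (length(bad)) abort(sprintf("unknown config block(s): %s",
                                 paste(bad, collapse = ", ")))
  if (is.null(raw$model$tag)) abort("config must set model: tag")
  ctor <- switch(raw$model$tag,
                 egt = egt_params, sr = sr_params, toy = toy_params,
                 abort(sprintf("unknown model tag '%s'", raw$model$tag)))
  margs <- raw$model[setdiff(names(raw$model), "tag")]
  allowed <- names(formals(ctor))
  badf <- setdiff(names(margs), allowed)
  if (length(badf)) abort(sprintf("unknown model field(s): %s",
                                  paste0("model.", badf, collapse = ", ")))
  params <- do.call(ctor, margs)

  resolve <- function(block) {
    user <- raw[[block]] %||% list()
    defs <- config_defaults[[block]]
    badf <- setdiff(names(user), names(defs))
    if (length(badf)) abort(sprintf("unknown config field(s): %s",
                                    paste0(block, ".", badf, collapse = ", ")))
    out <- modifyList(defs, user)
    attr(out, "provenance") <-
      setNames(ifelse(names(defs) %in% names(user), "user", "default"),
               names(defs))
    out
  }
  sim <- resolve("simulation")
  # canonical forms, so round-tripped configs hash identically
  sim$s_bar <- as.numeric(unlist(sim$s_bar))
  if (!is.list(sim$x0)) sim$x0 <- list(sim$x0)
  sim$x0 <- lapply(sim$x0, as.numeric)
  cfg <- list(params = params,
              model_tag = raw$model$tag,
              grid = resolve("grid"),
              solver = resolve("solver"),
              simulation = sim,
              output = raw$output %||% list(dir = "thresholdtx-output"))
  structure(cfg, class = "tx_config",
            provenance = list(
              model = setNames(ifelse(allowed %in% names(margs),
                                      "user", "default"), allowed),
              grid = attr(cfg$grid, "provenance"),
              solver = attr(cfg$solver, "provenance"),
              simulation = attr(cfg$simulation, "provenance")))
}

#' Save a configuration back to YAML
#'
#' Writes the resolved configuration so that [load_config()] round-trips it.
#'
#' @param config a `tx_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "tx_config"))
  pars <- unclass(config$params)
  out <- list(model = c(list(tag = config$model_tag), pars),
              grid = strip_attrs(config$grid),
              solver = strip_attrs(config$solver),
              simulation = strip_attrs(config$simulation),
              output = config$output)
  # drop NULLs (yaml cannot represent them losslessly)
  out <- purrr::map(out, function(b) b[!vapply(b, is.null, logical(1))])
  yaml::write_yaml(out, path)
  invisible(path)
}

strip_attrs <- function(x) { attributes(x) <- list(names = names(x)); x }

config_hash <- function(config) rlang::hash(strip_config(config))
strip_config <- function(config) {
  list(params = unclass(config$params), tag = config$model_tag,
       grid = strip_attrs(config$grid), solver = strip_attrs(config$solver),
       simulation = strip_attrs(config$simulation))
}

#' Run a full config-driven experiment
#'
#' Orchestrates the standard experiment pattern: solve the deterministic HJB
#' for the cost-to-go `u` and its bang-bang policy, solve the threshold-aware
#' HJB for the success-probability cube `v`, simulate cost ensembles from each
#' configured initial state under the deterministic-optimal policy, the MTD
#' policy and each configured threshold-aware budget (with the configured
#' fallback after depletion), and write CSV/JSON outputs. Re-running with the
#' same configuration and seed reproduces identical payloads; every output
#' name is listed in the returned manifest and each CSV carries the config
#' hash in a comment header.
#'
#' @param config a `tx_config` from [load_config()].
#' @param out_dir output directory (created if needed); defaults to the
#'   config's `output$dir`.
#' @return A tibble manifest of written files (invisibly also written as
#'   `manifest.csv`).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "tx_config"))
  out_dir <- out_dir %||% config$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  model <- controlled_diffusion(config$params)
  g <- config$grid; so <- config$solver; si <- config$simulation

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("experiment stage '%s' failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }

  u <- stage("solve-deterministic", solve_deterministic_hjb(
    model, nq = g$nq, np = g$np, u_max = so$u_max,
    tol = so$tol, max_sweeps = so$max_sweeps))
  files <- write_value_field(u, file.path(out_dir, "u"), hash = hash)

  cube <- stage("solve-threshold", solve_threshold_hjb(
    model, s_bar = g$s_bar, nq = g$nq, np = g$np,
    ds_store = g$ds_store, cfl = so$cfl))
  files <- c(files, write_value_cube(cube, file.path(out_dir, "v"),
                                     hash = hash))

  fb <- switch(si$fallback,
               dstar = u, mtd = constant_policy(model$params$d_max, model),
               none = constant_policy(0, model),
               abort("simulation.fallback must be 'dstar', 'mtd' or 'none'"))
  x0s <- si$x0
  if (!is.list(x0s)) x0s <- list(x0s)
  cdf_rows <- list()
  sum_rows <- list()
  for (ix in seq_along(x0s)) {
    x0 <- as_state(x0s[[ix]])
    pols <- list(dstar = list(policy = u),
                 mtd = list(policy = constant_policy(model$params$d_max, model)))
    for (sb in unlist(si$s_bar)) {
      pols[[sprintf("threshold_s%g", sb)]] <-
        list(policy = cube, s_bar = sb, fallback = fb)
    }
    cmp <- stage("simulate", compare_policies(
      model, x0, pols, dt = si$dt, n = si$n_paths, seed = si$seed,
      t_max = si$t_max))
    cdf_rows[[ix]] <- dplyr::mutate(as_tibble(cmp), q0 = x0[1], p0 = x0[2])
    sums <- purrr::imap_dfr(attr(cmp, "ensembles"), function(e, nm) {
      dplyr::mutate(summarize_ensemble(e), policy = nm, .before = 1)
    })
    sum_rows[[ix]] <- dplyr::mutate(sums, q0 = x0[1], p0 = x0[2])
  }
  cdf_path <- file.path(out_dir, "cdf.csv")
  write_csv_hashed(dplyr::bind_rows(cdf_rows), cdf_path, hash)
  sum_path <- file.path(out_dir, "summary.csv")
  write_csv_hashed(dplyr::bind_rows(sum_rows), sum_path, hash)
  files <- c(files, cdf_path, sum_path)

  manifest <- tibble(file = files, config_hash = hash,
                     seed = si$seed)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

write_csv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  write.csv(dplyr::select(df, !dplyr::where(is.list)), con, row.names = FALSE)
  invisible(path)
}

#' Serialize a value field or cube to plain text
#'
#' Writes the grid values as long-format CSV plus a JSON metadata sidecar
#' (grid axes, solver diagnostics, parameter echo, optional config hash).
#'
#' @param field a `value_field`.
#' @param prefix output path prefix; `<prefix>.csv` and `<prefix>_meta.json`
#'   are written.
#' @param hash optional config hash to embed.
#' @return The written file paths.
#' @export
write_value_field <- function(field, prefix, hash = NULL) {
  stopifnot(inherits(field, "value_field"))
  csv <- paste0(prefix, ".csv"); meta <- paste0(prefix, "_meta.json")
  write.csv(tidy(field), csv, row.names = FALSE)
  jsonlite::write_json(
    list(kind = "value_field", params = unclass(field$model$params),
         model = field$model$label, u_max = field$u_max,
         residual = field$residual, sweeps = field$sweeps,
         converged = field$converged, config_hash = hash),
    meta, auto_unbox = TRUE, digits = NA, null = "null")
  c(csv, meta)
}

#' @rdname write_value_field
#' @export
read_value_field <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$kind, "value_field")) abort("not a value_field payload")
  df <- read.csv(paste0(prefix, ".csv"))
  qs <- sort(unique(df$q)); ps <- sort(unique(df$p))
  df <- df[order(df$p, df$q), ]
  params <- meta$params
  ctor <- switch(meta$model, egt_params = egt_params, sr_params = sr_params,
                 toy_params = toy_params)
  pobj <- do.call(ctor, as.list(params))
  model <- controlled_diffusion(pobj)
  structure(
    list(u = matrix(df$u, length(qs), length(ps)),
         policy = matrix(as.integer(df$dose > 0), length(qs), length(ps)),
         q = qs, p = ps, u_max = meta$u_max, tol = NA_real_,
         sweeps = meta$sweeps, residual = meta$residual,
         residual_history = NULL, converged = meta$converged, model = model),
    class = "value_field")
}

#' @rdname write_value_field
#' @param cube a `value_cube`.
#' @param s budget slices to write (default: up to 6 evenly chosen stored
#'   slices).
#' @export
write_value_cube <- function(cube, prefix, s = NULL, hash = NULL) {
  stopifnot(inherits(cube, "value_cube"))
  if (is.null(s)) {
    ns <- length(cube$s)
    s <- cube$s[unique(round(seq(1, ns, length.out = min(6, ns))))]
  }
  csv <- paste0(prefix, ".csv"); meta <- paste0(prefix, "_meta.json")
  write.csv(tidy(cube, s = s), csv, row.names = FALSE)
  jsonlite::write_json(
    list(kind = "value_cube", params = unclass(cube$model$params),
         model = cube$model$label, s_bar = cube$s_bar, ds = cube$ds,
         n_levels = cube$n_levels, cfl_bound = cube$cfl_bound,
         max_clip = cube$max_clip, s_written = s, config_hash = hash),
    meta, auto_unbox = TRUE, digits = NA, null = "null")
  c(csv, meta)
}
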