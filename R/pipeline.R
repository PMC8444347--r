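# End-to-end pipeline: model -> solver -> RDMs -> observables -> fit.
#
# Configuration is a plain named list (or a YAML file of one); every key is
# validated and unknown keys are errors, so a typo in `dtau` or a seed can
# never silently corrupt a run.  1-based orbital indexing everywhere in
# user-facing files (FCIDUMP convention).

CONFIG_KEYS <- list(
  top = c("workspace", "model", "sector", "solver", "engine", "observables",
          "fit"),
  model = c("type", "n_sites", "t", "U", "topology", "n_centers",
            "orbitals_per_center", "intra_exchange", "inter_hopping",
            "on_site_U", "path"),
  sector = c("n_electrons", "twice_S"),
  engine = c("n_iterations", "dtau", "target_walkers", "seeds", "rdm",
             "n_core", "burnin", "kill_threshold", "shift_damping",
             "shift_interval", "initial_walkers", "rdm_floor"),
  observables = c("fragments", "reference_orbital"),
  fit = c("model", "S_A", "S_B", "S_values", "solver"))

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0L)
    stop(sprintf("unknown %s configuration key(s): %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' Validate and normalize a run configuration
#'
#' @param config A named list, or the path of a YAML file containing one.
#' @return The validated configuration list (class `"gugaci_config"`).
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  check_keys(config, CONFIG_KEYS$top, "top-level")
  if (is.null(config$model) || is.null(config$model$type))
    stop("config requires `model$type`", call. = FALSE)
  check_keys(config$model, CONFIG_KEYS$model, "model")
  if (is.null(config$sector))
    stop("config requires `sector` (n_electrons, twice_S)", call. = FALSE)
  check_keys(config$sector, CONFIG_KEYS$sector, "sector")
  config$solver <- match.arg(config$solver %||% "exact",
                             c("exact", "fciqmc"))
  if (!is.null(config$engine)) {
    check_keys(config$engine, CONFIG_KEYS$engine, "engine")
    if (!is.null(config$engine$dtau) && config$engine$dtau <= 0)
      stop("`engine$dtau` must be positive", call. = FALSE)
    if (isTRUE(config$engine$rdm %||% TRUE) &&
        !is.null(config$engine$seeds) &&
        length(config$engine$seeds) >= 2L &&
        config$engine$seeds[1] == config$engine$seeds[2])
      stop("replica seeds must be distinct when RDM sampling is enabled",
           call. = FALSE)
  }
  if (!is.null(config$observables))
    check_keys(config$observables, CONFIG_KEYS$observables, "observables")
  if (!is.null(config$fit)) check_keys(config$fit, CONFIG_KEYS$fit, "fit")
  class(config) <- c("gugaci_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_integrals <- function(config) {
  md <- config$model
  switch(md$type,
    hubbard = hubbard_model(md$n_sites, md$t %||% 1, md$U %||% 4,
                            md$topology %||% "chain"),
    exchange_cluster = exchange_cluster_model(
      md$n_centers, md$orbitals_per_center,
      md$intra_exchange %||% 1, md$inter_hopping %||% 0.1,
      md$on_site_U %||% 8),
    fcidump = read_fcidump(md$path),
    stop(sprintf("unknown model type '%s'", md$type), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Builds the model integrals, solves the requested spin sector (exact
#' CASCI or FCIQMC), forms the spin-free RDMs, computes the requested spin
#' observables, and optionally scans a spin ladder and fits it to a
#' (bi)quadratic Heisenberg model. Every artifact is stamped with the
#' configuration hash and seeds; identical configurations give identical
#' numeric outputs.
#'
#' @param config Configuration list or YAML path; see [load_config()].
#' @return An object of class `"gugaci_pipeline"`: a list with
#'   `integrals`, `result` (solver output), `rdms`, `observables` (tibble),
#'   `ladder`, `fit`, `checks`, `stamp`.
#' @export
run_pipeline <- function(config) {
  config <- load_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  integrals <- stage("model", config_integrals(config))
  space <- stage("sector", spin_space(integrals$n_orbitals,
                                      config$sector$n_electrons,
                                      config$sector$twice_S))
  eng_cfg <- config$engine %||% list()
  if (config$solver == "exact") {
    result <- stage("solve", exact_casci(integrals, space))
    rdms <- result$rdms
    energy <- result$energy
  } else {
    result <- stage("solve", do.call(run_fciqmc, c(
      list(integrals = integrals, space = space),
      eng_cfg[setdiff(names(eng_cfg), character(0))],
      if (is.null(eng_cfg$rdm)) list(rdm = TRUE))))
    rdms <- result$rdms
    energy <- fciqmc_energy(result)$estimate[1L]
  }
  obs <- NULL
  if (!is.null(config$observables)) {
    obs <- stage("observables", {
      rows <- list()
      frs <- config$observables$fragments
      if (!is.null(frs)) {
        for (nm in names(frs)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            observable = sprintf("local_spin[%s]", nm),
            value = local_spin(rdms, frs[[nm]]))
        }
        if (length(frs) > 1L)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            observable = sprintf("fragment_spin_sum[%s]",
                                 paste(names(frs), collapse = "+")),
            value = fragment_spin_sum(rdms, unname(frs)))
      }
      ro <- config$observables$reference_orbital
      if (!is.null(ro)) {
        prof <- correlation_profile(rdms, ro)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          observable = sprintf("corr[%d,%d]", ro, prof$orbital),
          value = prof$correlation)
      }
      dplyr::bind_rows(rows)
    })
  }
  ladder <- NULL; fit <- NULL
  if (!is.null(config$fit)) {
    ladder <- stage("ladder", spin_ladder_scan(
      integrals, config$sector$n_electrons,
      config$fit$S_values %||% unique(c(config$sector$twice_S / 2)),
      solver = config$fit$solver %||% "exact",
      engine = eng_cfg))
    if (nrow(ladder) >= 2L)
      fit <- stage("fit", fit_ladder(
        ladder, model = config$fit$model %||% "bilinear",
        S_A = config$fit$S_A %||% (5 / 2), S_B = config$fit$S_B %||% (5 / 2)))
  }
  checks <- list(
    trace_gamma = sum(diag(rdms$gamma)),
    n_electrons = space$n_electrons,
    s2 = rdm_s2(rdms),
    s2_target = space$twice_S / 2 * (space$twice_S / 2 + 1),
    rdm_energy = rdm_energy(rdms, integrals),
    solver_energy = energy)
  stamp <- list(schema_version = "1.0",
                config_hash = rlang::hash(unclass(config)),
                seeds = eng_cfg$seeds %||% NA,
                solver = config$solver)
  out <- structure(
    list(config = config, integrals = integrals, space = space,
         result = result, rdms = rdms, observables = obs, ladder = ladder,
         fit = fit, checks = checks, stamp = stamp),
    class = "gugaci_pipeline")
  if (!is.null(config$workspace)) write_pipeline(out, config$workspace)
  out
}

#' @export
print.gugaci_pipeline <- function(x, ...) {
  cat(sprintf("<gugaci_pipeline> solver = %s, E = %.8f, <S^2> = %.6f\n",
              x$config$solver, x$checks$solver_energy, x$checks$s2))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' Scan ground-state energies across spin sectors
#'
#' One ground-state energy per requested total spin, from the same
#' integrals — the computed spin ladder. Sectors that are invalid for the
#' electron count are skipped with a warning.
#'
#' @param integrals An [integral_set()].
#' @param n_electrons Electron count.
#' @param S_values Total spins to scan (half-integers allowed).
#' @param solver `"exact"` or `"fciqmc"`.
#' @param engine List of [run_fciqmc()] arguments for the stochastic
#'   solver.
#' @return A tibble with columns `S` and `energy`.
#' @export
spin_ladder_scan <- function(integrals, n_electrons, S_values,
                             solver = c("exact", "fciqmc"), engine = list()) {
  solver <- match.arg(solver)
  assert_integral_set(integrals)
  rows <- list()
  for (S in S_values) {
    space <- tryCatch(
      spin_space(integrals$n_orbitals, n_electrons, round(2 * S)),
      error = function(e) {
        warning(sprintf("skipping invalid sector S = %s: %s", format(S),
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(space)) next
    energy <- if (solver == "exact") {
      exact_casci(integrals, space)$energy
    } else {
      run <- do.call(run_fciqmc, c(list(integrals = integrals, space = space),
                                   engine))
      fciqmc_energy(run)$estimate[1L]
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(S = S, energy = energy)
  }
  if (length(rows) == 0L) return(tibble::tibble(S = numeric(0),
                                                energy = numeric(0)))
  dplyr::bind_rows(rows)
}

# Plain-text artifact bundle: trajectory and ladder as CSV, RDMs as CSV
# (gamma dense, Gamma in flat i,j,k,l,value form), fit and stamp as JSON.
write_pipeline <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(x$stamp, x$checks)
  jsonlite::write_json(meta, file.path(dir, "run.json"), auto_unbox = TRUE,
                       digits = NA)
  write_rdms(x$rdms, file.path(dir, "rdms"))
  if (!is.null(x$observables))
    utils::write.csv(x$observables, file.path(dir, "observables.csv"),
                     row.names = FALSE)
  if (inherits(x$result, "fciqmc_run"))
    utils::write.csv(x$result$trajectory, file.path(dir, "trajectory.csv"),
                     row.names = FALSE)
  if (!is.null(x$ladder))
    utils::write.csv(x$ladder, file.path(dir, "ladder.csv"), row.names = FALSE)
  if (!is.null(x$fit))
    jsonlite::write_json(
      list(model = x$fit$model, J = x$fit$J,
           J_biquadratic = x$fit$J_biquadratic, omega = x$fit$omega,
           residuals = x$fit$residuals),
      file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write and read RDMs as plain text
#'
#' `<basename>_gamma.csv` holds the dense one-body RDM (`i`, `j`,
#' `value`); `<basename>_Gamma.csv` holds the nonzero two-body entries in
#' flat `i`, `j`, `k`, `l`, `value` form; `<basename>_meta.json` records
#' the sector and sampling metadata.
#'
#' @param rdms An [rdm_pair()].
#' @param basename Output path prefix.
#' @return The basename, invisibly.
#' @export
write_rdms <- function(rdms, basename) {
  if (!is_rdm_pair(rdms)) stop("expected an `rdm_pair`", call. = FALSE)
  n <- rdms$n_orbitals
  g <- expand.grid(i = seq_len(n), j = seq_len(n))
  g$value <- as.vector(rdms$gamma)
  utils::write.csv(g, paste0(basename, "_gamma.csv"), row.names = FALSE)
  G <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n),
                   l = seq_len(n))
  G$value <- as.vector(rdms$Gamma)
  G <- G[G$value != 0, , drop = FALSE]
  utils::write.csv(G, paste0(basename, "_Gamma.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_orbitals = n, n_electrons = rdms$n_electrons,
         twice_S = rdms$twice_S, finalized = rdms$finalized,
         meta = rdms$meta[setdiff(names(rdms$meta), "checks")]),
    paste0(basename, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(basename)
}

#' @rdname write_rdms
#' @export
read_rdms <- function(basename) {
  meta <- jsonlite::read_json(paste0(basename, "_meta.json"),
                              simplifyVector = TRUE)
  n <- meta$n_orbitals
  g <- utils::read.csv(paste0(basename, "_gamma.csv"))
  gamma <- matrix(0, n, n)
  gamma[cbind(g$i, g$j)] <- g$value
  G <- utils::read.csv(paste0(basename, "_Gamma.csv"))
  Gamma <- array(0, rep(n, 4L))
  Gamma[cbind(G$i, G$j, G$k, G$l)] <- G$value
  rdm_pair(gamma, Gamma, meta$n_electrons, meta$twice_S,
           finalized = meta$finalized, meta = list(source = "file"))
}
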