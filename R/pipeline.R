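# Configuration-driven orchestration of the full analysis: structures ->
# tag modelling -> DEER inversion with uncertainty -> state populations ->
# oligomer statistics -> kinetics, with per-stage tables and a
# machine-readable results file.

pipeline_log <- function(stage, ...) {
  message(sprintf("[deerscape] %s: %s", stage, sprintf(...)))
}

#' Locate a locally cached deposited structure
#'
#' Deposited coordinate files are not bundled; place `<PDBID>.pdb` files in
#' `inst/extdata/pdb` of a source checkout or point the option
#' `deerscape.pdb_dir` at a directory containing them.
#'
#' @param pdb_id Four-character PDB accession.
#' @return Path to the file, or `NA_character_` when it is not available.
#' @export
deposited_structure_path <- function(pdb_id) {
  dirs <- c(getOption("deerscape.pdb_dir", ""),
            system.file("extdata", "pdb", package = "deerscape"))
  for (d in dirs) {
    if (!nzchar(d)) next
    for (f in file.path(d, c(paste0(toupper(pdb_id), ".pdb"),
                             paste0(tolower(pdb_id), ".pdb"))))
      if (file.exists(f)) return(f)
  }
  NA_character_
}

#' Read a deposited structure and apply the numbering convention
#'
#' @param pdb_id Four-character PDB accession (must be in
#'   [numbering_offsets()] or `offset` given).
#' @param offset Explicit numbering offset (otherwise looked up).
#' @return A renumbered `structure3d`.
#' @export
read_deposited_structure <- function(pdb_id, offset = NULL) {
  path <- deposited_structure_path(pdb_id)
  if (is.na(path))
    stop(sprintf(paste0("deposited structure %s not available locally; ",
                        "place %s.pdb under the directory named by ",
                        "options(deerscape.pdb_dir = ...)"),
                 pdb_id, toupper(pdb_id)), call. = FALSE)
  s <- parse_pdb(file = path, provenance = toupper(pdb_id))
  if (is.null(offset)) renumber(s, pdb_id = pdb_id)
  else renumber(s, offset = offset)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in a fixed order: structure loading and
#' tag modelling, DEER inversion (with L-curve selection, validation band
#' and reliability zones), state classification and populations, trimer
#' tag-dilution statistics, and Michaelis-Menten kinetics. Synthetic
#' specifications can stand in for any input. All randomness derives from
#' `config$seed`.
#'
#' @param config Named list, or path to a YAML file. Recognized blocks:
#'   `seed`; `protein` (selects built-in state definitions);
#'   `structure` (`file`, `pdb_id`/`offset`, `sites`, optional
#'   `mode = "ensemble"`); `deer` (`trace_file`+`time_unit`, or `synthetic`
#'   with Gaussian-mixture ground-truth fields; `window`, `alpha`,
#'   `validate`); `trajectory` (`table_file` with a `ca_nm` column, or
#'   `synthetic` with `means`, `sds`, `names`, `P`, `n_frames`);
#'   `trimer` (`tagged_fraction`); `kinetics` (`csv` with
#'   substrate/rate/enzyme columns, or `table` with KM/kcat/SE values).
#' @param out_dir Output directory for stage tables and `results.json`
#'   (NULL: nothing written).
#' @return Nested results list, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(seed = seed)
  # fail on missing inputs before any compute
  for (blk in c("structure", "deer", "trajectory", "kinetics")) {
    f <- config[[blk]][["file"]] %||% config[[blk]][["trace_file"]] %||%
      config[[blk]][["table_file"]] %||% config[[blk]][["csv"]]
    if (!is.null(f) && !file.exists(f))
      stop(sprintf("configuration error in '%s': input path '%s' does not exist",
                   blk, f), call. = FALSE)
  }
  defs <- NULL
  if (!is.null(config$protein)) {
    defs <- load_state_definitions(config$protein)
    pipeline_log("config", "protein %s: %d state windows", config$protein,
                 nrow(defs))
  }

  if (!is.null(config$structure)) {
    sc <- config$structure
    s <- if (!is.null(sc$file)) {
      st <- parse_pdb(file = sc$file)
      if (!is.null(sc$pdb_id)) renumber(st, pdb_id = sc$pdb_id)
      else if (!is.null(sc$offset)) renumber(st, offset = sc$offset)
      else st
    } else if (!is.null(sc$synthetic)) {
      make_two_domain_structure(sc$synthetic$theta %||% 0,
                                do.call(hinge_spec,
                                        sc$synthetic[setdiff(names(sc$synthetic),
                                                             "theta")]))
    } else stop("structure block needs 'file' or 'synthetic'", call. = FALSE)
    sites <- sc$sites
    stopifnot(length(sites) == 2L)
    ca <- ca_distance(s, sites[[1]], sites[[2]])
    gd_point <- gd_gd_distance(s, sites[[1]], sites[[2]], mode = "point")
    pipeline_log("structure", "Ca-Ca %.1f nm, Gd-Gd (point) %.1f nm", ca,
                 gd_point)
    results$structure <- list(ca_nm = ca, gd_point_nm = gd_point)
    if (identical(sc$mode, "ensemble")) {
      pd <- gd_gd_distance(s, sites[[1]], sites[[2]], mode = "ensemble")
      results$structure$gd_ensemble <- summarize_distribution(pd)
      if (!is.null(out_dir)) write_distribution(pd,
        file.path(out_dir, "gd_ensemble_distribution.tsv"))
    }
  }

  inverted <- NULL
  if (!is.null(config$deer)) {
    dc <- config$deer
    trace <- if (!is.null(dc$trace_file)) {
      read_deer_trace(dc$trace_file, time_unit = dc$time_unit %||% "us")
    } else if (!is.null(dc$synthetic)) {
      sy <- dc$synthetic
      truth <- deer_ground_truth(means = unlist(sy$means),
                                 sds = unlist(sy$sds),
                                 weights = unlist(sy$weights %||%
                                                    rep(1, length(sy$means))),
                                 lambda = sy$lambda %||% 0.4,
                                 k = sy$k %||% 0.1, d = sy$d %||% 3,
                                 snr = sy$snr %||% 50,
                                 t_max = sy$t_max %||% 4, seed = seed)
      ds <- make_deer_dataset(truth)
      results$deer_truth <- summarize_distribution(ds$truth)
      ds$trace
    } else stop("deer block needs 'trace_file' or 'synthetic'", call. = FALSE)
    ana <- deer_analyze(trace, window = dc$window %||% 0.6,
                        alpha = dc$alpha %||% "lcurve")
    inverted <- ana$distribution
    sm <- summarize_distribution(inverted)
    rz <- reliability_zones(max(trace$t))
    pipeline_log("deer", "alpha %.3g; peaks %s nm; mean %.2f nm",
                 ana$alpha,
                 paste(sprintf("%.1f", sm$peaks), collapse = "/"), sm$mean)
    results$deer <- list(alpha = ana$alpha, peaks = sm$peaks,
                         mean_nm = sm$mean,
                         lambda = ana$lambda, k = ana$k, d = ana$d,
                         reliability = unclass(rz)[1:4])
    if (isTRUE(dc$validate)) {
      band <- validate_uncertainty(trace, alpha = attr(inverted, "alpha"),
                                   seed = seed)
      results$deer$band_trials <- band$n
      if (!is.null(out_dir))
        utils::write.table(data.frame(r_nm = band$r, estimate = band$estimate,
                                      lower = band$lower, upper = band$upper),
                           file.path(out_dir, "deer_uncertainty_band.tsv"),
                           row.names = FALSE, quote = FALSE, sep = "\t")
    }
    if (!is.null(out_dir))
      write_distribution(inverted, file.path(out_dir, "deer_distribution.tsv"))
    if (!is.null(defs) && !any(is.na(defs$gd_lo))) {
      pops <- populations_from_distribution(inverted, defs)
      results$deer$populations <- stats::setNames(as.list(pops$fractions),
                                                  pops$states)
    }
  }

  if (!is.null(config$trajectory)) {
    tc <- config$trajectory
    traj <- if (!is.null(tc$table_file)) {
      utils::read.table(tc$table_file, header = TRUE)
    } else if (!is.null(tc$synthetic)) {
      sy <- tc$synthetic
      states <- data.frame(name = unlist(sy$names),
                           ca_mean = unlist(sy$means),
                           ca_sd = unlist(sy$sds))
      P <- matrix(unlist(sy$P), nrow(states), nrow(states), byrow = TRUE)
      make_trajectory(trajectory_spec(states, P,
                                      n_frames = sy$n_frames %||% 5000L,
                                      seed = seed))
    } else stop("trajectory block needs 'table_file' or 'synthetic'",
                call. = FALSE)
    if (is.null(defs))
      stop("trajectory stage needs state definitions ('protein' or inline)",
           call. = FALSE)
    labels <- classify_snapshot(traj$ca_nm, defs)
    pops <- populations_from_trajectory(labels, defs)
    pipeline_log("states", "%d frames: %s", nrow(traj),
                 paste(sprintf("%s %.2f", pops$states, pops$fractions),
                       collapse = ", "))
    results$states <- stats::setNames(as.list(pops$fractions), pops$states)
    if (!is.null(out_dir))
      utils::write.table(cbind(traj[, c("time_ns", "ca_nm",
                                        intersect("rg_nm", names(traj)))],
                               label = labels),
                         file.path(out_dir, "trajectory_labels.tsv"),
                         row.names = FALSE, quote = FALSE, sep = "\t")
  }

  if (!is.null(config$trimer)) {
    p <- config$trimer$tagged_fraction
    mix <- trimer_tag_mix(p)
    pipeline_log("trimer", "p=%.2f: k=1 %.1f%%, k=2 %.1f%%, k=3 %.2f%%", p,
                 100 * mix$probabilities[2], 100 * mix$probabilities[3],
                 100 * mix$probabilities[4])
    results$trimer <- as.list(mix$probabilities)
  }

  if (!is.null(config$kinetics)) {
    kc <- config$kinetics
    fit <- if (!is.null(kc$csv)) {
      d <- utils::read.csv(kc$csv)
      fit_mm(rate_series(d$substrate, d$rate, d$enzyme[1]))
    } else if (!is.null(kc$table)) {
      with(kc$table, mm_fit_values(KM, KM_se, kcat, kcat_se))
    } else stop("kinetics block needs 'csv' or 'table'", call. = FALSE)
    eff <- efficiency(fit)
    pipeline_log("kinetics", "KM %.3g uM, kcat %.3g 1/s, kcat/KM %.3g 1/(M s)",
                 fit$KM, fit$kcat, eff$value)
    results$kinetics <- list(KM = fit$KM, KM_se = fit$KM_se,
                             kcat = fit$kcat, kcat_se = fit$kcat_se,
                             efficiency = eff$value, efficiency_se = eff$se)
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(results, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    pipeline_log("done", "results written to %s", out_dir)
    return(invisible(results))
  }
  results
}

`%||%` <- function(a, b) if (is.null(a)) b else a
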