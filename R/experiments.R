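#' Named experiment presets
#'
#' Families of simulation sweeps mirroring the main computational
#' experiments: the bounded 5-swimmer arena across all strategies and k,
#' the unbounded 5-swimmer ensembles, the attraction cut-off sweeps for
#' the most-influential (k = 1) and nearest (k = 2) strategies, and the
#' group-size / neighbor-count sweeps. Every run of a preset is fully
#' determined by (preset, master seed, scale).
#'
#' @return a character vector of preset names.
#' @export
experiment_presets <- function() {
  c(
    "bounded_n5", "unbounded_n5",
    "cutoff_sweep_influential", "cutoff_sweep_nearest",
    "size_sweep_influential", "size_sweep_nearest"
  )
}

preset_spec <- function(name, scale) {
  desk <- scale == "desk"
  n_runs <- if (desk) 100 else 1000
  kicks <- 10000L
  switch(name,
    bounded_n5 = list(
      kind = "conditions", mode = "bounded", n_agents = 5L,
      n_runs = if (desk) 10 else 100, kicks = kicks,
      conditions = c(
        list(list(kind = "none", k = 0L)),
        unlist(lapply(c("nearest", "random", "influential"), function(s) {
          lapply(1:3, function(k) list(kind = s, k = k))
        }), recursive = FALSE),
        list(list(kind = "all", k = 4L))
      ),
      reference = list(kind = "influential", k = 2L)
    ),
    unbounded_n5 = list(
      kind = "ensembles", mode = "unbounded", n_agents = 5L,
      n_runs = n_runs, kicks = kicks,
      conditions = c(
        list(list(kind = "none", k = 0L)),
        unlist(lapply(c("nearest", "influential"), function(s) {
          lapply(1:4, function(k) list(kind = s, k = k))
        }), recursive = FALSE)
      )
    ),
    cutoff_sweep_influential = list(
      kind = "cutoff", mode = "unbounded", n_agents = 5L,
      strat = strategy("influential", 1), grid = seq(0.3, 1.5, by = 0.1),
      n_runs = n_runs, kicks = kicks
    ),
    cutoff_sweep_nearest = list(
      kind = "cutoff", mode = "unbounded", n_agents = 5L,
      strat = strategy("nearest", 2), grid = seq(1, 6, by = 0.5),
      n_runs = n_runs, kicks = kicks
    ),
    size_sweep_influential = list(
      kind = "size", mode = "unbounded",
      sizes = if (desk) c(5L, 10L, 20L, 40L) else c(5L, 10L, 20L, 40L, 70L),
      strat_for = function(n) strategy("influential", 1),
      n_runs = if (desk) 20 else n_runs, kicks = kicks
    ),
    size_sweep_nearest = list(
      kind = "ksweep", mode = "unbounded", n_agents = 20L,
      k_values = function(n) seq_len(n - 1L),
      n_runs = if (desk) 20 else n_runs, kicks = kicks
    ),
    stop("unknown preset '", name, "'; see experiment_presets()")
  )
}

#' Run an experiment preset
#'
#' Executes a named sweep at the requested scale and returns a report
#' bundle: one row per condition with steady-state summaries, the raw
#' per-condition ensembles, Hellinger distance matrices against the
#' preset's reference condition where one is defined, and a manifest
#' capturing the complete configuration. When `out_dir` is given, each
#' condition's summary is written as CSV as it completes and previously
#' completed conditions are skipped, so an interrupted sweep resumes.
#'
#' @param name a preset name from [experiment_presets()].
#' @param master_seed integer master seed; all per-condition seeds derive
#'   from it.
#' @param scale `"desk"` (reduced replicate counts, documented in the
#'   manifest) or `"full"` (the published protocol sizes).
#' @param out_dir optional output directory for CSV summaries + manifest.
#' @param overrides named list overriding preset fields (e.g.
#'   `list(n_runs = 5, kicks = 1000)`) for quick exploration.
#' @return a list with `summary` (tibble), `details` (per-condition
#'   objects), `distances` (tibble or NULL) and `manifest` (list).
#' @export
run_preset <- function(name, master_seed = 1L, scale = c("desk", "full"),
                       out_dir = NULL, overrides = NULL) {
  scale <- match.arg(scale)
  spec <- preset_spec(name, scale)
  if (!is.null(overrides)) spec[names(overrides)] <- overrides
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  # unbounded mode drops the wall term inside the engine, so the same
  # preset serves both domains
  params <- school_params("model")

  done_path <- function(tag) {
    if (is.null(out_dir)) NULL else file.path(out_dir, paste0(tag, ".csv"))
  }
  summarize_cond <- function(tag, fun) {
    p <- done_path(tag)
    if (!is.null(p) && file.exists(p)) {
      return(list(summary = tibble::tibble(utils::read.csv(p)), detail = NULL))
    }
    res <- fun()
    if (!is.null(p)) utils::write.csv(res$summary, p, row.names = FALSE)
    res
  }

  details <- list()
  rows <- list()
  distances <- NULL

  if (spec$kind %in% c("conditions", "ensembles")) {
    ref_obs <- NULL
    for (i in seq_along(spec$conditions)) {
      cond <- spec$conditions[[i]]
      tag <- paste0(name, "_", cond$kind, "_k", cond$k)
      res <- summarize_cond(tag, function() {
        cfg <- sim_config(
          n_agents = spec$n_agents, params = params,
          strat = strategy(cond$kind, max(cond$k, 1L)),
          mode = spec$mode, total_kicks = spec$kicks,
          seed = master_seed + i
        )
        ens <- run_ensemble(cfg, n_runs = spec$n_runs)
        list(
          summary = tibble::tibble(
            strategy = cond$kind, k = cond$k,
            mean_C_ss = ens$mean_C_ss, mean_P_ss = ens$mean_P_ss,
            n_runs = spec$n_runs, kicks = spec$kicks
          ),
          detail = ens
        )
      })
      rows[[tag]] <- res$summary
      details[[tag]] <- res$detail
    }
    # Hellinger ranking against the reference condition, from fresh
    # single long runs per condition (bounded preset only)
    if (!is.null(spec$reference)) {
      obs_for <- function(cond, seed) {
        cfg <- sim_config(
          n_agents = spec$n_agents, params = params,
          strat = strategy(cond$kind, max(cond$k, 1L)),
          mode = spec$mode,
          total_kicks = spec$kicks, seed = seed, frame_dt = 0.2
        )
        compute_observables(run_simulation(cfg),
          arena_radius = if (spec$mode == "bounded") params$arena_radius else NULL
        )
      }
      ref_obs <- obs_for(spec$reference, master_seed + 10000)
      distances <- purrr::map_dfr(seq_along(spec$conditions), function(i) {
        cond <- spec$conditions[[i]]
        d <- observable_distances(
          ref_obs, obs_for(cond, master_seed + 20000 + i),
          bins = default_pdf_bins(params$arena_radius)
        )
        dplyr::mutate(d, strategy = cond$kind, k = cond$k, .before = 1)
      })
    }
  } else if (spec$kind == "cutoff") {
    cfg <- sim_config(
      n_agents = spec$n_agents, params = params, strat = spec$strat,
      mode = spec$mode, total_kicks = spec$kicks, seed = master_seed
    )
    sweep <- find_critical_cutoff(cfg, spec$grid, n_runs = spec$n_runs)
    rows[["cutoff"]] <- dplyr::mutate(sweep$sweep,
      strategy = spec$strat$kind, k = spec$strat$k, .before = 1
    )
    details[["cutoff"]] <- sweep
  } else if (spec$kind == "size") {
    for (nn in spec$sizes) {
      tag <- paste0(name, "_N", nn)
      res <- summarize_cond(tag, function() {
        cfg <- sim_config(
          n_agents = nn, params = params, strat = spec$strat_for(nn),
          mode = spec$mode, total_kicks = spec$kicks,
          seed = master_seed + nn, init_radius = 0.25 * sqrt(nn / 5)
        )
        ens <- run_ensemble(cfg, n_runs = spec$n_runs)
        list(
          summary = tibble::tibble(
            n_agents = nn, mean_C_ss = ens$mean_C_ss,
            mean_P_ss = ens$mean_P_ss, n_runs = spec$n_runs
          ),
          detail = ens
        )
      })
      rows[[tag]] <- res$summary
      details[[tag]] <- res$detail
    }
  } else if (spec$kind == "ksweep") {
    nn <- spec$n_agents
    for (k in spec$k_values(nn)) {
      tag <- paste0(name, "_k", k)
      res <- summarize_cond(tag, function() {
        cfg <- sim_config(
          n_agents = nn, params = params, strat = strategy("nearest", k),
          mode = spec$mode, total_kicks = spec$kicks,
          seed = master_seed + k, init_radius = 0.25 * sqrt(nn / 5)
        )
        ens <- run_ensemble(cfg, n_runs = spec$n_runs)
        list(
          summary = tibble::tibble(
            n_agents = nn, k = k, mean_C_ss = ens$mean_C_ss,
            mean_P_ss = ens$mean_P_ss, n_runs = spec$n_runs
          ),
          detail = ens
        )
      })
      rows[[tag]] <- res$summary
      details[[tag]] <- res$detail
    }
  }

  manifest <- list(
    preset = name, scale = scale, master_seed = master_seed,
    params = unclass(params), timestamp = format(Sys.time()),
    package_version = as.character(utils::packageVersion("schoolsim")),
    overrides = overrides
  )
  if (!is.null(out_dir)) {
    yaml::write_yaml(
      rapply(manifest, function(v) if (is.infinite(v)) "infinite" else v,
        classes = "numeric", how = "replace"
      ),
      file.path(out_dir, paste0(name, "_manifest.yaml"))
    )
  }
  list(
    summary = dplyr::bind_rows(rows), details = details,
    distances = distances, manifest = manifest
  )
}
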