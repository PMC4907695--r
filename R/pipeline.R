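# End-to-end pipeline: simulate -> analyse traces -> histogram -> fit ->
# select model -> report, driven by a single seeded configuration.

#' Build a pipeline configuration
#'
#' @param seed Master seed; every stage derives its own sub-seed from it,
#'   so a config is fully reproducible.
#' @param stages Character vector of stages to run, any of `"simulate"`,
#'   `"traces"`, `"histograms"`, `"fit"`, `"svd"`, `"gillespie"`,
#'   `"binding"`, `"decay"`. Empty = nothing runs.
#' @param output_dir Directory for JSON results (`NULL` = don't write).
#' @param conditions Named list of three-state weight vectors, one per
#'   simulated condition; defaults to the `alone` and `ATP` entries of
#'   [lateral_gate_conditions()].
#' @param n_traces Number of synthetic TIRF traces in the `"traces"`
#'   stage.
#' @param bin_edges Histogram bin edges.
#' @param two_state [two_state_model()] for the `"gillespie"` stage.
#' @param titration [titration_spec()] for the `"binding"` stage.
#' @param decay [decay_spec()] for the `"decay"` stage.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       stages = character(0),
                       output_dir = NULL,
                       conditions = NULL,
                       n_traces = 50,
                       bin_edges = default_bin_edges(),
                       two_state = two_state_model(),
                       titration = NULL,
                       decay = NULL) {
  known <- c("simulate", "traces", "histograms", "fit", "svd",
             "gillespie", "binding", "decay")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_invalid("unknown stage(s): ",
                                paste(bad, collapse = ", "))
  if (is.null(conditions)) {
    conditions <- lateral_gate_conditions()[c("alone", "ATP")]
  }
  structure(
    list(seed = as.integer(seed), stages = stages,
         output_dir = output_dir,
         conditions = conditions, n_traces = n_traces,
         bin_edges = bin_edges, two_state = two_state,
         titration = titration, decay = decay),
    class = "run_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()]; nested
#' `two_state`, `titration` and `decay` blocks are passed to their
#' constructors.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stop_invalid("config not found: ", path)
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("seed", "stages", "output_dir", "n_traces")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$bin_edges)) args$bin_edges <- as.numeric(y$bin_edges)
  if (!is.null(y$conditions)) args$conditions <- lapply(y$conditions,
                                                        as.numeric)
  if (!is.null(y$two_state)) {
    args$two_state <- do.call(two_state_model, y$two_state)
  }
  if (!is.null(y$titration)) args$titration <- do.call(titration_spec,
                                                       y$titration)
  if (!is.null(y$decay)) args$decay <- do.call(decay_spec, y$decay)
  do.call(run_config, args)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order and returns (and optionally
#' writes) a machine-readable results bundle. Identical configs produce
#' identical bundles: every source of randomness derives its seed from
#' `config$seed`.
#'
#' Stage outputs:
#' \describe{
#'   \item{simulate}{per-condition replicate FRET-efficiency samples}
#'   \item{traces}{synthetic TIRF trace batch analysed by step detection
#'     and selection; acceptance counts and efficiency estimates}
#'   \item{histograms}{per-condition averaged histograms}
#'   \item{fit}{staged three-Gaussian global fit (means, widths,
#'     amplitudes, orientation-corrected amplitudes, ANOVA errors)}
#'   \item{svd}{SVD component count of the replicate histogram matrix}
#'   \item{gillespie}{two-state simulation, TIRF emulation, dwell-rate
#'     recovery and occupancy}
#'   \item{binding}{tight-binding titration generation + fit}
#'   \item{decay}{exponential decay generation + fit}
#' }
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return Named list of stage results (class `lgfret_results`), with
#'   `seed` recorded. Stage failures abort with the stage name.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config_yaml(config)
  stopifnot(inherits(config, "run_config"))
  results <- list(seed = config$seed)
  sub_seed <- function(offset) (config$seed + offset) %% .Machine$integer.max

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        paste0("stage '", name, "' failed: ", conditionMessage(e)),
        class = c("lgfret_stage_failure", "error")))
    })
  }

  samples <- NULL
  histograms <- NULL

  if ("simulate" %in% config$stages) {
    results$simulate <- run_stage("simulate", {
      samples <- list()
      for (i in seq_along(config$conditions)) {
        cn <- names(config$conditions)[i]
        spec <- lateral_gate_mixture(weights = config$conditions[[i]],
                                     seed = sub_seed(100 + i))
        samples[[cn]] <- sample_mixture(spec)
      }
      lapply(samples, function(reps) {
        list(n_replicates = length(reps),
             n_per_replicate = lengths(reps),
             replicate_means = vapply(reps, mean, numeric(1)))
      })
    })
  }

  if ("traces" %in% config$stages) {
    results$traces <- run_stage("traces", {
      spec <- lateral_gate_mixture(n_per_replicate = config$n_traces,
                                   n_replicates = 1,
                                   seed = sub_seed(200))
      e_true <- sample_mixture(spec)[[1]]
      e_true <- pmin(pmax(e_true, 0.05), 0.95)
      traces <- lapply(seq_along(e_true), function(i) {
        generate_intensity_trace(trace_params(
          fret_efficiency_true = e_true[i], seed = sub_seed(300 + i)))
      })
      res <- analyze_traces(traces)
      list(n_traces = length(traces),
           n_accepted = length(res$efficiencies),
           rejections = as.list(res$rejections),
           mean_error = if (length(res$efficiencies))
             mean(res$efficiencies -
                    e_true[vapply(res$observations,
                                  function(o) isTRUE(o$accepted),
                                  logical(1))]) else NA_real_,
           efficiencies = res$efficiencies)
    })
  }

  if ("histograms" %in% config$stages || "fit" %in% config$stages ||
      "svd" %in% config$stages) {
    if (is.null(samples) &&
        any(c("histograms", "fit", "svd") %in% config$stages)) {
      # histogram stages need samples even if 'simulate' not requested
      samples <- run_stage("histograms", {
        out <- list()
        for (i in seq_along(config$conditions)) {
          cn <- names(config$conditions)[i]
          spec <- lateral_gate_mixture(weights = config$conditions[[i]],
                                       seed = sub_seed(100 + i))
          out[[cn]] <- sample_mixture(spec)
        }
        out
      })
    }
    histograms <- run_stage("histograms", {
      hs <- list()
      for (cn in names(samples)) {
        for (r in seq_along(samples[[cn]])) {
          hs[[length(hs) + 1L]] <- build_histogram(
            samples[[cn]][[r]], config$bin_edges,
            condition = cn, replicate = r)
        }
      }
      hs
    })
  }

  if ("histograms" %in% config$stages) {
    results$histograms <- run_stage("histograms", {
      conds <- vapply(histograms, function(h) h$condition, character(1))
      lapply(split(histograms, conds), function(hh) {
        a <- average_replicates(hh)
        list(condition = a$condition, mean = a$mean, sem = a$sem)
      })
    })
  }

  if ("fit" %in% config$stages) {
    results$fit <- run_stage("fit", {
      fit <- fit_staged_mixture(histograms, seed = sub_seed(400))
      alone_amp <- fit$condition_amplitudes["alone", ]
      corrected <- t(apply(fit$condition_amplitudes, 1,
                           orientation_correct, alone_amp))
      anova <- anova_amplitudes(fit$replicate_amplitudes)
      list(components = fit$components,
           condition_amplitudes = fit$condition_amplitudes,
           orientation_corrected = corrected,
           anova = anova, rss = as.list(fit$rss),
           over_constrained = fit$over_constrained_flag)
    })
  }

  if ("svd" %in% config$stages) {
    results$svd <- run_stage("svd", {
      m <- vapply(histograms, function(h) h$counts,
                  numeric(length(config$bin_edges) - 1))
      conds <- vapply(histograms, function(h) h$condition, character(1))
      sv <- svd_components(m, conditions = conds)
      list(singular_values = sv$singular_values,
           n_significant = sv$n_significant,
           noise_floor = sv$noise_floor)
    })
  }

  if ("gillespie" %in% config$stages) {
    results$gillespie <- run_stage("gillespie", {
      traj <- simulate_two_state(config$two_state, seed = sub_seed(500))
      trace <- emulate_tirf(traj, seed = sub_seed(501))
      hist <- trajectory_histogram(trace, config$bin_edges)
      rates <- tryCatch(estimate_dwell_rates(traj),
                        error = function(e) NULL)
      occ <- mean(traj$states == "high")
      list(occupancy_high = occ,
           occupancy_expected = stationary_occupancy(config$two_state),
           dwell_rates = rates,
           histogram_counts = hist$counts,
           modal_E = hist$mids[which.max(hist$counts)])
    })
  }

  if ("binding" %in% config$stages) {
    results$binding <- run_stage("binding", {
      spec <- config$titration
      if (is.null(spec)) {
        spec <- titration_spec(F0 = 1, Bmax = 0.47, E0 = 10, KD = 23.5,
                               concentrations = c(0, 2, 5, 10, 20, 40, 80,
                                                  160, 320, 640),
                               noise_sd = 0, seed = sub_seed(600))
      }
      series <- generate_titration(spec)
      fit <- fit_tight_binding(series, seed = sub_seed(601))
      list(KD = fit$KD, Bmax = fit$Bmax, F0 = fit$F0,
           se = as.list(fit$se), rss = fit$rss)
    })
  }

  if ("decay" %in% config$stages) {
    results$decay <- run_stage("decay", {
      spec <- config$decay
      if (is.null(spec)) {
        spec <- decay_spec(rates = c(0.5, 0.05), amplitudes = c(0.5, 0.5),
                           offset = 0, duration = 120, dt = 0.05,
                           noise_sd = 0, seed = sub_seed(700))
      }
      trace <- generate_decay(spec)
      fit <- fit_exponentials(trace, n_components = length(spec$rates),
                              seed = sub_seed(701))
      list(rates = fit$rates,
           amplitudes_normalised = fit$amplitudes_normalised,
           t_half = fit$t_half, rss = fit$rss)
    })
  }

  class(results) <- c("lgfret_results", class(results))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_json(unclass(results),
                       file.path(config$output_dir, "results.json"))
  }
  results
}
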