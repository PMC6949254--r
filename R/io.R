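#' Write a trace ensemble to a delimited text file
#'
#' Tab-separated with a header row and columns `trace_id`, `frame_index`
#' (0-based, contiguous per trace), `time_s`, `intensity_donor`,
#' `intensity_acceptor`, `fret`, and `truth_state` when ground truth is
#' available. A JSON sidecar (`<path>.json`) records the frame interval and,
#' for simulated ensembles, the generating rate model and master seed.
#'
#' @param traces A `fret_ensemble` or list of [fret_trace()].
#' @param path Output file path.
#' @param sidecar Write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, sidecar = TRUE) {
  rows <- lapply(traces, function(tr) {
    df <- data.frame(trace_id = attr(tr, "trace_id"),
                     frame_index = seq_len(nrow(tr)) - 1L,
                     time_s = tr$time_s,
                     intensity_donor = tr$donor,
                     intensity_acceptor = tr$acceptor,
                     fret = tr$fret)
    if (!is.null(tr$truth_state)) df$truth_state <- tr$truth_state
    df
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    dt <- attr(traces, "dt")
    if (is.null(dt)) dt <- attr(traces[[1]], "dt")
    meta <- list(dt = dt, n_traces = length(traces))
    model <- attr(traces, "model")
    if (!is.null(model))
      meta$rate_model <- list(K = model$K,
                              emission_level = model$emission_level,
                              state_labels = model$state_labels)
    if (!is.null(attr(traces, "seed"))) meta$seed <- attr(traces, "seed")
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a trace ensemble from a delimited text file
#'
#' Inverse of [write_traces()]: a lossless round trip for the known columns;
#' unknown columns are preserved as extra data-frame columns. Malformed
#' headers and non-contiguous frame indices raise errors naming the column
#' or the offending line.
#'
#' @param path Path to a trace file.
#' @return A `fret_ensemble`.
#' @export
read_traces <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  if (nrow(tab) == 0) stop("trace file is empty: ", path)
  required <- c("trace_id", "frame_index", "time_s", "intensity_donor",
                "intensity_acceptor")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("trace file is missing required column(s): ",
         paste(missing, collapse = ", "))
  ids <- unique(tab$trace_id)
  traces <- vector("list", length(ids))
  dt_all <- NA_real_
  for (k in seq_along(ids)) {
    sub <- tab[tab$trace_id == ids[k], , drop = FALSE]
    fi <- sub$frame_index
    if (!identical(as.integer(fi), seq_len(nrow(sub)) - 1L)) {
      bad <- which(as.integer(fi) != seq_len(nrow(sub)) - 1L)[1]
      stop("non-contiguous frame_index for trace '", ids[k],
           "' near file row ", rownames(sub)[bad])
    }
    dt <- if (nrow(sub) > 1) sub$time_s[2] - sub$time_s[1] else 1
    if (max(abs(sub$time_s - fi * dt)) > 1e-9 + 1e-9 * max(sub$time_s))
      stop("time_s is not frame_index * dt for trace '", ids[k], "'")
    dt_all <- dt
    fret <- if ("fret" %in% names(sub)) sub$fret else NULL
    truth <- if ("truth_state" %in% names(sub)) sub$truth_state else NULL
    tr <- fret_trace(donor = sub$intensity_donor,
                     acceptor = sub$intensity_acceptor,
                     dt = dt, fret = fret, truth_state = truth,
                     trace_id = as.character(ids[k]))
    extra <- setdiff(names(sub), c(required, "fret", "truth_state"))
    for (col in extra) tr[[col]] <- sub[[col]]
    traces[[k]] <- tr
  }
  structure(traces, dt = dt_all, class = "fret_ensemble")
}

#' Run the full kinetic analysis pipeline
#'
#' classify -> dwell statistics -> survival fits -> global HMM with BIC model
#' selection -> rate and thermodynamic tables. Results are written into one
#' directory together with a machine-readable run log (all seeds, parameter
#' choices, package version). Any stage failure aborts with the stage name;
#' outputs of completed stages are preserved.
#'
#' @param config Named list (or path to a JSON file) with entries:
#'   `traces` (path to a trace file), `out_dir`, and optionally `threshold`
#'   (default 0.375), `ligand_conc_nM` (default 35), `temperature_K`
#'   (default 298), `n_boot` (default 100), `seed` (default 1),
#'   `min_dwell_frames` (default 1).
#' @return List of stage results, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(threshold = 0.375, ligand_conc_nM = 35,
                   temperature_K = 298, n_boot = 100, seed = 1L,
                   min_dwell_frames = 1)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$traces) || is.null(config$out_dir))
    stop("config must name 'traces' and 'out_dir'")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ensemble <- stage("read", read_traces(config$traces))
  dt <- attr(ensemble, "dt")

  results$summaries <- stage("classify", {
    s <- summarize_ensemble(ensemble, threshold = config$threshold,
                            min_dwell_frames = config$min_dwell_frames)
    classes <- attr(s, "classes")
    utils::write.table(
      data.frame(trace_id = vapply(ensemble, attr, "", "trace_id"),
                 class = classes),
      file.path(config$out_dir, "molecule_classes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(s, file.path(config$out_dir, "dwell_summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    s
  })

  results$dwells <- stage("dwell", {
    dyn <- attr(results$summaries, "classes") == "dynamic"
    dw <- ensemble_dwells(structure(ensemble[dyn], dt = dt,
                                    class = "fret_ensemble"),
                          threshold = config$threshold,
                          min_dwell_frames = config$min_dwell_frames)
    utils::write.table(dw, file.path(config$out_dir, "dwell_times.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dw
  })

  results$survival <- stage("survival", {
    out <- list()
    for (st in c("zero", "high")) {
      sc <- survival_curve(results$dwells, st)
      if (length(attr(sc, "durations")) >= 20) {
        out[[st]] <- list(
          biexp = fit_biexponential(sc, t_min = 2 * dt,
                                    n_boot = config$n_boot,
                                    seed = config$seed),
          stretched = fit_stretched_exp(sc, t_min = 2 * dt,
                                        n_boot = config$n_boot,
                                        seed = config$seed))
      }
    }
    out
  })

  results$kd <- stage("per_molecule_kd", {
    kd <- per_molecule_kd(results$summaries, config$ligand_conc_nM)
    kd <- kd[is.finite(kd)]
    if (length(kd) >= 10)
      fit_logistic_cdf(kd, n_boot = config$n_boot, seed = config$seed)
    else NULL
  })

  results$hmm <- stage("hmm", {
    dyn <- attr(results$summaries, "classes") == "dynamic"
    traces <- ensemble[dyn]
    em <- emissions_from_traces(traces)
    sel <- select_model(traces,
                        list(spec_two_state(), spec_three_state_degenerate()),
                        fixed_emissions = em, seed = config$seed)
    utils::write.table(sel, file.path(config$out_dir, "bic_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    best <- attr(sel, "fits")[[1]]
    K <- transition_to_rates(best$A, dt)
    pops <- state_population_kd(best, config$ligand_conc_nM)
    list(emissions = em, selection = sel, best = best, rates = K,
         populations = pops)
  })

  results$thermo <- stage("thermo", {
    K <- results$hmm$rates
    consts <- thermo_constants(T_K = config$temperature_K)
    tab <- thermo_table(k_on_pseudo = K[1, 2],
                        k_off = K[2, 1],
                        kd_nM = results$hmm$populations$kd,
                        ligand_conc_M = config$ligand_conc_nM * 1e-9,
                        constants = consts)
    utils::write.table(tab, file.path(config$out_dir, "rate_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })

  log <- list(config = config,
              package_version = as.character(utils::packageVersion("fretkin")),
              n_traces = length(ensemble), dt = dt,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
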