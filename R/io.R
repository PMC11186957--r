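## File dialects and the pipeline driver.
##
## Trace files: CSV with header `time_h,velocity_um_per_h` and optional
## comment lines `# key: value` (t_end_h, units, sigma) before the header.
## Protocol files: YAML with duration_h, segments [{t0,t1,strength_normalized}]
## and optional reference_field_V_per_cm (must be 3 when present).
## Control solutions: CSV + JSON summary. Every pipeline run writes a
## manifest JSON next to its outputs.

#' Read and write bulk-velocity traces
#'
#' Traces are stored as CSV with header \code{time_h,velocity_um_per_h} and
#' optional leading comment lines of the form \code{# key: value} carrying
#' the switch-off time (\code{t_end_h}), the noise level (\code{sigma}) and
#' the velocity units (\code{units}, which must be \code{um_per_h} when
#' declared). Values round-trip at full double precision.
#'
#' @param path File path.
#' @param trace A \code{\link{velocity_trace}}.
#' @return \code{read_trace} returns a \code{\link{velocity_trace}};
#'   \code{write_trace} returns \code{path} invisibly.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  if (!is.null(meta$units) && meta$units != "um_per_h")
    stop("unit error: trace declares velocity units '", meta$units,
         "', expected um_per_h", call. = FALSE)
  body <- lines[setdiff(seq_along(lines), hdr)]
  df <- read.csv(text = paste(body, collapse = "\n"))
  need <- c("time_h", "velocity_um_per_h")
  if (!all(need %in% names(df)))
    stop("format error: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "),
         " in ", path, call. = FALSE)
  if (is.unsorted(df$time_h, strictly = TRUE)) {
    bad <- which(diff(df$time_h) <= 0)[1] + 1L
    line_no <- length(hdr) + 1L + bad # comments + header + data row
    stop("format error: non-monotone time at data line ", line_no,
         " of ", path, call. = FALSE)
  }
  t_end <- if (!is.null(meta$t_end_h)) as.numeric(meta$t_end_h)
           else max(df$time_h)
  tr <- velocity_trace(df$time_h, df$velocity_um_per_h, t_end = t_end)
  if (!is.null(meta$sigma)) attr(tr, "sigma") <- as.numeric(meta$sigma)
  tr
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "velocity_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# t_end_h: %.17g", attr(trace, "t_end")),
               "# units: um_per_h",
               if (!is.null(attr(trace, "sigma")))
                 sprintf("# sigma: %.17g", attr(trace, "sigma")),
               "time_h,velocity_um_per_h"), con)
  writeLines(sprintf("%.17g,%.17g", trace$time_h, trace$velocity_um_per_h),
             con)
  invisible(path)
}

#' Read and write stimulation protocols
#'
#' Protocols are stored as YAML with fields \code{duration_h},
#' \code{segments} (list of \code{t0}, \code{t1}, \code{strength_normalized})
#' and optional \code{reference_field_V_per_cm} (3 when present; other values
#' are rejected so normalized units stay unambiguous).
#'
#' @param path File path.
#' @param protocol A segment-based \code{stimulus_protocol}.
#' @return \code{read_protocol} returns a \code{stimulus_protocol};
#'   \code{write_protocol} returns \code{path} invisibly.
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$reference_field_V_per_cm) &&
      abs(y$reference_field_V_per_cm - REFERENCE_FIELD_V_PER_CM) > 1e-12)
    stop("unit error: reference field must be 3 V/cm per normalized unit",
         call. = FALSE)
  segs <- do.call(rbind, lapply(y$segments, function(s)
    data.frame(t0 = s$t0, t1 = s$t1, strength = s$strength_normalized)))
  p <- protocol_segments(segs)
  if (!is.null(y$duration_h) && abs(p$duration - y$duration_h) > 1e-9)
    stop("format error: declared duration_h does not match segments",
         call. = FALSE)
  p
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (protocol$kind != "segments")
    stop("only segment protocols can be serialised", call. = FALSE)
  y <- list(duration_h = protocol$duration,
            reference_field_V_per_cm = REFERENCE_FIELD_V_PER_CM,
            segments = lapply(seq_len(nrow(protocol$segments)), function(i)
              list(t0 = protocol$segments$t0[i],
                   t1 = protocol$segments$t1[i],
                   strength_normalized = protocol$segments$strength[i])))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a control solution to disk
#'
#' Writes the trajectory table
#' (\code{time_h,s_star_normalized,s_star_V_per_cm,v_um_per_h,lambda_v,}
#' \code{lambda_seff,lambda_I}) as CSV and a JSON summary (kind, objective,
#' multiplier, feasibility flags, peak fields in both unit systems).
#'
#' @param solution A \code{control_solution}.
#' @param csv_path,json_path Output paths (either may be NULL to skip).
#' @return Invisibly, the summary list.
#' @export
write_control_solution <- function(solution, csv_path = NULL,
                                   json_path = NULL) {
  stopifnot(inherits(solution, "control_solution"))
  tab <- data.frame(time_h = solution$times,
                    s_star_normalized = solution$s_star,
                    s_star_V_per_cm = solution$s_star_V_per_cm,
                    v_um_per_h = solution$state$velocity_um_per_h,
                    lambda_v = solution$adjoints$lambda_v,
                    lambda_seff = solution$adjoints$lambda_seff,
                    lambda_I = solution$adjoints$lambda_I)
  if (!is.null(csv_path))
    write.csv(tab, csv_path, row.names = FALSE)
  summary <- list(kind = solution$kind,
                  objective = solution$objective,
                  objective_units = solution$objective_units,
                  mu_star = solution$mu_star,
                  peak_field_normalized = max(solution$s_star),
                  peak_field_V_per_cm = max(solution$s_star_V_per_cm),
                  feasibility = solution$feasibility)
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  invisible(summary)
}

## ---- pipeline -------------------------------------------------------------

.config_hash <- function(config) {
  ## order-stable content hash without external digest dependency
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997 + 1)) %% 2^31
}

#' Run the full analysis pipeline
#'
#' Executes a subset of the stages \code{synth} (generate a synthetic trace),
#' \code{fit_gamma} (friction-rate fit on the trace tail), \code{calibrate}
#' (MCMC posterior for the remaining parameters) and \code{control} (solve
#' the requested control problems at the calibrated or supplied parameters),
#' each stage consuming the previous one's outputs, and writes all artifacts
#' plus a run manifest into \code{out_dir}. Deterministic given the seeds in
#' the configuration.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{stages}{character vector, subset of
#'       \code{c("synth", "fit_gamma", "calibrate", "control")}.}
#'     \item{seed}{integer master seed.}
#'     \item{params}{list with gamma, alpha, tau_e, tau_a (generator truth
#'       and/or control parameters when \code{calibrate} is skipped).}
#'     \item{protocol}{list with \code{strength} and \code{duration_h}
#'       (default 1, 3).}
#'     \item{synth}{list with \code{sigma}, \code{dt}, \code{tail_h}.}
#'     \item{calibrate}{list with \code{n_chains}, \code{max_iter}.}
#'     \item{control}{list with \code{kinds} (subset of max_distance,
#'       max_terminal_velocity, cruise, cruise_window, bang_bang),
#'       \code{s_budget}, \code{v_star} (default: model mean velocity under
#'       the protocol), \code{t1}, \code{s_max}.}
#'   }
#' @param out_dir Output directory (created if missing).
#' @param verbose Log stage progress to standard error (default TRUE).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  stages <- config$stages %||% c("synth", "fit_gamma", "calibrate", "control")
  known <- c("synth", "fit_gamma", "calibrate", "control")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[voltaxis] ", ...)
  t0 <- Sys.time()
  seed <- config$seed %||% 1L

  pl <- config$protocol %||% list()
  protocol <- protocol_constant(pl$strength %||% 1, pl$duration_h %||% 3)
  pcfg <- config$params %||% list(gamma = 1.765, alpha = 149.92,
                                  tau_e = 0.260, tau_a = 2.038)
  gen_params <- model_params(pcfg$gamma, pcfg$alpha, pcfg$tau_e, pcfg$tau_a)

  results <- list()

  trace <- NULL
  if ("synth" %in% stages) {
    say("synth: generating trace")
    sc <- config$synth %||% list()
    cfg <- synth_config(gen_params, protocol,
                        dt = sc$dt %||% 1 / 6,
                        sigma = sc$sigma %||% 3,
                        tail_h = sc$tail_h %||% 2.5,
                        seed = seed)
    trace <- generate_trace(cfg)
    write_trace(trace, file.path(out_dir, "trace.csv"))
    results$trace <- trace
  } else if (!is.null(config$trace_file)) {
    trace <- read_trace(config$trace_file)
    results$trace <- trace
  }

  gamma <- gen_params$gamma
  if ("fit_gamma" %in% stages) {
    if (is.null(trace))
      stop("dependency error: fit_gamma needs a trace (synth stage or trace_file)",
           call. = FALSE)
    say("fit_gamma: least-squares decay fit")
    fit <- fit_gamma_decay(trace)
    results$gamma_fit <- fit
    jsonlite::write_json(fit, file.path(out_dir, "gamma_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  post <- NULL
  cal_params <- gen_params
  if ("calibrate" %in% stages) {
    if (is.null(trace))
      stop("dependency error: calibrate needs a trace", call. = FALSE)
    say("calibrate: running MCMC")
    cc <- config$calibrate %||% list()
    post <- run_mcmc(trace, protocol, gamma = gamma,
                     n_chains = cc$n_chains %||% 4L,
                     max_iter = cc$max_iter %||% 2e4L,
                     seed = seed + 100L)
    results$posterior <- post
    pooled <- do.call(rbind, post$chains)
    write.csv(as.data.frame(pooled),
              file.path(out_dir, "posterior_samples.csv"), row.names = FALSE)
    jsonlite::write_json(list(means = as.list(post$means),
                              rhat = as.list(post$rhat),
                              converged = post$converged,
                              quantiles = as.data.frame(post$quantiles)),
                         file.path(out_dir, "posterior_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    cal_params <- model_params(gamma, post$means["alpha"],
                               post$means["tau_e"], post$means["tau_a"])
  }

  if ("control" %in% stages) {
    say("control: solving control problems")
    ctl <- config$control %||% list()
    kinds <- ctl$kinds %||% c("max_distance", "max_terminal_velocity",
                              "cruise", "cruise_window", "bang_bang")
    T <- protocol$duration
    s_budget <- ctl$s_budget %||%
      (protocol_value(protocol, T / 2)^2 * T)
    v_star <- ctl$v_star %||% {
      traj <- simulate_model(cal_params, protocol,
                             t_grid = seq(0, T, length.out = 1001L))
      distance_travelled(traj) / T
    }
    sols <- list()
    for (k in kinds) {
      sols[[k]] <- switch(
        k,
        max_distance = solve_max_distance(cal_params, T, s_budget),
        max_terminal_velocity =
          solve_max_terminal_velocity(cal_params, T, s_budget),
        cruise = solve_cruise_bvp(cal_params, T, v_star,
                                  s_max = ctl$s_max %||% NULL),
        cruise_window = solve_cruise_window(cal_params, T,
                                            t1 = ctl$t1 %||% 0.75,
                                            v_star = v_star),
        bang_bang = bang_bang_policy(cal_params, T,
                                     s_max = ctl$bang_s_max %||% 1),
        stop("unknown control kind: ", k, call. = FALSE))
      write_control_solution(sols[[k]],
                             csv_path = file.path(out_dir,
                                                  paste0("control_", k, ".csv")),
                             json_path = file.path(out_dir,
                                                   paste0("control_", k, ".json")))
    }
    results$controls <- sols
  }

  manifest <- list(command = "run_pipeline",
                   stages = stages,
                   seed = seed,
                   config_hash = .config_hash(config),
                   package_version = as.character(utils::packageVersion("voltaxis")),
                   r_version = R.version.string,
                   out_dir = normalizePath(out_dir),
                   outputs = list.files(out_dir),
                   wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")),
                   timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  say("done in ", sprintf("%.1f s", manifest$wall_time_s))
  invisible(results)
}
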