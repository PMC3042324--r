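#' Parse a sequencer script
#'
#' The sequencer understands a minimal line-oriented pseudo-code (statements
#' separated by newlines or `;`, comments starting with `#`):
#'
#' ```
#' load <sample_id>      # mount a sample from the system's sample table
#' align                 # feedback alignment at 0 and 90 degrees
#' roi [fraction]        # measure length (once per load) and go to the ROI
#' scan <label>          # record a scan at the current position (no-op scan)
#' unload                # return the sample to the tray
#' wait <steps>          # advance the simulated clock
#' repeat <n> ... end    # repeat the enclosed block n times
#' ```
#'
#' @param text Script source, a character scalar or vector of lines.
#' @return An object of class `sequence_script` (list of step lists, with
#'   `repeat` steps holding a nested `body`). Parse failures raise one error
#'   listing every offending line.
#' @export
parse_script <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  errors <- character(0)
  root <- list(steps = list())
  stack <- list(root)                     # stack of open blocks
  push_step <- function(step) {
    top <- stack[[length(stack)]]
    top$steps[[length(top$steps) + 1]] <- step
    stack[[length(stack)]] <<- top
  }
  for (ln in seq_along(lines)) {
    stmts <- strsplit(lines[ln], ";", fixed = TRUE)[[1]]
    for (stmt in stmts) {
      stmt <- sub("#.*$", "", stmt)
      stmt <- trimws(stmt)
      if (stmt == "") next
      tok <- strsplit(stmt, "[[:space:]]+")[[1]]
      kind <- tok[1]
      arg <- if (length(tok) > 1) tok[2] else NA_character_
      if (length(tok) > 2) {
        errors <- c(errors, sprintf("line %d: too many tokens in '%s'", ln, stmt))
        next
      }
      switch(kind,
        load = {
          if (is.na(arg)) errors <- c(errors, sprintf("line %d: load needs a sample id", ln))
          else push_step(list(kind = "load", sample = arg, line = ln))
        },
        align = push_step(list(kind = "align", line = ln)),
        roi = {
          frac <- if (is.na(arg)) NA_real_ else suppressWarnings(as.numeric(arg))
          if (!is.na(arg) && (is.na(frac) || frac <= 0 || frac >= 1))
            errors <- c(errors, sprintf("line %d: roi fraction must be in (0, 1)", ln))
          else push_step(list(kind = "roi", fraction = frac, line = ln))
        },
        scan = {
          if (is.na(arg)) errors <- c(errors, sprintf("line %d: scan needs a label", ln))
          else push_step(list(kind = "scan", label = arg, line = ln))
        },
        unload = push_step(list(kind = "unload", line = ln)),
        wait = {
          n <- suppressWarnings(as.numeric(arg))
          if (is.na(n) || n < 0) errors <- c(errors, sprintf("line %d: wait needs a nonnegative interval", ln))
          else push_step(list(kind = "wait", interval = n, line = ln))
        },
        `repeat` = {
          n <- suppressWarnings(as.integer(arg))
          if (is.na(n) || n < 1) {
            errors <- c(errors, sprintf("line %d: repeat needs a positive count", ln))
          } else {
            stack[[length(stack) + 1]] <- list(kind = "repeat", n = n,
                                               line = ln, steps = list())
          }
        },
        end = {
          if (length(stack) == 1) {
            errors <- c(errors, sprintf("line %d: 'end' without matching 'repeat'", ln))
          } else {
            blk <- stack[[length(stack)]]
            stack[[length(stack)]] <- NULL
            push_step(list(kind = "repeat", n = blk$n, line = blk$line,
                           body = blk$steps))
          }
        },
        errors <- c(errors, sprintf("line %d: unknown step kind '%s'", ln, kind))
      )
    }
  }
  if (length(stack) > 1)
    errors <- c(errors,
                sprintf("line %d: 'repeat' block never closed", stack[[2]]$line))
  if (length(errors))
    stop(paste(c("script parse errors:", errors), collapse = "\n  "))
  # static check: a load must precede any sample-referencing step
  check_loaded <- function(steps, loaded) {
    for (s in steps) {
      if (s$kind == "load") loaded <- TRUE
      else if (s$kind == "unload") loaded <- FALSE
      else if (s$kind %in% c("align", "roi", "scan") && !loaded)
        stop(sprintf("script parse errors:\n  line %d: '%s' before any 'load'",
                     s$line, s$kind))
      if (s$kind == "repeat") loaded <- check_loaded(s$body, loaded)
    }
    loaded
  }
  check_loaded(stack[[1]]$steps, FALSE)
  structure(stack[[1]]$steps, class = "sequence_script")
}

#' Assemble a virtual system for the sequencer
#'
#' @param samples Named list of [phantom_sample()]s addressable by script
#'   `load` steps.
#' @param det A [detector_config()].
#' @param th A [thresholds()] object.
#' @param pm A [placement_model()] applied on every `load`.
#' @param params An [align_params()].
#' @param cal Optional [calibration()].
#' @return An object of class `virtual_system`.
#' @export
virtual_system <- function(samples, det, th = thresholds(),
                           pm = placement_model(), params = align_params(),
                           cal = NULL) {
  stopifnot(is.list(samples), length(samples) >= 1,
            !is.null(names(samples)), all(nzchar(names(samples))))
  structure(list(samples = samples, det = det, th = th, pm = pm,
                 params = params, cal = cal), class = "virtual_system")
}

#' Run a sequencer script against the virtual beamline
#'
#' Executes the parsed steps in order, maintaining the virtual stage and a
#' simulated clock (each acquisition and `wait` interval advances it; nothing
#' sleeps). Every step is logged exactly once with a terminal status and a
#' stage snapshot; a fresh seed is drawn and logged per step so any run can
#' be replayed. Specimen length is measured once per load and cached for
#' subsequent `roi` steps.
#'
#' @param script A [parse_script()] result (or script text).
#' @param system A [virtual_system()].
#' @param seed Integer seed for the whole run.
#' @param on_error `"abort"` (default) stops at the first failed step,
#'   `"skip_sample"` skips to the next `load`/`unload`, `"continue"` carries
#'   on with the next step.
#' @return An object of class `batch_report`: `log` (one data-frame row per
#'   executed step: kind, status, simulated clock, stage snapshot) and
#'   `details` (per-step payloads such as alignment results).
#' @export
run_batch <- function(script, system, seed = 1,
                      on_error = c("abort", "skip_sample", "continue")) {
  if (is.character(script)) script <- parse_script(script)
  stopifnot(inherits(script, "sequence_script"),
            inherits(system, "virtual_system"))
  on_error <- match.arg(on_error)
  set.seed(seed)

  env <- new.env(parent = emptyenv())
  env$bl <- NULL
  env$length_mm <- NA_real_
  env$bottom_state <- NULL
  env$clock <- 0
  env$skipping <- FALSE
  env$log <- list()
  env$details <- list()

  flatten <- function(steps) {
    out <- list()
    for (s in steps) {
      if (s$kind == "repeat") {
        for (i in seq_len(s$n)) out <- c(out, flatten(s$body))
      } else out <- c(out, list(s))
    }
    out
  }
  steps <- flatten(unclass(script))

  log_step <- function(s, status, step_seed, detail = NULL) {
    st <- if (is.null(env$bl)) stage_state() else env$bl$stage
    env$log[[length(env$log) + 1]] <- data.frame(
      step = length(env$log) + 1L, line = s$line, kind = s$kind,
      arg = if (!is.null(s$sample)) s$sample
            else if (!is.null(s$label)) s$label
            else if (!is.null(s$fraction) && !is.na(s$fraction)) as.character(s$fraction)
            else NA_character_,
      status = status, clock = env$clock, seed = step_seed,
      x = st$x, y = st$y, z = st$z, omega = st$omega,
      gonio_u = st$gonio_u, gonio_v = st$gonio_v)
    if (!is.null(detail))
      env$details[[length(env$log)]] <- detail
  }

  exec <- function(s) {
    switch(s$kind,
      load = {
        smp <- system$samples[[s$sample]]
        if (is.null(smp)) stop(sprintf("unknown sample '%s'", s$sample))
        stage <- load_sample(smp, system$pm, seed = NULL)
        env$bl <- virtual_beamline(smp, stage, system$det, system$th,
                                   system$cal)
        env$length_mm <- NA_real_
        env$bottom_state <- NULL
        env$skipping <- FALSE
        NULL
      },
      align = {
        res <- align_sample(env$bl, system$params)
        env$bl <- res$bl
        env$clock <- env$clock + length(res$result$trace)
        if (!res$result$converged)
          stop("alignment did not converge")
        res$result
      },
      roi = {
        params <- system$params
        if (!is.na(s$fraction)) params$roi_fraction <- s$fraction
        if (is.na(env$length_mm)) {
          lm_ <- measure_length(env$bl, params)
          env$bl <- lm_$bl
          env$length_mm <- lm_$length_mm
          env$bottom_state <- lm_$state_bottom
          env$clock <- env$clock + 4
        }
        env$bl$stage <- goto_roi(env$bl$stage, env$length_mm,
                                 env$bottom_state, params)
        list(length_mm = env$length_mm, y = env$bl$stage$y)
      },
      scan = {
        env$clock <- env$clock + 1
        list(label = s$label, stage = env$bl$stage)
      },
      unload = {
        env$bl <- NULL
        env$length_mm <- NA_real_
        env$skipping <- FALSE
        NULL
      },
      wait = {
        env$clock <- env$clock + s$interval
        NULL
      })
  }

  for (s in steps) {
    if (env$skipping && !s$kind %in% c("load", "unload")) {
      log_step(s, "skipped", NA_integer_)
      next
    }
    step_seed <- sample.int(.Machine$integer.max, 1)
    set.seed(step_seed)
    res <- tryCatch(list(ok = TRUE, detail = exec(s)),
                    error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    if (res$ok) {
      log_step(s, "ok", step_seed, res$detail)
    } else {
      log_step(s, paste0("error: ", res$msg), step_seed)
      if (on_error == "abort")
        break
      if (on_error == "skip_sample")
        env$skipping <- TRUE
    }
  }
  structure(list(log = do.call(rbind, env$log), details = env$details),
            class = "batch_report")
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf("<batch_report> %d step(s), %d ok, clock %g\n",
              nrow(x$log), sum(x$log$status == "ok"),
              max(x$log$clock)))
  invisible(x)
}

#' Repeat-loading precision study
#'
#' The repeat-precision protocol: the same phantom is loaded `n_reps` times,
#' each time displaced to a random position up to one field of view away,
#' fully aligned, its length measured and the field of view moved to the
#' fractional-length region of interest; the final x, y, z motor positions
#' are recorded. Because the stage is a reliable absolute reference, the
#' standard deviation of these positions across repetitions is the alignment
#' precision. Non-convergent repetitions are recorded but excluded from the
#' statistics, with a warning.
#'
#' @param sample A [phantom_sample()].
#' @param n_reps Number of load/align repetitions (>= 2).
#' @param pm A [placement_model()].
#' @param det A [detector_config()].
#' @param th A [thresholds()] object.
#' @param params An [align_params()].
#' @param cal Optional [calibration()].
#' @param seed Integer seed for the whole study.
#' @return An object of class `precision_study`: `runs` (one data-frame row
#'   per repetition with final positions, measured length, iteration counts
#'   and flags) and `summary` (a one-row data frame with mean and sd of
#'   length and of the x, y, z positions over converged repetitions).
#' @export
precision_study <- function(sample, n_reps = 20, pm = placement_model(),
                            det = detector_config(), th = thresholds(),
                            params = align_params(), cal = NULL, seed = 1) {
  stopifnot(n_reps >= 2)
  set.seed(seed)
  runs <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    stage <- load_sample(sample, pm, seed = NULL)
    bl <- virtual_beamline(sample, stage, det, th, cal)
    rec <- list(rep = i, converged = FALSE, out_of_fov = NA, clipped = NA,
                iters_0 = NA_integer_, iters_90 = NA_integer_,
                length_mm = NA_real_, x = NA_real_, y = NA_real_,
                z = NA_real_, n_steps = NA_integer_)
    ok <- tryCatch({
      al <- align_sample(bl, params)
      bl <- al$bl
      lm_ <- measure_length(bl, params)
      bl <- lm_$bl
      bl$stage <- goto_roi(bl$stage, lm_$length_mm, lm_$state_bottom, params)
      rec$converged <- al$result$converged
      rec$out_of_fov <- al$result$out_of_fov
      rec$clipped <- al$result$clipped_frac
      rec$iters_0 <- al$result$iterations_per_plane[1]
      rec$iters_90 <- al$result$iterations_per_plane[2]
      rec$length_mm <- lm_$length_mm
      rec$x <- bl$stage$x; rec$y <- bl$stage$y; rec$z <- bl$stage$z
      rec$n_steps <- length(al$result$trace) + 4
      TRUE
    }, error = function(e) FALSE)
    runs[[i]] <- as.data.frame(rec)
  }
  runs <- do.call(rbind, runs)
  good <- runs$converged %in% TRUE
  if (sum(good) < n_reps)
    warning(sprintf("%d of %d repetitions did not converge and were excluded",
                    n_reps - sum(good), n_reps))
  if (sum(good) < 2)
    stop("fewer than two converged repetitions: no precision estimate")
  g <- runs[good, ]
  summary <- data.frame(
    n_repetitions = sum(good),
    steps_mean = mean(g$n_steps), steps_sd = stats::sd(g$n_steps),
    length_mean = mean(g$length_mm), length_sd = stats::sd(g$length_mm),
    x_mean = mean(g$x), x_sd = stats::sd(g$x),
    y_mean = mean(g$y), y_sd = stats::sd(g$y),
    z_mean = mean(g$z), z_sd = stats::sd(g$z))
  structure(list(runs = runs, summary = summary), class = "precision_study")
}

#' @export
print.precision_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<precision_study> n=%d | length %.2f +/- %.3f mm | X %.1f +/- %.2f um | Y %.1f +/- %.2f um | Z %.1f +/- %.2f um\n",
    s$n_repetitions, s$length_mean, s$length_sd,
    s$x_mean, s$x_sd, s$y_mean, s$y_sd, s$z_mean, s$z_sd))
  invisible(x)
}

#' Write precision-study rows as a CSV table
#'
#' One row per study, with `value +/- sd` columns for length and the three
#' stage positions, mirroring the layout of a beamline repeatability report.
#'
#' @param studies A `precision_study` or list of them.
#' @param path Output CSV path.
#' @return The formatted data frame, invisibly.
#' @export
write_precision_csv <- function(studies, path) {
  if (inherits(studies, "precision_study")) studies <- list(studies)
  fmt <- function(m, s, digits = 1) sprintf("%.*f ± %.*f", digits, m, digits, s)
  rows <- lapply(seq_along(studies), function(i) {
    s <- studies[[i]]$summary
    data.frame(
      sample = i,
      n_repetitions = s$n_repetitions,
      steps = fmt(s$steps_mean, s$steps_sd, 0),
      length_mm = fmt(s$length_mean, s$length_sd, 2),
      x_um = fmt(s$x_mean, s$x_sd),
      y_um = fmt(s$y_mean, s$y_sd),
      z_um = fmt(s$z_mean, s$z_sd))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(out)
}
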