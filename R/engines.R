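# Simulation backends and SED-ML experiment execution.
#
# Two independent engines share one run contract:
#   * "rk"    - an adaptive explicit Dormand-Prince 4(5) integrator written
#               here from scratch (FSAL, hitting output points exactly);
#   * "stiff" - an implicit BDF multistep integrator delegated to deSolve.
# Both honor tolerance_settings including the per-variable absolute
# tolerance vector.

#' Engine descriptor
#'
#' @param name unique engine name.
#' @param algorithm_family `"explicit_rk"`, `"implicit_multistep"` or
#'   `"external"`.
#' @param capabilities feature tags (see `FEATURE_TAGS`) the engine can
#'   simulate in addition to core ODE semantics.
#' @param integrate integrator function
#'   `(rhs, y0, times, rtol, atol) -> list(ok, y, nsteps, log)`.
#' @return an `engine_descriptor`.
#' @export
engine_descriptor <- function(name, algorithm_family, capabilities,
                              integrate) {
  structure(list(name = name, algorithm_family = algorithm_family,
                 capabilities = capabilities, integrate = integrate),
            class = "engine_descriptor")
}

.engine_registry <- new.env(parent = emptyenv())

#' Register a simulation engine
#'
#' External adapters (for example wrappers around real simulators) can be
#' plugged in through the same contract as the built-in engines.
#' @param engine an [engine_descriptor()].
#' @export
register_engine <- function(engine) {
  stopifnot(inherits(engine, "engine_descriptor"))
  assign(engine$name, engine, envir = .engine_registry)
  invisible(engine)
}

#' Look up engines
#'
#' @param name engine name; `"all"` or `NULL` returns every registered
#'   engine.
#' @return an `engine_descriptor` or list of them.
#' @export
get_engine <- function(name = NULL) {
  if (is.null(name) || identical(name, "all")) {
    nms <- sort(ls(.engine_registry))
    return(lapply(nms, function(n) get(n, envir = .engine_registry)))
  }
  if (!exists(name, envir = .engine_registry))
    stop("unknown engine: ", name, call. = FALSE)
  get(name, envir = .engine_registry)
}

## ---- Dormand-Prince 4(5) -------------------------------------------------

.dp_a <- list(
  c(1/5),
  c(3/40, 9/40),
  c(44/45, -56/15, 32/9),
  c(19372/6561, -25360/2187, 64448/6561, -212/729),
  c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
  c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84))
.dp_c <- c(0, 1/5, 3/10, 4/5, 8/9, 1, 1)
.dp_b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
.dp_b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)
.dp_e <- .dp_b5 - .dp_b4

#' @noRd
dp45_integrate <- function(rhs, y0, times, rtol, atol,
                           max_steps = 5e6) {
  n <- length(y0)
  atol <- rep_len(atol, n)
  nt <- length(times)
  out <- matrix(NA_real_, nrow = nt, ncol = n)
  t <- times[1]
  y <- as.numeric(y0)
  out[1, ] <- y
  k1 <- rhs(t, y)
  if (any(!is.finite(k1)))
    return(list(ok = FALSE, y = out, nsteps = 0L,
                log = "non-finite derivative at initial state"))
  # initial step heuristic
  sc <- atol + rtol * abs(y)
  d0 <- sqrt(mean((y / sc)^2)); d1 <- sqrt(mean((k1 / sc)^2))
  span <- times[nt] - times[1]
  h <- min(if (d1 > 0) 0.01 * d0 / d1 else 1e-6, span / 10)
  if (h <= 0 || !is.finite(h)) h <- 1e-6
  nsteps <- 0L
  K <- matrix(0, nrow = 7, ncol = n)
  for (ti in 2:nt) {
    t_target <- times[ti]
    while (t < t_target) {
      if (nsteps >= max_steps)
        return(list(ok = FALSE, y = out, nsteps = nsteps,
                    log = sprintf("step budget exceeded at t=%g", t)))
      h_use <- min(h, t_target - t)
      K[1, ] <- k1
      for (s in 2:6) {
        acc <- .dp_a[[s - 1]][1] * K[1, ]
        if (s > 2) for (q in 2:(s - 1)) acc <- acc + .dp_a[[s - 1]][q] * K[q, ]
        K[s, ] <- rhs(t + .dp_c[s] * h_use, y + h_use * acc)
      }
      acc5 <- .dp_b5[1] * K[1, ]
      for (q in 2:6) acc5 <- acc5 + .dp_b5[q] * K[q, ]
      y5 <- y + h_use * acc5
      K[7, ] <- rhs(t + h_use, y5)
      errv <- .dp_e[1] * K[1, ]
      for (q in 2:7) errv <- errv + .dp_e[q] * K[q, ]
      errv <- h_use * errv
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean((errv / sc)^2))
      if (!is.finite(err)) {
        h <- h_use / 10
        if (h < 1e-14 * max(abs(t), 1))
          return(list(ok = FALSE, y = out, nsteps = nsteps,
                      log = sprintf("non-finite state at t=%g", t)))
        k1 <- rhs(t, y)
        next
      }
      if (err <= 1) {
        t <- t + h_use
        y <- y5
        k1 <- K[7, ]   # FSAL
        nsteps <- nsteps + 1L
        fac <- 0.9 * err^(-0.2)
        h <- h_use * min(5, max(0.2, fac))
      } else {
        h <- h_use * max(0.2, 0.9 * err^(-0.2))
        if (h < 1e-14 * max(abs(t), 1))
          return(list(ok = FALSE, y = out, nsteps = nsteps,
                      log = sprintf("step-size collapse at t=%g", t)))
      }
    }
    out[ti, ] <- y
  }
  list(ok = TRUE, y = out, nsteps = nsteps, log = "")
}

#' @noRd
bdf_integrate <- function(rhs, y0, times, rtol, atol) {
  fn <- function(t, y, parms) list(rhs(t, y))
  res <- tryCatch(
    deSolve::ode(y = as.numeric(y0), times = times, func = fn, parms = NULL,
                 method = "bdf", rtol = rtol, atol = atol),
    error = function(e) e, warning = function(w) w)
  if (inherits(res, "condition"))
    return(list(ok = FALSE, y = NULL, nsteps = NA_integer_,
                log = conditionMessage(res)))
  y <- unclass(res)[, -1, drop = FALSE]
  ist <- attributes(res)$istate
  nsteps <- if (!is.null(ist) && length(ist) >= 3) as.integer(ist[3]) else NA_integer_
  if (nrow(y) < length(times) || any(!is.finite(y)))
    return(list(ok = FALSE, y = y, nsteps = nsteps,
                log = "integration stopped early or produced non-finite values"))
  list(ok = TRUE, y = y, nsteps = nsteps, log = "")
}

# engines are registered at package load; see zzz.R
make_builtin_engines <- function() {
  list(
    engine_descriptor("rk", "explicit_rk",
                      capabilities = "noninteger_stoichiometry",
                      integrate = dp45_integrate),
    engine_descriptor("stiff", "implicit_multistep",
                      capabilities = "noninteger_stoichiometry",
                      integrate = bdf_integrate))
}

## ---- task execution ------------------------------------------------------

resolve_tolerances <- function(settings, algorithm) {
  s <- settings
  if (!is.null(algorithm) && length(algorithm$parameters)) {
    p <- algorithm$parameters
    if (!is.null(p[["KISAO:0000209"]])) {
      v <- suppressWarnings(as.numeric(p[["KISAO:0000209"]]))
      if (is.finite(v) && v > 0) s$rtol <- v
    }
    if (!is.null(p[["KISAO:0000211"]])) {
      v <- suppressWarnings(as.numeric(p[["KISAO:0000211"]]))
      if (is.finite(v) && v > 0) { s$atol_factor <- v; s$use_atol_vector <- FALSE }
    }
    # absolute tolerance adjustment factor
    if (!is.null(p[["KISAO:0000571"]])) {
      v <- suppressWarnings(as.numeric(p[["KISAO:0000571"]]))
      if (is.finite(v) && v > 0) { s$atol_factor <- v; s$use_atol_vector <- TRUE }
    }
  }
  s
}

numeric_condition <- function(msg) {
  structure(class = c("sedverify_numeric", "error", "condition"),
            list(message = msg, call = NULL))
}

apply_changes <- function(info, changes) {
  for (ch in changes) {
    ref <- resolve_xpath(ch$target, info)
    if (is.null(ref))
      stop("change targets unresolvable element: ", ch$target, call. = FALSE)
    val <- as.numeric(ch$new_value)
    info <- set_model_value(info, ref, val)
  }
  info
}

set_model_value <- function(info, ref, val) {
  if (ref$kind == "species") {
    for (i in seq_along(info$species))
      if (info$species[[i]]$id == ref$id) {
        info$species[[i]]$initial <- val
        return(info)
      }
  } else if (ref$kind == "parameter") {
    for (i in seq_along(info$parameters))
      if (info$parameters[[i]]$id == ref$id) {
        info$parameters[[i]]$value <- val
        return(info)
      }
  } else if (ref$kind == "local_parameter") {
    for (i in seq_along(info$local_parameters)) {
      lp <- info$local_parameters[[i]]
      if (lp$id == ref$id &&
          (is.null(ref$reaction_id) || lp$reaction_id == ref$reaction_id)) {
        info$local_parameters[[i]]$value <- val
        return(info)
      }
    }
  } else if (ref$kind == "compartment") {
    for (i in seq_along(info$compartments))
      if (info$compartments[[i]]$id == ref$id) {
        info$compartments[[i]]$size <- val
        return(info)
      }
  }
  stop("cannot set value of ", ref$kind, " ", ref$id, call. = FALSE)
}

check_capabilities <- function(info, engine) {
  missing <- setdiff(info$feature_tags, engine$capabilities)
  if (length(missing)) stop(unsupported_condition(missing))
  invisible(TRUE)
}

# integrate one uniform time course; returns list(times, values (named cols),
# nsteps)
run_time_course <- function(ode, sim, engine, settings, y0 = NULL) {
  if (sim$output_start_time < sim$initial_time)
    stop(numeric_condition("output start precedes initial time"))
  if (sim$output_end_time < sim$output_start_time)
    stop(numeric_condition("output end precedes output start"))
  np <- sim$number_of_points
  if (is.na(np) || np < 1) stop(numeric_condition("number_of_points < 1"))
  grid <- seq(sim$output_start_time, sim$output_end_time, length.out = np + 1)
  if (is.null(y0)) y0 <- ode$initial_state
  atol <- if (settings$use_atol_vector) atol_vector(settings, ode$initial_state)
          else settings$atol_factor
  times <- grid
  lead <- 0L
  if (sim$initial_time < grid[1]) {
    times <- c(sim$initial_time, grid)
    lead <- 1L
  }
  res <- engine$integrate(ode$rhs, y0, times, settings$rtol, atol)
  if (!res$ok) stop(numeric_condition(res$log))
  y <- res$y[(lead + 1):nrow(res$y), , drop = FALSE]
  list(times = grid, states = y, nsteps = res$nsteps,
       final_state = res$y[nrow(res$y), ])
}

run_steady_state <- function(ode, engine, settings,
                             conv_tol = 1e-8, time_budget = 1e6) {
  y <- as.numeric(ode$initial_state)
  atol <- if (settings$use_atol_vector) atol_vector(settings, ode$initial_state)
          else settings$atol_factor
  t0 <- 0
  chunk <- 10
  nsteps <- 0L
  while (t0 < time_budget) {
    t1 <- min(t0 + chunk, time_budget)
    res <- engine$integrate(ode$rhs, y, c(t0, t1), settings$rtol, atol)
    if (!res$ok) stop(numeric_condition(res$log))
    y <- res$y[nrow(res$y), ]
    nsteps <- nsteps + ifelse(is.na(res$nsteps), 0L, res$nsteps)
    dy <- ode$rhs(t1, y)
    if (max(abs(dy) / (1 + abs(y))) < conv_tol)
      return(list(times = t1, states = matrix(y, nrow = 1), nsteps = nsteps,
                  final_state = y))
    t0 <- t1
    chunk <- chunk * 10
  }
  stop(numeric_condition(sprintf(
    "steady state not reached within time budget %g", time_budget)))
}

#' Run one SED-ML task on one engine
#'
#' Applies the model's attribute changes, promotes local parameters,
#' compiles the ODE system, and integrates. Uniform time courses report
#' `number_of_points + 1` equally spaced output points (integration spans
#' initial -> output start silently); steady-state simulations integrate in
#' growing chunks until `max |dx/dt| < 1e-8 (1 + |x|)`; repeated tasks
#' iterate the range, applying per-iteration set-value changes, and stack
#' each iteration's output.
#'
#' @param doc a `sed_document`.
#' @param task_id id of the task to run.
#' @param engine an [engine_descriptor()].
#' @param settings [tolerance_settings()].
#' @param models named list mapping model id to `sbml_info`.
#' @return list with `times`, `states` matrix, a `lookup(target, symbol)`
#'   accessor, and `nsteps`.
#' @export
run_task <- function(doc, task_id, engine, settings, models) {
  task <- NULL
  for (tk in doc$tasks) if (tk$id == task_id) task <- tk
  if (is.null(task)) stop("no such task: ", task_id, call. = FALSE)

  run_plain <- function(task, info_override = NULL, y0 = NULL) {
    sim <- NULL
    for (s in doc$simulations) if (s$id == task$simulation_ref) sim <- s
    if (is.null(sim)) stop("task ", task$id, " references unknown simulation ",
                           task$simulation_ref, call. = FALSE)
    info <- if (is.null(info_override)) models[[task$model_ref]] else info_override
    if (is.null(info)) stop("task ", task$id, " references unknown model ",
                            task$model_ref, call. = FALSE)
    check_capabilities(info, engine)
    info <- promote_local_params(info)
    mdl <- NULL
    for (m in doc$models) if (m$id == task$model_ref) mdl <- m
    if (!is.null(mdl) && length(mdl$changes) && is.null(info_override))
      info <- apply_changes(info, mdl$changes)
    ode <- compile_ode(info)
    tol <- resolve_tolerances(settings, sim$algorithm)
    res <- if (sim$type == "utc") run_time_course(ode, sim, engine, tol, y0)
           else run_steady_state(ode, engine, tol)
    res$ode <- ode
    res$info <- info
    res
  }

  if (task$type == "task") {
    res <- run_plain(task)
  } else {
    values <- switch(task$range$type,
      uniform = seq(task$range$start, task$range$end,
                    length.out = task$range$count + 1),
      vector = task$range$values,
      stop(unsupported_condition("functional_range")))
    if (!length(task$subtasks)) stop("repeated task has no subtasks",
                                     call. = FALSE)
    sub_id <- task$subtasks[[1]]
    sub <- NULL
    for (tk in doc$tasks) if (tk$id == sub_id) sub <- tk
    if (is.null(sub) || sub$type != "task")
      stop("unsupported subtask nesting in ", task$id, call. = FALSE)
    base_info <- models[[sub$model_ref]]
    mdl <- NULL
    for (m in doc$models) if (m$id == sub$model_ref) mdl <- m
    if (!is.null(mdl) && length(mdl$changes))
      base_info <- apply_changes(promote_local_params(base_info), mdl$changes)
    times <- c(); states <- NULL; nsteps <- 0L
    carry <- NULL
    iter_info <- base_info
    for (v in values) {
      info_i <- if (task$reset_model) base_info else iter_info
      for (ch in task$changes) {
        ref <- resolve_xpath(ch$target, info_i)
        if (is.null(ref)) stop("setValue targets unresolvable element: ",
                               ch$target, call. = FALSE)
        env <- stats::setNames(list(v), task$range_variable)
        info_i <- set_model_value(info_i, ref, eval_math(ch$math, env))
      }
      res_i <- run_plain(sub, info_override = info_i,
                         y0 = if (task$reset_model) NULL else carry)
      carry <- res_i$final_state
      iter_info <- info_i
      times <- c(times, res_i$times)
      states <- rbind(states, res_i$states)
      nsteps <- nsteps + res_i$nsteps
    }
    res <- res_i
    res$times <- times
    res$states <- states
    res$nsteps <- nsteps
    res$iterations <- length(values)
  }

  ode <- res$ode
  res$lookup <- function(target = NULL, symbol = NULL) {
    if (!is.null(symbol) && !is.na(symbol) && symbol == "time")
      return(res$times)
    ref <- resolve_xpath(target, ode$info)
    if (is.null(ref)) stop("variable targets unresolvable element: ", target,
                           call. = FALSE)
    idx <- match(ref$id, ode$state_ids)
    nt <- nrow(res$states)
    if (!is.na(idx)) {
      conv <- if (idx <= ode$n_species_states) ode$species_conv[idx] else 1
      return(res$states[, idx] * conv)
    }
    # constant or assigned quantity: evaluate through the reporter per row
    vapply(seq_len(nt), function(i) {
      rep_i <- ode$report(res$times[i], res$states[i, ])
      v <- rep_i[[ref$id]]
      if (is.null(v)) stop("no observable value for ", ref$id, call. = FALSE)
      v
    }, 1)
  }
  res
}

## ---- experiment execution ------------------------------------------------

#' Execute a full experiment on one engine
#'
#' Runs every task needed by the document's outputs, evaluates data
#' generators, and assembles report and plot matrices. Failures are encoded
#' in the result status (`failed_parse`, `failed_unsupported`,
#' `failed_numeric`), never thrown.
#'
#' @param archive an `omex_archive` (repaired or lint-clean).
#' @param engine an [engine_descriptor()] or engine name.
#' @param settings [tolerance_settings()].
#' @return a `run_result`: engine, status, unsupported_tags, `reports`
#'   (named list of numeric matrices), `column_labels`, `log`, `nsteps`.
#' @export
execute_experiment <- function(archive, engine,
                               settings = tolerance_settings()) {
  if (is.character(engine)) engine <- get_engine(engine)
  fail <- function(status, msg, tags = character(0)) {
    structure(list(engine = engine$name, status = status,
                   unsupported_tags = tags, reports = list(),
                   column_labels = list(), log = msg, nsteps = NA_integer_),
              class = "run_result")
  }
  doc <- tryCatch(parse_sedml(find_sedml_entry(archive)$content),
                  error = function(e) e)
  if (inherits(doc, "error"))
    return(fail("failed_parse", conditionMessage(doc)))

  models <- list()
  for (m in doc$models) {
    src <- sub("^\\./", "", m$source)
    entry <- archive_get(archive, src)
    if (is.null(entry))
      return(fail("failed_parse",
                  paste0("model source not found in archive: ", m$source)))
    info <- tryCatch(parse_sbml_info(entry$content), error = function(e) e)
    if (inherits(info, "error"))
      return(fail("failed_parse", conditionMessage(info)))
    models[[m$id]] <- info
  }

  dg_index <- stats::setNames(doc$data_generators,
                              vapply(doc$data_generators, `[[`, "", "id"))
  needed_dgs <- unique(unlist(lapply(doc$outputs, function(o) {
    if (o$kind == "report") vapply(o$datasets, `[[`, "", "data_ref")
    else unlist(lapply(o$curves, function(c) c(c$x_ref, c$y_ref)))
  })))
  needed_tasks <- unique(unlist(lapply(dg_index[needed_dgs], function(g)
    vapply(g$variables, `[[`, "", "task_ref"))))

  task_results <- list()
  total_steps <- 0L
  for (tid in needed_tasks) {
    res <- tryCatch(run_task(doc, tid, engine, settings, models),
                    sedverify_unsupported = function(e) e,
                    sedverify_numeric = function(e) e,
                    error = function(e) e)
    if (inherits(res, "sedverify_unsupported"))
      return(fail("failed_unsupported", conditionMessage(res), res$tags))
    if (inherits(res, "error"))
      return(fail("failed_numeric", conditionMessage(res)))
    task_results[[tid]] <- res
    if (is.finite(res$nsteps)) total_steps <- total_steps + res$nsteps
  }

  eval_dg <- function(g) {
    env <- new.env(parent = math_fun_env)
    n <- NULL
    for (v in g$variables) {
      tr <- task_results[[v$task_ref]]
      if (is.null(tr)) stop("data generator ", g$id,
                            " references unrun task ", v$task_ref,
                            call. = FALSE)
      col <- tr$lookup(target = v$target, symbol = v$symbol)
      assign(v$id, col, envir = env)
      if (!is.null(v$symbol) && !is.na(v$symbol) && v$symbol == "time")
        assign("time", col, envir = env)
      n <- max(n, length(col))
    }
    val <- eval(math_to_expr(g$math), env)
    if (length(val) == 1L && !is.null(n)) val <- rep(val, n)
    as.numeric(val)
  }

  dg_values <- list()
  for (gid in needed_dgs) {
    v <- tryCatch(eval_dg(dg_index[[gid]]), error = function(e) e)
    if (inherits(v, "error"))
      return(fail("failed_numeric", conditionMessage(v)))
    dg_values[[gid]] <- v
  }

  reports <- list()
  labels <- list()
  for (o in doc$outputs) {
    if (o$kind == "report") {
      cols <- lapply(o$datasets, function(d) dg_values[[d$data_ref]])
      labs <- vapply(o$datasets, `[[`, "", "label")
    } else {
      cols <- list(); labs <- character(0)
      for (cv in o$curves) {
        cols <- c(cols, list(dg_values[[cv$x_ref]], dg_values[[cv$y_ref]]))
        labs <- c(labs, paste0(cv$id, ".x"), paste0(cv$id, ".y"))
      }
    }
    nr <- unique(vapply(cols, length, 1L))
    if (length(nr) != 1L)
      return(fail("failed_numeric",
                  paste0("ragged columns in output ", o$id)))
    m <- do.call(cbind, cols)
    colnames(m) <- labs
    reports[[o$id]] <- m
    labels[[o$id]] <- labs
  }
  if (any(vapply(reports, function(m) any(!is.finite(m)), TRUE)))
    return(fail("failed_numeric", "non-finite values in output"))

  structure(list(engine = engine$name, status = "succeeded",
                 unsupported_tags = character(0), reports = reports,
                 column_labels = labels, log = "", nsteps = total_steps),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result>", x$engine, "-", x$status, "\n")
  for (nm in names(x$reports))
    cat(sprintf("  %s: %d x %d\n", nm, nrow(x$reports[[nm]]),
                ncol(x$reports[[nm]])))
  if (nzchar(x$log)) cat("  log:", x$log, "\n")
  invisible(x)
}

#' Export run results
#'
#' Writes one CSV file per report (header row = column labels) plus a JSON
#' sidecar with engine, status and log.
#'
#' @param result a `run_result`.
#' @param dir destination directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(result$reports)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(result$reports[[nm]]), f,
                     row.names = FALSE)
    written <- c(written, f)
  }
  meta <- file.path(dir, "run.json")
  jsonlite::write_json(list(engine = result$engine, status = result$status,
                            unsupported_tags = result$unsupported_tags,
                            log = result$log),
                       meta, auto_unbox = TRUE)
  invisible(c(written, meta))
}
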