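# SBML -> ODE compilation and the wrapper-style model transforms
# (local-parameter promotion, initial-assignment folding), plus the
# per-variable absolute-tolerance vector.

#' Integrator tolerance settings
#'
#' `atol_factor` mirrors the simulators' absolute-tolerance default of
#' 1e-12; with `use_atol_vector = TRUE` it is scaled by each state's initial
#' value (see [atol_vector()]) instead of being passed as a scalar.
#'
#' @param rtol relative tolerance (> 0).
#' @param atol_factor base absolute tolerance / adjustment factor (> 0).
#' @param use_atol_vector scale `atol_factor` by initial values per state.
#' @return a `tolerance_settings` list.
#' @export
tolerance_settings <- function(rtol = 1e-6, atol_factor = 1e-12,
                               use_atol_vector = TRUE) {
  stopifnot(rtol > 0, atol_factor > 0)
  structure(list(rtol = rtol, atol_factor = atol_factor,
                 use_atol_vector = isTRUE(use_atol_vector)),
            class = "tolerance_settings")
}

#' Per-variable absolute-tolerance vector
#'
#' Scales the base factor by the magnitude of each state's initial value;
#' states starting at zero fall back to the bare factor so they are never
#' assigned a zero tolerance.
#'
#' @param settings a [tolerance_settings()] with `use_atol_vector = TRUE`.
#' @param initial_state numeric vector of initial state values.
#' @return numeric vector of per-state absolute tolerances.
#' @export
atol_vector <- function(settings, initial_state) {
  stopifnot(inherits(settings, "tolerance_settings"),
            isTRUE(settings$use_atol_vector))
  out <- settings$atol_factor * abs(initial_state)
  out[initial_state == 0] <- settings$atol_factor
  out
}

# rename symbols in an AST according to a named map old -> new
math_rename <- function(ast, map) {
  switch(ast$kind,
    sym = if (!is.null(map[[ast$id]])) m_sym(map[[ast$id]]) else ast,
    apply = { ast$args <- lapply(ast$args, math_rename, map = map); ast },
    piecewise = {
      ast$pieces <- lapply(ast$pieces, function(p)
        list(value = math_rename(p$value, map), cond = math_rename(p$cond, map)))
      ast$otherwise <- math_rename(ast$otherwise, map)
      ast
    },
    ast)
}

#' Promote local parameters to global parameters
#'
#' Each local parameter `p` of reaction `R` becomes a global parameter
#' `R_p` (suffix `_2`, `_3`, ... on collision with an existing id); the
#' reaction's kinetic law is rewritten to the new symbol. XPath targets
#' addressing the local parameter re-resolve to the promoted global via the
#' recorded mapping. This mirrors the workaround applied for simulators
#' that cannot adjust local parameters on the fly.
#'
#' @param info an `sbml_info`.
#' @return the transformed `sbml_info`.
#' @export
promote_local_params <- function(info) {
  if (!length(info$local_parameters)) return(info)
  existing <- sbml_ids(info)
  promoted <- list()
  per_reaction_map <- list()
  for (lp in info$local_parameters) {
    base <- paste0(lp$reaction_id, "_", lp$id)
    nm <- base
    i <- 2L
    while (nm %in% existing) { nm <- paste0(base, "_", i); i <- i + 1L }
    existing <- c(existing, nm)
    info$parameters[[length(info$parameters) + 1L]] <-
      list(id = nm, value = lp$value, constant = TRUE)
    promoted[[length(promoted) + 1L]] <-
      list(reaction_id = lp$reaction_id, old_id = lp$id, new_id = nm)
    m <- per_reaction_map[[lp$reaction_id]]
    if (is.null(m)) m <- list()
    m[[lp$id]] <- nm
    per_reaction_map[[lp$reaction_id]] <- m
  }
  for (i in seq_along(info$reactions)) {
    r <- info$reactions[[i]]
    m <- per_reaction_map[[r$id]]
    if (!is.null(m) && !is.null(r$kinetic_law))
      info$reactions[[i]]$kinetic_law <- math_rename(r$kinetic_law, m)
  }
  info$local_parameters <- list()
  info$promoted_locals <- c(info$promoted_locals, promoted)
  info
}

# dependency-ordered evaluation sequence for a set of (target, math) rules;
# errors on cycles naming the cycle members
topo_order <- function(rules, label) {
  targets <- vapply(rules, `[[`, "", "target")
  n <- length(rules)
  deps <- lapply(rules, function(r) intersect(math_symbols(r$math), targets))
  order <- integer(0)
  done <- character(0)
  remaining <- seq_len(n)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i)
      all(deps[[i]] %in% done), TRUE)]
    if (!length(ready))
      stop("cyclic ", label, " dependencies involving: ",
           paste(targets[remaining], collapse = ", "), call. = FALSE)
    order <- c(order, ready)
    done <- c(done, targets[ready])
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' Fold initial assignments into initial values
#'
#' Evaluates each initial assignment at t = 0 in dependency order, replaces
#' the target's initial value with the result, and removes the construct
#' (the workaround used for simulators without initial-assignment support).
#'
#' @param info an `sbml_info`.
#' @return the transformed `sbml_info`.
#' @export
fold_initial_assignments <- function(info) {
  if (!length(info$initial_assignments)) return(info)
  ord <- topo_order(info$initial_assignments, "initial-assignment")
  env <- initial_env(info)
  for (i in ord) {
    ia <- info$initial_assignments[[i]]
    val <- eval_math(ia$math, env)
    env[[ia$target]] <- val
    info <- set_initial_value(info, ia$target, val)
  }
  info$initial_assignments <- list()
  info
}

# named list of initial values for evaluation contexts at t0: species are
# exposed in their math framing (concentration unless substance-only)
initial_env <- function(info) {
  env <- list(time = 0)
  for (cp in info$compartments) env[[cp$id]] <- cp$size
  comp_size <- function(id) {
    for (cp in info$compartments) if (cp$id == id) return(cp$size)
    1
  }
  for (s in info$species) {
    v <- s$initial
    if (is.na(v)) v <- 0
    if (!s$substance_only && !s$init_is_conc) v <- v / comp_size(s$compartment)
    if (s$substance_only && s$init_is_conc) v <- v * comp_size(s$compartment)
    env[[s$id]] <- v
  }
  for (p in info$parameters) env[[p$id]] <- p$value
  env
}

set_initial_value <- function(info, target, value) {
  for (i in seq_along(info$species))
    if (info$species[[i]]$id == target) {
      info$species[[i]]$initial <- value
      # value is in math framing; record as concentration unless substance-only
      info$species[[i]]$init_is_conc <- !info$species[[i]]$substance_only
      return(info)
    }
  for (i in seq_along(info$parameters))
    if (info$parameters[[i]]$id == target) {
      info$parameters[[i]]$value <- value
      return(info)
    }
  for (i in seq_along(info$compartments))
    if (info$compartments[[i]]$id == target) {
      info$compartments[[i]]$size <- value
      return(info)
    }
  stop("initial assignment targets unknown element: ", target, call. = FALSE)
}

# condition helper for unsupported-feature failures
unsupported_condition <- function(tags) {
  structure(class = c("sedverify_unsupported", "error", "condition"),
            list(message = paste("unsupported SBML features:",
                                 paste(tags, collapse = ", ")),
                 call = NULL, tags = tags))
}

#' Compile an SBML model to an ODE system
#'
#' Species amounts (plus rate-rule targets) form the state vector; the
#' derivative of each species amount is the stoichiometry-weighted sum of
#' kinetic-law rates. Assignment rules are evaluated before every
#' right-hand-side evaluation; initial assignments are applied at t0 in
#' dependency order; boundary and constant species are held fixed.
#' Concentration-framed species are reported as amount / compartment size.
#'
#' @param info an `sbml_info` free of unsupported feature tags (delays,
#'   algebraic rules, events, fast reactions, assigned stoichiometries).
#' @return an `ode_system`: list with `state_ids`, `initial_state`, `rhs`,
#'   `report` (maps a state vector to all observable quantities), `nsteps`
#'   bookkeeping fields.
#' @export
compile_ode <- function(info) {
  hard <- intersect(info$feature_tags,
                    c("events", "delayed_events", "delay_csymbol",
                      "algebraic_rules", "fast_reactions",
                      "assigned_stoichiometry"))
  if (length(hard)) stop(unsupported_condition(hard))
  if (length(info$local_parameters)) info <- promote_local_params(info)

  comp_size <- function(id) {
    for (cp in info$compartments) if (cp$id == id) return(cp$size)
    1
  }

  # apply initial assignments (in math framing) without removing them from
  # info: folding is a separate, optional transform
  if (length(info$initial_assignments)) {
    ord <- topo_order(info$initial_assignments, "initial-assignment")
    env0 <- initial_env(info)
    for (i in ord) {
      ia <- info$initial_assignments[[i]]
      val <- eval_math(ia$math, env0)
      env0[[ia$target]] <- val
      info <- set_initial_value(info, ia$target, val)
    }
  }

  rule_targets <- vapply(info$assignment_rules, `[[`, "", "target")
  rr_targets <- vapply(info$rate_rules, `[[`, "", "target")

  is_state_species <- function(s) {
    if (isTRUE(s$constant)) return(FALSE)
    if (s$id %in% c(rule_targets, rr_targets)) return(FALSE)
    if (isTRUE(s$boundary)) return(FALSE)
    TRUE
  }
  state_species <- Filter(is_state_species, info$species)
  sp_ids <- vapply(state_species, `[[`, "", "id")
  # conversion factor state amount -> math/report value (concentration)
  sp_conv <- vapply(state_species, function(s)
    if (s$substance_only) 1 else 1 / comp_size(s$compartment), 1)
  sp_init <- vapply(state_species, function(s) {
    v <- s$initial
    if (is.na(v)) stop("species ", s$id, " has no initial value", call. = FALSE)
    if (s$init_is_conc) v * comp_size(s$compartment) else v
  }, 1)

  rr_states <- info$rate_rules
  rr_ids <- vapply(rr_states, `[[`, "", "target")
  rr_init <- vapply(rr_ids, function(id) {
    env0 <- initial_env(info)
    v <- env0[[id]]
    if (is.null(v) || is.na(v)) stop("rate-rule target ", id,
                                     " has no initial value", call. = FALSE)
    v
  }, 1)

  state_ids <- c(sp_ids, rr_ids)
  initial_state <- c(sp_init, rr_init)
  names(initial_state) <- state_ids

  # stoichiometry matrix over state species
  nr <- length(info$reactions)
  S <- matrix(0, nrow = length(sp_ids), ncol = nr,
              dimnames = list(sp_ids, NULL))
  rate_exprs <- vector("list", nr)
  for (j in seq_len(nr)) {
    r <- info$reactions[[j]]
    for (ref in r$reactants) {
      i <- match(ref$species, sp_ids)
      if (!is.na(i)) S[i, j] <- S[i, j] - ref$stoichiometry
    }
    for (ref in r$products) {
      i <- match(ref$species, sp_ids)
      if (!is.na(i)) S[i, j] <- S[i, j] + ref$stoichiometry
    }
    if (is.null(r$kinetic_law))
      stop("reaction ", r$id, " has no kinetic law", call. = FALSE)
    rate_exprs[[j]] <- math_to_expr(r$kinetic_law)
  }

  ar_ord <- if (length(info$assignment_rules))
    topo_order(info$assignment_rules, "assignment-rule") else integer(0)
  ar_exprs <- lapply(info$assignment_rules, function(r) math_to_expr(r$math))
  rr_exprs <- lapply(rr_states, function(r) math_to_expr(r$math))

  # evaluation environment with every non-state quantity bound
  base_env <- new.env(parent = math_fun_env)
  for (cp in info$compartments) assign(cp$id, cp$size, envir = base_env)
  for (p in info$parameters) assign(p$id, p$value, envir = base_env)
  env0 <- initial_env(info)
  for (s in info$species)
    if (!(s$id %in% state_ids)) assign(s$id, env0[[s$id]], envir = base_env)

  eval_env <- new.env(parent = base_env)
  nsp <- length(sp_ids)

  bind_state <- function(t, y) {
    y <- unname(y)
    assign("time", t, envir = eval_env)
    if (nsp) for (i in seq_len(nsp))
      assign(sp_ids[i], y[i] * sp_conv[i], envir = eval_env)
    if (length(rr_ids)) for (i in seq_along(rr_ids))
      assign(rr_ids[i], y[nsp + i], envir = eval_env)
    for (i in ar_ord)
      assign(info$assignment_rules[[i]]$target,
             eval(ar_exprs[[i]], eval_env), envir = eval_env)
  }

  rhs <- function(t, y) {
    bind_state(t, y)
    rates <- if (nr) vapply(rate_exprs, function(e) eval(e, eval_env), 1)
             else numeric(0)
    dy_sp <- if (nsp) as.numeric(S %*% rates) else numeric(0)
    dy_rr <- if (length(rr_exprs))
      vapply(rr_exprs, function(e) eval(e, eval_env), 1) else numeric(0)
    c(dy_sp, dy_rr)
  }

  # observable value of any model element id at (t, y)
  report <- function(t, y) {
    bind_state(t, y)
    y <- unname(y)
    out <- list(time = t)
    for (i in seq_len(nsp)) out[[sp_ids[i]]] <- y[i] * sp_conv[i]
    for (i in seq_along(rr_ids)) out[[rr_ids[i]]] <- y[nsp + i]
    for (p in info$parameters)
      out[[p$id]] <- get(p$id, envir = eval_env)
    for (cp in info$compartments)
      out[[cp$id]] <- get(cp$id, envir = eval_env)
    for (s in info$species)
      if (!(s$id %in% state_ids)) out[[s$id]] <- get(s$id, envir = eval_env)
    out
  }

  structure(list(state_ids = state_ids, initial_state = initial_state,
                 rhs = rhs, report = report, info = info,
                 species_conv = sp_conv, n_species_states = nsp),
            class = "ode_system")
}
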