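# Defect catalogue: detection (lint) and automatic repair.
#
# Rule catalogue:
#   R1  model source missing/dangling          -> resolve against archive
#   R2  dangling target/variable references    -> drop change / variable chain
#   R3  unused models/simulations/tasks/generators -> prune
#   R4  duplicate elements (semantic duplicates)   -> merge, rewrite refs
#   R5  malformed element pointers             -> rewrite to canonical XPath
#   R6  inconsistent simulation parameters     -> clamp / drop / reject
#   R7  excessive output points                -> warn; clamp when opted in
#   R8  unused non-finite SBML parameter       -> set value 0
#   R9  file hygiene                           -> delegate to archive layer
#   R10 annotation URN form                    -> rewrite to URL form
#
# Repair applies enabled rules in the fixed order R1, R5, R2, R4, R3, R6,
# R7, R8, R10, R9 (source resolution must precede target validation) and is
# idempotent: repairing a repaired archive yields zero actions.

#' Repair policy
#'
#' @param enabled_rules character vector of rule ids to apply.
#' @param point_cap maximum tolerated `number_of_points` (>= 2).
#' @param clamp_points actually clamp oversized grids (changes the output
#'   grid, hence opt-in; otherwise R7 only warns).
#' @param urn_rewrite rewrite URN-form annotations to URL form.
#' @return a `repair_policy`.
#' @export
repair_policy <- function(enabled_rules = paste0("R", 1:10),
                          point_cap = 10000L, clamp_points = FALSE,
                          urn_rewrite = TRUE) {
  stopifnot(point_cap >= 2)
  structure(list(enabled_rules = enabled_rules,
                 point_cap = as.numeric(point_cap),
                 clamp_points = isTRUE(clamp_points),
                 urn_rewrite = isTRUE(urn_rewrite)), class = "repair_policy")
}

lint_frame <- function() {
  data.frame(rule_id = character(), severity = character(),
             location = character(), message = character(),
             repairable = logical(), stringsAsFactors = FALSE)
}

action_frame <- function() {
  data.frame(rule_id = character(), location = character(),
             before = character(), after = character(),
             stringsAsFactors = FALSE)
}

# every (context, target) pair in a document, with the owning model id
doc_target_contexts <- function(doc) {
  out <- list()
  task_model <- list()
  for (tk in doc$tasks)
    if (tk$type == "task") task_model[[tk$id]] <- tk$model_ref
  for (tk in doc$tasks)
    if (tk$type == "repeat" && length(tk$subtasks)) {
      m <- task_model[[tk$subtasks[[1]]]]
      if (!is.null(m)) task_model[[tk$id]] <- m
    }
  for (m in doc$models)
    for (i in seq_along(m$changes))
      out[[length(out) + 1L]] <- list(kind = "change", model = m$id,
                                      owner = m$id, index = i,
                                      target = m$changes[[i]]$target)
  for (g in doc$data_generators)
    for (i in seq_along(g$variables)) {
      v <- g$variables[[i]]
      if (is.na(v$target)) next
      out[[length(out) + 1L]] <- list(kind = "variable",
                                      model = task_model[[v$task_ref]],
                                      owner = g$id, index = i,
                                      target = v$target)
    }
  for (tk in doc$tasks)
    if (tk$type == "repeat")
      for (i in seq_along(tk$changes))
        out[[length(out) + 1L]] <- list(kind = "setvalue",
                                        model = task_model[[tk$id]],
                                        owner = tk$id, index = i,
                                        target = tk$changes[[i]]$target)
  out
}

doc_usage <- function(doc) {
  used_models <- character(0); used_sims <- character(0)
  used_tasks <- character(0); used_dgs <- character(0)
  for (o in doc$outputs) {
    refs <- if (o$kind == "report") vapply(o$datasets, `[[`, "", "data_ref")
            else unlist(lapply(o$curves, function(c) c(c$x_ref, c$y_ref)))
    used_dgs <- union(used_dgs, refs)
  }
  for (g in doc$data_generators)
    if (g$id %in% used_dgs)
      used_tasks <- union(used_tasks,
                          vapply(g$variables, `[[`, "", "task_ref"))
  # a subtask of a used repeated task is used
  repeat_done <- FALSE
  while (!repeat_done) {
    repeat_done <- TRUE
    for (tk in doc$tasks)
      if (tk$type == "repeat" && tk$id %in% used_tasks &&
          !all(tk$subtasks %in% used_tasks)) {
        used_tasks <- union(used_tasks, tk$subtasks)
        repeat_done <- FALSE
      }
  }
  for (tk in doc$tasks)
    if (tk$id %in% used_tasks && tk$type == "task") {
      used_models <- union(used_models, tk$model_ref)
      used_sims <- union(used_sims, tk$simulation_ref)
    }
  list(models = used_models, sims = used_sims, tasks = used_tasks,
       dgs = used_dgs)
}

dg_signature <- function(g) {
  vars <- lapply(g$variables, function(v)
    list(task_ref = v$task_ref,
         target = if (is.na(v$target)) NULL else v$target,
         symbol = if (is.null(v$symbol) || is.na(v$symbol)) NULL else v$symbol))
  ord <- order(vapply(g$variables, `[[`, "", "id"))
  # the math is compared with variable ids replaced by their (task, target)
  # signature so renamed-but-identical generators are recognized
  map <- list()
  for (v in g$variables)
    map[[v$id]] <- paste0("v<", v$task_ref, "|",
                          if (!is.na(v$target)) v$target else v$symbol, ">")
  sig_math <- math_canonical(math_rename(g$math, map))
  paste(utils::capture.output(str(list(vars[ord], sig_math), give.attr = FALSE)),
        collapse = "")
}

urn_pattern <- "urn:miriam:([A-Za-z0-9._-]+):([^\"'<>[:space:]]+)"

#' Lint an archive
#'
#' Detects every defect of the rule catalogue without modifying the
#' archive. Parse failures are reported as issues rather than thrown. The
#' issue list is deterministic, ordered by (location, rule id).
#'
#' @param archive an `omex_archive`.
#' @param policy a [repair_policy()] (affects which R7/R10 findings count
#'   as repairable).
#' @return data.frame with columns `rule_id`, `severity`, `location`,
#'   `message`, `repairable`.
#' @export
lint <- function(archive, policy = repair_policy()) {
  issues <- lint_frame()
  add <- function(rule, sev, loc, msg, repairable) {
    issues[nrow(issues) + 1L, ] <<- list(rule, sev, loc, msg, repairable)
  }

  hyg <- hygiene_scan(archive)
  for (i in seq_len(nrow(hyg)))
    add("R9", "warning", hyg$location[i],
        paste0("file hygiene: ", hyg$kind[i],
               if (!is.na(hyg$suggested_fix[i]))
                 paste0(" (suggest ", hyg$suggested_fix[i], ")") else ""),
        TRUE)

  for (e in find_sbml_entries(archive)) {
    info <- tryCatch(parse_sbml_info(e$content), error = function(err) err)
    if (inherits(info, "error")) {
      add("R9", "error", e$location,
          paste0("unparseable SBML: ", conditionMessage(info)), FALSE)
      next
    }
    used_syms <- sbml_referenced_symbols(info)
    for (p in info$parameters) {
      if (is.na(p$value) || is.finite(p$value)) next
      if (p$id %in% used_syms)
        add("R8", "error", paste0(e$location, "#", p$id),
            sprintf("parameter %s has non-finite value %s and is referenced in model math",
                    p$id, p$value), FALSE)
      else
        add("R8", "error", paste0(e$location, "#", p$id),
            sprintf("unused parameter %s has non-finite value %s", p$id,
                    p$value), TRUE)
    }
    txt <- rawToChar(e$content)
    urns <- regmatches(txt, gregexpr(urn_pattern, txt))[[1]]
    for (u in unique(urns))
      add("R10", "warning", e$location,
          paste0("annotation resource in URN form: ", u),
          policy$urn_rewrite)
  }

  for (e in archive$entries) {
    if (!format_is_sedml(e$format)) next
    doc <- tryCatch(parse_sedml(e$content), error = function(err) err)
    if (inherits(doc, "error")) {
      add("R9", "error", e$location,
          paste0("unparseable SED-ML: ", conditionMessage(doc)), FALSE)
      next
    }
    loc <- function(id) paste0(e$location, "#", id)

    # R1: model sources
    resolved_infos <- list()
    dangling <- character(0)
    for (m in doc$models) {
      src <- sub("^\\./", "", m$source)
      entry <- archive_get(archive, src)
      if (is.null(entry)) {
        dangling <- c(dangling, m$id)
        res <- resolve_model_source(doc, archive)
        ok <- !is.na(res$map[[m$id]])
        add("R1", "error", loc(m$id),
            if (ok) sprintf("model source '%s' does not exist (resolves to '%s')",
                            m$source, res$map[[m$id]])
            else sprintf("model source '%s' does not exist and cannot be resolved (%s)",
                         m$source, res$note),
            ok)
      } else {
        info <- tryCatch(parse_sbml_info(entry$content),
                         error = function(err) NULL)
        if (!is.null(info)) resolved_infos[[m$id]] <- info
      }
    }

    # R2 / R5: element pointers
    for (ctx in doc_target_contexts(doc)) {
      if (is.null(ctx$model) || !ctx$model %in% names(resolved_infos)) next
      info <- resolved_infos[[ctx$model]]
      parsed <- tryCatch(parse_xpath_target(ctx$target),
                         error = function(err) NULL)
      if (is.null(parsed)) {
        add("R2", "error", loc(ctx$owner),
            paste0("unparseable element pointer: ", ctx$target), TRUE)
        next
      }
      ref <- resolve_xpath(parsed, info)
      if (is.null(ref)) {
        add("R2", "error", loc(ctx$owner),
            paste0("pointer to nonexistent model element: ", ctx$target),
            TRUE)
      } else if (!identical(ctx$target, canonical_xpath(ref))) {
        add("R5", "warning", loc(ctx$owner),
            paste0("non-canonical element pointer: ", ctx$target), TRUE)
      }
    }

    # R3: unused elements
    usage <- doc_usage(doc)
    for (m in doc$models)
      if (!m$id %in% usage$models)
        add("R3", "warning", loc(m$id), "model is never used by a task", TRUE)
    for (s in doc$simulations)
      if (!s$id %in% usage$sims)
        add("R3", "warning", loc(s$id),
            "simulation is defined but never used", TRUE)
    for (tk in doc$tasks)
      if (!tk$id %in% usage$tasks)
        add("R3", "warning", loc(tk$id),
            "task is never referenced by a data generator", TRUE)
    for (g in doc$data_generators)
      if (!g$id %in% usage$dgs)
        add("R3", "warning", loc(g$id),
            "data generator is never referenced by an output", TRUE)

    # R4: semantic duplicates among data generators
    sigs <- vapply(doc$data_generators, dg_signature, "")
    if (length(sigs)) {
      first <- !duplicated(sigs)
      for (i in which(!first)) {
        keep <- vapply(doc$data_generators, `[[`, "", "id")[
          match(sigs[i], sigs)]
        add("R4", "warning", loc(doc$data_generators[[i]]$id),
            paste0("semantic duplicate of data generator ", keep), TRUE)
      }
    }

    # R6 / R7: simulation settings
    for (s in doc$simulations) {
      if (s$type != "utc") next
      if (!is.na(s$output_start_time) && !is.na(s$initial_time) &&
          s$output_start_time < s$initial_time)
        add("R6", "error", loc(s$id),
            sprintf("output start %g precedes initial time %g",
                    s$output_start_time, s$initial_time), TRUE)
      if (!is.na(s$output_end_time) && !is.na(s$output_start_time) &&
          s$output_end_time < s$output_start_time)
        add("R6", "error", loc(s$id),
            sprintf("output end %g precedes output start %g",
                    s$output_end_time, s$output_start_time), FALSE)
      if (is.na(s$number_of_points) || s$number_of_points < 1)
        add("R6", "warning", loc(s$id), "number of points below 1", TRUE)
      for (k in names(s$algorithm$parameters)) {
        v <- suppressWarnings(as.numeric(s$algorithm$parameters[[k]]))
        if (is.na(v))
          add("R6", "warning", loc(s$id),
              sprintf("algorithm parameter %s has non-numeric value '%s'",
                      k, s$algorithm$parameters[[k]]), TRUE)
      }
      if (!is.na(s$number_of_points) && s$number_of_points > policy$point_cap)
        add("R7", "warning", loc(s$id),
            sprintf("%g output points exceed the cap of %g",
                    s$number_of_points, policy$point_cap),
            policy$clamp_points)
    }
  }

  issues[order(issues$location, issues$rule_id), , drop = FALSE]
}

#' Resolve dangling model sources against the archive
#'
#' For each model whose source does not name an existing entry: if the
#' archive holds exactly one SBML file, that file is chosen; with several
#' candidates each is scored by reference coverage (the fraction of element
#' ids mentioned by the document's pointers that exist in the candidate),
#' tie-broken by the longest common substring between the stated source and
#' the candidate filename. Only a strict winner resolves; ties and empty
#' candidate sets stay unresolved (`NA` in the map).
#'
#' @param doc a `sed_document`.
#' @param archive the containing `omex_archive`.
#' @return list with `map` (model id -> location or `NA`), `scores`
#'   (per-candidate data.frame) and `note`.
#' @export
resolve_model_source <- function(doc, archive) {
  sbml_entries <- find_sbml_entries(archive)
  cand_locs <- vapply(sbml_entries, function(e) e$location, "")
  doc_ids <- unique(stats::na.omit(vapply(doc_target_contexts(doc),
    function(ctx) {
      p <- tryCatch(parse_xpath_target(ctx$target), error = function(e) NULL)
      if (is.null(p)) NA_character_ else p$element_id
    }, "")))
  map <- list()
  scores <- NULL
  note <- ""
  for (m in doc$models) {
    src <- sub("^\\./", "", m$source)
    if (!is.null(archive_get(archive, src))) {
      map[[m$id]] <- src
      next
    }
    if (length(sbml_entries) == 0L) {
      map[[m$id]] <- NA_character_
      note <- "no SBML entries in archive"
      next
    }
    if (length(sbml_entries) == 1L) {
      map[[m$id]] <- cand_locs[1]
      next
    }
    cov <- vapply(sbml_entries, function(e) {
      info <- tryCatch(parse_sbml_info(e$content), error = function(err) NULL)
      if (is.null(info) || !length(doc_ids)) return(0)
      mean(doc_ids %in% sbml_ids(info))
    }, 1)
    lcs <- vapply(cand_locs, function(l) lcs_length(src, l), 1)
    sc <- data.frame(model = m$id, candidate = cand_locs, coverage = cov,
                     lcs = lcs, stringsAsFactors = FALSE)
    scores <- rbind(scores, sc)
    best_cov <- max(cov)
    top <- which(cov == best_cov)
    if (length(top) > 1L) {
      best_lcs <- max(lcs[top])
      top <- top[lcs[top] == best_lcs]
    }
    if (length(top) == 1L) {
      map[[m$id]] <- cand_locs[top]
    } else {
      map[[m$id]] <- NA_character_
      note <- paste0("tie among candidates: ",
                     paste(sprintf("%s (coverage %.2f, lcs %d)",
                                   cand_locs[top], cov[top], lcs[top]),
                           collapse = ", "))
    }
  }
  list(map = map, scores = scores, note = note)
}

# longest common substring length (small inputs only)
lcs_length <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  if (!length(a) || !length(b)) return(0L)
  prev <- integer(length(b))
  best <- 0L
  for (i in seq_along(a)) {
    cur <- integer(length(b))
    for (j in seq_along(b)) {
      if (a[i] == b[j]) {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

#' Canonicalize and prune element pointers of a document
#'
#' Rewrites every resolvable but non-canonical target to its canonical
#' XPath (rule R5) and removes content depending on unresolvable targets
#' (rule R2): attribute changes are dropped; variables are dropped together
#' with their data generators and any datasets or curves referencing them.
#'
#' @param doc a `sed_document`.
#' @param infos a single `sbml_info` (applied to every model) or a named
#'   list keyed by model id.
#' @return list `doc`, `actions`.
#' @export
fix_targets <- function(doc, infos) {
  if (inherits(infos, "sbml_info")) {
    infos <- stats::setNames(rep(list(infos), length(doc$models)),
                             vapply(doc$models, `[[`, "", "id"))
  }
  actions <- action_frame()
  act <- function(rule, loc, before, after)
    actions[nrow(actions) + 1L, ] <<- list(rule, loc, before, after)

  canon_or_drop <- function(target, model_id, owner, rule_loc) {
    if (is.null(model_id) || is.null(infos[[model_id]]))
      return(list(keep = TRUE, target = target))
    info <- infos[[model_id]]
    parsed <- tryCatch(parse_xpath_target(target), error = function(e) NULL)
    ref <- if (is.null(parsed)) NULL else resolve_xpath(parsed, info)
    if (is.null(ref)) return(list(keep = FALSE, target = target))
    canon <- canonical_xpath(ref)
    if (!identical(canon, target)) {
      act("R5", rule_loc, target, canon)
      return(list(keep = TRUE, target = canon))
    }
    list(keep = TRUE, target = target)
  }

  task_model <- list()
  for (tk in doc$tasks)
    if (tk$type == "task") task_model[[tk$id]] <- tk$model_ref
  for (tk in doc$tasks)
    if (tk$type == "repeat" && length(tk$subtasks)) {
      m <- task_model[[tk$subtasks[[1]]]]
      if (!is.null(m)) task_model[[tk$id]] <- m
    }

  for (i in seq_along(doc$models)) {
    m <- doc$models[[i]]
    keep <- rep(TRUE, length(m$changes))
    for (j in seq_along(m$changes)) {
      r <- canon_or_drop(m$changes[[j]]$target, m$id, m$id, m$id)
      if (!r$keep) {
        keep[j] <- FALSE
        act("R2", m$id, m$changes[[j]]$target, "")
      } else doc$models[[i]]$changes[[j]]$target <- r$target
    }
    doc$models[[i]]$changes <- doc$models[[i]]$changes[keep]
  }

  dropped_dgs <- character(0)
  keep_dg <- rep(TRUE, length(doc$data_generators))
  for (i in seq_along(doc$data_generators)) {
    g <- doc$data_generators[[i]]
    for (j in seq_along(g$variables)) {
      v <- g$variables[[j]]
      if (is.na(v$target)) next
      r <- canon_or_drop(v$target, task_model[[v$task_ref]], g$id, g$id)
      if (!r$keep) {
        keep_dg[i] <- FALSE
        act("R2", g$id, v$target, "")
      } else doc$data_generators[[i]]$variables[[j]]$target <- r$target
    }
  }
  dropped_dgs <- vapply(doc$data_generators[!keep_dg], `[[`, "", "id")
  doc$data_generators <- doc$data_generators[keep_dg]
  if (length(dropped_dgs)) {
    for (i in seq_along(doc$outputs)) {
      o <- doc$outputs[[i]]
      if (o$kind == "report") {
        keep <- vapply(o$datasets, function(d)
          !(d$data_ref %in% dropped_dgs), TRUE)
        doc$outputs[[i]]$datasets <- o$datasets[keep]
      } else {
        keep <- vapply(o$curves, function(cv)
          !(cv$x_ref %in% dropped_dgs || cv$y_ref %in% dropped_dgs), TRUE)
        doc$outputs[[i]]$curves <- o$curves[keep]
      }
    }
  }

  for (i in seq_along(doc$tasks)) {
    tk <- doc$tasks[[i]]
    if (tk$type != "repeat") next
    keep <- rep(TRUE, length(tk$changes))
    for (j in seq_along(tk$changes)) {
      r <- canon_or_drop(tk$changes[[j]]$target, task_model[[tk$id]],
                         tk$id, tk$id)
      if (!r$keep) {
        keep[j] <- FALSE
        act("R2", tk$id, tk$changes[[j]]$target, "")
      } else doc$tasks[[i]]$changes[[j]]$target <- r$target
    }
    doc$tasks[[i]]$changes <- doc$tasks[[i]]$changes[keep]
  }

  list(doc = doc, actions = actions)
}

#' Clamp or flag oversized output grids
#'
#' @param doc a `sed_document`.
#' @param policy a [repair_policy()].
#' @return list `doc`, `issues` (lint rows when not clamping), `actions`
#'   (when clamping).
#' @export
clamp_output_points <- function(doc, policy = repair_policy()) {
  issues <- lint_frame(); actions <- action_frame()
  for (i in seq_along(doc$simulations)) {
    s <- doc$simulations[[i]]
    if (s$type != "utc" || is.na(s$number_of_points)) next
    if (s$number_of_points > policy$point_cap) {
      if (policy$clamp_points) {
        actions[nrow(actions) + 1L, ] <-
          list("R7", s$id, format_num(s$number_of_points),
               format_num(policy$point_cap))
        doc$simulations[[i]]$number_of_points <- policy$point_cap
      } else {
        issues[nrow(issues) + 1L, ] <-
          list("R7", "warning", s$id,
               sprintf("%g output points exceed the cap of %g",
                       s$number_of_points, policy$point_cap), FALSE)
      }
    }
  }
  list(doc = doc, issues = issues, actions = actions)
}

#' Zero out unused non-finite SBML parameters
#'
#' A parameter initialized to infinity or NaN that no mathematics
#' references is set to 0 (any finite value is observationally equivalent
#' for an unused parameter). A referenced non-finite parameter is left
#' untouched; it remains an unrepairable lint error.
#'
#' @param info the model's `sbml_info`.
#' @param sbml raw SBML bytes.
#' @return list `sbml` (edited bytes), `actions`.
#' @export
fix_nonfinite_params <- function(info, sbml) {
  actions <- action_frame()
  used <- sbml_referenced_symbols(info)
  fixable <- Filter(function(p) !is.na(p$value) && !is.finite(p$value) &&
                      !(p$id %in% used), info$parameters)
  if (!length(fixable)) return(list(sbml = sbml, actions = actions))
  x <- xml2::read_xml(sbml)
  for (p in fixable) {
    node <- xml2::xml_find_first(x, sprintf(
      "//*[local-name()='listOfParameters']/*[local-name()='parameter'][@id='%s']",
      p$id))
    if (inherits(node, "xml_missing")) next
    before <- xml2::xml_attr(node, "value")
    xml2::xml_set_attr(node, "value", "0")
    actions[nrow(actions) + 1L, ] <- list("R8", p$id, before, "0")
  }
  list(sbml = charToRaw(as.character(x)), actions = actions)
}

#' Rewrite URN-form annotation resources to URL form
#'
#' `urn:miriam:<ns>:<id>` becomes `https://identifiers.org/<ns>:<id>` with
#' percent-decoding of the id part (when the decoded id already carries its
#' namespace prefix, the prefix is not repeated). URL-form resources are
#' untouched.
#'
#' @param sbml raw SBML bytes.
#' @return list `sbml`, `actions`.
#' @export
urn_to_url <- function(sbml) {
  actions <- action_frame()
  txt <- rawToChar(sbml)
  ms <- regmatches(txt, gregexpr(urn_pattern, txt))[[1]]
  for (u in unique(ms)) {
    parts <- regmatches(u, regexec(urn_pattern, u))[[1]]
    ns <- parts[2]
    id <- utils::URLdecode(parts[3])
    url <- if (grepl(":", id, fixed = TRUE))
      paste0("https://identifiers.org/", id)
    else paste0("https://identifiers.org/", ns, ":", id)
    txt <- gsub(u, url, txt, fixed = TRUE)
    actions[nrow(actions) + 1L, ] <- list("R10", "annotation", u, url)
  }
  list(sbml = charToRaw(txt), actions = actions)
}

#' Repair an archive
#'
#' Applies the enabled rules in the fixed order R1, R5, R2, R4, R3, R6,
#' R7, R8, R10, R9. Unrepairable defects are left as lint issues, never
#' raised. Idempotent: repairing an already repaired archive produces an
#' empty action list.
#'
#' @param archive an `omex_archive`.
#' @param policy a [repair_policy()].
#' @return list `archive` (repaired), `actions` (data.frame).
#' @export
repair <- function(archive, policy = repair_policy()) {
  on <- function(rule) rule %in% policy$enabled_rules
  actions <- action_frame()
  act <- function(rows) actions <<- rbind(actions, rows)
  act1 <- function(rule, loc, before, after)
    actions[nrow(actions) + 1L, ] <<- list(rule, loc, before, after)

  for (ei in seq_along(archive$entries)) {
    e <- archive$entries[[ei]]
    if (!format_is_sedml(e$format)) next
    doc <- tryCatch(parse_sedml(e$content), error = function(err) NULL)
    if (is.null(doc)) next
    n_actions_before <- nrow(actions)

    # R1: resolve dangling model sources
    if (on("R1")) {
      res <- resolve_model_source(doc, archive)
      for (i in seq_along(doc$models)) {
        m <- doc$models[[i]]
        src <- sub("^\\./", "", m$source)
        if (!is.null(archive_get(archive, src))) next
        new <- res$map[[m$id]]
        if (!is.null(new) && !is.na(new)) {
          act1("R1", m$id, m$source, new)
          doc$models[[i]]$source <- new
        }
      }
    }

    infos <- list()
    for (m in doc$models) {
      entry <- archive_get(archive, sub("^\\./", "", m$source))
      if (!is.null(entry)) {
        info <- tryCatch(parse_sbml_info(entry$content),
                         error = function(err) NULL)
        if (!is.null(info)) infos[[m$id]] <- info
      }
    }

    # R5 then R2 (both inside fix_targets, which canonicalizes before
    # dropping)
    if (on("R5") || on("R2")) {
      ft <- fix_targets(doc, infos)
      keep_rules <- c(if (on("R5")) "R5", if (on("R2")) "R2")
      ft$actions <- ft$actions[ft$actions$rule_id %in% keep_rules, ,
                               drop = FALSE]
      if (nrow(ft$actions)) {
        doc <- ft$doc
        act(ft$actions)
      }
    }

    # R4: merge semantically duplicate data generators
    if (on("R4") && length(doc$data_generators) > 1L) {
      sigs <- vapply(doc$data_generators, dg_signature, "")
      ids <- vapply(doc$data_generators, `[[`, "", "id")
      dup <- which(duplicated(sigs))
      if (length(dup)) {
        remap <- character(0)
        for (i in dup) {
          keep_id <- ids[match(sigs[i], sigs)]
          remap[[ids[i]]] <- keep_id
          act1("R4", ids[i], ids[i], keep_id)
        }
        doc$data_generators <- doc$data_generators[-dup]
        for (i in seq_along(doc$outputs)) {
          o <- doc$outputs[[i]]
          if (o$kind == "report") {
            for (j in seq_along(o$datasets)) {
              r <- o$datasets[[j]]$data_ref
              if (r %in% names(remap))
                doc$outputs[[i]]$datasets[[j]]$data_ref <- remap[[r]]
            }
          } else {
            for (j in seq_along(o$curves)) {
              if (o$curves[[j]]$x_ref %in% names(remap))
                doc$outputs[[i]]$curves[[j]]$x_ref <-
                  remap[[o$curves[[j]]$x_ref]]
              if (o$curves[[j]]$y_ref %in% names(remap))
                doc$outputs[[i]]$curves[[j]]$y_ref <-
                  remap[[o$curves[[j]]$y_ref]]
            }
          }
        }
      }
    }

    # R3: prune unused elements to a fixpoint
    if (on("R3")) {
      repeat {
        usage <- doc_usage(doc)
        ids <- function(lst) vapply(lst, `[[`, "", "id")
        un_m <- setdiff(ids(doc$models), usage$models)
        un_s <- setdiff(ids(doc$simulations), usage$sims)
        un_t <- setdiff(ids(doc$tasks), usage$tasks)
        un_g <- setdiff(ids(doc$data_generators), usage$dgs)
        if (!length(c(un_m, un_s, un_t, un_g))) break
        for (id in c(un_m, un_s, un_t, un_g)) act1("R3", id, id, "")
        doc$models <- Filter(function(m) !(m$id %in% un_m), doc$models)
        doc$simulations <- Filter(function(s) !(s$id %in% un_s),
                                  doc$simulations)
        doc$tasks <- Filter(function(tk) !(tk$id %in% un_t), doc$tasks)
        doc$data_generators <- Filter(function(g) !(g$id %in% un_g),
                                      doc$data_generators)
      }
    }

    # R6: inconsistent simulation settings
    if (on("R6")) {
      for (i in seq_along(doc$simulations)) {
        s <- doc$simulations[[i]]
        if (s$type != "utc") next
        if (!is.na(s$output_start_time) && !is.na(s$initial_time) &&
            s$output_start_time < s$initial_time) {
          act1("R6", s$id, format_num(s$output_start_time),
               format_num(s$initial_time))
          doc$simulations[[i]]$output_start_time <- s$initial_time
        }
        if (!is.na(s$number_of_points) && s$number_of_points < 1) {
          act1("R6", s$id, format_num(s$number_of_points), "1")
          doc$simulations[[i]]$number_of_points <- 1
        }
        bad <- names(s$algorithm$parameters)[is.na(suppressWarnings(
          as.numeric(s$algorithm$parameters)))]
        for (k in bad) {
          act1("R6", s$id, paste0(k, "=", s$algorithm$parameters[[k]]), "")
          doc$simulations[[i]]$algorithm$parameters <-
            doc$simulations[[i]]$algorithm$parameters[
              setdiff(names(doc$simulations[[i]]$algorithm$parameters), k)]
        }
      }
    }

    # R7: clamp oversized grids when opted in
    if (on("R7") && policy$clamp_points) {
      cl <- clamp_output_points(doc, policy)
      doc <- cl$doc
      act(cl$actions)
    }

    if (nrow(actions) > n_actions_before) {
      e$content <- write_sedml(doc)
      archive <- archive_set(archive, e)
    }
  }

  # R8 / R10: SBML byte edits
  for (ei in seq_along(archive$entries)) {
    e <- archive$entries[[ei]]
    if (!format_is_sbml(e$format)) next
    if (on("R8")) {
      info <- tryCatch(parse_sbml_info(e$content), error = function(err) NULL)
      if (!is.null(info)) {
        fx <- fix_nonfinite_params(info, e$content)
        if (nrow(fx$actions)) {
          fx$actions$location <- paste0(e$location, "#", fx$actions$location)
          e$content <- fx$sbml
          act(fx$actions)
        }
      }
    }
    if (on("R10") && policy$urn_rewrite) {
      ux <- urn_to_url(e$content)
      if (nrow(ux$actions)) {
        ux$actions$location <- e$location
        e$content <- ux$sbml
        act(ux$actions)
      }
    }
    archive$entries[[ei]] <- e
  }

  # R9: file hygiene last (renames rewrite model sources)
  if (on("R9")) {
    hyg <- hygiene_scan(archive)
    zero <- hyg$location[hyg$kind == "zero_length"]
    nf <- normalize_filenames(archive)
    for (z in zero) act1("R9", z, z, "")
    for (i in seq_len(nrow(nf$renames)))
      act1("R9", nf$renames$old[i], nf$renames$old[i], nf$renames$new[i])
    archive <- nf$archive
  }

  list(archive = archive, actions = actions)
}
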