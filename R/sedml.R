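# SED-ML (L1 V1-V4 read; L1 V3/V4 write) document model.
#
# A sed_document is a plain list: models (with attribute changes),
# simulations (uniform time course / steady state), tasks (plain and
# repeated), data generators, outputs (reports and 2D plots), plus a
# provenance marker distinguishing generated template experiments from
# curation-derived ones.

SEDML_NS <- c("1" = "http://sed-ml.org/",
              "2" = "http://sed-ml.org/sed-ml/level1/version2",
              "3" = "http://sed-ml.org/sed-ml/level1/version3",
              "4" = "http://sed-ml.org/sed-ml/level1/version4")
PROV_NS <- "https://sedverify.org/provenance"
SBML_URN <- "urn:sedml:language:sbml"

#' Construct a SED-ML document
#'
#' @param models,simulations,tasks,data_generators,outputs lists of element
#'   records (see the parser for field names).
#' @param provenance one of `"template"`, `"curation"`, `"unknown"`.
#' @param extra_xml character vector of serialized unknown top-level
#'   elements, carried through for round-tripping.
#' @return an object of class `sed_document`.
#' @export
sed_document <- function(models = list(), simulations = list(), tasks = list(),
                         data_generators = list(), outputs = list(),
                         provenance = "unknown", extra_xml = character(0)) {
  doc <- structure(list(models = models, simulations = simulations,
                        tasks = tasks, data_generators = data_generators,
                        outputs = outputs, provenance = provenance,
                        extra_xml = extra_xml),
                   class = "sed_document")
  ids <- sed_all_ids(doc)
  if (anyDuplicated(ids))
    stop("duplicate SED-ML ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (!provenance %in% c("template", "curation", "unknown"))
    stop("invalid provenance: ", provenance, call. = FALSE)
  doc
}

sed_all_ids <- function(doc) {
  c(vapply(doc$models, `[[`, "", "id"),
    vapply(doc$simulations, `[[`, "", "id"),
    vapply(doc$tasks, `[[`, "", "id"),
    vapply(doc$data_generators, `[[`, "", "id"),
    vapply(doc$outputs, `[[`, "", "id"))
}

#' @export
print.sed_document <- function(x, ...) {
  cat("<sed_document> provenance:", x$provenance, "\n")
  cat(sprintf("  %d model(s), %d simulation(s), %d task(s), %d data generator(s), %d output(s)\n",
              length(x$models), length(x$simulations), length(x$tasks),
              length(x$data_generators), length(x$outputs)))
  invisible(x)
}

## ---- parsing -------------------------------------------------------------

#' Parse a SED-ML document
#'
#' Accepts SED-ML Level 1 versions 1-4 (the element vocabulary used here is
#' shared across versions). Unknown top-level elements are carried through
#' as opaque serialized blobs.
#'
#' @param xml raw vector or character scalar.
#' @return a `sed_document`.
#' @export
parse_sedml <- function(xml) {
  if (is.character(xml)) xml <- charToRaw(paste(xml, collapse = "\n"))
  doc <- xml2::read_xml(xml)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sedML")
    stop("not a SED-ML document (root <", xml2::xml_name(root), ">)",
         call. = FALSE)
  xml2::xml_ns_strip(doc)

  num_attr <- function(node, attr) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) NA_real_ else suppressWarnings(as.numeric(v))
  }

  provenance <- "unknown"
  prov_node <- xml2::xml_find_first(root, "./annotation/provenance")
  if (!inherits(prov_node, "xml_missing")) {
    p <- xml2::xml_attr(prov_node, "source")
    if (!is.na(p) && p %in% c("template", "curation")) provenance <- p
  }

  parse_algorithm <- function(parent) {
    alg <- xml2::xml_find_first(parent, "./algorithm")
    if (inherits(alg, "xml_missing")) return(list(kisao_id = NA_character_,
                                                  parameters = character(0)))
    ps <- xml2::xml_find_all(alg, "./listOfAlgorithmParameters/algorithmParameter")
    params <- stats::setNames(xml2::xml_attr(ps, "value"),
                              xml2::xml_attr(ps, "kisaoID"))
    list(kisao_id = xml2::xml_attr(alg, "kisaoID"), parameters = params)
  }

  models <- lapply(xml2::xml_find_all(root, "./listOfModels/model"), function(n) {
    changes <- lapply(xml2::xml_find_all(n, "./listOfChanges/changeAttribute"),
      function(c) list(target = xml2::xml_attr(c, "target"),
                       new_value = xml2::xml_attr(c, "newValue")))
    list(id = xml2::xml_attr(n, "id"),
         source = xml2::xml_attr(n, "source"),
         changes = changes)
  })

  simulations <- lapply(
    xml2::xml_find_all(root, "./listOfSimulations/uniformTimeCourse | ./listOfSimulations/steadyState"),
    function(n) {
      if (xml2::xml_name(n) == "uniformTimeCourse") {
        list(type = "utc", id = xml2::xml_attr(n, "id"),
             initial_time = num_attr(n, "initialTime"),
             output_start_time = num_attr(n, "outputStartTime"),
             output_end_time = num_attr(n, "outputEndTime"),
             number_of_points = {
               p <- num_attr(n, "numberOfPoints")
               if (is.na(p)) num_attr(n, "numberOfSteps") else p
             },
             algorithm = parse_algorithm(n))
      } else {
        list(type = "steady", id = xml2::xml_attr(n, "id"),
             algorithm = parse_algorithm(n))
      }
    })

  tasks <- lapply(
    xml2::xml_find_all(root, "./listOfTasks/task | ./listOfTasks/repeatedTask"),
    function(n) {
      if (xml2::xml_name(n) == "task") {
        list(type = "task", id = xml2::xml_attr(n, "id"),
             model_ref = xml2::xml_attr(n, "modelReference"),
             simulation_ref = xml2::xml_attr(n, "simulationReference"))
      } else {
        tid <- xml2::xml_attr(n, "id")
        rng_id <- xml2::xml_attr(n, "range")
        ur <- xml2::xml_find_first(n, "./listOfRanges/uniformRange")
        vr <- xml2::xml_find_first(n, "./listOfRanges/vectorRange")
        fr <- xml2::xml_find_first(n, "./listOfRanges/functionalRange")
        range <- if (!inherits(ur, "xml_missing")) {
          list(type = "uniform", id = xml2::xml_attr(ur, "id"),
               start = num_attr(ur, "start"), end = num_attr(ur, "end"),
               count = {
                 p <- num_attr(ur, "numberOfPoints")
                 if (is.na(p)) num_attr(ur, "numberOfSteps") else p
               })
        } else if (!inherits(vr, "xml_missing")) {
          list(type = "vector", id = xml2::xml_attr(vr, "id"),
               values = as.numeric(xml2::xml_text(
                 xml2::xml_find_all(vr, "./value"))))
        } else if (!inherits(fr, "xml_missing")) {
          list(type = "functional", id = xml2::xml_attr(fr, "id"))
        } else stop("repeatedTask ", tid, " has no range", call. = FALSE)
        changes <- lapply(xml2::xml_find_all(n, "./listOfChanges/setValue"),
          function(c) {
            math <- tryCatch(parse_math_child(c), error = function(e)
              stop("malformed math in setValue of repeatedTask ", tid, ": ",
                   conditionMessage(e), call. = FALSE))
            list(target = xml2::xml_attr(c, "target"), math = math)
          })
        subtasks <- xml2::xml_attr(
          xml2::xml_find_all(n, "./listOfSubTasks/subTask"), "task")
        list(type = "repeat", id = tid, range = range,
             range_variable = if (is.na(rng_id)) range$id else rng_id,
             changes = changes, subtasks = subtasks,
             reset_model = tolower(xml2::xml_attr(n, "resetModel")) %in% "true")
      }
    })

  data_generators <- lapply(
    xml2::xml_find_all(root, "./listOfDataGenerators/dataGenerator"),
    function(n) {
      gid <- xml2::xml_attr(n, "id")
      vars <- lapply(xml2::xml_find_all(n, "./listOfVariables/variable"),
        function(v) {
          sym <- xml2::xml_attr(v, "symbol")
          list(id = xml2::xml_attr(v, "id"),
               task_ref = xml2::xml_attr(v, "taskReference"),
               target = xml2::xml_attr(v, "target"),
               symbol = if (!is.na(sym) && grepl("time", sym)) "time"
                        else if (is.na(sym)) NA_character_ else sym)
        })
      math <- tryCatch(parse_math_child(n), error = function(e)
        stop("malformed math in dataGenerator ", gid, ": ",
             conditionMessage(e), call. = FALSE))
      if (is.null(math)) stop("dataGenerator ", gid, " has no math",
                              call. = FALSE)
      list(id = gid, variables = vars, math = math)
    })

  outputs <- lapply(
    xml2::xml_find_all(root, "./listOfOutputs/report | ./listOfOutputs/plot2D"),
    function(n) {
      oid <- xml2::xml_attr(n, "id")
      if (xml2::xml_name(n) == "report") {
        ds <- lapply(xml2::xml_find_all(n, "./listOfDataSets/dataSet"),
          function(d) list(label = xml2::xml_attr(d, "label"),
                           data_ref = xml2::xml_attr(d, "dataReference")))
        labels <- vapply(ds, `[[`, "", "label")
        if (anyDuplicated(labels))
          stop("duplicate dataset labels in report ", oid, call. = FALSE)
        list(id = oid, kind = "report", datasets = ds)
      } else {
        cv <- lapply(xml2::xml_find_all(n, "./listOfCurves/curve"),
          function(c) list(id = xml2::xml_attr(c, "id"),
                           x_ref = xml2::xml_attr(c, "xDataReference"),
                           y_ref = xml2::xml_attr(c, "yDataReference")))
        list(id = oid, kind = "plot2d", curves = cv)
      }
    })

  known <- c("annotation", "notes", "listOfModels", "listOfSimulations",
             "listOfTasks", "listOfDataGenerators", "listOfOutputs")
  extra <- character(0)
  for (k in xml2::xml_children(root))
    if (!(xml2::xml_name(k) %in% known))
      extra <- c(extra, as.character(k))

  sed_document(models, simulations, tasks, data_generators, outputs,
               provenance, extra)
}

## ---- writing -------------------------------------------------------------

#' Serialize a SED-ML document
#'
#' Emits SED-ML Level 1 Version 3 by default (Version 4 selectable).
#' `parse_sedml(write_sedml(d))` is semantically equal to `d`.
#'
#' @param doc a `sed_document`.
#' @param version `"3"` or `"4"`.
#' @return raw vector of XML bytes.
#' @export
write_sedml <- function(doc, version = "3") {
  stopifnot(inherits(doc, "sed_document"), version %in% c("3", "4"))
  doc <- sed_document(doc$models, doc$simulations, doc$tasks,
                      doc$data_generators, doc$outputs, doc$provenance,
                      doc$extra_xml)  # re-validate invariants
  root <- xml2::xml_new_root("sedML", xmlns = SEDML_NS[[version]],
                             level = "1", version = version)
  if (doc$provenance != "unknown") {
    ann <- xml2::xml_add_child(root, "annotation")
    xml2::xml_add_child(ann, "provenance", xmlns = PROV_NS,
                        source = doc$provenance)
  }
  fmt <- function(x) format_num(as.numeric(x))

  if (length(doc$models)) {
    lom <- xml2::xml_add_child(root, "listOfModels")
    for (m in doc$models) {
      mn <- xml2::xml_add_child(lom, "model", id = m$id,
                                language = SBML_URN, source = m$source)
      if (length(m$changes)) {
        loc <- xml2::xml_add_child(mn, "listOfChanges")
        for (ch in m$changes)
          xml2::xml_add_child(loc, "changeAttribute", target = ch$target,
                              newValue = as.character(ch$new_value))
      }
    }
  }

  add_algorithm <- function(parent, alg) {
    if (is.null(alg) || is.na(alg$kisao_id)) return(invisible())
    an <- xml2::xml_add_child(parent, "algorithm", kisaoID = alg$kisao_id)
    if (length(alg$parameters)) {
      lap <- xml2::xml_add_child(an, "listOfAlgorithmParameters")
      for (k in names(alg$parameters))
        xml2::xml_add_child(lap, "algorithmParameter", kisaoID = k,
                            value = alg$parameters[[k]])
    }
  }

  if (length(doc$simulations)) {
    los <- xml2::xml_add_child(root, "listOfSimulations")
    for (s in doc$simulations) {
      if (s$type == "utc") {
        pts_attr <- if (version == "4") "numberOfSteps" else "numberOfPoints"
        args <- list(los, "uniformTimeCourse", id = s$id,
                     initialTime = fmt(s$initial_time),
                     outputStartTime = fmt(s$output_start_time),
                     outputEndTime = fmt(s$output_end_time))
        args[[pts_attr]] <- fmt(s$number_of_points)
        sn <- do.call(xml2::xml_add_child, args)
      } else {
        sn <- xml2::xml_add_child(los, "steadyState", id = s$id)
      }
      add_algorithm(sn, s$algorithm)
    }
  }

  if (length(doc$tasks)) {
    lot <- xml2::xml_add_child(root, "listOfTasks")
    for (tk in doc$tasks) {
      if (tk$type == "task") {
        xml2::xml_add_child(lot, "task", id = tk$id,
                            modelReference = tk$model_ref,
                            simulationReference = tk$simulation_ref)
      } else {
        rn <- xml2::xml_add_child(lot, "repeatedTask", id = tk$id,
                                  range = tk$range_variable,
                                  resetModel = tolower(as.character(tk$reset_model)))
        lor <- xml2::xml_add_child(rn, "listOfRanges")
        if (tk$range$type == "uniform") {
          xml2::xml_add_child(lor, "uniformRange", id = tk$range_variable,
                              start = fmt(tk$range$start),
                              end = fmt(tk$range$end),
                              numberOfPoints = fmt(tk$range$count),
                              type = "linear")
        } else if (tk$range$type == "vector") {
          vn <- xml2::xml_add_child(lor, "vectorRange", id = tk$range_variable)
          for (v in tk$range$values) xml2::xml_add_child(vn, "value", fmt(v))
        } else stop("cannot write range of type ", tk$range$type, call. = FALSE)
        if (length(tk$changes)) {
          loc <- xml2::xml_add_child(rn, "listOfChanges")
          for (ch in tk$changes) {
            cn <- xml2::xml_add_child(loc, "setValue", target = ch$target,
                                      range = tk$range_variable)
            append_mathml(cn, ch$math)
          }
        }
        lst <- xml2::xml_add_child(rn, "listOfSubTasks")
        for (i in seq_along(tk$subtasks))
          xml2::xml_add_child(lst, "subTask", order = as.character(i),
                              task = tk$subtasks[[i]])
      }
    }
  }

  if (length(doc$data_generators)) {
    lod <- xml2::xml_add_child(root, "listOfDataGenerators")
    for (g in doc$data_generators) {
      gn <- xml2::xml_add_child(lod, "dataGenerator", id = g$id)
      if (length(g$variables)) {
        lov <- xml2::xml_add_child(gn, "listOfVariables")
        for (v in g$variables) {
          vn <- xml2::xml_add_child(lov, "variable", id = v$id,
                                    taskReference = v$task_ref)
          if (!is.na(v$target)) xml2::xml_set_attr(vn, "target", v$target)
          if (!is.null(v$symbol) && !is.na(v$symbol) && v$symbol == "time")
            xml2::xml_set_attr(vn, "symbol", "urn:sedml:symbol:time")
        }
      }
      append_mathml(gn, g$math)
    }
  }

  if (length(doc$outputs)) {
    loo <- xml2::xml_add_child(root, "listOfOutputs")
    for (o in doc$outputs) {
      if (o$kind == "report") {
        on <- xml2::xml_add_child(loo, "report", id = o$id)
        lds <- xml2::xml_add_child(on, "listOfDataSets")
        for (i in seq_along(o$datasets)) {
          d <- o$datasets[[i]]
          xml2::xml_add_child(lds, "dataSet",
                              id = paste0(o$id, "_ds_", i),
                              label = d$label, dataReference = d$data_ref)
        }
      } else {
        on <- xml2::xml_add_child(loo, "plot2D", id = o$id)
        lcv <- xml2::xml_add_child(on, "listOfCurves")
        for (cv in o$curves)
          xml2::xml_add_child(lcv, "curve", id = cv$id, logX = "false",
                              logY = "false", xDataReference = cv$x_ref,
                              yDataReference = cv$y_ref)
      }
    }
  }

  for (blob in doc$extra_xml) {
    frag <- tryCatch(xml2::read_xml(blob), error = function(e) NULL)
    if (!is.null(frag)) xml2::xml_add_child(root, frag)
  }
  charToRaw(as.character(root))
}

## ---- semantic equality ---------------------------------------------------

sed_canonical <- function(doc) {
  num <- function(x) as.numeric(x)
  sort_by_id <- function(lst) {
    if (!length(lst)) return(lst)
    lst[order(vapply(lst, `[[`, "", "id"))]
  }
  models <- lapply(sort_by_id(doc$models), function(m) {
    ch <- lapply(m$changes, function(c)
      list(target = c$target, new_value = num(c$new_value)))
    if (length(ch)) ch <- ch[order(vapply(ch, `[[`, "", "target"))]
    list(id = m$id, source = sub("^\\./", "", m$source), changes = ch)
  })
  sims <- lapply(sort_by_id(doc$simulations), function(s) {
    alg <- s$algorithm
    alg$parameters <- alg$parameters[order(names(alg$parameters))]
    if (s$type == "utc")
      list(type = "utc", id = s$id, t0 = num(s$initial_time),
           os = num(s$output_start_time), oe = num(s$output_end_time),
           np = num(s$number_of_points), alg = alg)
    else list(type = "steady", id = s$id, alg = alg)
  })
  tasks <- lapply(sort_by_id(doc$tasks), function(tk) {
    if (tk$type == "task") tk
    else {
      tk$changes <- lapply(tk$changes, function(c)
        list(target = c$target, math = math_canonical(c$math)))
      tk$range <- lapply(tk$range, num_or_pass)
      tk
    }
  })
  dgs <- lapply(sort_by_id(doc$data_generators), function(g) {
    vars <- lapply(g$variables, function(v)
      list(id = v$id, task_ref = v$task_ref,
           target = if (is.na(v$target)) NULL else v$target,
           symbol = if (is.null(v$symbol) || is.na(v$symbol)) NULL else v$symbol))
    if (length(vars)) vars <- vars[order(vapply(g$variables, `[[`, "", "id"))]
    list(id = g$id, variables = vars, math = math_canonical(g$math))
  })
  outs <- lapply(sort_by_id(doc$outputs), function(o) {
    if (o$kind == "report") {
      ds <- o$datasets[order(vapply(o$datasets, `[[`, "", "label"))]
      list(id = o$id, kind = "report", datasets = ds)
    } else {
      cv <- o$curves[order(vapply(o$curves, `[[`, "", "id"))]
      list(id = o$id, kind = "plot2d", curves = cv)
    }
  })
  list(models = models, sims = sims, tasks = tasks, dgs = dgs, outs = outs,
       provenance = doc$provenance,
       extra = sort(gsub("[[:space:]]+", "",
                         gsub("\\s+xmlns(:[A-Za-z0-9]+)?=\"[^\"]*\"", "",
                              doc$extra_xml))))
}

num_or_pass <- function(x) {
  if (is.character(x)) {
    n <- suppressWarnings(as.numeric(x))
    if (!anyNA(n)) return(n)
  }
  x
}

#' Semantic equality of two SED-ML documents
#'
#' True iff the documents are isomorphic up to element order within lists
#' and insignificant whitespace; mathematics is compared structurally,
#' numeric attributes numerically.
#'
#' @param a,b `sed_document` objects.
#' @return logical scalar.
#' @export
semantic_equal <- function(a, b) {
  isTRUE(all.equal(sed_canonical(a), sed_canonical(b), tolerance = 1e-12,
                   check.attributes = FALSE))
}
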