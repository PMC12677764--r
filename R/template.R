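# Template experiment generation: a generic time-course over ten time units
# exporting every variable species, used to test cross-engine agreement for
# models that ship without any experiment description.

#' Which species of a model can change over time?
#'
#' Variable species are those not flagged constant and not boundary species
#' without a rule targeting them.
#' @noRd
variable_species <- function(info) {
  rule_targets <- c(vapply(info$assignment_rules, `[[`, "", "target"),
                    vapply(info$rate_rules, `[[`, "", "target"))
  Filter(function(s) {
    if (isTRUE(s$constant)) return(FALSE)
    if (isTRUE(s$boundary) && !(s$id %in% rule_targets)) return(FALSE)
    TRUE
  }, info$species)
}

#' Generate a template time-course experiment
#'
#' Builds a SED-ML document that loads the model, runs a deterministic ODE
#' time course over ten time units (101 output points), and exports time
#' plus the level of every variable species, both as a report and as a 2D
#' plot. The document is marked with template provenance.
#'
#' @param info an `sbml_info` for the model.
#' @param model_location the model's location inside its archive.
#' @return a `sed_document`.
#' @export
generate_template <- function(info, model_location) {
  stopifnot(inherits(info, "sbml_info"))
  vs <- variable_species(info)
  if (!length(vs))
    stop("model has no variable species: nothing to export", call. = FALSE)
  sim <- list(type = "utc", id = "sim1", initial_time = 0,
              output_start_time = 0, output_end_time = 10,
              number_of_points = 100,
              algorithm = list(kisao_id = "KISAO:0000019",
                               parameters = character(0)))
  task <- list(type = "task", id = "task1", model_ref = "model1",
               simulation_ref = "sim1")
  dgs <- list(list(
    id = "dg_time",
    variables = list(list(id = "var_time", task_ref = "task1",
                          target = NA_character_, symbol = "time")),
    math = m_sym("var_time")))
  datasets <- list(list(label = "time", data_ref = "dg_time"))
  curves <- list()
  for (s in vs) {
    vid <- paste0("var_", s$id)
    gid <- paste0("dg_", s$id)
    dgs[[length(dgs) + 1L]] <- list(
      id = gid,
      variables = list(list(id = vid, task_ref = "task1",
                            target = canonical_xpath(list(kind = "species",
                                                          id = s$id)),
                            symbol = NA_character_)),
      math = m_sym(vid))
    datasets[[length(datasets) + 1L]] <- list(label = s$id, data_ref = gid)
    curves[[length(curves) + 1L]] <- list(id = paste0("curve_", s$id),
                                          x_ref = "dg_time", y_ref = gid)
  }
  sed_document(
    models = list(list(id = "model1", source = model_location,
                       changes = list())),
    simulations = list(sim),
    tasks = list(task),
    data_generators = dgs,
    outputs = list(list(id = "report1", kind = "report", datasets = datasets),
                   list(id = "plot1", kind = "plot2d", curves = curves)),
    provenance = "template")
}

#' Is this document a generated template experiment?
#'
#' Reads the provenance marker; absence of a marker means unknown, which is
#' not treated as template.
#'
#' @param doc a `sed_document`.
#' @return logical scalar.
#' @export
is_template <- function(doc) {
  identical(doc$provenance, "template")
}
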