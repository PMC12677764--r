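# SBML (L2/L3 core) introspection.  The model is inventoried into a plain
# list (`sbml_info`) carrying everything the ODE compiler and the lint rules
# need: element tables, parsed kinetic/rule mathematics, and capability
# feature tags for constructs the built-in engines cannot simulate.

FEATURE_TAGS <- c("events", "delayed_events", "delay_csymbol",
                  "algebraic_rules", "fast_reactions",
                  "assigned_stoichiometry", "noninteger_stoichiometry")

#' Introspect an SBML model
#'
#' Parses SBML Level 2 or 3 (core) into an element inventory with parsed
#' mathematics and a set of capability feature tags naming constructs that
#' require special simulator support (events, delays, algebraic rules, fast
#' reactions, assigned or non-integer stoichiometries).
#'
#' @param xml raw vector or character scalar of SBML.
#' @return an object of class `sbml_info`.
#' @export
parse_sbml_info <- function(xml) {
  if (is.character(xml)) xml <- charToRaw(paste(xml, collapse = "\n"))
  doc <- xml2::read_xml(xml)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml")
    stop("not an SBML document (root <", xml2::xml_name(root), ">)",
         call. = FALSE)
  level <- as.integer(xml2::xml_attr(root, "level"))
  if (is.na(level) || level < 2L)
    stop("unsupported SBML level: ", xml2::xml_attr(root, "level"),
         " (only Level 2 and 3 are supported)", call. = FALSE)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, "./model")
  if (inherits(model, "xml_missing"))
    stop("SBML document has no <model>", call. = FALSE)

  tags <- character(0)
  add_tag <- function(t) tags <<- union(tags, t)

  num_attr <- function(node, attr, default = NA_real_) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) return(default)
    switch(toupper(v), "INF" = Inf, "+INF" = Inf, "-INF" = -Inf, "NAN" = NaN,
           suppressWarnings(as.numeric(v)))
  }
  bool_attr <- function(node, attr, default = FALSE) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) default else tolower(v) %in% c("true", "1")
  }

  compartments <- lapply(xml2::xml_find_all(model, ".//listOfCompartments/compartment"),
    function(n) list(
      id = xml2::xml_attr(n, "id"),
      size = num_attr(n, if (!is.na(xml2::xml_attr(n, "size"))) "size" else "volume",
                      default = 1),
      constant = bool_attr(n, "constant", default = TRUE)))

  species <- lapply(xml2::xml_find_all(model, ".//listOfSpecies/species"),
    function(n) {
      amt <- num_attr(n, "initialAmount")
      conc <- num_attr(n, "initialConcentration")
      list(
        id = xml2::xml_attr(n, "id"),
        compartment = xml2::xml_attr(n, "compartment"),
        initial = if (!is.na(amt)) amt else conc,
        init_is_conc = is.na(amt) && !is.na(conc),
        substance_only = bool_attr(n, "hasOnlySubstanceUnits"),
        boundary = bool_attr(n, "boundaryCondition"),
        constant = bool_attr(n, "constant"))
    })

  parameters <- lapply(xml2::xml_find_all(model, "./listOfParameters/parameter"),
    function(n) list(
      id = xml2::xml_attr(n, "id"),
      value = num_attr(n, "value"),
      constant = bool_attr(n, "constant", default = TRUE)))

  local_parameters <- list()
  reactions <- list()
  sref_ids <- character(0)
  for (rn in xml2::xml_find_all(model, "./listOfReactions/reaction")) {
    rid <- xml2::xml_attr(rn, "id")
    if (bool_attr(rn, "fast")) add_tag("fast_reactions")
    parse_refs <- function(xp) {
      lapply(xml2::xml_find_all(rn, xp), function(s) {
        st <- num_attr(s, "stoichiometry", default = 1)
        sid <- xml2::xml_attr(s, "id")
        if (!is.na(sid)) sref_ids <<- c(sref_ids, sid)
        if (!inherits(xml2::xml_find_first(s, "./stoichiometryMath"), "xml_missing"))
          add_tag("assigned_stoichiometry")
        if (is.finite(st) && st != round(st)) add_tag("noninteger_stoichiometry")
        list(species = xml2::xml_attr(s, "species"), stoichiometry = st)
      })
    }
    reactants <- parse_refs("./listOfReactants/speciesReference")
    products  <- parse_refs("./listOfProducts/speciesReference")
    kl <- xml2::xml_find_first(rn, "./kineticLaw")
    kmath <- NULL
    if (!inherits(kl, "xml_missing")) {
      kmath <- parse_math_child(kl)
      for (lp in xml2::xml_find_all(kl, "./listOfLocalParameters/localParameter | ./listOfParameters/parameter")) {
        local_parameters[[length(local_parameters) + 1L]] <-
          list(reaction_id = rid, id = xml2::xml_attr(lp, "id"),
               value = num_attr(lp, "value"))
      }
    }
    reactions[[length(reactions) + 1L]] <- list(
      id = rid, reactants = reactants, products = products,
      reversible = bool_attr(rn, "reversible", default = level == 2L),
      kinetic_law = kmath)
  }

  assignment_rules <- lapply(xml2::xml_find_all(model, ".//listOfRules/assignmentRule"),
    function(n) list(target = xml2::xml_attr(n, "variable"),
                     math = parse_math_child(n)))
  rate_rules <- lapply(xml2::xml_find_all(model, ".//listOfRules/rateRule"),
    function(n) list(target = xml2::xml_attr(n, "variable"),
                     math = parse_math_child(n)))
  if (length(xml2::xml_find_all(model, ".//listOfRules/algebraicRule")))
    add_tag("algebraic_rules")

  initial_assignments <- lapply(
    xml2::xml_find_all(model, ".//listOfInitialAssignments/initialAssignment"),
    function(n) list(target = xml2::xml_attr(n, "symbol"),
                     math = parse_math_child(n)))

  events <- xml2::xml_find_all(model, ".//listOfEvents/event")
  if (length(events)) {
    add_tag("events")
    for (ev in events)
      if (!inherits(xml2::xml_find_first(ev, "./delay"), "xml_missing"))
        add_tag("delayed_events")
  }

  all_math <- c(lapply(reactions, function(r) r$kinetic_law),
                lapply(assignment_rules, function(r) r$math),
                lapply(rate_rules, function(r) r$math),
                lapply(initial_assignments, function(r) r$math))
  all_math <- Filter(Negate(is.null), all_math)
  if (any(vapply(all_math, math_has_delay, TRUE))) add_tag("delay_csymbol")

  rule_targets <- c(vapply(assignment_rules, function(r) r$target, ""),
                    vapply(rate_rules, function(r) r$target, ""),
                    vapply(initial_assignments, function(r) r$target, ""))
  if (length(intersect(sref_ids, rule_targets))) add_tag("assigned_stoichiometry")

  info <- structure(list(
    model_id = xml2::xml_attr(model, "id"),
    level = level,
    compartments = compartments,
    species = species,
    parameters = parameters,
    local_parameters = local_parameters,
    reactions = reactions,
    assignment_rules = assignment_rules,
    rate_rules = rate_rules,
    initial_assignments = initial_assignments,
    feature_tags = sort(tags)
  ), class = "sbml_info")
  check_sbml_ids(info)
  info
}

sbml_ids <- function(info) {
  c(vapply(info$compartments, `[[`, "", "id"),
    vapply(info$species, `[[`, "", "id"),
    vapply(info$parameters, `[[`, "", "id"),
    vapply(info$reactions, `[[`, "", "id"))
}

check_sbml_ids <- function(info) {
  ids <- sbml_ids(info)
  if (anyDuplicated(ids))
    stop("duplicate SBML ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  invisible(info)
}

#' @export
print.sbml_info <- function(x, ...) {
  cat("<sbml_info> model", x$model_id, "(SBML L", x$level, ")\n")
  cat(" ", length(x$species), "species,", length(x$reactions), "reactions,",
      length(x$parameters), "parameters,",
      length(x$local_parameters), "local parameters\n")
  if (length(x$feature_tags))
    cat("  feature tags:", paste(x$feature_tags, collapse = ", "), "\n")
  invisible(x)
}

# all symbols referenced by any math in the model (used by the non-finite
# parameter rule: a parameter is 'unused' if nothing references it)
sbml_referenced_symbols <- function(info) {
  maths <- c(lapply(info$reactions, function(r) r$kinetic_law),
             lapply(info$assignment_rules, function(r) r$math),
             lapply(info$rate_rules, function(r) r$math),
             lapply(info$initial_assignments, function(r) r$math))
  maths <- Filter(Negate(is.null), maths)
  unique(unlist(lapply(maths, math_symbols)))
}
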