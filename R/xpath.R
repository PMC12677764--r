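# XPath targets addressing SBML model elements.  SED-ML points into models
# with XPath strings; in the wild these come with or without namespace
# prefixes, with id or name predicates, and occasionally mangled.  The
# canonical form used on output is `/sbml:sbml/sbml:model/...` with a single
# `[@id='...']` predicate.

#' Parse an XPath target string
#'
#' Tolerant parser for SBML element pointers: accepts missing `sbml:`
#' prefixes and `[@name='...']` predicates. Distinguishes an unparseable
#' string (error) from a parseable one that may not resolve.
#'
#' @param raw the XPath string.
#' @return list with fields `raw`, `element_kind`
#'   (species/parameter/local_parameter/compartment/reaction/other),
#'   `element_id` (possibly `NA`), `reaction_id` (for local parameters).
#' @export
parse_xpath_target <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(trimws(raw)))
    stop("unparseable XPath target: empty string", call. = FALSE)
  seg_re <- "^([A-Za-z_][A-Za-z0-9_.]*:)?([A-Za-z_][A-Za-z0-9_.]*)(\\[@(id|name)='([^']*)'\\])?$"
  segs <- strsplit(sub("^/", "", trimws(raw)), "/", fixed = TRUE)[[1]]
  if (!length(segs)) stop("unparseable XPath target: ", raw, call. = FALSE)
  parsed <- lapply(segs, function(s) {
    m <- regmatches(s, regexec(seg_re, s))[[1]]
    if (!length(m)) stop("unparseable XPath target: ", raw, call. = FALSE)
    list(name = m[3], pred_attr = if (nzchar(m[5])) m[5] else NA_character_,
         pred_val = if (nzchar(m[5])) m[6] else NA_character_)
  })
  last <- parsed[[length(parsed)]]
  names_all <- vapply(parsed, `[[`, "", "name")
  in_reaction <- any(names_all == "reaction") || any(names_all == "kineticLaw")
  kind <- switch(last$name,
    species = "species",
    compartment = "compartment",
    reaction = "reaction",
    localParameter = "local_parameter",
    parameter = if (in_reaction) "local_parameter" else "parameter",
    "other")
  reaction_id <- NA_character_
  for (p in parsed)
    if (p$name == "reaction" && !is.na(p$pred_val)) reaction_id <- p$pred_val
  list(raw = raw, element_kind = kind, element_id = last$pred_val,
       reaction_id = reaction_id)
}

#' Resolve an XPath target against a model inventory
#'
#' @param target an XPath string or the result of [parse_xpath_target()].
#' @param info an `sbml_info`.
#' @return a typed element reference (list with `kind`, `id`, and for local
#'   parameters `reaction_id`), or `NULL` when no element matches.
#' @export
resolve_xpath <- function(target, info) {
  if (is.character(target)) target <- parse_xpath_target(target)
  id <- target$element_id
  if (is.na(id)) return(NULL)
  kind <- target$element_kind
  has <- function(tab) any(vapply(tab, function(x) identical(x$id, id), TRUE))
  if (kind %in% c("species", "other") && has(info$species))
    return(list(kind = "species", id = id))
  if (kind %in% c("parameter", "other") && has(info$parameters))
    return(list(kind = "parameter", id = id))
  if (kind %in% c("local_parameter", "other")) {
    for (lp in info$local_parameters) {
      if (identical(lp$id, id) &&
          (is.na(target$reaction_id) || identical(lp$reaction_id, target$reaction_id)))
        return(list(kind = "local_parameter", id = id,
                    reaction_id = lp$reaction_id))
    }
    # locals promoted to globals re-resolve through the recorded mapping
    for (pm in info$promoted_locals) {
      if (identical(pm$old_id, id) &&
          (is.na(target$reaction_id) || identical(pm$reaction_id, target$reaction_id)))
        return(list(kind = "parameter", id = pm$new_id))
    }
    if (kind == "local_parameter" && has(info$parameters))
      return(list(kind = "parameter", id = id))
  }
  if (kind %in% c("compartment", "other") && has(info$compartments))
    return(list(kind = "compartment", id = id))
  if (kind %in% c("reaction", "other") && has(info$reactions))
    return(list(kind = "reaction", id = id))
  NULL
}

#' Canonical XPath string for a model element reference
#'
#' @param ref element reference as returned by [resolve_xpath()].
#' @return the canonical XPath string with `sbml:` prefixes and an
#'   `[@id='...']` predicate.
#' @export
canonical_xpath <- function(ref) {
  stopifnot(is.list(ref), !is.null(ref$kind), !is.null(ref$id))
  base <- "/sbml:sbml/sbml:model"
  switch(ref$kind,
    species = sprintf("%s/sbml:listOfSpecies/sbml:species[@id='%s']",
                      base, ref$id),
    parameter = sprintf("%s/sbml:listOfParameters/sbml:parameter[@id='%s']",
                        base, ref$id),
    compartment = sprintf("%s/sbml:listOfCompartments/sbml:compartment[@id='%s']",
                          base, ref$id),
    reaction = sprintf("%s/sbml:listOfReactions/sbml:reaction[@id='%s']",
                       base, ref$id),
    local_parameter = sprintf(
      "%s/sbml:listOfReactions/sbml:reaction[@id='%s']/sbml:kineticLaw/sbml:listOfLocalParameters/sbml:localParameter[@id='%s']",
      base, ref$reaction_id, ref$id),
    stop("cannot canonicalize element of kind ", ref$kind, call. = FALSE)
  )
}

# is `raw` already the canonical string for the element it resolves to?
xpath_is_canonical <- function(raw, info) {
  ref <- tryCatch(resolve_xpath(raw, info), error = function(e) NULL)
  if (is.null(ref)) return(NA)
  identical(raw, canonical_xpath(ref))
}
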