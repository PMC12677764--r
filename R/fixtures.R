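# Synthetic fixture archives with analytic oracles, plus a corrupter that
# injects exactly one defect of a chosen lint-rule class.  Every generator is
# deterministic: the same arguments (and seed) give byte-identical archives.

## ---- SBML construction ---------------------------------------------------

SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"

# spec list: list(id=, init=, conc=FALSE, compartment="cell", boundary=, constant=)
# reaction list: list(id=, reactants=c(S=stoich), products=c(...), math=<ast>,
#                     local_params=c(k=value), reversible=)
build_sbml <- function(model_id, species, reactions,
                       parameters = list(), compartments = NULL,
                       annotation_resource = NULL) {
  if (is.null(compartments))
    compartments <- list(list(id = "cell", size = 1))
  root <- xml2::xml_new_root("sbml", xmlns = SBML_L3_NS,
                             level = "3", version = "1")
  model <- xml2::xml_add_child(root, "model", id = model_id)
  if (!is.null(annotation_resource)) {
    ann <- xml2::xml_add_child(model, "annotation")
    frag <- xml2::read_xml(sprintf(
      '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/"><rdf:Description rdf:about="#%s"><bqbiol:is><rdf:Bag><rdf:li rdf:resource="%s"/></rdf:Bag></bqbiol:is></rdf:Description></rdf:RDF>',
      model_id, annotation_resource))
    xml2::xml_add_child(ann, frag)
  }
  loc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cp in compartments)
    xml2::xml_add_child(loc, "compartment", id = cp$id,
                        size = format_num(cp$size), constant = "true")
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (s in species) {
    sn <- xml2::xml_add_child(
      los, "species", id = s$id,
      compartment = if (is.null(s$compartment)) "cell" else s$compartment,
      hasOnlySubstanceUnits = "false",
      boundaryCondition = tolower(as.character(isTRUE(s$boundary))),
      constant = tolower(as.character(isTRUE(s$constant))))
    if (isTRUE(s$conc))
      xml2::xml_set_attr(sn, "initialConcentration", format_num(s$init))
    else
      xml2::xml_set_attr(sn, "initialAmount", format_num(s$init))
  }
  if (length(parameters)) {
    lop <- xml2::xml_add_child(model, "listOfParameters")
    for (p in parameters)
      xml2::xml_add_child(lop, "parameter", id = p$id,
                          value = format_num(p$value),
                          constant = tolower(as.character(
                            !isFALSE(p$constant))))
  }
  if (length(reactions)) {
    lor <- xml2::xml_add_child(model, "listOfReactions")
    for (r in reactions) {
      rn <- xml2::xml_add_child(lor, "reaction", id = r$id,
                                reversible = tolower(as.character(
                                  isTRUE(r$reversible))),
                                fast = "false")
      add_refs <- function(listname, refs) {
        if (!length(refs)) return(invisible())
        ln <- xml2::xml_add_child(rn, listname)
        for (sp in names(refs))
          xml2::xml_add_child(ln,
                              "speciesReference", species = sp,
                              stoichiometry = format_num(refs[[sp]]),
                              constant = "true")
      }
      add_refs("listOfReactants", r$reactants)
      add_refs("listOfProducts", r$products)
      kl <- xml2::xml_add_child(rn, "kineticLaw")
      append_mathml(kl, r$math)
      if (length(r$local_params)) {
        llp <- xml2::xml_add_child(kl, "listOfLocalParameters")
        for (p in names(r$local_params))
          xml2::xml_add_child(llp, "localParameter", id = p,
                              value = format_num(r$local_params[[p]]))
      }
    }
  }
  charToRaw(as.character(root))
}

# product of rate constant symbol and species symbols: k * A * B ...
mass_action_law <- function(k, species_ids) {
  args <- c(list(if (is.character(k)) m_sym(k) else m_num(k)),
            lapply(species_ids, m_sym))
  if (length(args) == 1L) args[[1]] else m_apply("times", args)
}

fixture_archive <- function(name, sbml_bytes, extra_entries = list()) {
  info <- parse_sbml_info(sbml_bytes)
  model_loc <- paste0(name, ".xml")
  doc <- generate_template(info, model_loc)
  entries <- c(list(
    archive_entry(model_loc, sbml_bytes, FMT_SBML),
    archive_entry(paste0(name, ".sedml"), write_sedml(doc), FMT_SEDML,
                  is_master = TRUE)),
    extra_entries)
  new_archive(entries)
}

## ---- generators ----------------------------------------------------------

#' Linear decay-chain fixture
#'
#' Species `X0 -> X1 -> ... -> Xn` under mass action with the given rate
#' constants; `X0(0) = 10`, the rest 0. The closed-form Bateman solution is
#' available through [analytic_solution()]. The archive bundles the SBML
#' model with a generated template experiment.
#'
#' @param n number of reactions (the chain has `n + 1` species).
#' @param rates numeric vector of `n` positive rate constants.
#' @param seed unused (the generator is fully deterministic); kept so all
#'   fixture generators share one signature.
#' @return an `omex_archive`.
#' @export
gen_decay_chain <- function(n, rates, seed = 1L) {
  stopifnot(n >= 1, length(rates) == n)
  if (any(rates <= 0)) stop("rates must be positive", call. = FALSE)
  species <- lapply(0:n, function(i)
    list(id = paste0("X", i), init = if (i == 0) 10 else 0))
  parameters <- lapply(seq_len(n), function(i)
    list(id = paste0("k", i), value = rates[i]))
  reactions <- lapply(seq_len(n), function(i)
    list(id = paste0("J", i),
         reactants = stats::setNames(1, paste0("X", i - 1L)),
         products = stats::setNames(1, paste0("X", i)),
         math = mass_action_law(paste0("k", i), paste0("X", i - 1L))))
  sbml <- build_sbml(paste0("decay_chain_", n), species, reactions, parameters,
                     annotation_resource = "https://identifiers.org/GO:0009056")
  fixture_archive(paste0("decay_chain_", n), sbml)
}

#' Closed-form solution of the decay chain
#'
#' Bateman solution for `X0 -> X1 -> ... -> Xn` with distinct rates and
#' `X0(0) = x0`. Terminal species has decay constant 0.
#'
#' @param rates positive rate constants (all distinct).
#' @param times numeric vector of evaluation times.
#' @param x0 initial amount of the first species.
#' @return matrix `length(times) x (length(rates)+1)`, columns `X0..Xn`.
#' @export
analytic_solution <- function(rates, times, x0 = 10) {
  lambda <- c(rates, 0)
  if (anyDuplicated(lambda))
    stop("analytic_solution requires distinct rates", call. = FALSE)
  n <- length(lambda)
  out <- matrix(0, nrow = length(times), ncol = n,
                dimnames = list(NULL, paste0("X", seq_len(n) - 1L)))
  for (i in seq_len(n)) {          # species index (1-based; i-1 conversions)
    lam <- lambda[seq_len(i)]
    coef <- x0 * prod(lambda[seq_len(i - 1L)])
    acc <- 0
    for (j in seq_len(i)) {
      denom <- prod(lam[-j] - lam[j])
      if (i == 1L) denom <- 1
      acc <- acc + exp(-lam[j] * times) / denom
    }
    out[, i] <- coef * acc
  }
  out
}

#' Random conserved mass-action network fixture
#'
#' Conversion (`A -> B`) and reversible binding (`A + B <-> C`) reactions
#' with log-uniform rate constants in `[1e-2, 1]`. Species carry integer
#' weights (1 for monomers, 2 for complexes) chosen so the weighted total
#' amount is exactly conserved; the weights and the conserved total are
#' recorded in a `conservation.json` entry of the archive. Identical seeds
#' give byte-identical archives.
#'
#' @param n_species number of species (>= 2).
#' @param n_reactions number of reactions (>= 1).
#' @param seed integer RNG seed.
#' @return an `omex_archive`.
#' @export
gen_mass_action_network <- function(n_species, n_reactions, seed = 1L) {
  if (n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  stopifnot(n_reactions >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)

  n_complex <- if (n_species >= 3) max(1L, n_species %/% 3L) else 0L
  n_mono <- n_species - n_complex
  ids <- paste0("S", seq_len(n_species))
  weights <- c(rep(1L, n_mono), rep(2L, n_complex))
  inits <- c(rep(2, n_mono), rep(0, n_complex))

  rate <- function() 10^stats::runif(1, -2, 0)
  reactions <- list()
  rate_params <- list()
  for (r in seq_len(n_reactions)) {
    can_bind <- n_mono >= 2 && n_complex >= 1
    bind <- can_bind && stats::runif(1) < 0.5
    if (bind) {
      ab <- sample.int(n_mono, 2L)
      cc <- n_mono + sample.int(n_complex, 1L)
      kf <- paste0("kf", r); kr <- paste0("kr", r)
      rate_params[[kf]] <- rate(); rate_params[[kr]] <- rate()
      law <- m_apply("minus",
                     mass_action_law(kf, ids[ab]),
                     mass_action_law(kr, ids[cc]))
      reactions[[r]] <- list(
        id = paste0("J", r),
        reactants = stats::setNames(c(1, 1), ids[ab]),
        products = stats::setNames(1, ids[cc]),
        math = law, reversible = TRUE)
    } else {
      # conversion between two species of equal weight
      pool <- if (n_mono >= 2) seq_len(n_mono) else (n_mono + seq_len(n_complex))
      ab <- sample(pool, 2L)
      kk <- paste0("k", r)
      rate_params[[kk]] <- rate()
      reactions[[r]] <- list(
        id = paste0("J", r),
        reactants = stats::setNames(1, ids[ab[1]]),
        products = stats::setNames(1, ids[ab[2]]),
        math = mass_action_law(kk, ids[ab[1]]))
    }
  }
  species <- lapply(seq_len(n_species), function(i)
    list(id = ids[i], init = inits[i]))
  parameters <- lapply(names(rate_params), function(p)
    list(id = p, value = rate_params[[p]]))
  name <- sprintf("network_%d_%d_%d", n_species, n_reactions, as.integer(seed))
  sbml <- build_sbml(name, species, reactions, parameters,
                     annotation_resource = "https://identifiers.org/GO:0008152")
  meta <- jsonlite::toJSON(list(weights = stats::setNames(as.list(weights), ids),
                                total = sum(weights * inits)),
                           auto_unbox = TRUE, digits = NA)
  fixture_archive(name, sbml, list(
    archive_entry("conservation.json", charToRaw(as.character(meta)),
                  "http://purl.org/NET/mediatypes/application/json")))
}

#' Stiff three-species fixture (Robertson-type kinetics)
#'
#' The classic autocatalytic scheme with rate constants 0.04, 3e7, 1e4,
#' initial concentrations (1, 0, 0), simulated over ten time units. The
#' system is strongly stiff after the initial transient and exercises the
#' per-variable absolute-tolerance scaling.
#'
#' @return an `omex_archive`.
#' @export
gen_stiff <- function() {
  species <- list(list(id = "y1", init = 1, conc = TRUE),
                  list(id = "y2", init = 0, conc = TRUE),
                  list(id = "y3", init = 0, conc = TRUE))
  parameters <- list(list(id = "k1", value = 0.04),
                     list(id = "k2", value = 3e7),
                     list(id = "k3", value = 1e4))
  reactions <- list(
    list(id = "J1", reactants = c(y1 = 1), products = c(y2 = 1),
         math = mass_action_law("k1", "y1")),
    list(id = "J2", reactants = c(y2 = 2), products = c(y2 = 1, y3 = 1),
         math = mass_action_law("k2", c("y2", "y2"))),
    list(id = "J3", reactants = c(y2 = 1, y3 = 1), products = c(y1 = 1, y3 = 1),
         math = mass_action_law("k3", c("y2", "y3"))))
  sbml <- build_sbml("robertson", species, reactions, parameters,
                     annotation_resource = "https://identifiers.org/GO:0008152")
  fixture_archive("robertson", sbml)
}

#' Oscillating two-species fixture (Lotka-Volterra kinetics)
#'
#' Autocatalytic prey-predator scheme `X -> 2X`, `X + Y -> 2Y`, `Y -> 0`
#' with period of order one over the ten-unit template window. Used as a
#' comparison stress fixture: small phase shifts produce large element-wise
#' deviations.
#'
#' @return an `omex_archive`.
#' @export
gen_oscillator <- function() {
  species <- list(list(id = "prey", init = 1),
                  list(id = "predator", init = 1))
  parameters <- list(list(id = "a", value = 2),
                     list(id = "b", value = 1),
                     list(id = "c", value = 2))
  reactions <- list(
    list(id = "growth", reactants = c(prey = 1), products = c(prey = 2),
         math = mass_action_law("a", "prey")),
    list(id = "predation", reactants = c(prey = 1, predator = 1),
         products = c(predator = 2),
         math = mass_action_law("b", c("prey", "predator"))),
    list(id = "death", reactants = c(predator = 1), products = c(),
         math = mass_action_law("c", "predator")))
  sbml <- build_sbml("lotka_volterra", species, reactions, parameters,
                     annotation_resource = "https://identifiers.org/GO:0008152")
  fixture_archive("lotka_volterra", sbml)
}

## ---- corruption ----------------------------------------------------------

#' Inject exactly one defect of a chosen lint-rule class
#'
#' Takes a lint-clean archive and returns a copy carrying precisely one
#' defect of class `rule_id` (R1, R2, R3, R4, R5, R6, R7, R8 or R10).
#' Deterministic under `seed`.
#'
#' @param archive a lint-clean `omex_archive`.
#' @param rule_id the rule class to inject.
#' @param seed integer (reserved for rules with random placement).
#' @return the corrupted `omex_archive`.
#' @export
corrupt_archive <- function(archive, rule_id, seed = 1L) {
  rule_id <- match.arg(rule_id, paste0("R", c(1:8, 10)))
  sed_entry <- find_sedml_entry(archive)
  sbml_entry <- find_sbml_entries(archive)[[1]]
  doc <- parse_sedml(sed_entry$content)

  put_sed <- function(doc) {
    sed_entry$content <- write_sedml(doc)
    archive_set(archive, sed_entry)
  }

  switch(rule_id,
    R1 = {
      if (identical(doc$models[[1]]$source, "model.xml"))
        stop("R1 inapplicable: source already model.xml", call. = FALSE)
      doc$models[[1]]$source <- "model.xml"
      put_sed(doc)
    },
    R2 = {
      hit <- FALSE
      for (i in seq_along(doc$data_generators)) {
        g <- doc$data_generators[[i]]
        for (j in seq_along(g$variables)) {
          v <- g$variables[[j]]
          if (!is.na(v$target)) {
            doc$data_generators[[i]]$variables[[j]]$target <-
              sub("@id='[^']*'", "@id='ghost_species'", v$target)
            hit <- TRUE; break
          }
        }
        if (hit) break
      }
      if (!hit) stop("R2 inapplicable: no targeted variable", call. = FALSE)
      put_sed(doc)
    },
    R3 = {
      s <- doc$simulations[[1]]
      s$id <- "orphan_sim"
      doc$simulations[[length(doc$simulations) + 1L]] <- s
      put_sed(doc)
    },
    R4 = {
      gi <- NULL
      for (i in seq_along(doc$data_generators))
        if (length(doc$data_generators[[i]]$variables) &&
            !is.na(doc$data_generators[[i]]$variables[[1]]$target)) { gi <- i; break }
      if (is.null(gi)) stop("R4 inapplicable: no species generator", call. = FALSE)
      g <- doc$data_generators[[gi]]
      orig_id <- g$id
      g$id <- paste0(orig_id, "_dup")
      doc$data_generators[[length(doc$data_generators) + 1L]] <- g
      hit <- FALSE
      for (i in seq_along(doc$outputs)) {
        o <- doc$outputs[[i]]
        if (o$kind != "plot2d") next
        for (j in seq_along(o$curves)) {
          if (identical(o$curves[[j]]$y_ref, orig_id)) {
            doc$outputs[[i]]$curves[[j]]$y_ref <- g$id
            hit <- TRUE; break
          }
        }
        if (hit) break
      }
      if (!hit) stop("R4 inapplicable: no curve references the generator",
                     call. = FALSE)
      put_sed(doc)
    },
    R5 = {
      hit <- FALSE
      for (i in seq_along(doc$data_generators)) {
        g <- doc$data_generators[[i]]
        for (j in seq_along(g$variables)) {
          v <- g$variables[[j]]
          if (!is.na(v$target) && grepl("sbml:", v$target, fixed = TRUE)) {
            doc$data_generators[[i]]$variables[[j]]$target <-
              gsub("sbml:", "", v$target, fixed = TRUE)
            hit <- TRUE; break
          }
        }
        if (hit) break
      }
      if (!hit) stop("R5 inapplicable: no prefixed target", call. = FALSE)
      put_sed(doc)
    },
    R6 = {
      si <- NULL
      for (i in seq_along(doc$simulations))
        if (doc$simulations[[i]]$type == "utc") { si <- i; break }
      if (is.null(si)) stop("R6 inapplicable: no time course", call. = FALSE)
      doc$simulations[[si]]$output_start_time <-
        doc$simulations[[si]]$initial_time - 1
      put_sed(doc)
    },
    R7 = {
      si <- NULL
      for (i in seq_along(doc$simulations))
        if (doc$simulations[[i]]$type == "utc") { si <- i; break }
      if (is.null(si)) stop("R7 inapplicable: no time course", call. = FALSE)
      doc$simulations[[si]]$number_of_points <- 2e6
      put_sed(doc)
    },
    R8 = {
      x <- xml2::read_xml(sbml_entry$content)
      xml2::xml_ns_strip(x)
      model <- xml2::xml_find_first(x, "./model")
      lop <- xml2::xml_find_first(model, "./listOfParameters")
      if (inherits(lop, "xml_missing"))
        lop <- xml2::xml_add_child(model, "listOfParameters")
      xml2::xml_add_child(lop, "parameter", id = "unused_nonfinite",
                          value = "INF", constant = "true")
      sbml_entry$content <- charToRaw(as.character(x))
      archive_set(archive, sbml_entry)
    },
    R10 = {
      txt <- rawToChar(sbml_entry$content)
      m <- regmatches(txt, regexpr("https://identifiers\\.org/[A-Za-z0-9.]+:[A-Za-z0-9]+", txt))
      if (!length(m)) stop("R10 inapplicable: no URL-form annotation",
                           call. = FALSE)
      parts <- strsplit(sub("https://identifiers\\.org/", "", m[1]), ":")[[1]]
      ns <- if (grepl("^GO$", parts[1])) "obo.go" else tolower(parts[1])
      urn <- sprintf("urn:miriam:%s:%s", ns,
                     utils::URLencode(paste(parts, collapse = ":"),
                                      reserved = TRUE))
      txt <- sub(m[1], urn, txt, fixed = TRUE)
      sbml_entry$content <- charToRaw(txt)
      archive_set(archive, sbml_entry)
    }
  )
}

find_sedml_entry <- function(archive) {
  for (e in archive$entries) if (format_is_sedml(e$format)) return(e)
  stop("archive has no SED-ML entry", call. = FALSE)
}

find_sbml_entries <- function(archive) {
  Filter(function(e) format_is_sbml(e$format), archive$entries)
}
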