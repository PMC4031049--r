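#' Read a metabolic model
#'
#' Supported dialects:
#' \describe{
#'   \item{\code{tsv-triplet}}{a directory holding \code{reactions.tsv},
#'     \code{metabolites.tsv} and optionally \code{genes.tsv}; the plain-text
#'     dialect this package defines for fixtures (see Details).}
#'   \item{\code{json}}{BiGG-style JSON model.}
#'   \item{\code{sbml-fbc}}{SBML Level 3 with the FBC package (flux bounds,
#'     gene-product associations, biomass objective).}
#' }
#'
#' @details The tsv-triplet dialect: \code{reactions.tsv} has columns
#' \code{id}, \code{stoichiometry} (entries \code{"met:coef"} joined by
#' \code{";"}, negative = consumed), \code{lower_bound}, \code{upper_bound},
#' \code{gpr}, \code{subsystem}, \code{is_exchange}, \code{is_biomass};
#' \code{metabolites.tsv} has \code{id}, \code{name}, \code{compartment},
#' \code{is_external}; \code{genes.tsv} has \code{gene_id}. Bounds are in
#' mmol/(gDW h); GPR strings use \code{and}/\code{or} and parentheses.
#'
#' @param path file (json/sbml) or directory (tsv-triplet).
#' @param format one of \code{"tsv-triplet"}, \code{"json"},
#'   \code{"sbml-fbc"}; default guessed from the path.
#' @return a validated \code{\link{metabolic_model}}.
#' @export
read_model <- function(path, format = c("guess", "tsv-triplet", "json", "sbml-fbc")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (dir.exists(path)) "tsv-triplet"
      else if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
      else "sbml-fbc"
  }
  switch(format,
    "tsv-triplet" = read_model_tsv(path),
    "json" = read_model_json(path),
    "sbml-fbc" = read_model_sbml(path)
  )
}

read_model_tsv <- function(dir) {
  rpath <- file.path(dir, "reactions.tsv")
  mpath <- file.path(dir, "metabolites.tsv")
  if (!file.exists(rpath)) stop("tsv-triplet model: missing ", rpath)
  if (!file.exists(mpath)) stop("tsv-triplet model: missing ", mpath)
  rxn <- utils::read.delim(rpath, stringsAsFactors = FALSE, na.strings = NULL,
                           colClasses = "character")
  met <- utils::read.delim(mpath, stringsAsFactors = FALSE, na.strings = NULL,
                           colClasses = "character")
  need <- c("id", "stoichiometry", "lower_bound", "upper_bound")
  miss <- setdiff(need, names(rxn))
  if (length(miss)) stop("reactions.tsv: missing column ", miss[1])
  stoich <- lapply(rxn$stoichiometry, parse_stoich_string)
  names(stoich) <- rxn$id
  reactions <- data.frame(
    id = rxn$id,
    lower_bound = as.numeric(rxn$lower_bound),
    upper_bound = as.numeric(rxn$upper_bound),
    gpr = if (is.null(rxn$gpr)) "" else rxn$gpr,
    subsystem = if (is.null(rxn$subsystem)) "" else rxn$subsystem,
    is_exchange = parse_bool(if (is.null(rxn$is_exchange)) "FALSE" else rxn$is_exchange),
    is_biomass = parse_bool(if (is.null(rxn$is_biomass)) "FALSE" else rxn$is_biomass),
    stringsAsFactors = FALSE
  )
  metabolites <- data.frame(
    id = met$id,
    name = if (is.null(met$name)) met$id else met$name,
    compartment = if (is.null(met$compartment)) "c" else met$compartment,
    is_external = parse_bool(if (is.null(met$is_external)) "FALSE" else met$is_external),
    stringsAsFactors = FALSE
  )
  metabolic_model(metabolites, reactions, stoich, id = basename(normalizePath(dir)))
}

parse_stoich_string <- function(s) {
  if (!nzchar(trimws(s))) stop("empty stoichiometry string")
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed stoichiometry entry '", parts[bad][1], "'")
  coefs <- as.numeric(vapply(kv, `[[`, character(1), 2L))
  if (anyNA(coefs)) stop("non-numeric stoichiometric coefficient in '", s, "'")
  stats::setNames(coefs, trimws(vapply(kv, `[[`, character(1), 1L)))
}

format_stoich_string <- function(st) {
  paste(sprintf("%s:%.10g", names(st), unname(st)), collapse = ";")
}

parse_bool <- function(x) {
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
}

#' Write a model in the tsv-triplet dialect
#'
#' Round-trips exactly through [read_model()]: stoichiometry, bounds, GPR
#' strings and subsystem labels are preserved verbatim.
#'
#' @param model a \code{metabolic_model}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_model_tsv <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rxn <- model$reactions
  out <- data.frame(
    id = rxn$id,
    stoichiometry = vapply(model$stoichiometry[rxn$id], format_stoich_string,
                           character(1)),
    lower_bound = rxn$lower_bound,
    upper_bound = rxn$upper_bound,
    gpr = rxn$gpr,
    subsystem = rxn$subsystem,
    is_exchange = rxn$is_exchange,
    is_biomass = rxn$is_biomass,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(model$metabolites[, c("id", "name", "compartment", "is_external")],
                     file.path(dir, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = model$genes),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$reactions) || is.null(j$metabolites)) {
    stop("JSON model ", path, ": missing 'reactions' or 'metabolites'")
  }
  metabolites <- data.frame(
    id = vapply(j$metabolites, function(m) m$id, character(1)),
    name = vapply(j$metabolites, function(m) m$name %||% m$id, character(1)),
    compartment = vapply(j$metabolites, function(m) m$compartment %||% "c", character(1)),
    is_external = vapply(j$metabolites, function(m) isTRUE(m$boundary), logical(1)),
    stringsAsFactors = FALSE
  )
  stoich <- lapply(j$reactions, function(r) {
    st <- unlist(r$metabolites)
    if (is.null(st)) stop("JSON model: reaction ", r$id, " has no metabolites")
    st
  })
  ids <- vapply(j$reactions, function(r) r$id, character(1))
  names(stoich) <- ids
  obj <- vapply(j$reactions, function(r) as.numeric(r$objective_coefficient %||% 0),
                numeric(1))
  n_m <- vapply(stoich, length, integer(1))
  reactions <- data.frame(
    id = ids,
    lower_bound = vapply(j$reactions, function(r) as.numeric(r$lower_bound %||% -1000),
                         numeric(1)),
    upper_bound = vapply(j$reactions, function(r) as.numeric(r$upper_bound %||% 1000),
                         numeric(1)),
    gpr = vapply(j$reactions, function(r) r$gene_reaction_rule %||% "", character(1)),
    subsystem = vapply(j$reactions, function(r) r$subsystem %||% "", character(1)),
    is_exchange = (n_m == 1L | grepl("^(R_)?EX_", ids)) & obj == 0,
    is_biomass = obj != 0,
    stringsAsFactors = FALSE
  )
  if (!any(reactions$is_biomass)) {
    stop("JSON model ", path, ": no reaction with a nonzero objective coefficient ",
         "(missing biomass objective)")
  }
  metabolic_model(metabolites, reactions, stoich,
                  id = j$id %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# attribute lookup tolerant of namespace prefixes (fbc:lowerFluxBound etc.)
xml_attr_any <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | grepl(paste0(":", name, "$"), names(at)))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path) # namespace-agnostic local-name() XPath below
  sbml_model <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  if (inherits(sbml_model, "xml_missing")) stop("SBML file ", path, ": no <model> element")

  params <- xml2::xml_find_all(doc, "//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  species <- xml2::xml_find_all(doc, "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(species) == 0L) stop("SBML file ", path, ": no species")
  metabolites <- data.frame(
    id = xml2::xml_attr(species, "id"),
    name = ifelse(is.na(xml2::xml_attr(species, "name")),
                  xml2::xml_attr(species, "id"), xml2::xml_attr(species, "name")),
    compartment = ifelse(is.na(xml2::xml_attr(species, "compartment")), "c",
                         xml2::xml_attr(species, "compartment")),
    is_external = !is.na(xml2::xml_attr(species, "boundaryCondition")) &
      tolower(xml2::xml_attr(species, "boundaryCondition")) == "true",
    stringsAsFactors = FALSE
  )

  gp <- xml2::xml_find_all(doc, "//*[local-name()='geneProduct']")
  gp_label <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gp, "label")), xml2::xml_attr(gp, "id"),
           xml2::xml_attr(gp, "label")),
    xml2::xml_attr(gp, "id"))

  gpa_to_string <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml_attr_any(node, "geneProduct")
      return(if (!is.na(ref) && ref %in% names(gp_label)) gp_label[[ref]] else ref)
    }
    kids <- xml2::xml_children(node)
    inner <- vapply(kids, gpa_to_string, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(inner, collapse = op), ")")
  }

  obj_refs <- xml2::xml_find_all(doc, "//*[local-name()='fluxObjective']")
  biomass <- character(0)
  if (length(obj_refs)) {
    coef <- as.numeric(vapply(obj_refs, xml_attr_any, character(1), "coefficient"))
    rid <- vapply(obj_refs, xml_attr_any, character(1), "reaction")
    biomass <- rid[!is.na(coef) & coef != 0]
  }

  rnodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rnodes) == 0L) stop("SBML file ", path, ": no reactions")
  ids <- xml2::xml_attr(rnodes, "id")
  stoich <- vector("list", length(rnodes))
  lbs <- ubs <- numeric(length(rnodes))
  gprs <- subs <- character(length(rnodes))
  for (k in seq_along(rnodes)) {
    rn <- rnodes[[k]]
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rn, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")) {
      s <- xml2::xml_attr(sr, "species")
      co <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (is.na(co)) co <- 1
      st[s] <- (if (s %in% names(st)) st[[s]] else 0) - co
    }
    for (sr in xml2::xml_find_all(rn, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")) {
      s <- xml2::xml_attr(sr, "species")
      co <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (is.na(co)) co <- 1
      st[s] <- (if (s %in% names(st)) st[[s]] else 0) + co
    }
    if (length(st) == 0L) stop("SBML reaction ", ids[k], ": no participants")
    stoich[[k]] <- st
    lref <- xml_attr_any(rn, "lowerFluxBound")
    uref <- xml_attr_any(rn, "upperFluxBound")
    rev <- isTRUE(tolower(xml2::xml_attr(rn, "reversible")) == "true")
    lbs[k] <- if (!is.na(lref) && lref %in% names(pval)) pval[[lref]]
      else if (rev) -1000 else 0
    ubs[k] <- if (!is.na(uref) && uref %in% names(pval)) pval[[uref]] else 1000
    gpa <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    gprs[k] <- if (inherits(gpa, "xml_missing")) "" else {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) gpa_to_string(kids[[1]]) else ""
    }
    subs[k] <- ""
  }
  names(stoich) <- ids
  internal_per_rxn <- vapply(stoich, function(st) {
    sum(!metabolites$is_external[match(names(st), metabolites$id)])
  }, integer(1))
  reactions <- data.frame(
    id = ids, lower_bound = lbs, upper_bound = ubs, gpr = gprs, subsystem = subs,
    is_exchange = internal_per_rxn == 1L &
      (vapply(stoich, length, integer(1)) == 1L | grepl("^(R_)?EX_", ids)) &
      !(ids %in% biomass),
    is_biomass = ids %in% biomass,
    stringsAsFactors = FALSE
  )
  if (!any(reactions$is_biomass)) {
    stop("SBML model ", path, ": no active FBC objective (missing biomass reaction)")
  }
  # drop boundary species rows from exchanges written with explicit boundary mets
  metabolic_model(metabolites, reactions, stoich,
                  id = xml2::xml_attr(sbml_model, "id") %||% basename(path))
}

#' Read a medium (or media panel) from TSV
#'
#' Expected columns: \code{exchange_reaction_id}, \code{lower_bound};
#' optional \code{medium_label} (long format: one medium per label),
#' \code{is_salt} and \code{varied_element} (used by the media-panel
#' machinery).
#'
#' @param path TSV file.
#' @return a single \code{\link{medium}} if at most one label is present,
#'   otherwise a named list of media.
#' @export
read_medium_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("exchange_reaction_id", "lower_bound")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("medium file ", path, ": missing column ", miss[1])
  mk <- function(dd, label) {
    m <- medium(stats::setNames(as.numeric(dd$lower_bound), dd$exchange_reaction_id),
                label = label)
    if (!is.null(dd$is_salt)) attr(m, "is_salt") <-
        stats::setNames(parse_bool(dd$is_salt), dd$exchange_reaction_id)
    m
  }
  if (is.null(d$medium_label) || length(unique(d$medium_label)) <= 1L) {
    lab <- if (is.null(d$medium_label)) sub("\\.tsv$", "", basename(path))
      else d$medium_label[1]
    return(mk(d, lab))
  }
  labs <- unique(d$medium_label)
  stats::setNames(lapply(labs, function(l) mk(d[d$medium_label == l, ], l)), labs)
}

#' Write media to a long-format TSV
#' @param media a \code{medium} or list of media.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_media_tsv <- function(media, path) {
  if (inherits(media, "medium")) media <- list(media)
  rows <- do.call(rbind, lapply(media, function(m) {
    if (length(m$uptake_bounds) == 0L) return(NULL)
    data.frame(medium_label = m$label,
               exchange_reaction_id = names(m$uptake_bounds),
               lower_bound = unname(m$uptake_bounds),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-essentiality annotation from TSV
#'
#' Expected columns: \code{gene_id}, \code{status} with values
#' \code{essential}, \code{nonessential} or \code{unknown}.
#'
#' @param path TSV file.
#' @param unknown_policy passed to [essentiality_annotation()].
#' @return an \code{essentiality_annotation}.
#' @export
read_essentiality_tsv <- function(path, unknown_policy = "nonessential") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "status"), names(d))
  if (length(miss)) stop("essentiality file ", path, ": missing column ", miss[1])
  essentiality_annotation(stats::setNames(d$status, d$gene_id),
                          source = basename(path), unknown_policy = unknown_policy)
}
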