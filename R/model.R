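#' Construct a metabolic model
#'
#' The central container of the package: a stoichiometric network with flux
#' bounds, GPR rules, pathway (subsystem) labels and a single biomass
#' objective. Exchange reactions import/export a boundary metabolite; by
#' convention a negative flux through an exchange written \code{met <-> 0}
#' is uptake, matching the usual \code{-10 mmol/(gDW h)} bound notation.
#'
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{is_external}. Missing optional columns are
#'   filled with defaults.
#' @param reactions data.frame with columns \code{id}, \code{lower_bound},
#'   \code{upper_bound}, \code{gpr} (string), \code{subsystem},
#'   \code{is_exchange}, \code{is_biomass}.
#' @param stoichiometry named list (by reaction id) of named numeric vectors
#'   (by metabolite id); negative coefficients are consumed.
#' @param id model identifier string.
#' @return object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry, id = "model") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(metabolites$is_external)) metabolites$is_external <- FALSE
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""
  gpr_trees <- lapply(reactions$gpr, parse_gpr)
  names(gpr_trees) <- reactions$id
  model <- structure(list(
    id = id,
    metabolites = metabolites,
    reactions = reactions,
    stoichiometry = stoichiometry[reactions$id],
    gpr = gpr_trees,
    genes = sort(unique(unlist(lapply(gpr_trees, `[[`, "genes"))))
  ), class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks structural invariants: unique identifiers, consistent bounds,
#' exactly one biomass reaction, exchange reactions touching exactly one
#' metabolite, and all stoichiometry references resolvable.
#'
#' @param model a \code{metabolic_model}.
#' @return the model, invisibly; errors describe the offending element.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met <- model$metabolites; rxn <- model$reactions
  if (anyDuplicated(met$id)) {
    stop("duplicate metabolite id: ", met$id[duplicated(met$id)][1])
  }
  if (anyDuplicated(rxn$id)) {
    stop("duplicate reaction id: ", rxn$id[duplicated(rxn$id)][1])
  }
  if (any(rxn$lower_bound > rxn$upper_bound)) {
    bad <- rxn$id[rxn$lower_bound > rxn$upper_bound][1]
    stop("reaction ", bad, ": lower_bound exceeds upper_bound")
  }
  nb <- sum(rxn$is_biomass)
  if (nb != 1L) stop("model must have exactly one biomass reaction, found ", nb)
  for (r in rxn$id) {
    st <- model$stoichiometry[[r]]
    if (is.null(st) || length(st) == 0L) stop("reaction ", r, ": empty stoichiometry")
    miss <- setdiff(names(st), met$id)
    if (length(miss)) stop("reaction ", r, ": unknown metabolite ", miss[1])
    if (rxn$is_exchange[rxn$id == r]) {
      internal <- names(st)[!met$is_external[match(names(st), met$id)]]
      if (length(internal) != 1L) {
        stop("exchange reaction ", r, " must touch exactly one internal metabolite")
      }
    }
  }
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' Rows are internal (balanced) metabolites, columns are reactions; external
#' boundary metabolites are excluded from the steady-state balance.
#'
#' @param model a \code{metabolic_model}.
#' @return dense numeric matrix with dimnames.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id[!model$metabolites$is_external]
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$stoichiometry[[rxns[j]]]
    keep <- names(st) %in% mets
    if (any(keep)) S[names(st)[keep], j] <- st[keep]
  }
  S
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      " (", sum(!x$metabolites$is_external), " internal)\n",
      "  reactions:   ", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), " exchange)\n",
      "  genes:       ", length(x$genes), "\n",
      "  biomass:     ", biomass_id(x), "\n", sep = "")
  invisible(x)
}

#' Identifier of the biomass reaction
#' @param model a \code{metabolic_model}.
#' @return reaction id string.
#' @export
biomass_id <- function(model) {
  model$reactions$id[model$reactions$is_biomass][1]
}

#' Exchange reaction identifiers
#' @param model a \code{metabolic_model}.
#' @return character vector.
#' @export
exchange_ids <- function(model) {
  model$reactions$id[model$reactions$is_exchange]
}

#' Delete reactions from a model (knockout)
#'
#' A knockout zeroes both flux bounds of the reaction, removing the forward
#' and reverse direction together. The reaction stays in the network so that
#' indices and graphs are unaffected.
#'
#' @param model a \code{metabolic_model}.
#' @param rxns character vector of reaction ids.
#' @return modified model.
#' @export
knockout <- function(model, rxns) {
  miss <- setdiff(rxns, model$reactions$id)
  if (length(miss)) stop("unknown reaction id: ", miss[1])
  i <- model$reactions$id %in% rxns
  model$reactions$lower_bound[i] <- 0
  model$reactions$upper_bound[i] <- 0
  model
}

#' Construct a growth medium
#'
#' A medium assigns lower bounds to exchange reactions: a negative bound
#' allows uptake of the corresponding metabolite at up to that rate
#' (mmol/(gDW h)). Exchanges not listed default to zero uptake when the
#' medium is applied; secretion stays allowed.
#'
#' @param uptake_bounds named numeric vector, names are exchange reaction ids.
#' @param label medium label string.
#' @return object of class \code{medium}.
#' @export
medium <- function(uptake_bounds = numeric(0), label = "medium") {
  stopifnot(is.numeric(uptake_bounds))
  if (length(uptake_bounds) && is.null(names(uptake_bounds))) {
    stop("uptake_bounds must be named by exchange reaction id")
  }
  structure(list(uptake_bounds = uptake_bounds, label = label), class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat("<medium> ", x$label, ": ", length(x$uptake_bounds), " exchange bounds\n", sep = "")
  invisible(x)
}

#' Apply a medium to a model
#'
#' Overwrites exchange lower bounds with the medium's assignments; every
#' exchange absent from the medium gets lower bound zero (uptake closed,
#' secretion still allowed). Non-exchange bounds are untouched. Applying the
#' same medium twice equals applying it once.
#'
#' @param model a \code{metabolic_model}.
#' @param medium a \code{medium}.
#' @return modified copy of the model; the medium label is recorded in
#'   \code{model$medium_label}.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(model, "metabolic_model"), inherits(medium, "medium"))
  ex <- exchange_ids(model)
  bad <- setdiff(names(medium$uptake_bounds), ex)
  if (length(bad)) {
    stop("medium key '", bad[1], "' is not an exchange reaction of the model")
  }
  i <- model$reactions$id %in% ex
  model$reactions$lower_bound[i] <- 0
  if (length(medium$uptake_bounds)) {
    j <- match(names(medium$uptake_bounds), model$reactions$id)
    model$reactions$lower_bound[j] <- unname(medium$uptake_bounds)
    # an uptake bound above a closed upper bound would invert the interval
    model$reactions$upper_bound[j] <- pmax(model$reactions$upper_bound[j], 0)
  }
  model$medium_label <- medium$label
  model
}

#' Restrict the candidate space to gene-associated reactions
#'
#' Spontaneous reactions and reactions with no known gene association are
#' discarded as knockout candidates. They are \emph{not} deleted from the
#' network -- their fluxes must remain available to carry metabolism -- unless
#' \code{drop = TRUE}, which reproduces the harsher reading where such
#' reactions are removed outright.
#'
#' @param model a \code{metabolic_model}.
#' @param drop if \code{TRUE}, removed reactions are also deleted from the
#'   network (bounds zeroed). Default \code{FALSE}.
#' @return list with \code{model} (annotated, see \code{gene_associated}
#'   attribute on its reactions) and \code{removed} (ids of non-exchange,
#'   non-biomass reactions lacking a GPR).
#' @export
filter_gene_associated <- function(model, drop = FALSE) {
  has_gpr <- vapply(model$gpr, function(g) !is.null(g$expression), logical(1))
  removable <- !has_gpr & !model$reactions$is_exchange & !model$reactions$is_biomass
  removed <- model$reactions$id[removable]
  model$reactions$gene_associated <- has_gpr & !model$reactions$is_exchange &
    !model$reactions$is_biomass
  if (drop && length(removed)) model <- knockout(model, removed)
  list(model = model, removed = removed)
}

#' Gene essentiality annotation
#'
#' @param status named character vector over gene ids with values
#'   \code{"essential"}, \code{"nonessential"} or \code{"unknown"}.
#' @param source free-text provenance label.
#' @param unknown_policy how to resolve genes that are absent or annotated
#'   \code{"unknown"}: \code{"nonessential"} (default, the usual convention
#'   for genes absent from a transposon study) or \code{"strict"} (error).
#' @return object of class \code{essentiality_annotation}.
#' @export
essentiality_annotation <- function(status = character(0), source = "",
                                    unknown_policy = c("nonessential", "strict")) {
  unknown_policy <- match.arg(unknown_policy)
  if (length(status)) {
    stopifnot(!is.null(names(status)))
    ok <- status %in% c("essential", "nonessential", "unknown")
    if (!all(ok)) stop("invalid essentiality status: ", status[!ok][1])
  }
  structure(list(status = status, source = source, unknown_policy = unknown_policy),
            class = "essentiality_annotation")
}

#' Resolve essentiality of genes under the configured policy
#' @param ann an \code{essentiality_annotation}.
#' @param genes character vector of gene ids.
#' @return logical vector: TRUE = essential.
#' @export
is_gene_essential <- function(ann, genes) {
  stopifnot(inherits(ann, "essentiality_annotation"))
  st <- ann$status[genes]
  unknown <- is.na(st) | st == "unknown"
  if (any(unknown) && ann$unknown_policy == "strict") {
    stop("gene(s) without essentiality annotation under strict policy: ",
         paste(genes[unknown], collapse = ", "))
  }
  unname(!is.na(st) & st == "essential")
}
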