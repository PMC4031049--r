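#' Bipartite metabolite-reaction graph
#'
#' Metabolism as a bipartite directed network: a directed edge runs from a
#' metabolite to every reaction consuming it and from a reaction to every
#' metabolite it produces. Reversible reactions contribute edges in both
#' orientations (their reverse direction consumes products and produces
#' substrates). No currency-metabolite pruning happens by default -- hub
#' metabolites can be excluded explicitly, which is recorded in the graph's
#' \code{excluded} attribute since it shortcuts path lengths.
#'
#' @param model a \code{metabolic_model}.
#' @param exclude_metabolites optional character vector of metabolite ids to
#'   leave out of the graph (currency metabolites such as ATP or water).
#' @return an \pkg{igraph} directed graph; vertex attribute \code{type} is
#'   \code{"metabolite"} or \code{"reaction"}.
#' @export
build_bipartite_graph <- function(model, exclude_metabolites = character(0)) {
  mets <- setdiff(model$metabolites$id, exclude_metabolites)
  rxns <- model$reactions$id
  from <- character(0); to <- character(0)
  for (j in seq_along(rxns)) {
    r <- rxns[j]
    st <- model$stoichiometry[[r]]
    st <- st[names(st) %in% mets]
    if (length(st) == 0L) next
    consumed <- names(st)[st < 0]
    produced <- names(st)[st > 0]
    from <- c(from, consumed, rep(r, length(produced)))
    to <- c(to, rep(r, length(consumed)), produced)
    if (model$reactions$lower_bound[j] < 0) { # reversible: both orientations
      from <- c(from, produced, rep(r, length(consumed)))
      to <- c(to, rep(r, length(produced)), consumed)
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = c(mets, rxns),
                          type = c(rep("metabolite", length(mets)),
                                   rep("reaction", length(rxns))),
                          stringsAsFactors = FALSE))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
  igraph::graph_attr(g, "excluded") <- exclude_metabolites
  g
}

#' Network distance between two reactions
#'
#' The topological distance between reactions in the bipartite graph,
#' counted as the minimal number of intermediate nodes (metabolites and
#' reactions, endpoints excluded) visited along a directed path. Two
#' reactions coupled through a single shared metabolite (product of one,
#' substrate of the other) are at distance 1. The reported pair distance is
#' symmetrized as \code{min(d(r1 -> r2), d(r2 -> r1))}; unreachable pairs
#' are at \code{Inf}, and a reaction is at distance 0 from itself.
#'
#' @param graph bipartite graph from [build_bipartite_graph()].
#' @param r1,r2 reaction ids.
#' @param symmetric take the minimum over both orientations (default); with
#'   \code{FALSE} only the directed distance \code{r1 -> r2} is reported.
#' @return nonnegative number (possibly \code{Inf}).
#' @export
reaction_distance <- function(graph, r1, r2, symmetric = TRUE) {
  vnames <- igraph::V(graph)$name
  if (!(r1 %in% vnames)) stop("unknown reaction id: ", r1)
  if (!(r2 %in% vnames)) stop("unknown reaction id: ", r2)
  if (r1 == r2) return(0)
  d <- igraph::distances(graph, v = r1, to = r2, mode = "out")[1, 1]
  if (symmetric) {
    d <- min(d, igraph::distances(graph, v = r2, to = r1, mode = "out")[1, 1])
  }
  # d is an edge count; intermediate nodes = edges - 1
  if (is.infinite(d)) Inf else d - 1
}

#' Mean network distance of synthetic lethal pairs, per subtype
#'
#' Arithmetic mean of the finite pair distances per subtype, plus the
#' fraction of pairs directly connected through a common metabolite
#' (distance 1).
#'
#' @param pairs classified \code{sl_pairs} table.
#' @param graph bipartite graph of the same model.
#' @return data.frame with columns \code{subtype}, \code{n_pairs},
#'   \code{n_finite}, \code{mean_distance} (NA when no finite distance),
#'   \code{fraction_direct}; the per-pair distances are attached as
#'   \code{attr(, "distances")}.
#' @export
mean_pair_distance <- function(pairs, graph) {
  d <- vapply(seq_len(nrow(pairs)), function(k) {
    reaction_distance(graph, pairs$rxn_a[k], pairs$rxn_b[k])
  }, numeric(1))
  per <- do.call(rbind, lapply(sort(unique(pairs$subtype)), function(s) {
    ds <- d[pairs$subtype == s]
    fin <- ds[is.finite(ds)]
    data.frame(subtype = s, n_pairs = length(ds), n_finite = length(fin),
               mean_distance = if (length(fin)) mean(fin) else NA_real_,
               fraction_direct = if (length(ds)) mean(ds == 1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  attr(per, "distances") <- data.frame(rxn_a = pairs$rxn_a, rxn_b = pairs$rxn_b,
                                       subtype = pairs$subtype, distance = d,
                                       stringsAsFactors = FALSE)
  per
}

#' Pathway entanglement graph
#'
#' Pathway-level summary of synthetic lethality: nodes are pathway
#' (subsystem) labels; every PSL pair adds weight 1 to a \emph{directed}
#' edge from the backup reaction's pathway to the active reaction's pathway,
#' and every RSL pair adds weight 1 to an \emph{undirected} edge between its
#' two pathways. Pairs within one pathway create self-loops. Inconsistent
#' subtypes (\code{PSL_I}/\code{RSL_I}) are aggregated with their base
#' subtype unless \code{drop_inconsistent} is set. Reactions without a
#' pathway label are bucketed as \code{"unannotated"}.
#'
#' @param pairs classified \code{sl_pairs} table.
#' @param drop_inconsistent exclude \code{*_I} pairs (default FALSE).
#' @return list of class \code{entanglement_graph} with \code{edges}
#'   (data.frame \code{source_pathway}, \code{target_pathway},
#'   \code{subtype}, \code{weight}, \code{directed}) and \code{graph}
#'   (an \pkg{igraph} object with the same edge attributes).
#' @export
entanglement_graph <- function(pairs, drop_inconsistent = FALSE) {
  if (drop_inconsistent) pairs <- pairs[!grepl("_I$", pairs$subtype), ]
  lab <- function(x) ifelse(is.na(x) | !nzchar(x), "unannotated", x)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    base <- sub("_I$", "", pairs$subtype[k])
    if (base == "PSL") {
      act <- pairs$active_reaction[k]
      pa <- lab(if (identical(act, pairs$rxn_a[k])) pairs$pathway_a[k] else pairs$pathway_b[k])
      pb <- lab(if (identical(act, pairs$rxn_a[k])) pairs$pathway_b[k] else pairs$pathway_a[k])
      rows[[length(rows) + 1L]] <- data.frame(
        source_pathway = pb, target_pathway = pa, subtype = "PSL",
        directed = TRUE, stringsAsFactors = FALSE) # backup -> active
    } else {
      ps <- sort(c(lab(pairs$pathway_a[k]), lab(pairs$pathway_b[k])))
      rows[[length(rows) + 1L]] <- data.frame(
        source_pathway = ps[1], target_pathway = ps[2], subtype = "RSL",
        directed = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) {
    e <- do.call(rbind, rows)
    agg <- stats::aggregate(list(weight = rep(1L, nrow(e))),
                            e[, c("source_pathway", "target_pathway",
                                  "subtype", "directed")], FUN = sum)
    agg <- agg[order(agg$subtype, agg$source_pathway, agg$target_pathway), ]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(source_pathway = character(0), target_pathway = character(0),
                      subtype = character(0), directed = logical(0),
                      weight = integer(0), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    agg[, c("source_pathway", "target_pathway", "subtype", "directed", "weight")],
    directed = TRUE,
    vertices = unique(c(agg$source_pathway, agg$target_pathway)))
  structure(list(edges = agg, graph = g), class = "entanglement_graph")
}

#' @export
print.entanglement_graph <- function(x, ...) {
  cat("<entanglement_graph> ", nrow(x$edges), " edges, ",
      sum(x$edges$weight), " pairs\n", sep = "")
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' Export an entanglement graph
#' @param x an \code{entanglement_graph}.
#' @param path output file; format by extension (\code{.graphml} or
#'   \code{.tsv}).
#' @return \code{path}, invisibly.
#' @export
write_entanglement <- function(x, path) {
  stopifnot(inherits(x, "entanglement_graph"))
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(x$graph, path, format = "graphml")
  } else {
    utils::write.table(x$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Intra- vs inter-pathway pair counts per subtype
#'
#' @param pairs classified \code{sl_pairs} table.
#' @return data.frame with columns \code{subtype}, \code{intra}, \code{inter}.
#' @export
intra_inter_counts <- function(pairs) {
  lab <- function(x) ifelse(is.na(x) | !nzchar(x), "unannotated", x)
  same <- lab(pairs$pathway_a) == lab(pairs$pathway_b)
  do.call(rbind, lapply(sort(unique(pairs$subtype)), function(s) {
    i <- pairs$subtype == s
    data.frame(subtype = s, intra = sum(same & i), inter = sum(!same & i),
               stringsAsFactors = FALSE)
  }))
}
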