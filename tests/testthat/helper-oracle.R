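# Independent oracles for the pipeline, deliberately separate code paths
# from the package:
#
# * pyoracle.py (same directory) re-implements the whole screen -- wild-type
#   growth, essentials, candidate construction, exhaustive pair enumeration
#   and subtype calls -- in Python on scipy's HiGHS solver, reading the
#   tsv-triplet fixture files straight from disk. run_py_oracle() drives it.
# * the functions below rebuild the bipartite graph from the fixture files
#   with plain read.delim and compute shortest paths by hand-rolled BFS,
#   independent of igraph.

run_py_oracle <- function(fixture_parent_dir) {
  script <- testthat::test_path("pyoracle.py")
  stopifnot(file.exists(script))
  if (Sys.which("python") == "") {
    stop("python interpreter not found; the oracle needs python + scipy")
  }
  out <- tempfile(fileext = ".json")
  code <- system2("python", c(shQuote(script), shQuote(fixture_parent_dir),
                              shQuote(out)), stdout = "", stderr = "")
  stopifnot(code == 0, file.exists(out))
  jsonlite::read_json(out, simplifyVector = FALSE)
}

oracle_read <- function(dir) {
  rx <- utils::read.delim(file.path(dir, "reactions.tsv"),
                          colClasses = "character", na.strings = NULL)
  met <- utils::read.delim(file.path(dir, "metabolites.tsv"),
                           colClasses = "character", na.strings = NULL)
  truthy <- function(x) tolower(x) %in% c("true", "t", "1", "yes")
  internal <- met$id[!truthy(met$is_external)]
  ids <- rx$id
  S <- matrix(0, length(internal), length(ids),
              dimnames = list(internal, ids))
  for (j in seq_along(ids)) {
    for (kv in strsplit(rx$stoichiometry[j], ";", fixed = TRUE)[[1]]) {
      p <- strsplit(kv, ":", fixed = TRUE)[[1]]
      if (p[1] %in% internal) S[p[1], j] <- as.numeric(p[2])
    }
  }
  list(S = S, lb = as.numeric(rx$lower_bound), ub = as.numeric(rx$upper_bound),
       ids = ids, gpr = rx$gpr, is_ex = truthy(rx$is_exchange),
       is_bm = truthy(rx$is_biomass))
}

# edges built straight from the stoichiometry columns; distances counted in
# edges, intermediate nodes = edges - 1
oracle_edges <- function(om) {
  from <- character(0); to <- character(0)
  for (j in seq_along(om$ids)) {
    r <- om$ids[j]
    col <- om$S[, j]
    cons <- rownames(om$S)[col < 0]
    prod <- rownames(om$S)[col > 0]
    from <- c(from, cons, rep(r, length(prod)))
    to <- c(to, rep(r, length(cons)), prod)
    if (om$lb[j] < 0) {
      from <- c(from, prod, rep(r, length(cons)))
      to <- c(to, rep(r, length(prod)), cons)
    }
  }
  unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
}

oracle_bfs <- function(edges, src, dst) {
  if (src == dst) return(0)
  dist <- stats::setNames(0, src)
  queue <- src
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in edges$to[edges$from == v]) {
      if (w %in% names(dist)) next
      dist[[w]] <- dist[[v]] + 1
      if (w == dst) return(dist[[w]])
      queue <- c(queue, w)
    }
  }
  Inf
}

oracle_reaction_distance <- function(om, r1, r2) {
  if (r1 == r2) return(0)
  e <- oracle_edges(om)
  d <- min(oracle_bfs(e, r1, r2), oracle_bfs(e, r2, r1))
  if (is.infinite(d)) Inf else d - 1
}

# write a fixture's model (with medium already applied) to a temp dir in the
# tsv-triplet dialect so the oracles can read it file-first
oracle_dir_for <- function(fx) {
  d <- tempfile("oracle_fx_")
  write_model_tsv(fx$model, d)
  d
}
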