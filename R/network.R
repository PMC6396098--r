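#' Default heterogeneous-network schema
#'
#' The eleven association layers joining the five node types. Each layer
#' names the (unordered) pair of node types its edges may join: five
#' within-type similarity/interaction layers (herb-herb, symptom-symptom,
#' disease-disease, drug-drug, protein-protein) and six cross-type
#' association layers (herb-symptom, herb-disease, disease-symptom,
#' drug-symptom, drug-disease, drug-protein). Known herb-target
#' interactions are the supervised label set, not a network layer.
#'
#' @return Named list mapping layer name to a length-2 character vector of
#'   endpoint node types.
#' @export
hti_schema <- function() {
  list(
    herb_herb       = c("herb", "herb"),
    symptom_symptom = c("symptom", "symptom"),
    disease_disease = c("disease", "disease"),
    drug_drug       = c("drug", "drug"),
    protein_protein = c("protein", "protein"),
    herb_symptom    = c("herb", "symptom"),
    herb_disease    = c("herb", "disease"),
    disease_symptom = c("disease", "symptom"),
    drug_symptom    = c("drug", "symptom"),
    drug_disease    = c("drug", "disease"),
    drug_protein    = c("drug", "protein")
  )
}

node_types <- c("herb", "symptom", "disease", "drug", "protein")

# Namespace a raw id by its node type ("herb:x"). Ids already carrying the
# correct prefix are left alone, so round-trips are stable.
namespace_id <- function(id, type) {
  pref <- paste0(type, ":")
  ifelse(startsWith(id, pref), id, paste0(pref, id))
}

#' Node type of a namespaced node id
#' @param id character vector of namespaced node ids (e.g. `"herb:h1"`).
#' @return character vector of node types.
#' @export
node_type <- function(id) {
  sub(":.*$", "", id)
}

#' Construct a validated heterogeneous network
#'
#' Builds the typed, weighted, undirected multi-layer graph from an edge
#' table. Edges are undirected and stored once per (unordered pair, layer);
#' duplicate symmetric rows are collapsed (keeping the maximum weight).
#' Self-loops are dropped with a warning. Node ids are namespaced by type
#' to keep vocabularies from colliding.
#'
#' For random walks, parallel edges between the same pair in different
#' layers are collapsed to a single adjacency entry whose weight is the
#' maximum over layers.
#'
#' @param edges data.frame with columns `source`, `target`, `layer` and
#'   optionally `weight` (defaults to 1). Ids may be raw (namespaced here
#'   using the layer's endpoint types) or already namespaced.
#' @param schema named list mapping layer names to endpoint-type pairs;
#'   defaults to [hti_schema()].
#' @param extra_nodes optional data.frame with columns `id`, `type` for
#'   isolated nodes that carry no edges.
#' @return An object of class `hti_network` with elements `nodes`
#'   (data.frame `id`, `type`), `edges` (data.frame `u`, `v`, `layer`,
#'   `weight`, with `u < v`), `schema`, and `graph` (the collapsed weighted
#'   [igraph::graph] used for walking and propagation).
#' @export
hti_network <- function(edges, schema = hti_schema(), extra_nodes = NULL) {
  stopifnot(is.list(schema), length(schema) > 0)
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(source = character(), target = character(),
                        layer = character(), weight = numeric())
  }
  if (!all(c("source", "target", "layer") %in% names(edges))) {
    stop("edges must have columns source, target, layer")
  }
  if (is.null(edges$weight)) edges$weight <- rep(1.0, nrow(edges))
  edges$weight[is.na(edges$weight)] <- 1.0

  unknown <- setdiff(unique(edges$layer), names(schema))
  if (length(unknown) > 0) {
    stop("unknown layer name(s): ", paste(unknown, collapse = ", "))
  }
  bad_w <- !is.finite(edges$weight) | edges$weight <= 0 | edges$weight > 1
  if (any(bad_w)) {
    stop("edge weights must be finite and in (0, 1]; ",
         sum(bad_w), " offending row(s)")
  }

  if (nrow(edges) > 0) {
    tpair <- do.call(rbind, lapply(schema[edges$layer], function(x) x[1:2]))
    src <- as.character(edges$source)
    tgt <- as.character(edges$target)
    ta <- tpair[, 1]; tb <- tpair[, 2]
    # Endpoint types per row. Rows may list endpoints in either order;
    # prefixed ids ("symptom:s1") are authoritative, raw ids are resolved
    # to a consistent type across rows where possible, falling back to the
    # layer-name order (source = first endpoint type).
    pref_s <- node_type(src); pref_s[!(pref_s %in% node_types)] <- NA
    pref_t <- node_type(tgt); pref_t[!(pref_t %in% node_types)] <- NA
    known <- new.env(parent = emptyenv())
    for (i in seq_along(src)) {
      if (!is.na(pref_s[i])) assign(src[i], pref_s[i], envir = known)
      if (!is.na(pref_t[i])) assign(tgt[i], pref_t[i], envir = known)
    }
    res_s <- pref_s; res_t <- pref_t
    unresolved <- which(is.na(res_s) | is.na(res_t))
    repeat {
      progressed <- FALSE
      still <- integer()
      for (i in unresolved) {
        st <- if (!is.na(res_s[i])) res_s[i]
              else get0(src[i], envir = known, ifnotfound = NA)
        tt <- if (!is.na(res_t[i])) res_t[i]
              else get0(tgt[i], envir = known, ifnotfound = NA)
        ok_fwd <- (is.na(st) || st == ta[i]) && (is.na(tt) || tt == tb[i])
        ok_rev <- (is.na(st) || st == tb[i]) && (is.na(tt) || tt == ta[i])
        if (!ok_fwd && !ok_rev) {
          stop("endpoint type mismatch for layer '", edges$layer[i], "': ",
               src[i], " -- ", tgt[i])
        }
        if (ok_fwd && ok_rev && (is.na(st) || is.na(tt)) && ta[i] != tb[i]) {
          still <- c(still, i)  # genuinely ambiguous so far
          next
        }
        fwd <- ok_fwd
        res_s[i] <- if (fwd) ta[i] else tb[i]
        res_t[i] <- if (fwd) tb[i] else ta[i]
        if (is.na(get0(src[i], envir = known, ifnotfound = NA))) {
          assign(src[i], res_s[i], envir = known); progressed <- TRUE
        }
        if (is.na(get0(tgt[i], envir = known, ifnotfound = NA))) {
          assign(tgt[i], res_t[i], envir = known); progressed <- TRUE
        }
        progressed <- TRUE
      }
      unresolved <- still
      if (length(unresolved) == 0) break
      if (!progressed) {
        # break the tie for one row using layer-name order, then let the
        # assignment propagate to the remaining ambiguous rows
        i <- unresolved[1]
        res_s[i] <- ta[i]; res_t[i] <- tb[i]
        if (is.na(get0(src[i], envir = known, ifnotfound = NA))) {
          assign(src[i], ta[i], envir = known)
        }
        if (is.na(get0(tgt[i], envir = known, ifnotfound = NA))) {
          assign(tgt[i], tb[i], envir = known)
        }
        unresolved <- unresolved[-1]
        if (length(unresolved) == 0) break
      }
    }
    bad <- !((res_s == ta & res_t == tb) | (res_s == tb & res_t == ta))
    if (any(bad)) {
      i <- which(bad)[1]
      stop("endpoint type mismatch for layer '", edges$layer[i], "': ",
           src[i], " -- ", tgt[i])
    }
    u <- namespace_id(src, res_s)
    v <- namespace_id(tgt, res_t)

    loops <- u == v
    if (any(loops)) {
      warning("dropping ", sum(loops), " self-loop edge(s)")
      u <- u[!loops]; v <- v[!loops]
      edges <- edges[!loops, , drop = FALSE]
    }
    # canonical orientation u < v within the unordered pair
    flip <- u > v
    tmp <- u[flip]; u[flip] <- v[flip]; v[flip] <- tmp
    ed <- data.frame(u = u, v = v, layer = edges$layer,
                     weight = edges$weight, stringsAsFactors = FALSE)
    # collapse duplicate rows within a layer, keeping the max weight
    key <- paste(ed$u, ed$v, ed$layer, sep = "\r")
    if (anyDuplicated(key)) {
      w <- tapply(ed$weight, key, max)
      ed <- ed[!duplicated(key), , drop = FALSE]
      ed$weight <- as.numeric(w[paste(ed$u, ed$v, ed$layer, sep = "\r")])
    }
    ed <- ed[order(ed$layer, ed$u, ed$v), , drop = FALSE]
    rownames(ed) <- NULL
  } else {
    ed <- data.frame(u = character(), v = character(),
                     layer = character(), weight = numeric())
  }

  ids <- unique(c(ed$u, ed$v))
  if (!is.null(extra_nodes) && nrow(extra_nodes) > 0) {
    ids <- unique(c(ids, namespace_id(as.character(extra_nodes$id),
                                      as.character(extra_nodes$type))))
  }
  ids <- sort(ids)
  nodes <- data.frame(id = ids, type = node_type(ids),
                      stringsAsFactors = FALSE)
  if (nrow(nodes) > 0 && !all(nodes$type %in% node_types)) {
    stop("invalid node type(s): ",
         paste(setdiff(nodes$type, node_types), collapse = ", "))
  }

  # collapsed single-layer view for walking/propagation: max weight over layers
  if (nrow(ed) > 0) {
    pkey <- paste(ed$u, ed$v, sep = "\r")
    wmax <- tapply(ed$weight, pkey, max)
    coll <- ed[!duplicated(pkey), c("u", "v"), drop = FALSE]
    coll$weight <- as.numeric(wmax[paste(coll$u, coll$v, sep = "\r")])
  } else {
    coll <- data.frame(u = character(), v = character(), weight = numeric())
  }
  g <- igraph::graph_from_data_frame(coll, directed = FALSE, vertices = nodes)

  structure(list(nodes = nodes, edges = ed, schema = schema, graph = g),
            class = "hti_network")
}

#' Read a heterogeneous network from tab-separated edge lists
#'
#' Each file is TSV with columns `source`, `target`, `layer` and optional
#' `weight` (no header; missing weight column defaults to 1.0). Rows are
#' validated against the schema; duplicate and symmetric rows collapse to
#' a single undirected edge.
#'
#' @param paths character vector of file paths.
#' @param schema layer to endpoint-type mapping; defaults to [hti_schema()].
#' @return An [hti_network()] object.
#' @export
read_edge_lists <- function(paths, schema = hti_schema()) {
  tabs <- lapply(paths, function(p) {
    tab <- tryCatch(
      read.delim(p, header = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character"),
      error = function(e) NULL)
    if (is.null(tab) || nrow(tab) == 0) return(NULL)
    if (ncol(tab) < 3) stop("edge list ", p, " needs >= 3 columns")
    names(tab)[1:3] <- c("source", "target", "layer")
    tab$weight <- if (ncol(tab) >= 4) as.numeric(tab[[4]]) else 1.0
    tab[, c("source", "target", "layer", "weight")]
  })
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  edges <- if (length(tabs) > 0) do.call(rbind, tabs) else NULL
  hti_network(edges, schema = schema)
}

#' Write a network back to a tab-separated edge list
#'
#' Emits one row per (layer, edge) with namespaced ids, suitable for
#' [read_edge_lists()] round-trips.
#'
#' @param network an `hti_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "hti_network"))
  ed <- network$edges
  out <- data.frame(ed$u, ed$v, ed$layer, format(ed$weight, digits = 15))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Node and edge counts per type and layer
#'
#' @param object an `hti_network`.
#' @param ... unused.
#' @return A list with `nodes` (named count per node type), `edges` (named
#'   count per layer), `n_nodes`, `n_edges`.
#' @export
summary.hti_network <- function(object, ...) {
  nt <- table(factor(object$nodes$type, levels = node_types))
  et <- table(factor(object$edges$layer, levels = names(object$schema)))
  structure(list(nodes = c(nt), edges = c(et),
                 n_nodes = nrow(object$nodes), n_edges = nrow(object$edges)),
            class = "summary.hti_network")
}

#' @export
print.summary.hti_network <- function(x, ...) {
  cat("Heterogeneous network:", x$n_nodes, "nodes,", x$n_edges, "edges\n")
  cat("Nodes per type:\n")
  print(x$nodes)
  cat("Edges per layer:\n")
  print(x$edges)
  invisible(x)
}

#' @export
print.hti_network <- function(x, ...) {
  cat("<hti_network> ", nrow(x$nodes), " nodes (",
      length(unique(x$nodes$type)), " types), ",
      nrow(x$edges), " edges (",
      length(unique(x$edges$layer)), " layers)\n", sep = "")
  invisible(x)
}

#' Nodes of a given type
#' @param network an `hti_network`.
#' @param type one of herb, symptom, disease, drug, protein.
#' @return character vector of namespaced node ids.
#' @export
nodes_of_type <- function(network, type) {
  stopifnot(inherits(network, "hti_network"))
  network$nodes$id[network$nodes$type == type]
}

# Flattened CSR adjacency of the collapsed graph (0-based, neighbors sorted
# within each node) for the compiled walk simulator.
walk_graph <- function(network) {
  g <- network$graph
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1.0, nrow(el))
  from <- c(el[, 1], el[, 2]) - 1L
  to <- c(el[, 2], el[, 1]) - 1L
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]; wts <- c(w, w)[ord]
  offsets <- c(0L, cumsum(tabulate(from + 1L, nbins = n)))
  list(ids = ids, offsets = as.integer(offsets),
       neighbors = as.integer(to), weights = as.numeric(wts), n = n)
}
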