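# Cytokine-centric kinase subnetworks on a reference interaction graph.
# Edge weights follow the convention: higher weight = less likely interaction,
# so minimum-total-weight paths are the most plausible connections.

#' Load a reference interaction network
#'
#' Reads an undirected weighted edge list from a 3-column tab-separated file
#' (`node  node  weight`) or a SIF file (`node  relation  node  [weight]`;
#' missing weights default to 1). Self-loops are dropped with a warning;
#' duplicate edges are collapsed to their minimum weight. Non-positive or
#' non-numeric weights are a parse error reported with the line number.
#'
#' @param path edge-list file.
#' @param format `"auto"` (by extension), `"tsv"` or `"sif"`.
#' @param invert_confidence set `TRUE` when the third column is a confidence
#'   score (higher = more likely): weights are replaced by their reciprocal so
#'   that higher weight means less likely interaction, as required here.
#' @return An undirected [igraph::graph] with a positive `weight` edge
#'   attribute.
#' @export
load_reference_network <- function(path, format = c("auto", "tsv", "sif"),
                                   invert_confidence = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  rows <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "[\t ]+")
  first <- TRUE
  from <- to <- character(0); w <- numeric(0); lineno <- integer(0)
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (format == "tsv") {
      if (length(f) != 3)
        stop("line ", rows[i], ": expected 3 columns (node, node, weight)",
             call. = FALSE)
      a <- f[1]; b <- f[2]; ws <- f[3]
    } else {
      if (!length(f) %in% c(3, 4))
        stop("line ", rows[i],
             ": expected SIF columns (node, relation, node[, weight])",
             call. = FALSE)
      a <- f[1]; b <- f[3]; ws <- if (length(f) == 4) f[4] else "1"
    }
    wi <- suppressWarnings(as.numeric(ws))
    if (is.na(wi)) {
      if (first) { first <- FALSE; next }  # header row
      stop("line ", rows[i], ": non-numeric weight '", ws, "'", call. = FALSE)
    }
    first <- FALSE
    if (!is.finite(wi) || wi <= 0)
      stop("line ", rows[i], ": non-positive weight ", ws, call. = FALSE)
    from <- c(from, a); to <- c(to, b); w <- c(w, wi)
    lineno <- c(lineno, rows[i])
  }
  self <- from == to
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped (line ",
            paste(lineno[self], collapse = ", "), ")", call. = FALSE)
    from <- from[!self]; to <- to[!self]; w <- w[!self]
  }
  if (invert_confidence) w <- 1 / w
  # collapse duplicate unordered edges to the minimum weight
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  minw <- tapply(w, key, min)
  uniq <- !duplicated(key)
  df <- data.frame(from = from[uniq], to = to[uniq],
                   weight = as.numeric(minw[key[uniq]]))
  igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Write an interaction network as a 3-column edge list
#'
#' @param net an igraph with a `weight` edge attribute.
#' @param path output file (tab-separated: node, node, weight).
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  df <- igraph::as_data_frame(net, what = "edges")
  write.table(df[, c("from", "to", "weight")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Hop-bounded minimum-weight distances from the anchor.
# Returns a (max_hops + 1) x n matrix D where D[h + 1, v] is the minimum
# total weight of a path from anchor to v using at most h edges (Inf if
# unreachable). With strictly positive weights, minimum walks are paths.
.hop_distances <- function(edges, n, anchor_idx, max_hops) {
  D <- matrix(Inf, max_hops + 1, n)
  D[1, anchor_idx] <- 0
  for (h in seq_len(max_hops)) {
    d <- D[h, ]
    cand <- pmin(d,
                 .edge_relax(edges, d, n))
    D[h + 1, ] <- cand
  }
  D
}

.edge_relax <- function(edges, d, n) {
  out <- rep(Inf, n)
  a <- edges$a; b <- edges$b; w <- edges$w
  ca <- d[a] + w  # relax a -> b
  cb <- d[b] + w  # relax b -> a
  for (i in seq_along(a)) {
    if (ca[i] < out[b[i]]) out[b[i]] <- ca[i]
    if (cb[i] < out[a[i]]) out[a[i]] <- cb[i]
  }
  out
}

#' Extract a cytokine-centric kinase subnetwork
#'
#' For each informative kinase present in the reference network, finds the
#' minimum-total-weight path(s) of at most `max_hops` edges to the cytokine's
#' anchor node and returns the union of all such paths (all tied minimal paths
#' are kept, for determinism). Kinases with no qualifying path are reported as
#' disconnected; kinases absent from the network are reported as missing.
#'
#' @param net reference network from [load_reference_network()].
#' @param anchor the cytokine's gene node (must exist in the network).
#' @param kinases character vector of informative kinase ids.
#' @param max_hops maximum path length in edges.
#' @param tol numeric tolerance for weight-tie comparisons.
#' @return An object of class `"cytokine_subnetwork"`: `cytokine_id`,
#'   `anchor`, `graph` (the retained igraph), `kinases` (connected),
#'   `disconnected`, `missing`, and `path_weight` (named minimal weights).
#' @export
extract_cytokine_network <- function(net, anchor, kinases, max_hops = 2,
                                     tol = 1e-9) {
  vn <- igraph::V(net)$name
  if (!anchor %in% vn)
    stop("anchor node '", anchor, "' is not in the network", call. = FALSE)
  if (max_hops < 1) stop("max_hops must be >= 1", call. = FALSE)
  missing <- setdiff(kinases, vn)
  if (length(missing))
    message(length(missing), " kinase(s) absent from the network: ",
            paste(missing, collapse = ", "))
  present <- setdiff(intersect(kinases, vn), anchor)

  eldf <- igraph::as_data_frame(net, what = "edges")
  edges <- list(a = match(eldf$from, vn), b = match(eldf$to, vn),
                w = eldf$weight)
  D <- .hop_distances(edges, length(vn), match(anchor, vn), max_hops)
  dmin <- D[max_hops + 1, ]

  # adjacency list for backtracking
  adj <- vector("list", length(vn))
  for (i in seq_along(edges$a)) {
    a <- edges$a[i]; b <- edges$b[i]; w <- edges$w[i]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  anchor_idx <- match(anchor, vn)
  edge_keys <- new.env(parent = emptyenv())
  collect <- function(v, budget, target) {
    if (v == anchor_idx && target <= tol) return(invisible())
    if (budget == 0) return(invisible())
    nb <- adj[[v]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      u <- nb[r, 1]; w <- nb[r, 2]
      if (w <= target + tol && abs(w + D[budget, u] - target) <= tol) {
        assign(paste(min(v, u), max(v, u)), TRUE, envir = edge_keys)
        collect(u, budget - 1, target - w)
      }
    }
  }
  connected <- character(0); path_weight <- numeric(0)
  for (k in present) {
    ki <- match(k, vn)
    if (!is.finite(dmin[ki])) next
    connected <- c(connected, k)
    path_weight[k] <- dmin[ki]
    collect(ki, max_hops, dmin[ki])
  }
  disconnected <- setdiff(present, connected)

  keys <- ls(edge_keys)
  if (length(keys)) {
    pairs <- do.call(rbind, strsplit(keys, " "))
    vids <- as.vector(t(matrix(as.integer(pairs), ncol = 2)))
    eids <- igraph::get_edge_ids(net, vids)
    g <- igraph::subgraph_from_edges(net, eids, delete.vertices = TRUE)
  } else {
    g <- igraph::induced_subgraph(net, anchor)
  }
  if (!anchor %in% igraph::V(g)$name)
    g <- igraph::add_vertices(g, 1, name = anchor)
  role <- ifelse(igraph::V(g)$name == anchor, "anchor",
                 ifelse(igraph::V(g)$name %in% connected, "kinase",
                        "connector"))
  g <- igraph::set_vertex_attr(g, "role", value = role)
  structure(list(cytokine_id = anchor, anchor = anchor, graph = g,
                 kinases = connected, disconnected = disconnected,
                 missing = missing, path_weight = path_weight,
                 max_hops = max_hops),
            class = "cytokine_subnetwork")
}

#' Prune a cytokine subnetwork by edge weight
#'
#' Retains edges with weight at or below `threshold` (the "weight bar"),
#' then drops every node no longer connected to the anchor. Idempotent:
#' pruning twice at the same threshold changes nothing.
#'
#' @param sub a `"cytokine_subnetwork"`.
#' @param threshold positive weight cutoff.
#' @return The pruned `"cytokine_subnetwork"`.
#' @export
prune_by_weight <- function(sub, threshold) {
  stopifnot(inherits(sub, "cytokine_subnetwork"))
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  g <- sub$graph
  drop <- igraph::E(g)[igraph::E(g)$weight > threshold]
  g <- igraph::delete_edges(g, drop)
  comp <- igraph::components(g)
  anchor_comp <- comp$membership[sub$anchor]
  g <- igraph::induced_subgraph(g, names(comp$membership)[
    comp$membership == anchor_comp])
  present <- igraph::V(g)$name
  kept <- intersect(sub$kinases, present)
  structure(list(cytokine_id = sub$cytokine_id, anchor = sub$anchor,
                 graph = g, kinases = kept,
                 disconnected = union(sub$disconnected,
                                      setdiff(sub$kinases, kept)),
                 missing = sub$missing,
                 path_weight = sub$path_weight[kept],
                 max_hops = sub$max_hops, threshold = threshold),
            class = "cytokine_subnetwork")
}

#' @export
print.cytokine_subnetwork <- function(x, ...) {
  cat(sprintf(
    "Cytokine subnetwork [%s]: %d nodes, %d edges; %d kinase(s) connected, %d disconnected, %d missing\n",
    x$anchor, igraph::vcount(x$graph), igraph::ecount(x$graph),
    length(x$kinases), length(x$disconnected), length(x$missing)))
  invisible(x)
}

#' Export a subnetwork for browser rendering
#'
#' `write_network_graphml()` writes GraphML (node `role` and edge `weight`
#' attributes included); `network_to_json()` returns (or writes) a plain
#' nodes/edges list with the anchor flagged.
#'
#' @param sub a `"cytokine_subnetwork"` (or, for GraphML, any igraph).
#' @param path output file; for `network_to_json`, `NULL` returns the list.
#' @return Invisibly `path`, or the list for `network_to_json(path = NULL)`.
#' @export
write_network_graphml <- function(sub, path) {
  g <- if (inherits(sub, "cytokine_subnetwork")) sub$graph else sub
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
network_to_json <- function(sub, path = NULL) {
  stopifnot(inherits(sub, "cytokine_subnetwork"))
  g <- sub$graph
  el <- igraph::as_data_frame(g, what = "edges")
  obj <- list(
    cytokine = sub$cytokine_id,
    nodes = data.frame(id = igraph::V(g)$name,
                       role = igraph::V(g)$role,
                       is_anchor = igraph::V(g)$name == sub$anchor),
    edges = if (nrow(el)) el[, c("from", "to", "weight")]
            else data.frame(from = character(0), to = character(0),
                            weight = numeric(0)),
    disconnected_kinases = sub$disconnected,
    missing_kinases = sub$missing)
  if (is.null(path)) return(obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
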