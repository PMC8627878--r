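#' Convert a typed graph to an igraph object
#'
#' Vertex attributes: `name` (node id), `label` (human-readable name),
#' `kind` (substance/reaction), `is_boundary`. Edge attributes: `role`,
#' `sign`.
#'
#' @param graph a `typed_graph`.
#' @return an [igraph::graph] (directed).
#' @export
as_igraph <- function(graph) {
  verts <- rbind(
    data.frame(name = graph$substances$id, label = graph$substances$name,
               kind = rep("substance", nrow(graph$substances)),
               is_boundary = graph$substances$is_boundary,
               stringsAsFactors = FALSE),
    data.frame(name = graph$reactions$id, label = graph$reactions$name,
               kind = rep("reaction", nrow(graph$reactions)),
               is_boundary = rep(FALSE, nrow(graph$reactions)),
               stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = verts)
}

#' Write a typed graph to GraphML
#'
#' Nodes carry attributes `kind` (substance or reaction), `label` and
#' `is_boundary`; edges carry `role` and `sign`. [load_graphml()] reads the
#' file back to an identical graph.
#'
#' @param graph a `typed_graph`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_graphml <- function(graph, path) {
  ig <- as_igraph(graph)
  # igraph writes logicals as "true"/"false" strings; keep it simple
  igraph::V(ig)$is_boundary <- as.integer(igraph::V(ig)$is_boundary)
  tryCatch(igraph::write_graph(ig, path, format = "graphml"),
           error = function(e) stop("cannot write GraphML to ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a typed graph from GraphML
#'
#' Expects the attribute scheme of [write_graphml()]: node attributes
#' `kind` plus optional `label`/`is_boundary`, edge attributes `role` and
#' optional `sign`.
#'
#' @param path GraphML file.
#' @return a validated [typed_graph()].
#' @export
load_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ig <- tryCatch(igraph::read_graph(path, format = "graphml"),
                 error = function(e) stop("cannot parse GraphML ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  va <- igraph::vertex_attr_names(ig)
  if (igraph::vcount(ig) > 0L && !"kind" %in% va)
    stop("GraphML ", path, " lacks the node attribute 'kind'", call. = FALSE)
  ids <- if ("name" %in% va) igraph::V(ig)$name else
    if ("id" %in% va) igraph::V(ig)$id else as.character(seq_len(igraph::vcount(ig)))
  kind <- if (igraph::vcount(ig) > 0L) igraph::V(ig)$kind else character()
  label <- if ("label" %in% va) igraph::V(ig)$label else ids
  bdry <- if ("is_boundary" %in% va)
    as.logical(as.integer(igraph::V(ig)$is_boundary)) else
      rep(FALSE, igraph::vcount(ig))
  sub_i <- which(kind == "substance")
  rea_i <- which(kind == "reaction")
  if (length(sub_i) + length(rea_i) != igraph::vcount(ig))
    stop("GraphML ", path, " has nodes with kind outside {substance, reaction}",
         call. = FALSE)
  el <- igraph::as_edgelist(ig, names = TRUE)
  ea <- igraph::edge_attr_names(ig)
  role <- if ("role" %in% ea) igraph::E(ig)$role else
    rep(NA_character_, nrow(el))
  sign <- if ("sign" %in% ea) igraph::E(ig)$sign else rep("unknown", nrow(el))
  typed_graph(
    substances = data.frame(id = ids[sub_i], name = label[sub_i],
                            is_boundary = bdry[sub_i]),
    reactions = data.frame(id = ids[rea_i], name = label[rea_i]),
    edges = data.frame(source = el[, 1], target = el[, 2],
                       role = role, sign = sign))
}
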