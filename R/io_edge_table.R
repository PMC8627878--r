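#' Read a typed graph from a plain edge table
#'
#' The edge-table dialect is tab-separated UTF-8 with a header row, columns
#' `source`, `target`, `role` (one of substrate/product/regulator) and an
#' optional `sign` column (activation/inhibition/unknown, meaningful for
#' regulator edges only). Lines starting with `#` are comments. Node kinds
#' are inferred from edge roles: sources of substrate/regulator edges and
#' targets of product edges are substances; the opposite endpoints are
#' reactions. A node whose inferred kinds conflict is a validation error.
#'
#' @param path file to read.
#' @param sep field separator, tab by default.
#' @return a validated [typed_graph()].
#' @export
load_edge_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, sep = sep, comment.char = "#",
                      stringsAsFactors = FALSE, strip.white = TRUE,
                      fileEncoding = "UTF-8"),
    error = function(e) stop("cannot parse edge table ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  need <- c("source", "target", "role")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("edge table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"sign" %in% names(df)) df$sign <- "unknown"
  graph_from_edges(df)
}

# infer node kinds from roles and build a validated graph
graph_from_edges <- function(df) {
  df <- normalize_edges(df)
  bad <- which(!df$role %in% edge_roles)
  if (length(bad) > 0L)
    stop("unknown edge role '", df$role[bad[1]], "' at row ", bad[1],
         call. = FALSE)
  as_sub <- unique(c(df$source[df$role %in% c("substrate", "regulator")],
                     df$target[df$role == "product"]))
  as_rea <- unique(c(df$target[df$role %in% c("substrate", "regulator")],
                     df$source[df$role == "product"]))
  both <- intersect(as_sub, as_rea)
  if (length(both) > 0L)
    stop("node(s) used as both substance and reaction: ",
         paste(both, collapse = ", "), call. = FALSE)
  typed_graph(substances = data.frame(id = as_sub),
              reactions = data.frame(id = as_rea),
              edges = df)
}

#' Write a typed graph as a plain edge table
#'
#' Inverse of [load_edge_table()] for graphs whose every node touches at
#' least one edge (isolated nodes cannot be expressed in the edge dialect).
#'
#' @param graph a `typed_graph`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_edge_table <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
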