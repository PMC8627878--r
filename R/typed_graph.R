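#' Typed bipartite substance/reaction network
#'
#' A `typed_graph` holds the structural model of a molecular-genetic system:
#' substance nodes (metabolites, gene products), reaction nodes (processes),
#' and directed edges typed by role — `substrate` (substance to reaction),
#' `product` (reaction to substance) and `regulator` (substance to reaction,
#' carrying a sign: `activation`, `inhibition` or `unknown`).
#'
#' @param substances data.frame with columns `id`, and optionally `name`
#'   (defaults to `id`) and `is_boundary` (defaults to `FALSE`).
#' @param reactions data.frame with columns `id` and optionally `name`.
#' @param edges data.frame with columns `source`, `target`, `role` and
#'   optionally `sign` (defaults to `"unknown"`; forced to `"unknown"` on
#'   non-regulator edges).
#'
#' @return An object of class `typed_graph`. The constructor validates all
#'   structural invariants and signals an error listing every violation;
#'   use [validate_graph()] to collect violations without raising.
#' @examples
#' g <- typed_graph(
#'   substances = data.frame(id = c("A", "B")),
#'   reactions  = data.frame(id = "R1"),
#'   edges = data.frame(
#'     source = c("A", "R1", "B"), target = c("R1", "B", "R1"),
#'     role = c("substrate", "product", "regulator"),
#'     sign = c("unknown", "unknown", "inhibition"))
#' )
#' g
#' @export
typed_graph <- function(substances = NULL, reactions = NULL, edges = NULL) {
  g <- new_typed_graph(substances, reactions, edges)
  v <- validate_graph(g)
  if (nrow(v) > 0L) {
    stop("invalid typed_graph:\n", paste0("  - ", v$message, collapse = "\n"),
         call. = FALSE)
  }
  g
}

edge_roles <- c("substrate", "product", "regulator")
edge_signs <- c("activation", "inhibition", "unknown")

# low-level constructor: normalises columns, does not validate
new_typed_graph <- function(substances, reactions, edges) {
  substances <- normalize_nodes(substances, boundary = TRUE)
  reactions <- normalize_nodes(reactions, boundary = FALSE)
  edges <- normalize_edges(edges)
  structure(list(substances = substances, reactions = reactions,
                 edges = edges), class = "typed_graph")
}

normalize_nodes <- function(df, boundary) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0L) {
    df <- data.frame(id = character(), name = character(),
                     stringsAsFactors = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("node table needs an 'id' column", call. = FALSE)
  df$id <- as.character(df$id)
  if (!"name" %in% names(df)) df$name <- df$id
  df$name <- ifelse(is.na(df$name) | df$name == "", df$id, as.character(df$name))
  if (boundary) {
    if (!"is_boundary" %in% names(df)) df$is_boundary <- rep(FALSE, nrow(df))
    df$is_boundary <- as.logical(df$is_boundary)
    df <- df[, c("id", "name", "is_boundary")]
  } else {
    df <- df[, c("id", "name")]
  }
  rownames(df) <- NULL
  df
}

normalize_edges <- function(df) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0L) {
    df <- data.frame(source = character(), target = character(),
                     role = character(), sign = character(),
                     stringsAsFactors = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("source", "target", "role")) {
    if (!col %in% names(df)) stop("edge table needs a '", col, "' column",
                                  call. = FALSE)
    df[[col]] <- as.character(df[[col]])
  }
  if (!"sign" %in% names(df)) df$sign <- "unknown"
  df$sign <- as.character(df$sign)
  df$sign[is.na(df$sign) | df$sign == ""] <- "unknown"
  df <- df[, c("source", "target", "role", "sign")]
  rownames(df) <- NULL
  df
}

#' Collect structural violations of a typed graph
#'
#' Checks every invariant of the typed-graph data model and returns the full
#' list of violations instead of raising: unique non-empty node ids, edge
#' endpoints resolving to declared nodes, role-direction rules (substrate and
#' regulator edges run substance to reaction, product edges reaction to
#' substance), no duplicate `(source, target, role)` triple, and sign values
#' restricted to regulator edges.
#'
#' @param graph a `typed_graph` (or an equivalently shaped list).
#' @return data.frame with columns `rule`, `id` (offending node id or edge
#'   triple) and `message`; zero rows exactly when the graph is valid.
#' @export
validate_graph <- function(graph) {
  viol <- function(rule, id, message) {
    data.frame(rule = rule, id = id, message = message,
               stringsAsFactors = FALSE)
  }
  out <- list()
  sub <- graph$substances; rea <- graph$reactions; ed <- graph$edges

  ids <- c(sub$id, rea$id)
  empty <- ids[!nzchar(ids) | is.na(ids)]
  for (i in empty) out[[length(out) + 1L]] <-
    viol("node_id_nonempty", i, "node with empty id")
  dup <- unique(ids[duplicated(ids)])
  for (i in dup) out[[length(out) + 1L]] <-
    viol("node_id_unique", i, paste0("duplicate node id '", i, "'"))

  bad_role <- unique(ed$role[!ed$role %in% edge_roles])
  for (r in bad_role) out[[length(out) + 1L]] <-
    viol("edge_role", r, paste0("unknown edge role '", r, "'"))
  bad_sign <- unique(ed$sign[!ed$sign %in% edge_signs])
  for (s in bad_sign) out[[length(out) + 1L]] <-
    viol("edge_sign", s, paste0("unknown edge sign '", s, "'"))

  is_sub <- function(x) x %in% sub$id
  is_rea <- function(x) x %in% rea$id
  for (i in seq_len(nrow(ed))) {
    e <- ed[i, ]
    triple <- paste(e$source, e$target, e$role, sep = " -> ")
    if (!is_sub(e$source) && !is_rea(e$source))
      out[[length(out) + 1L]] <- viol("edge_endpoint", e$source,
        paste0("edge source '", e$source, "' is not a declared node"))
    if (!is_sub(e$target) && !is_rea(e$target))
      out[[length(out) + 1L]] <- viol("edge_endpoint", e$target,
        paste0("edge target '", e$target, "' is not a declared node"))
    if (e$role %in% c("substrate", "regulator")) {
      if (is_rea(e$source) || is_sub(e$target))
        out[[length(out) + 1L]] <- viol("role_direction", triple,
          paste0(e$role, " edge ", triple,
                 " must run substance -> reaction"))
      if (e$role == "substrate" && e$sign != "unknown")
        out[[length(out) + 1L]] <- viol("sign_on_flow_edge", triple,
          paste0("substrate edge ", triple, " carries a regulation sign"))
    } else if (e$role == "product") {
      if (is_sub(e$source) || is_rea(e$target))
        out[[length(out) + 1L]] <- viol("role_direction", triple,
          paste0("product edge ", triple, " must run reaction -> substance"))
      if (e$sign != "unknown")
        out[[length(out) + 1L]] <- viol("sign_on_flow_edge", triple,
          paste0("product edge ", triple, " carries a regulation sign"))
    }
  }
  key <- paste(ed$source, ed$target, ed$role)
  dupe <- unique(key[duplicated(key)])
  for (k in dupe) out[[length(out) + 1L]] <-
    viol("edge_unique", k, paste0("duplicate edge triple (", k, ")"))

  if (length(out) == 0L) {
    data.frame(rule = character(), id = character(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

#' @export
print.typed_graph <- function(x, ...) {
  n_inh <- sum(x$edges$role == "regulator" & x$edges$sign == "inhibition")
  cat("typed_graph: ", nrow(x$substances), " substances, ",
      nrow(x$reactions), " reactions, ", nrow(x$edges), " edges (",
      n_inh, " inhibitory regulator)\n", sep = "")
  invisible(x)
}

# ids of substances / reactions
substance_ids <- function(graph) graph$substances$id
reaction_ids <- function(graph) graph$reactions$id

node_name <- function(graph, id) {
  i <- match(id, graph$substances$id)
  out <- graph$substances$name[i]
  j <- match(id, graph$reactions$id)
  out[is.na(i)] <- graph$reactions$name[j[is.na(i)]]
  out
}

edges_of_role <- function(graph, role) {
  graph$edges[graph$edges$role == role, , drop = FALSE]
}

# substrates / products of one reaction
reaction_substrates <- function(graph, rid) {
  e <- graph$edges
  e$source[e$role == "substrate" & e$target == rid]
}
reaction_products <- function(graph, rid) {
  e <- graph$edges
  e$target[e$role == "product" & e$source == rid]
}

#' Compare two typed graphs for structural equality
#'
#' Equality up to row order of the node and edge tables; names and boundary
#' flags are compared as attributes of matching ids.
#'
#' @param a,b `typed_graph` objects.
#' @param ignore_boundary compare without the substances' boundary flags
#'   (useful when one side was derived from a kinetic model, which marks
#'   off-contour co-substrates as boundary species).
#' @return TRUE or FALSE.
#' @export
graph_equal <- function(a, b, ignore_boundary = FALSE) {
  ord <- function(df, cols) {
    df <- df[do.call(order, df[cols]), cols, drop = FALSE]
    rownames(df) <- NULL
    df
  }
  sub_cols <- if (ignore_boundary) c("id", "name") else
    c("id", "name", "is_boundary")
  identical(ord(a$substances, sub_cols),
            ord(b$substances, sub_cols)) &&
    identical(ord(a$reactions, c("id", "name")),
              ord(b$reactions, c("id", "name"))) &&
    identical(ord(a$edges, c("source", "target", "role", "sign")),
              ord(b$edges, c("source", "target", "role", "sign")))
}
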