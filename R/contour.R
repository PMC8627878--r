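#' Potentially oscillating contour
#'
#' A contour is an ordered, alternating substance/reaction cycle closed by a
#' single inhibitory regulator edge: the regulated reaction `r0` produces
#' substance `s1`, which is a substrate of reaction `r1` producing `s2`, and
#' so on until the last substance `sk`, whose inhibitory regulator edge back
#' onto `r0` closes the loop. The total node count on the cycle is
#' `2k` (k substances plus k reactions) and must exceed 3.
#'
#' @param substances ordered substance ids `s1..sk` along the mass-flow path.
#' @param reactions ordered reaction ids `r1..r(k-1)` interleaved with the
#'   substances (`si` is a substrate of `ri`, `ri` produces `si+1`).
#' @param regulated_reaction id of `r0`, the reaction producing `s1` and
#'   inhibited by `sk`.
#' @return an object of class `contour` with fields `substances`,
#'   `reactions`, `regulated_reaction`, `closing_edge`, `n_nodes` and
#'   `canonical_id`.
#' @export
contour <- function(substances, reactions, regulated_reaction) {
  x <- structure(list(substances = as.character(substances),
                      reactions = as.character(reactions),
                      regulated_reaction = as.character(regulated_reaction)),
                 class = "contour")
  k <- length(x$substances)
  if (length(x$reactions) != k - 1L)
    stop("contour needs exactly one fewer reaction than substances (",
         "got ", length(x$reactions), " for ", k, " substances)",
         call. = FALSE)
  nodes <- c(x$regulated_reaction, x$reactions, x$substances)
  if (anyDuplicated(nodes) > 0L)
    stop("contour repeats node '", nodes[anyDuplicated(nodes)], "'",
         call. = FALSE)
  x$n_nodes <- 2L * k
  if (x$n_nodes <= 3L)
    stop("contour has ", x$n_nodes, " nodes; more than 3 are required",
         call. = FALSE)
  x$closing_edge <- list(source = x$substances[k],
                         target = x$regulated_reaction,
                         role = "regulator", sign = "inhibition")
  x$canonical_id <- canonicalize(x)
  x
}

#' Canonical identifier of a contour
#'
#' The closing inhibitory edge fixes a unique start node — the regulated
#' reaction — so the id is simply the cycle's node ids joined with `|`
#' starting from that reaction. It is invariant under any representation of
#' the same cycle but distinguishes node-disjoint contours and different
#' closing edges.
#'
#' @param x a `contour`.
#' @return character scalar.
#' @export
canonicalize <- function(x) {
  k <- length(x$substances)
  if (k < 2L || length(x$reactions) != k - 1L)
    stop("malformed contour: ", k, " substances, ", length(x$reactions),
         " reactions", call. = FALSE)
  seq_nodes <- character(2L * k)
  seq_nodes[1L] <- x$regulated_reaction
  seq_nodes[seq(2L, 2L * k, by = 2L)] <- x$substances
  if (k > 1L) seq_nodes[seq(3L, 2L * k - 1L, by = 2L)] <- x$reactions
  paste(seq_nodes, collapse = "|")
}

#' @export
print.contour <- function(x, ...) {
  cat("contour (", x$n_nodes, " nodes): ", x$canonical_id, "\n",
      "  inhibitor: ", x$closing_edge$source, " -| ",
      x$regulated_reaction, "\n", sep = "")
  invisible(x)
}

# all (reaction, substance) cycle pairs in order: r0->s1, r1->s2, ...
contour_pairs <- function(x) {
  k <- length(x$substances)
  data.frame(reaction = c(x$regulated_reaction, x$reactions),
             substance = x$substances, stringsAsFactors = FALSE)
}

#' Check a contour against its graph
#'
#' Verifies every contour invariant in the context of `graph`: alternating
#' substrate/product edges along the path, the closing edge present with
#' sign inhibition, simplicity, and the node-count rule.
#'
#' @param x a `contour`.
#' @param graph the `typed_graph` it was found in.
#' @return TRUE (invisibly) or an error describing the violated invariant.
#' @export
validate_contour <- function(x, graph) {
  has_edge <- function(s, t, role, sign = NULL) {
    e <- graph$edges
    hit <- e$source == s & e$target == t & e$role == role
    if (!is.null(sign)) hit <- hit & e$sign == sign
    any(hit)
  }
  k <- length(x$substances)
  rs <- c(x$regulated_reaction, x$reactions)
  for (i in seq_len(k)) {
    if (!has_edge(rs[i], x$substances[i], "product"))
      stop("missing product edge ", rs[i], " -> ", x$substances[i],
           call. = FALSE)
    if (i < k && !has_edge(x$substances[i], x$reactions[i], "substrate"))
      stop("missing substrate edge ", x$substances[i], " -> ",
           x$reactions[i], call. = FALSE)
  }
  if (!has_edge(x$substances[k], x$regulated_reaction, "regulator",
                "inhibition"))
    stop("missing inhibitory closing edge ", x$substances[k], " -> ",
         x$regulated_reaction, call. = FALSE)
  invisible(TRUE)
}

#' Tabular summary of contours
#'
#' @param contours list of `contour` objects (as returned by
#'   [enumerate_contours()]).
#' @param graph the `typed_graph` they were found in (for full names).
#' @return data.frame with one row per contour: `canonical_id`, `n_nodes`,
#'   `substances` (comma-separated names), `regulated_reaction` and
#'   `inhibitor` (full substance name).
#' @export
contour_report <- function(contours, graph) {
  if (length(contours) == 0L) {
    return(data.frame(canonical_id = character(), n_nodes = integer(),
                      substances = character(),
                      regulated_reaction = character(),
                      inhibitor = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(contours, function(x) {
    data.frame(
      canonical_id = x$canonical_id,
      n_nodes = x$n_nodes,
      substances = paste(node_name(graph, x$substances), collapse = ", "),
      regulated_reaction = x$regulated_reaction,
      inhibitor = node_name(graph, x$closing_edge$source),
      stringsAsFactors = FALSE)
  }))
}

#' Extract the subgraph induced by a contour
#'
#' Returns the typed graph containing the contour's reactions with all their
#' substrate/product partners (on-contour substances plus off-contour
#' co-substrates and co-products) and the closing inhibitory regulator edge.
#' This is the structural model the contour's ODE reconstruction is based on.
#'
#' @param x a `contour`.
#' @param graph the parent `typed_graph`.
#' @return a `typed_graph`.
#' @export
contour_subgraph <- function(x, graph) {
  rids <- c(x$regulated_reaction, x$reactions)
  e <- graph$edges
  keep_flow <- (e$role == "substrate" & e$target %in% rids) |
    (e$role == "product" & e$source %in% rids)
  keep_close <- e$role == "regulator" &
    e$source == x$closing_edge$source &
    e$target == x$regulated_reaction & e$sign == "inhibition"
  ed <- e[keep_flow | keep_close, , drop = FALSE]
  sids <- unique(c(ed$source[ed$role %in% c("substrate", "regulator")],
                   ed$target[ed$role == "product"]))
  typed_graph(
    substances = graph$substances[graph$substances$id %in% sids, ],
    reactions = graph$reactions[graph$reactions$id %in% rids, ],
    edges = ed)
}
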