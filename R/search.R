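#' Enumerate potentially oscillating contours
#'
#' Finds every contour satisfying the two structural criteria for potential
#' oscillation: (1) a closed oriented path through more than 3 nodes, and
#' (2) orientation in one direction with the last node exerting an
#' inhibitory regulatory influence on the first. Concretely, for each
#' inhibitory regulator edge `sk -> r0` the search walks mass-flow chains
#' (`r0` product `s1`, substrate edge to `r1`, product edge to `s2`, ...)
#' by depth-first traversal and reports each simple path ending in `sk`.
#'
#' @param graph a `typed_graph`.
#' @param min_nodes smallest admissible cycle node count (substances plus
#'   reactions); must be at least 4.
#' @param max_nodes largest admissible cycle node count, `Inf` for
#'   unlimited.
#' @param assume_unknown_inhibitory if TRUE, regulator edges with
#'   `sign = "unknown"` may also close contours (conservative default:
#'   FALSE, only explicit inhibition closes).
#' @return list of [contour()] objects, sorted by `canonical_id`.
#' @seealso [brute_force_contours()] for the exhaustive oracle.
#' @export
enumerate_contours <- function(graph, min_nodes = 4L, max_nodes = Inf,
                               assume_unknown_inhibitory = FALSE) {
  if (min_nodes < 4L)
    stop("min_nodes must be >= 4: a contour passes through more than 3 nodes",
         call. = FALSE)
  if (max_nodes < min_nodes)
    stop("max_nodes must be >= min_nodes", call. = FALSE)
  e <- graph$edges
  signs_ok <- if (assume_unknown_inhibitory)
    c("inhibition", "unknown") else "inhibition"
  closing <- e[e$role == "regulator" & e$sign %in% signs_ok, , drop = FALSE]
  if (nrow(closing) == 0L) return(list())

  # adjacency: substance -> consuming reactions, reaction -> products
  sub_out <- split(e$target[e$role == "substrate"],
                   e$source[e$role == "substrate"])
  rea_out <- split(e$target[e$role == "product"],
                   e$source[e$role == "product"])

  found <- list()
  for (ci in seq_len(nrow(closing))) {
    sk <- closing$source[ci]
    r0 <- closing$target[ci]
    prods <- rea_out[[r0]]
    if (is.null(prods)) next
    # DFS over alternating substance/reaction path s1, r1, s2, ...
    walk <- function(s, subs, reas) {
      if (s == sk) {
        n <- 2L * length(subs)
        if (n >= min_nodes && n <= max_nodes) {
          found[[length(found) + 1L]] <<-
            contour(subs, reas, r0)
        }
        return(invisible())
      }
      for (r in sub_out[[s]]) {
        if (r == r0 || r %in% reas) next
        for (s2 in rea_out[[r]]) {
          if (s2 %in% subs) next
          walk(s2, c(subs, s2), c(reas, r))
        }
      }
      invisible()
    }
    for (s1 in prods) {
      if (s1 == sk && sk %in% prods) {
        # k = 1 cycle has 2 nodes; always below min_nodes
        next
      }
      walk(s1, s1, character())
    }
  }
  sort_contours(unique_contours(found))
}

unique_contours <- function(contours) {
  if (length(contours) == 0L) return(list())
  ids <- vapply(contours, function(x) x$canonical_id, character(1))
  contours[!duplicated(ids)]
}

sort_contours <- function(contours) {
  if (length(contours) == 0L) return(list())
  ids <- vapply(contours, function(x) x$canonical_id, character(1))
  contours[order(ids, method = "radix")]
}

#' Exhaustive contour oracle
#'
#' Independent verification route for [enumerate_contours()]: enumerates ALL
#' simple directed cycles of the typed graph (over every edge, regulator
#' edges included, with parallel edges expanded) by exhaustive anchored
#' depth-first search, then keeps exactly those cycles that satisfy the
#' contour invariants — exactly one regulator edge, that edge inhibitory,
#' all remaining edges mass-flow, and more than 3 (within
#' `[min_nodes, max_nodes]`) nodes. Intended for small graphs; guarded at
#' 20 nodes.
#'
#' @inheritParams enumerate_contours
#' @return list of [contour()] objects, sorted by `canonical_id`.
#' @export
brute_force_contours <- function(graph, min_nodes = 4L, max_nodes = Inf,
                                 assume_unknown_inhibitory = FALSE) {
  if (min_nodes < 4L)
    stop("min_nodes must be >= 4: a contour passes through more than 3 nodes",
         call. = FALSE)
  n_total <- nrow(graph$substances) + nrow(graph$reactions)
  if (n_total > 20L)
    stop("brute_force_contours is limited to graphs with <= 20 nodes (got ",
         n_total, ")", call. = FALSE)
  e <- graph$edges
  if (nrow(e) == 0L) return(list())
  nodes <- sort(c(graph$substances$id, graph$reactions$id))
  idx <- stats::setNames(seq_along(nodes), nodes)
  # edge list indexed by source node
  by_src <- split(seq_len(nrow(e)), e$source)

  signs_ok <- if (assume_unknown_inhibitory)
    c("inhibition", "unknown") else "inhibition"

  results <- list()
  consider_cycle <- function(edge_idx) {
    ce <- e[edge_idx, , drop = FALSE]
    reg <- which(ce$role == "regulator")
    if (length(reg) != 1L) return(invisible())
    if (!ce$sign[reg] %in% signs_ok) return(invisible())
    m <- nrow(ce)
    n <- m  # node count equals edge count on a simple cycle
    if (n <= 3L || n < min_nodes || n > max_nodes) return(invisible())
    # rotate so the regulator edge is last: r0 = its target starts the cycle
    rot <- c(seq_len(m), seq_len(m))[(reg + 1L):(reg + m)]
    ce <- ce[rot, , drop = FALSE]
    # now ce[1] starts at r0; expect product/substrate alternation
    roles <- ce$role[-m]
    if (!all(roles == rep(c("product", "substrate"),
                          length.out = m - 1L))) return(invisible())
    subs <- ce$target[ce$role == "product"]
    reas <- ce$source[ce$role == "product"][-1L]
    results[[length(results) + 1L]] <<- contour(subs, reas, ce$source[1L])
    invisible()
  }

  # anchored DFS: cycles whose minimal node (by sort order) is the anchor
  for (a in seq_along(nodes)) {
    anchor <- nodes[a]
    path_edges <- integer()
    on_path <- character()
    dfs <- function(v) {
      for (ei in by_src[[v]]) {
        w <- e$target[ei]
        if (idx[[w]] < a) next
        if (w == anchor) {
          consider_cycle(c(path_edges, ei))
        } else if (!w %in% on_path) {
          path_edges <<- c(path_edges, ei)
          on_path <<- c(on_path, w)
          dfs(w)
          path_edges <<- path_edges[-length(path_edges)]
          on_path <<- on_path[-length(on_path)]
        }
      }
    }
    on_path <- anchor
    dfs(anchor)
  }
  sort_contours(unique_contours(results))
}

#' Canonical-id set of a contour list
#'
#' @param contours list of `contour` objects.
#' @return sorted character vector of canonical ids.
#' @export
contour_ids <- function(contours) {
  sort(vapply(contours, function(x) x$canonical_id, character(1)))
}
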