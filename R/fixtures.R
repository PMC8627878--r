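# -- synthetic typed graphs with planted contours ----------------------------

#' Configuration for the random typed-graph generator
#'
#' @param n_substances,n_reactions background node budget (planted contour
#'   nodes are drawn from this budget).
#' @param edge_density expected number of background substrate and product
#'   edges per reaction (each reaction draws approximately this many random
#'   substrate and product partners).
#' @param n_planted_contours number of mass-flow chains closed by an
#'   inhibitory regulator edge to plant as ground truth.
#' @param planted_lengths substances per planted contour (recycled);
#'   each contour occupies `2 * length` nodes, which must be at least 4.
#' @param allow_background_inhibition if TRUE, background regulator edges
#'   may carry sign inhibition (adversarial mode: accidental contours can
#'   arise and the brute-force oracle defines truth). Default FALSE keeps
#'   planted ground truth clean — background regulators are
#'   activation/unknown.
#' @param seed mandatory integer RNG seed; generation is deterministic per
#'   seed.
#' @return validated `fixture_config` list.
#' @export
fixture_config <- function(n_substances = 10L, n_reactions = 8L,
                           edge_density = 1.5, n_planted_contours = 1L,
                           planted_lengths = 3L,
                           allow_background_inhibition = FALSE,
                           seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is mandatory for randomized generation",
         call. = FALSE)
  if (any(planted_lengths < 2L))
    stop("planted contours need at least 2 substances (4 cycle nodes)",
         call. = FALSE)
  need_sub <- if (n_planted_contours > 0L)
    sum(rep(planted_lengths, length.out = n_planted_contours)) else 0L
  if (need_sub > n_substances || need_sub > n_reactions)
    stop("planted contours need ", need_sub, " substances and reactions; ",
         "budget is ", n_substances, "/", n_reactions, call. = FALSE)
  structure(list(n_substances = as.integer(n_substances),
                 n_reactions = as.integer(n_reactions),
                 edge_density = edge_density,
                 n_planted_contours = as.integer(n_planted_contours),
                 planted_lengths = as.integer(planted_lengths),
                 allow_background_inhibition = allow_background_inhibition,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random typed graph with planted contours
#'
#' Builds a background bipartite substance/reaction graph with random
#' substrate and product edges, then plants the requested number of
#' mass-flow chains closed by inhibitory regulator edges. The planted
#' contours are returned as ground truth. Background regulator edges never
#' carry sign inhibition unless `allow_background_inhibition` is set, so by
#' default every inhibitory closure in the graph is a planted one (extra
#' contours can still arise when background mass-flow edges create
#' alternative paths onto a planted closing edge; the brute-force oracle
#' defines truth in that case). Deterministic per seed.
#'
#' @param config a [fixture_config()].
#' @return list with elements `graph` (a validated [typed_graph()]),
#'   `planted` (list of [contour()] ground truth) and `seed`.
#' @export
random_typed_graph <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    sub_ids <- sprintf("S%02d", seq_len(config$n_substances))
    rea_ids <- sprintf("R%02d", seq_len(config$n_reactions))
    edges <- list()
    add_edge <- function(s, t, role, sign = "unknown") {
      edges[[length(edges) + 1L]] <<- data.frame(
        source = s, target = t, role = role, sign = sign,
        stringsAsFactors = FALSE)
    }

    planted <- list()
    free_sub <- sub_ids
    free_rea <- rea_ids
    lens <- rep(config$planted_lengths,
                length.out = config$n_planted_contours)
    for (ci in seq_len(config$n_planted_contours)) {
      klen <- lens[ci]
      subs <- free_sub[seq_len(klen)]
      reas <- free_rea[seq_len(klen)]
      free_sub <- free_sub[-seq_len(klen)]
      free_rea <- free_rea[-seq_len(klen)]
      r0 <- reas[1L]
      add_edge(r0, subs[1L], "product")
      if (klen > 1L) {
        for (i in seq_len(klen - 1L)) {
          add_edge(subs[i], reas[i + 1L], "substrate")
          add_edge(reas[i + 1L], subs[i + 1L], "product")
        }
      }
      add_edge(subs[klen], r0, "regulator", "inhibition")
      planted[[ci]] <- contour(subs, reas[-1L], r0)
    }

    # background mass-flow edges: random substrate/product partners
    existing <- function() {
      if (length(edges) == 0L) character() else {
        e <- do.call(rbind, edges)
        paste(e$source, e$target, e$role)
      }
    }
    n_bg <- stats::rpois(1, config$edge_density * config$n_reactions)
    for (i in seq_len(n_bg)) {
      r <- sample(rea_ids, 1L)
      s <- sample(sub_ids, 1L)
      role <- sample(c("substrate", "product"), 1L)
      key <- if (role == "substrate") paste(s, r, role) else paste(r, s, role)
      if (key %in% existing()) next
      if (role == "substrate") add_edge(s, r, "substrate")
      else add_edge(r, s, "product")
    }
    # background regulator edges (sparser)
    n_reg <- stats::rpois(1, 0.3 * config$n_reactions)
    signs <- if (config$allow_background_inhibition)
      c("activation", "unknown", "inhibition") else c("activation", "unknown")
    for (i in seq_len(n_reg)) {
      r <- sample(rea_ids, 1L)
      s <- sample(sub_ids, 1L)
      if (paste(s, r, "regulator") %in% existing()) next
      add_edge(s, r, "regulator", sample(signs, 1L))
    }

    graph <- typed_graph(
      substances = data.frame(id = sub_ids),
      reactions = data.frame(id = rea_ids),
      edges = if (length(edges) > 0L) do.call(rbind, edges) else NULL)
    list(graph = graph, planted = planted, seed = config$seed)
  })
}

# -- the tryptophan-biosynthesis contour -------------------------------------

trp_substance_names <- c(
  CHOR = "Chorismate",
  GLN = "L-glutamine",
  PYR = "Pyruvate",
  GLU = "L-glutamate",
  AN = "Anthranilate",
  PRPP = "5-phospho-alpha-D-ribose 1-diphosphate",
  NPRAN = "N-(5-phosphoribosyl)-anthranilate",
  PPI = "Diphosphate",
  CPAD5P = "1-(2-carboxyphenylamino)-1-deoxy-D-ribulose 5-phosphate",
  IGP = "Indole-3-glycerol phosphate",
  SER = "L-serine",
  T3P1 = "Glyceraldehyde 3-phosphate",
  TRP = "L-tryptophan")

#' The tryptophan-biosynthesis feedback contour
#'
#' Builds the typed graph of the five-reaction tryptophan pathway segment
#' with end-product inhibition:
#' `CHOR + GLN -> AN + PYR + GLU` (anthranilate synthase, inhibited by
#' TRP), `AN + PRPP -> NPRAN + PPI` (anthranilate
#' phosphoribosyltransferase), `NPRAN -> CPAD5P` (phosphoribosyl-
#' anthranilate isomerase), `CPAD5P -> IGP` (indole-3-glycerol-phosphate
#' synthase) and `IGP + SER -> TRP + T3P1` (tryptophan synthase) — 13
#' substances, 5 reactions, with L-tryptophan the inhibitory regulator of
#' the first reaction. The unique contour in this graph has the 5 state
#' substances AN, NPRAN, CPAD5P, IGP, TRP; the remaining 8 species are
#' pathway inputs and by-products that become boundary species of the
#' generated kinetic model. Stoichiometry is unit throughout.
#'
#' @return a validated [typed_graph()].
#' @examples
#' g <- trp_fixture()
#' length(enumerate_contours(g))  # exactly 1
#' @export
trp_fixture <- function() {
  reactions <- data.frame(
    id = c("AS", "PRT", "PRAI", "IGPS", "TS"),
    name = c("anthranilate synthase",
             "anthranilate phosphoribosyltransferase",
             "phosphoribosylanthranilate isomerase",
             "indole-3-glycerol-phosphate synthase",
             "tryptophan synthase"),
    stringsAsFactors = FALSE)
  rx <- list(
    AS = list(sub = c("CHOR", "GLN"), prod = c("AN", "PYR", "GLU")),
    PRT = list(sub = c("AN", "PRPP"), prod = c("NPRAN", "PPI")),
    PRAI = list(sub = "NPRAN", prod = "CPAD5P"),
    IGPS = list(sub = "CPAD5P", prod = "IGP"),
    TS = list(sub = c("IGP", "SER"), prod = c("TRP", "T3P1")))
  edges <- list()
  for (rid in names(rx)) {
    for (s in rx[[rid]]$sub)
      edges[[length(edges) + 1L]] <- data.frame(
        source = s, target = rid, role = "substrate", sign = "unknown",
        stringsAsFactors = FALSE)
    for (pr in rx[[rid]]$prod)
      edges[[length(edges) + 1L]] <- data.frame(
        source = rid, target = pr, role = "product", sign = "unknown",
        stringsAsFactors = FALSE)
  }
  edges[[length(edges) + 1L]] <- data.frame(
    source = "TRP", target = "AS", role = "regulator", sign = "inhibition",
    stringsAsFactors = FALSE)
  typed_graph(
    substances = data.frame(id = names(trp_substance_names),
                            name = unname(trp_substance_names),
                            stringsAsFactors = FALSE),
    reactions = reactions,
    edges = do.call(rbind, edges))
}

# -- ring-repression gene networks -------------------------------------------

#' Ring-repression gene network (repressilator family)
#'
#' Builds a hypothetical gene network of `n_genes` products where each
#' product represses the synthesis of the next gene in the ring through a
#' Hill term, optionally with additional repressive links. Returns both a
#' typed graph (synthesis reactions `G1..Gn` producing products `P1..Pn`,
#' with inhibitory regulator edges for every repression) and a simulatable
#' Hill-repression ODE system:
#' `dp_j/dt = a * prod_r 1/(1 + p_r^h) - b * p_j` over all repressors `r`
#' of gene `j`.
#'
#' With `repressors_per_gene = 1` this is the repressilator ring
#' (sustained oscillation for odd rings at sufficient cooperativity, e.g.
#' the 3-gene ring at the defaults `a = 5, b = 1, h = 4`; no oscillation
#' at `h = 1`). With `repressors_per_gene = 2` each product represses its
#' two ring neighbours (the symmetric double-repression network, which
#' settles to a stationary state: its mutual-repression pairs form
#' positive circuits whose winner-take-all attractors dominate).
#'
#' The documented one-extra-link switch from stationary to cyclic dynamics
#' uses `ring_closed = FALSE`: the open repression chain `g1 -| g2 -| ...
#' -| gn` is a directed acyclic network and settles to a steady state for
#' every parameter set, and adding the single repressive link
#' `extra_links = list(c(3, 1))` (product of gene 3 represses gene 1)
#' closes an odd-length negative circuit that oscillates at the frozen
#' parameter set `a = 5, b = 1, h = 4` — the downstream genes follow as
#' slaves. (In this protein-only Hill reduction the doubly-repressed
#' topologies do not show the switch: their stationary attractors persist
#' after one added link; see the methods vignette.)
#'
#' @param n_genes number of genes (>= 3).
#' @param extra_links list of integer pairs `c(i, j)`: product of gene `i`
#'   also represses gene `j`.
#' @param repressors_per_gene 1 (next-in-ring repression) or 2 (both ring
#'   neighbours).
#' @param ring_closed if FALSE, the link from the last product back onto
#'   gene 1 (and, with two repressors per gene, every wrap-around link) is
#'   omitted, leaving an open repression chain.
#' @param a,b,h synthesis rate, degradation rate and Hill cooperativity.
#' @param initials optional named initial state (`P1..Pn`); the default is
#'   a small graded asymmetric start.
#' @return list with elements `graph` (a [typed_graph()]) and `model` (an
#'   [ode_system()]).
#' @export
ring_repression_network <- function(n_genes = 3L, extra_links = list(),
                                    repressors_per_gene = 1L,
                                    ring_closed = TRUE,
                                    a = 5, b = 1, h = 4, initials = NULL) {
  n <- as.integer(n_genes)
  if (n < 3L) stop("n_genes must be >= 3", call. = FALSE)
  if (!repressors_per_gene %in% c(1L, 2L))
    stop("repressors_per_gene must be 1 or 2", call. = FALSE)
  if (h < 1) stop("cooperativity h must be >= 1", call. = FALSE)
  ring <- function(i) ((i - 1L) %% n) + 1L
  repressors <- vector("list", n)
  for (j in seq_len(n)) {
    reps <- ring(j - 1L)
    if (repressors_per_gene == 2L) reps <- c(reps, ring(j + 1L))
    if (!ring_closed) reps <- reps[reps < j]  # keep only downstream links
    repressors[[j]] <- reps
  }
  for (lk in extra_links) {
    if (length(lk) != 2L || any(lk < 1L) || any(lk > n))
      stop("extra_links entries must be pairs of gene indices in 1..",
           n, call. = FALSE)
    repressors[[lk[2L]]] <- unique(c(repressors[[lk[2L]]], lk[1L]))
  }
  pid <- function(i) sprintf("P%d", i)
  gid <- function(i) sprintf("G%d", i)
  edges <- list()
  for (j in seq_len(n)) {
    edges[[length(edges) + 1L]] <- data.frame(
      source = gid(j), target = pid(j), role = "product", sign = "unknown",
      stringsAsFactors = FALSE)
    for (r in repressors[[j]])
      edges[[length(edges) + 1L]] <- data.frame(
        source = pid(r), target = gid(j), role = "regulator",
        sign = "inhibition", stringsAsFactors = FALSE)
  }
  graph <- typed_graph(
    substances = data.frame(id = pid(seq_len(n)),
                            name = sprintf("product of gene g%d",
                                           seq_len(n))),
    reactions = data.frame(id = gid(seq_len(n)),
                           name = sprintf("synthesis from gene g%d",
                                          seq_len(n))),
    edges = do.call(rbind, edges))

  p <- c(a = a, b = b, h = h)
  y0 <- if (is.null(initials))
    stats::setNames(0.1 * seq_len(n), pid(seq_len(n)))
  else {
    stopifnot(length(initials) == n)
    if (is.null(names(initials))) names(initials) <- pid(seq_len(n))
    initials
  }
  reps_idx <- repressors
  rhs <- function(t, y, p) {
    vapply(seq_len(n), function(j) {
      rep_term <- prod(1 / (1 + pmax(y[reps_idx[[j]]], 0)^p[["h"]]))
      p[["a"]] * rep_term - p[["b"]] * y[j]
    }, numeric(1))
  }
  model <- ode_system(
    name = sprintf("ring_repression_%dg", n),
    rhs = rhs, parameters = p, initials = y0,
    notes = sprintf(paste0("Hill-repression gene ring: %d genes, %d ",
                           "repressive links, cooperativity h = %g"),
                    n, sum(lengths(repressors)), h),
    default_tend = 200)
  list(graph = graph, model = model)
}
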