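# Bidirectional path retrieval between a disease and a gene under a
# path-length bound: a heuristic best-first mode driven by the W(n) node
# priority, and an exhaustive layered mode that is complete within the bound.

#' Heuristic priority of a frontier node
#'
#' \deqn{W(n) = e^{E_o(n) - E_i(n)} \times E_o(n) \times \varepsilon,}
#' where \eqn{E_i} counts n's edges incident to an input term, \eqn{E_o} the
#' remaining edges, and \eqn{\varepsilon} is a random factor in \[0.5, 1\]
#' providing exploration flexibility -- except that a node already present in
#' either frontier list gets \eqn{\varepsilon = 0}, hence priority 0.
#'
#' @param node a node id in the network.
#' @param net a `hetero_network`.
#' @param input_terms the query pair (both inputs count toward `E_i`).
#' @param frontier_nodes nodes already held in either frontier list.
#' @param epsilon pin the random factor (e.g. 1 for deterministic scoring);
#'   default draws from \[0.5, 1\] with the current RNG.
#' @return non-negative priority.
#' @export
node_priority <- function(node, net, input_terms = character(),
                          frontier_nodes = character(), epsilon = NULL) {
  stopifnot(inherits(net, "hetero_network"))
  if (!node %in% net$nodes$node) stop_arg("unknown node: ", node)
  if (node %in% frontier_nodes) return(0)
  e <- net$edges
  inc <- e$node1 == node | e$node2 == node
  other <- ifelse(e$node1[inc] == node, e$node2[inc], e$node1[inc])
  ei <- sum(other %in% input_terms)
  eo <- sum(inc) - ei
  eps <- epsilon %||% stats::runif(1, 0.5, 1)
  exp(eo - ei) * eo * eps
}

# reconstruct term1 ... shared ... term2 from the two parent maps
reconstruct_path <- function(shared, par1, par2) {
  chain <- function(par, node) {
    out <- node
    while (!is.na(par[[node]])) {
      node <- par[[node]]
      out <- c(out, node)
    }
    out
  }
  left <- rev(chain(par1, shared))          # term1 .. shared
  right <- chain(par2, shared)[-1L]         # (shared ..) term2
  c(left, right)
}

#' Find a path between a disease and a gene
#'
#' Bidirectional layered search from both query terms. In the default
#' heuristic mode each frontier expands, in turn, its best unexpanded node by
#' [node_priority()] (seeded random factor; duplicated nodes score 0 and are
#' never re-added), so retrieval is fast but may miss an existing path. With
#' `exhaustive = TRUE` frontiers expand full breadth-first layers, which
#' guarantees that a shortest path with at most `maxlength` edges is found
#' iff one exists. The search stops once the frontier depths together exceed
#' `maxlength` or both frontiers are exhausted.
#'
#' @param net a `hetero_network`.
#' @param term1,term2 query node ids (disease and gene, conventionally).
#' @param maxlength maximum number of edges in the path (>= 1).
#' @param seed integer seed for the heuristic random factor.
#' @param exhaustive replace the heuristic ordering with full BFS layers.
#' @param all_paths if `TRUE`, return every path recoverable from the shared
#'   frontier nodes at the end of the search (list of `scored_path`).
#' @return a [scored_path()] with confidence attached (or a list of them
#'   when `all_paths = TRUE`), or `NULL` when no path within `maxlength` was
#'   found.
#' @export
find_path <- function(net, term1, term2, maxlength, seed = 1L,
                      exhaustive = FALSE, all_paths = FALSE) {
  stopifnot(inherits(net, "hetero_network"))
  for (t in c(term1, term2)) {
    if (!t %in% net$nodes$node) stop_arg("unknown term: ", t)
  }
  if (!is.numeric(maxlength) || length(maxlength) != 1L || maxlength < 1) {
    stop_arg("`maxlength` must be a positive integer")
  }
  maxlength <- as.integer(maxlength)
  if (identical(term1, term2)) stop_arg("term1 and term2 must differ")

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  adj <- net_adjacency(net)
  inputs <- c(term1, term2)
  deg <- stats::setNames(
    vapply(net$nodes$node, function(n) nrow(adj[[n]]), integer(1)),
    net$nodes$node)
  # E_i/E_o per node are fixed by the query pair; precompute the
  # epsilon-free part of W(n)
  wbase <- vapply(net$nodes$node, function(n) {
    ei <- sum(adj[[n]]$neighbor %in% inputs)
    eo <- deg[[n]] - ei
    exp(eo - ei) * eo
  }, numeric(1))
  names(wbase) <- net$nodes$node

  # per-frontier state: parent map, depth map, expandable queue
  mk <- function(origin) {
    list(par = stats::setNames(list(NA_character_), origin),
         depth = stats::setNames(0L, origin),
         queue = origin,        # unexpanded, in priority order
         layers = 0L)
  }
  f1 <- mk(term1)
  f2 <- mk(term2)

  seen <- function(f) names(f$depth)
  best_candidate <- function() {
    shared <- intersect(seen(f1), seen(f2))
    if (!length(shared)) return(NULL)
    tot <- f1$depth[shared] + f2$depth[shared]
    ok <- shared[tot <= maxlength]
    if (!length(ok)) return(NULL)
    ok <- ok[order(tot[ok], ok)]
    for (s in ok) {
      nodes <- reconstruct_path(s, f1$par, f2$par)
      if (!anyDuplicated(nodes)) return(nodes)
    }
    NULL
  }

  expand_node <- function(f, node, heuristic) {
    nb <- adj[[node]]$neighbor
    new <- setdiff(nb, seen(f))
    if (heuristic) {
      # a node already held in either frontier list scores zero and is not
      # re-added; fresh nodes get W with a random epsilon
      held <- union(seen(f1), seen(f2))
      fresh <- setdiff(new, held)
      dup_only <- setdiff(new, fresh)
      w <- wbase[fresh] * stats::runif(length(fresh), 0.5, 1)
      ord <- order(-w, fresh)
      add <- c(fresh[ord][w[ord] > 0], dup_only)
      # duplicated-in-other-frontier nodes still enter this frontier's
      # parent map (they are exactly the meeting points), but with zero
      # priority they are never expanded
      queue_add <- fresh[ord][w[ord] > 0]
    } else {
      add <- sort(new)
      queue_add <- add
    }
    if (length(add)) {
      f$par[add] <- node
      f$depth[add] <- f$depth[[node]] + 1L
      f$queue <- c(f$queue, queue_add)
    }
    f$queue <- setdiff(f$queue, node)
    f
  }

  if (exhaustive) {
    repeat {
      found <- best_candidate()
      # a candidate found while layers can still shrink it is only returned
      # once no shorter meeting is possible
      if (!is.null(found) &&
          (length(found) - 1L <= f1$layers + f2$layers ||
           (!length(f1$queue) && !length(f2$queue)) ||
           f1$layers + f2$layers >= maxlength)) break
      if (f1$layers + f2$layers >= maxlength) break
      if (!length(f1$queue) && !length(f2$queue)) break
      # expand one full layer on the shallower non-exhausted side
      side <- if (length(f1$queue) &&
                  (f1$layers <= f2$layers || !length(f2$queue))) 1L else 2L
      f <- if (side == 1L) f1 else f2
      layer <- f$queue[f$depth[f$queue] == f$layers]
      if (!length(layer)) { # queue holds only deeper strays; advance
        if (side == 1L) f1$layers <- f1$layers + 1L
        else f2$layers <- f2$layers + 1L
        next
      }
      for (nd in layer) f <- expand_node(f, nd, heuristic = FALSE)
      f$layers <- f$layers + 1L
      if (side == 1L) f1 <- f else f2 <- f
    }
  } else {
    repeat {
      found <- best_candidate()
      if (!is.null(found)) break
      if (f1$layers + f2$layers >= maxlength) break
      if (!length(f1$queue) && !length(f2$queue)) break
      for (side in 1:2) {
        f <- if (side == 1L) f1 else f2
        if (!length(f$queue)) next
        head_node <- f$queue[1L]
        d <- f$depth[[head_node]]
        f <- expand_node(f, head_node, heuristic = TRUE)
        f$layers <- max(f$layers, d + 1L)
        if (side == 1L) f1 <- f else f2 <- f
      }
    }
  }

  if (all_paths) {
    shared <- intersect(seen(f1), seen(f2))
    tot <- f1$depth[shared] + f2$depth[shared]
    shared <- shared[tot <= maxlength]
    tot <- f1$depth[shared] + f2$depth[shared]
    shared <- shared[order(tot, shared)]
    paths <- list()
    for (s in shared) {
      nodes <- reconstruct_path(s, f1$par, f2$par)
      if (!anyDuplicated(nodes) && length(nodes) - 1L <= maxlength) {
        paths[[length(paths) + 1L]] <- scored_path(net, nodes)
      }
    }
    return(paths)
  }
  found <- best_candidate()
  if (is.null(found)) return(NULL)
  scored_path(net, found)
}
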