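#' Brute-force reference solver
#'
#' Definitionally correct solver used as the oracle for the sweep's
#' exactness contract. It enumerates vertex subsets of the compatibility
#' graph by depth-first extension, keeping exactly the subsets in which
#' every two members are adjacent (which enforces one-to-one pairing and
#' nonzero distances) and every two member RPDs are compatible. Both
#' conditions are hereditary, so infeasible prefixes are pruned without
#' losing any feasible subset. All subsets of maximum cardinality are
#' returned.
#'
#' @inheritParams mmm_solve
#' @param max_vertices safety guard: refuse graphs with more vertices
#'   (subset space too large for an oracle).
#' @return an `mmm_result` (with sweep-specific stats fields zero).
#' @export
brute_force_solve <- function(g, tol, max_vertices = 20L) {
  stopifnot(inherits(g, "mmm_graph"))
  tol <- as_tolerance(tol)
  nv <- nrow(g$vertices)
  if (nv > max_vertices) {
    stop(sprintf("brute_force_solve: %d vertices exceeds guard of %d",
                 nv, max_vertices))
  }
  stats <- list(vertices = nv, edges = g$n_edges,
                subproblems = 0L, pruned = 0L)
  if (nv == 0L) return(new_result(0L, list(), tol, "all", stats))

  best <- 0L                 # the DFS records singletons itself
  best_matches <- list()
  adj <- g$adj
  rpds <- g$rpd

  extend <- function(cur, start) {
    if (start > nv) return()
    for (v in seq.int(start, nv)) {
      new_cur <- c(cur, v)
      if (all_pairs_compatible(new_cur, adj, rpds, tol)) {
        sz <- length(new_cur)
        if (sz > best) {
          best <<- sz
          best_matches <<- list(new_cur)
        } else if (sz == best) {
          best_matches[[length(best_matches) + 1L]] <<- new_cur
        }
        extend(new_cur, v + 1L)
      }
    }
  }
  extend(integer(0), 1L)
  new_result(best, canonicalize_matches(best_matches), tol, "all", stats)
}

all_pairs_compatible <- function(members, adj, rpds, tol) {
  k <- length(members)
  if (k < 2L) return(TRUE)
  rs <- numeric(0)
  for (x in seq_len(k - 1L)) {
    for (y in seq.int(x + 1L, k)) {
      if (!adj[members[x], members[y]]) return(FALSE)
      rs <- c(rs, rpds[members[x], members[y]])
    }
  }
  if (tol$alpha >= 1) return(TRUE)
  max(rs) <= tol$delta * min(rs)
}
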