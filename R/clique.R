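#' Exact maximum-clique search (Ostergard branch and bound)
#'
#' Branch-and-bound maximum-clique engine for the small dense subgraphs
#' generated by the solver sweep. Vertices are processed in descending
#' index order and an incremental bound table `c[i]` (the maximum clique
#' size within the suffix subgraph induced by vertices `i..n`) prunes the
#' recursion, following Ostergard's scheme. Two entry points are provided:
#' [max_cliques_all()] continues the search past the first optimum and
#' collects every maximum clique exactly once; [max_clique_one()] keeps
#' the early-exit behaviour of the original algorithm and returns a single
#' witness, which is faster when only the score is needed.
#'
#' @param adj symmetric logical adjacency matrix with `FALSE` diagonal
#'   (no self-loops).
#' @return For `max_cliques_all`: list with `size` (maximum clique
#'   cardinality, 0 for an empty graph) and `cliques` (list of sorted
#'   integer vertex vectors in lexicographic order; for an empty graph a
#'   single empty clique). For `max_clique_one`: list with `size` and
#'   `clique`, or `size = NA` / `clique = NULL` when no clique of at least
#'   `lower_bound` vertices exists ("no improvement").
#' @name clique_engine
NULL

check_adjacency <- function(adj) {
  if (length(adj) == 0) return(matrix(FALSE, 0, 0))
  stopifnot(is.matrix(adj), is.logical(adj), nrow(adj) == ncol(adj))
  if (any(diag(adj))) stop("self-loop in adjacency matrix")
  if (!identical(adj, t(adj))) stop("adjacency matrix must be symmetric")
  adj
}

# Shared recursion. `collect_all` switches between tie enumeration (prune
# only branches that cannot *reach* the record) and the classic
# first-optimum early exit (prune branches that cannot *beat* it).
# A clique is recorded when its candidate set runs dry; a maximum clique
# always ends at such a leaf, and any recorded non-maximal tie is evicted
# as soon as its proper superset improves the record.
ostergard_search <- function(adj, lower_bound = 0L, collect_all = TRUE) {
  n <- nrow(adj)
  best <- as.integer(lower_bound)
  best_cliques <- list()
  found <- FALSE        # single mode: record improved in the current tree
  cbound <- integer(n)  # c[i]: max clique size within suffix {i..n}

  expand <- function(cand, cur) {
    if (!length(cand)) {
      sz <- length(cur)
      if (sz > best) {
        best <<- sz
        best_cliques <<- list(cur)
        found <<- TRUE
      } else if (collect_all && sz == best && sz > 0L) {
        best_cliques[[length(best_cliques) + 1L]] <<- cur
      }
      return()
    }
    while (length(cand)) {
      feasible <- length(cur) + length(cand)
      if (feasible < best || (!collect_all && feasible <= best)) return()
      v <- cand[[1]]
      reach <- length(cur) + cbound[[v]]
      if (reach < best || (!collect_all && reach <= best)) return()
      cand <- cand[-1]
      expand(cand[adj[v, cand]], c(cur, v))
      if (!collect_all && found) return()
    }
  }

  for (i in rev(seq_len(n))) {
    found <- FALSE
    suffix <- if (i < n) seq.int(i + 1L, n) else integer(0)
    expand(suffix[adj[i, suffix]], i)
    cbound[[i]] <- best
  }
  list(size = best, cliques = best_cliques)
}

clique_sort_key <- function(cl) paste(sprintf("%08d", cl), collapse = ",")

#' @rdname clique_engine
#' @export
max_cliques_all <- function(adj) {
  adj <- check_adjacency(adj)
  n <- nrow(adj)
  if (n == 0) return(list(size = 0L, cliques = list(integer(0))))
  res <- ostergard_search(adj, lower_bound = 0L, collect_all = TRUE)
  cliques <- lapply(res$cliques, sort.int)
  cliques <- cliques[order(vapply(cliques, clique_sort_key, character(1)))]
  list(size = res$size, cliques = cliques)
}

#' @rdname clique_engine
#' @param lower_bound smallest clique size of interest; the search reports
#'   "no improvement" (`size = NA`) if the true maximum is below it.
#' @export
max_clique_one <- function(adj, lower_bound = 0L) {
  adj <- check_adjacency(adj)
  n <- nrow(adj)
  lower_bound <- max(0L, as.integer(lower_bound))
  if (n == 0) {
    if (lower_bound > 0L) return(list(size = NA_integer_, clique = NULL))
    return(list(size = 0L, clique = integer(0)))
  }
  res <- ostergard_search(adj, lower_bound = lower_bound - 1L,
                          collect_all = FALSE)
  if (!length(res$cliques)) return(list(size = NA_integer_, clique = NULL))
  list(size = res$size, clique = sort.int(res$cliques[[1L]]))
}
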