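#' Solve the coevolution matching problem exactly
#'
#' Finds the largest *matches* between two protein families: sets of
#' one-to-one A-to-B pairings whose ratios of paired distances (RPDs) are
#' all mutually compatible at tolerance `alpha`. The size of the largest
#' match is the coevolution (MMM) score.
#'
#' The sweep treats every edge of the compatibility graph in turn as the
#' minimum-RPD edge `e_min` of a candidate match and works backwards to
#' the largest matches anchored on it:
#'
#' 1. For each vertex `v_i`, its neighbours are sorted in ascending order
#'    of the RPD of their edge to `v_i` (ties broken by ascending vertex
#'    index, so the order is total and deterministic).
#' 2. For each neighbour `v_j` with `j > i` (each edge is anchored once),
#'    `e_min = edge(v_i, v_j)`.
#' 3. Neighbours `v_k` strictly ahead of `v_j` in the sorted list enter
#'    the subgraph `H` when their edges to both `v_i` and `v_j` exist and
#'    are forward-compatible with `e_min`; the scan stops at the first
#'    `v_k` whose edge to `v_i` is no longer forward-compatible (the list
#'    is sorted on exactly that RPD). When `R(v_i,v_k)` or `R(v_j,v_k)`
#'    ties `R(e_min)` exactly, `v_k` is admitted only if `k > i` —
#'    otherwise the same match would be rediscovered from a later anchor.
#' 4. `H`'s edges join members whose mutual RPD is forward-compatible with
#'    `e_min`; on an exact tie with `R(e_min)` both endpoint indices must
#'    exceed `i`, again to keep every match unique to one anchor.
#' 5. If `|H| + 2` cannot reach the incumbent score the clique search is
#'    skipped.
#' 6. The maximum cliques of `H`, each extended by `v_i` and `v_j`, are
#'    matches; the globally largest ones are kept (ties collected).
#'
#' Every edge of `H` lies in the band `[R(e_min), delta * R(e_min)]`, so
#' all its edges are pairwise compatible by construction and every clique
#' of `H` plus the anchor pair is a genuine match. RPD tie tests use exact
#' floating-point equality: the ties the dedup rules target arise from
#' identical distance values, which produce bit-identical quotients.
#'
#' Scores below 3 are natural degenerate cases: a single edge is a match
#' of size 2 (no RPD pair to test), a lone vertex a match of size 1, the
#' empty graph scores 0. They are reported with `trivial = TRUE` so
#' downstream screens can filter at size >= 3.
#'
#' @param g a compatibility graph from [build_compatibility_graph()].
#' @param tol a [tolerance()] object or bare alpha in \[0, 1\].
#' @param maxtrees `"all"` to enumerate every maximum match, `"one"`
#'   (alias `"1"`) to return a single witness faster.
#' @return object of class `mmm_result`: list with `score`, `matches`
#'   (list of sorted vertex-index vectors, lexicographic order; under
#'   `maxtrees = "one"` at most one), `trivial` (`TRUE` when score < 3),
#'   `alpha`, `maxtrees`, and `stats` (vertices, edges, subproblems
#'   solved, subproblems pruned).
#' @export
mmm_solve <- function(g, tol, maxtrees = c("all", "one", "1")) {
  stopifnot(inherits(g, "mmm_graph"))
  tol <- as_tolerance(tol)
  maxtrees <- match.arg(as.character(maxtrees), c("all", "one", "1"))
  if (maxtrees == "1") maxtrees <- "one"
  single <- maxtrees == "one"
  nv <- nrow(g$vertices)
  adj <- g$adj
  rpds <- g$rpd
  stats <- list(vertices = nv, edges = g$n_edges,
                subproblems = 0L, pruned = 0L)

  if (nv == 0L) {
    return(new_result(0L, list(), tol, maxtrees, stats))
  }
  if (g$n_edges == 0L) {
    matches <- lapply(seq_len(nv), identity)
    if (single) matches <- matches[1]
    return(new_result(1L, matches, tol, maxtrees, stats))
  }

  best <- 2L
  best_matches <- list()

  for (i in seq_len(nv)) {
    nb <- which(adj[i, ])
    if (!length(nb)) next
    r_i <- rpds[i, nb]
    ord <- order(r_i, nb)            # ascending RPD, ties by vertex index
    nb <- nb[ord]; r_i <- r_i[ord]
    n_nb <- length(nb)
    for (pos_j in seq_len(n_nb)) {
      j <- nb[pos_j]
      if (j <= i) next
      r_min <- r_i[pos_j]
      # step 3: collect H's vertices from the tail of the sorted list
      H <- integer(0)
      pos_k <- pos_j + 1L
      while (pos_k <= n_nb) {
        r_ik <- r_i[pos_k]
        if (!forward_compatible(r_min, r_ik, tol)) break  # sorted: stop here
        k <- nb[pos_k]
        pos_k <- pos_k + 1L
        if (!adj[j, k]) next
        r_jk <- rpds[j, k]
        if (!forward_compatible(r_min, r_jk, tol)) next
        if ((r_ik == r_min || r_jk == r_min) && k <= i) next
        H <- c(H, k)
      }
      nh <- length(H)
      if (nh + 2L < best) {          # step 5: |H| + 2 cannot beat incumbent
        stats$pruned <- stats$pruned + 1L
        next
      }
      # step 4: H's edge set
      h_adj <- matrix(FALSE, nh, nh)
      if (nh >= 2L) {
        for (x in seq_len(nh - 1L)) {
          vx <- H[[x]]
          for (y in seq.int(x + 1L, nh)) {
            vy <- H[[y]]
            if (!adj[vx, vy]) next
            r_xy <- rpds[vx, vy]
            if (!forward_compatible(r_min, r_xy, tol)) next
            if (r_xy == r_min && (vx <= i || vy <= i)) next
            h_adj[x, y] <- TRUE
            h_adj[y, x] <- TRUE
          }
        }
      }
      stats$subproblems <- stats$subproblems + 1L
      if (single) {
        cl <- max_clique_one(h_adj, lower_bound = best - 1L)
        if (!is.na(cl$size)) {
          cand <- sort.int(c(i, j, H[cl$clique]))
          sz <- length(cand)
          if (sz > best || (sz == best && !length(best_matches))) {
            best <- sz
            best_matches <- list(cand)
          }
        }
      } else {
        cl <- max_cliques_all(h_adj)
        sz <- cl$size + 2L
        if (sz < best) next
        cands <- lapply(cl$cliques, function(c0) sort.int(c(i, j, H[c0])))
        if (sz > best) {
          best <- sz
          best_matches <- cands
        } else {
          best_matches <- c(best_matches, cands)
        }
      }
    }
  }

  if (!length(best_matches)) {
    # every edge is a size-2 match; reachable when best stayed at 2 and no
    # (i, j) anchor was ever accepted -- cannot happen since any edge with
    # j > i yields H (possibly empty) and a size >= 2 candidate
    best <- 2L
    best_matches <- edge_list(adj)
    if (single) best_matches <- best_matches[1]
  }
  best_matches <- canonicalize_matches(best_matches)
  if (single) best_matches <- best_matches[1]
  new_result(best, best_matches, tol, maxtrees, stats)
}

new_result <- function(score, matches, tol, maxtrees, stats) {
  structure(list(score = as.integer(score), matches = matches,
                 trivial = score < 3L, alpha = tol$alpha,
                 maxtrees = maxtrees, stats = stats),
            class = "mmm_result")
}

edge_list <- function(adj) {
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  lapply(seq_len(nrow(idx)), function(r) c(idx[r, 1], idx[r, 2]))
}

canonicalize_matches <- function(matches) {
  matches <- lapply(matches, function(m) sort.int(as.integer(m)))
  if (!length(matches)) return(matches)
  matches[order(vapply(matches, clique_sort_key, character(1)))]
}

#' @export
print.mmm_result <- function(x, ...) {
  cat(sprintf("<mmm_result> score = %d (%s), %d match%s, alpha = %g\n",
              x$score, if (x$trivial) "trivial" else "size >= 3",
              length(x$matches), if (length(x$matches) == 1) "" else "es",
              x$alpha))
  invisible(x)
}

#' Validate a candidate match against the graph
#'
#' Checks the definition directly: members are pairwise adjacent (hence
#' one-to-one, with all underlying distances nonzero) and every one of the
#' `choose(k, 2)` RPDs among them is compatible with every other at the
#' given tolerance.
#'
#' @param pairs integer vector of vertex indices into `g$vertices`.
#' @inheritParams mmm_solve
#' @return `TRUE` or `FALSE`.
#' @export
is_match <- function(pairs, g, tol) {
  stopifnot(inherits(g, "mmm_graph"))
  tol <- as_tolerance(tol)
  pairs <- as.integer(pairs)
  if (anyDuplicated(pairs)) return(FALSE)
  k <- length(pairs)
  if (k <= 1L) return(TRUE)
  for (x in seq_len(k - 1L)) {
    for (y in seq.int(x + 1L, k)) {
      if (!g$adj[pairs[x], pairs[y]]) return(FALSE)
    }
  }
  rs <- match_rpds(pairs, g)
  if (length(rs) >= 2L) {
    # all pairwise compatible <=> extremes compatible under the band model
    for (x in seq_len(length(rs) - 1L)) {
      for (y in seq.int(x + 1L, length(rs))) {
        if (!compatible(rs[x], rs[y], tol)) return(FALSE)
      }
    }
  }
  TRUE
}

match_rpds <- function(pairs, g) {
  k <- length(pairs)
  if (k < 2L) return(numeric(0))
  out <- numeric(0)
  for (x in seq_len(k - 1L)) {
    for (y in seq.int(x + 1L, k)) {
      out <- c(out, g$rpd[pairs[x], pairs[y]])
    }
  }
  out
}

#' Legacy triplet-based match criterion
#'
#' The original algorithm accepted a set of `k >= 3` pairings as a match
#' when every 3-subset formed a match of size 3, i.e. when the three RPDs
#' within each triplet are mutually compatible. This only ever compares
#' RPDs of edges that share a vertex; RPDs of vertex-disjoint edges are
#' never tested against each other, so the criterion is strictly weaker
#' than the all-pairs definition for `k > 3`. Provided as a reference
#' comparator, not a production path.
#'
#' @param pairs integer vector of at least 3 vertex indices, one-to-one.
#' @inheritParams mmm_solve
#' @return `TRUE` or `FALSE`.
#' @export
legacy_mmm_match_test <- function(pairs, g, tol) {
  stopifnot(inherits(g, "mmm_graph"))
  tol <- as_tolerance(tol)
  pairs <- as.integer(pairs)
  if (length(pairs) < 3L) stop("legacy match test requires at least 3 pairs")
  if (anyDuplicated(pairs)) stop("pairs must be distinct")
  for (trip in utils::combn(pairs, 3L, simplify = FALSE)) {
    rs <- match_rpds(trip, g)
    if (anyNA(rs)) return(FALSE)          # missing edge within the triplet
    if (!compatible(rs[1], rs[2], tol) ||
        !compatible(rs[1], rs[3], tol) ||
        !compatible(rs[2], rs[3], tol)) return(FALSE)
  }
  TRUE
}

#' Format a result's matches with protein labels
#'
#' @param x an `mmm_result`.
#' @param g the compatibility graph the result was computed on.
#' @return list of data.frames with columns `a` and `b` (protein labels).
#' @export
match_labels <- function(x, g) {
  stopifnot(inherits(x, "mmm_result"), inherits(g, "mmm_graph"))
  lapply(x$matches, function(m) {
    data.frame(a = g$vertices$a_label[m], b = g$vertices$b_label[m],
               stringsAsFactors = FALSE)
  })
}
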