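#' Tolerance model for RPD compatibility
#'
#' The tolerance parameter `alpha` in \[0, 1\] controls how much two
#' ratios of paired distances (RPDs) may differ and still be considered
#' compatible: 0 requires exact equality, 1 places no restriction. The
#' comparison is carried out through a derived multiplicative expansion
#' factor `delta >= 1`: two RPDs are compatible when the larger is at most
#' `delta` times the smaller.
#'
#' The mapping used is `delta = 1 / (1 - alpha)` for `alpha < 1` and
#' `delta = Inf` at `alpha = 1`. It satisfies every boundary requirement of
#' the model (exactness at 0, no restriction at 1, monotone in `alpha`)
#' and is isolated here so an alternative mapping is a one-line change.
#'
#' @param alpha numeric scalar in \[0, 1\].
#' @return object of class `mmm_tol` with fields `alpha` and `delta`.
#' @export
tolerance <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("alpha must be a single number in [0, 1]")
  }
  delta <- if (alpha >= 1) Inf else 1 / (1 - alpha)
  structure(list(alpha = alpha, delta = delta), class = "mmm_tol")
}

as_tolerance <- function(tol) {
  if (inherits(tol, "mmm_tol")) tol else tolerance(tol)
}

#' @export
print.mmm_tol <- function(x, ...) {
  cat(sprintf("<mmm_tol> alpha = %g, delta = %g\n", x$alpha, x$delta))
  invisible(x)
}

#' Are two RPDs compatible?
#'
#' Symmetric test: `r1` and `r2` are compatible iff
#' `max(r1, r2) <= delta * min(r1, r2)`. At `alpha = 0` this demands exact
#' equality; at `alpha = 1` it is unconditionally true.
#'
#' @param r1,r2 positive RPD values (vectorized, recycled).
#' @param tol an [tolerance()] object or a bare alpha value.
#' @return logical vector.
#' @export
compatible <- function(r1, r2, tol) {
  tol <- as_tolerance(tol)
  if (any(r1 <= 0) || any(r2 <= 0)) stop("RPDs must be positive")
  if (tol$alpha >= 1) return(rep(TRUE, length.out = max(length(r1), length(r2))))
  pmax(r1, r2) <= tol$delta * pmin(r1, r2)
}

#' Is an RPD forward-compatible with a reference minimum?
#'
#' One-sided variant of [compatible()] used by the solver: `r` is
#' forward-compatible with the anchor `r_min` iff
#' `r_min <= r <= delta * r_min`. Unlike compatibility this relation is
#' not symmetric (both directions hold only at equality). If every edge of
#' a set is forward-compatible with the set's minimum-RPD edge, then all
#' edges of the set are pairwise compatible, since every RPD then lies in
#' the band `[r_min, delta * r_min]`.
#'
#' @param r_min positive reference RPD (the anchor edge's RPD).
#' @param r positive RPD under test.
#' @inheritParams compatible
#' @return logical vector.
#' @export
forward_compatible <- function(r_min, r, tol) {
  tol <- as_tolerance(tol)
  if (any(r_min <= 0) || any(r <= 0)) stop("RPDs must be positive")
  r_min <= r & (tol$alpha >= 1 | r <= tol$delta * r_min)
}

#' Ratio of paired distances between two candidate pairings
#'
#' For two A-to-B pairings u = (a_u, b_x) and v = (a_v, b_y), the RPD is
#' `d_A(a_u, a_v) / d_B(b_x, b_y)`. When either distance is zero the RPD
#' is undefined and `NA` is returned: such vertex pairs carry no edge in
#' the compatibility graph.
#'
#' @param mat_a,mat_b [mmm_dist()] matrices for families A and B.
#' @param u,v length-2 integer vectors `c(a_index, b_index)`.
#' @return positive numeric RPD, or `NA_real_` when undefined.
#' @export
rpd <- function(mat_a, mat_b, u, v) {
  u <- as.integer(u); v <- as.integer(v)
  na <- length(mat_a$labels); nb <- length(mat_b$labels)
  if (any(c(u[1], v[1]) < 1L) || any(c(u[1], v[1]) > na) ||
      any(c(u[2], v[2]) < 1L) || any(c(u[2], v[2]) > nb)) {
    stop("vertex index out of range")
  }
  if (u[1] == v[1] || u[2] == v[2]) {
    stop("RPD undefined for vertices sharing a row or column")
  }
  da <- mat_a$values[u[1], v[1]]
  db <- mat_b$values[u[2], v[2]]
  if (da == 0 || db == 0) return(NA_real_)
  da / db
}

#' Build the compatibility graph for two families
#'
#' Vertices are all candidate A-to-B pairings `(a_i, b_j)` — restricted to
#' same-species pairs when both matrices carry species tags — indexed in
#' row-major `(a_index, b_index)` lexicographic order. An edge joins two
#' vertices unless they share a row or a column (which would force a zero
#' distance into the RPD) or either underlying distance is exactly zero;
#' each edge is labelled with its RPD `d_A / d_B`.
#'
#' @param mat_a,mat_b [mmm_dist()] objects (family A first: RPD numerators
#'   come from `mat_a`).
#' @return object of class `mmm_graph`: list with `vertices` (data.frame
#'   of `a`, `b` indices and labels), `adj` (logical adjacency matrix),
#'   `rpd` (numeric matrix, `NA` where no edge), `n_edges`, and the two
#'   input label vectors.
#' @export
build_compatibility_graph <- function(mat_a, mat_b) {
  stopifnot(inherits(mat_a, "mmm_dist"), inherits(mat_b, "mmm_dist"))
  na <- length(mat_a$labels); nb <- length(mat_b$labels)
  use_species <- !is.null(mat_a$species) && !is.null(mat_b$species)
  a_idx <- rep(seq_len(na), each = nb)
  b_idx <- rep(seq_len(nb), times = na)
  if (use_species) {
    keep <- mat_a$species[a_idx] == mat_b$species[b_idx]
    a_idx <- a_idx[keep]; b_idx <- b_idx[keep]
  }
  nv <- length(a_idx)
  vertices <- data.frame(
    a = a_idx, b = b_idx,
    a_label = if (nv) mat_a$labels[a_idx] else character(0),
    b_label = if (nv) mat_b$labels[b_idx] else character(0),
    stringsAsFactors = FALSE)
  adj <- matrix(FALSE, nv, nv)
  rpds <- matrix(NA_real_, nv, nv)
  if (nv >= 2) {
    da <- mat_a$values[cbind(rep(a_idx, times = nv), rep(a_idx, each = nv))]
    db <- mat_b$values[cbind(rep(b_idx, times = nv), rep(b_idx, each = nv))]
    same_row <- outer(a_idx, a_idx, "==")
    same_col <- outer(b_idx, b_idx, "==")
    ok <- !same_row & !same_col &
      matrix(da != 0 & db != 0, nv, nv)
    adj <- ok
    rpds[ok] <- (da / db)[as.vector(ok)]
  }
  structure(list(vertices = vertices, adj = adj, rpd = rpds,
                 n_edges = sum(adj) / 2,
                 labels_a = mat_a$labels, labels_b = mat_b$labels),
            class = "mmm_graph")
}

#' @export
print.mmm_graph <- function(x, ...) {
  cat(sprintf("<mmm_graph> %d vertices, %d edges\n",
              nrow(x$vertices), x$n_edges))
  invisible(x)
}
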