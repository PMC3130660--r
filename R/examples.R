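#' Constructed demonstration instances
#'
#' `example_triplet_pair()` builds the canonical worked example of a
#' size-3 match: family A holds five proteins of which {a2, a3, a5} have
#' mutual distances 0.4, 0.6, 0.8; family B holds eight proteins of which
#' {b3, b7, b8} have mutual distances 0.2, 0.3, 0.4. Every paired-distance
#' ratio between the three candidate pairings equals 2, so
#' {(a2, b3), (a3, b7), (a5, b8)} is a match of size 3 at any tolerance.
#' Species tags admit exactly those three pairings; all other proteins
#' carry unique species and padding distances.
#'
#' `example_legacy_witness()` builds a four-pairing instance on which the
#' legacy triplet-based criterion and the all-pairs criterion disagree at
#' `alpha = 0.1` (`delta = 10/9`). The B distances are all 1, so RPDs
#' equal the A distances: the two vertex-disjoint pairings have RPDs 1.0
#' and 1.2 (ratio 1.2 > delta, incompatible), while every RPD pair that
#' shares a vertex is within delta (all cross distances are 1.095). The
#' triplet test only ever compares RPDs of edges sharing a vertex, so it
#' accepts the full set of four pairings; the all-pairs definition
#' rejects it and the true score is 3.
#'
#' @return list with `mat_a`, `mat_b` ([mmm_dist()] objects carrying
#'   species tags) and, for the triplet instance, `expected_match` (the
#'   label pairing it is built to contain).
#' @name example_instances
NULL

#' @rdname example_instances
#' @export
example_triplet_pair <- function() {
  labels_a <- paste0("a", 1:5)
  labels_b <- paste0("b", 1:8)
  # deterministic positive padding, symmetric, well away from ratio 2
  pad <- function(n, offset) {
    m <- outer(seq_len(n), seq_len(n),
               function(i, j) offset + 0.07 * abs(i - j))
    diag(m) <- 0
    m
  }
  va <- pad(5, 0.9)
  va[2, 3] <- va[3, 2] <- 0.4   # d1
  va[2, 5] <- va[5, 2] <- 0.6   # d2
  va[3, 5] <- va[5, 3] <- 0.8   # d3
  vb <- pad(8, 1.3)
  vb[3, 7] <- vb[7, 3] <- 0.2   # d4
  vb[3, 8] <- vb[8, 3] <- 0.3   # d5
  vb[7, 8] <- vb[8, 7] <- 0.4   # d6
  species_a <- c("uA1", "sp1", "sp2", "uA4", "sp3")
  species_b <- c("uB1", "uB2", "sp1", "uB4", "uB5", "uB6", "sp2", "sp3")
  list(
    mat_a = mmm_dist(va, labels_a, species = species_a),
    mat_b = mmm_dist(vb, labels_b, species = species_b),
    expected_match = data.frame(a = c("a2", "a3", "a5"),
                                b = c("b3", "b7", "b8"),
                                stringsAsFactors = FALSE))
}

#' @rdname example_instances
#' @export
example_legacy_witness <- function() {
  labels <- paste0("p", 1:4)
  va <- matrix(1.095, 4, 4)
  va[1, 2] <- va[2, 1] <- 1.0
  va[3, 4] <- va[4, 3] <- 1.2
  diag(va) <- 0
  vb <- matrix(1, 4, 4)
  diag(vb) <- 0
  sp <- paste0("sp", 1:4)
  list(mat_a = mmm_dist(va, paste0("a_", labels), species = sp),
       mat_b = mmm_dist(vb, paste0("b_", labels), species = sp))
}
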