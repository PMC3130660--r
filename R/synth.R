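#' Specification of a synthetic matrix pair
#'
#' Describes the world the fixture generator emulates: two families whose
#' distance matrices derive from random additive trees, with a planted
#' coevolving subset in which the B distances are a common multiple of
#' the paired A distances, up to controlled multiplicative noise.
#'
#' @param n_a,n_b family sizes (at least 2).
#' @param shared_species number of species present in both families; the
#'   first `shared_species` proteins of each family carry matching species
#'   tags, all remaining proteins carry family-unique tags.
#' @param planted_size size of the planted coevolving subset (pairs
#'   `(a_i, b_i)`, `i = 1..planted_size`); must not exceed
#'   `min(n_a, n_b, shared_species)`.
#' @param scale positive factor applied to the planted A distances to
#'   produce the paired B distances.
#' @param noise multiplicative perturbation half-width `eps >= 0`: each
#'   planted B distance is additionally multiplied by an independent draw
#'   from `U[1 - eps, 1 + eps]`.
#' @param alpha the tolerance the fixture is meant to be solved at; the
#'   constructor asserts that the noise leaves the planted subset intact,
#'   i.e. `(1 + eps) / (1 - eps) <= delta(alpha)`.
#' @param seed RNG seed; identical specs generate identical matrices.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_a = 8L, n_b = 10L, shared_species = 6L,
                       planted_size = 5L, scale = 2, noise = 0.02,
                       alpha = 0.1, seed = 1L) {
  spec <- list(n_a = as.integer(n_a), n_b = as.integer(n_b),
               shared_species = as.integer(shared_species),
               planted_size = as.integer(planted_size),
               scale = as.numeric(scale), noise = as.numeric(noise),
               alpha = as.numeric(alpha), seed = as.integer(seed))
  if (spec$n_a < 2L || spec$n_b < 2L) stop("family sizes must be at least 2")
  if (spec$scale <= 0) stop("scale must be positive")
  if (spec$noise < 0 || spec$noise >= 1) stop("noise must be in [0, 1)")
  if (spec$planted_size < 0L ||
      spec$planted_size > min(spec$n_a, spec$n_b, spec$shared_species)) {
    stop("planted_size must be <= min(n_a, n_b, shared_species)")
  }
  tol <- tolerance(spec$alpha)
  if ((1 + spec$noise) / (1 - spec$noise) > tol$delta) {
    stop(sprintf(
      "infeasible spec: noise %g breaks the planted subset at alpha = %g (need (1+eps)/(1-eps) <= %g)",
      spec$noise, spec$alpha, tol$delta))
  }
  structure(spec, class = "synth_spec")
}

# Additive random tree -> pairwise leaf distances in a fixed label order.
# Sequential random joins with Exponential(mean 0.1) branch lengths, the
# typical magnitude of protein substitution distances.
random_tree_distances <- function(n, labels) {
  tree <- ape::rtree(n, tip.label = labels, br = stats::rexp, rate = 10)
  d <- ape::cophenetic.phylo(tree)
  d[labels, labels]
}

#' Generate a synthetic matrix pair with a planted match
#'
#' Family A's distances come from a random additive tree. Family B's come
#' from an independent random tree, except that the distances within the
#' planted subset are overwritten with `scale * d_A * f`, `f` drawn
#' independently per distance from `U[1 - noise, 1 + noise]`. The RPD of
#' any two planted pairings is therefore `1 / (scale * f)`, so at
#' `noise = 0` all planted RPDs coincide and the planted subset is a
#' perfect match of size `planted_size` at any alpha.
#'
#' @param spec a [synth_spec()].
#' @return list with `mat_a`, `mat_b` ([mmm_dist()] objects with species
#'   tags), `planted` (data.frame of planted `a`/`b` indices and labels)
#'   and `spec`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  shared <- sprintf("sp%02d", seq_len(spec$shared_species))
  species_a <- c(shared, sprintf("onlyA%02d",
                                 seq_len(spec$n_a - spec$shared_species)))
  species_b <- c(shared, sprintf("onlyB%02d",
                                 seq_len(spec$n_b - spec$shared_species)))
  species_a <- species_a[seq_len(spec$n_a)]
  species_b <- species_b[seq_len(spec$n_b)]
  # labels embed the species tag (delimiter rule "|", field 2), mimicking
  # identifiers that carry a species mnemonic
  labels_a <- sprintf("A%02d|%s", seq_len(spec$n_a), species_a)
  labels_b <- sprintf("B%02d|%s", seq_len(spec$n_b), species_b)
  va <- random_tree_distances(spec$n_a, labels_a)
  vb <- random_tree_distances(spec$n_b, labels_b)
  ps <- spec$planted_size
  if (ps >= 2L) {
    for (u in seq_len(ps - 1L)) {
      for (v in seq.int(u + 1L, ps)) {
        f <- stats::runif(1, 1 - spec$noise, 1 + spec$noise)
        vb[u, v] <- vb[v, u] <- spec$scale * va[u, v] * f
      }
    }
  }
  planted <- data.frame(a = seq_len(ps), b = seq_len(ps),
                        a_label = labels_a[seq_len(ps)],
                        b_label = labels_b[seq_len(ps)],
                        stringsAsFactors = FALSE)
  list(mat_a = mmm_dist(va, labels_a, species = species_a),
       mat_b = mmm_dist(vb, labels_b, species = species_b),
       planted = planted, spec = spec)
}

#' Map planted pairings to vertex indices of a compatibility graph
#'
#' @param pair output of [generate_pair()].
#' @param g graph built from the pair's matrices.
#' @return integer vector of vertex indices (NA if a planted pairing is
#'   not a vertex, which indicates an inconsistent species assignment).
#' @export
planted_vertices <- function(pair, g) {
  stopifnot(inherits(g, "mmm_graph"))
  vapply(seq_len(nrow(pair$planted)), function(r) {
    hit <- which(g$vertices$a == pair$planted$a[r] &
                   g$vertices$b == pair$planted$b[r])
    if (length(hit) == 1L) hit else NA_integer_
  }, integer(1))
}

#' Write a fixture pair to disk
#'
#' Emits `<base>_A.phy` and `<base>_B.phy` (PHYLIP square), two species
#' maps `<base>_A.species.tsv` / `<base>_B.species.tsv`, and a JSON
#' sidecar `<base>.json` recording the generating spec and the planted
#' match.
#'
#' @param pair output of [generate_pair()].
#' @param dir output directory (created if missing).
#' @param base file basename.
#' @return named character vector of the paths written, invisibly.
#' @export
write_fixture_pair <- function(pair, dir, base = "fixture") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    mat_a = file.path(dir, paste0(base, "_A.phy")),
    mat_b = file.path(dir, paste0(base, "_B.phy")),
    species_a = file.path(dir, paste0(base, "_A.species.tsv")),
    species_b = file.path(dir, paste0(base, "_B.species.tsv")),
    sidecar = file.path(dir, paste0(base, ".json")))
  write_phylip_square(pair$mat_a, paths[["mat_a"]])
  write_phylip_square(pair$mat_b, paths[["mat_b"]])
  utils::write.table(
    data.frame(pair$mat_a$labels, pair$mat_a$species),
    paths[["species_a"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(pair$mat_b$labels, pair$mat_b$species),
    paths[["species_b"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(pair$spec), planted = pair$planted),
    paths[["sidecar"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
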