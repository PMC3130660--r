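# Shared fixture builders and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# Random two-family instance with species tags keeping the vertex count
# small enough for the brute-force oracle. Distances are rounded to few
# decimals on purpose: rounding manufactures exact RPD ties, exercising
# the solver's dedup index rules.
random_instance <- function(max_family = 6L, max_vertices = 18L,
                            zero_dist_prob = 0.3) {
  repeat {
    na <- sample(2:max_family, 1)
    nb <- sample(2:max_family, 1)
    nsp <- sample(2:5, 1)
    spa <- sample(paste0("s", seq_len(nsp)), na, replace = TRUE)
    spb <- sample(paste0("s", seq_len(nsp)), nb, replace = TRUE)
    nv <- sum(outer(spa, spb, "=="))
    if (nv < 1 || nv > max_vertices) next
    va <- matrix(0, na, na)
    vb <- matrix(0, nb, nb)
    va[upper.tri(va)] <- round(stats::runif(na * (na - 1) / 2, 0.05, 2),
                               sample(1:3, 1))
    vb[upper.tri(vb)] <- round(stats::runif(nb * (nb - 1) / 2, 0.05, 2),
                               sample(1:3, 1))
    if (stats::runif(1) < zero_dist_prob && na > 2) va[1, 2] <- 0
    va <- va + t(va)
    vb <- vb + t(vb)
    return(list(
      mat_a = mmm_dist(va, paste0("a", seq_len(na)), species = spa),
      mat_b = mmm_dist(vb, paste0("b", seq_len(nb)), species = spb)))
  }
}

random_adjacency <- function(n, p) {
  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    up <- which(upper.tri(adj))
    adj[up[stats::runif(length(up)) < p]] <- TRUE
    adj <- adj | t(adj)
  }
  adj
}

# Independent clique oracle: plain enumeration of all 2^n vertex subsets.
enumerate_max_cliques <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(list(size = 0L, cliques = list(integer(0))))
  best <- 0L
  out <- list()
  for (mask in 0:(2^n - 1)) {
    vs <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    k <- length(vs)
    if (k < best || k == 0) next
    ok <- TRUE
    if (k >= 2) {
      for (x in seq_len(k - 1)) {
        for (y in seq.int(x + 1, k)) {
          if (!adj[vs[x], vs[y]]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (!ok) next
    if (k > best) {
      best <- k
      out <- list(vs)
    } else {
      out <- c(out, list(vs))
    }
  }
  list(size = best, cliques = out)
}

match_keys <- function(matches) {
  sort(vapply(matches, paste, character(1), collapse = ","))
}

expect_same_matchset <- function(res, oracle) {
  expect_identical(res$score, oracle$score)
  expect_identical(match_keys(res$matches), match_keys(oracle$matches))
  expect_false(anyDuplicated(match_keys(res$matches)) > 0)
}

# Exact scaled-copy pair: B = scale * A entrywise, one species per index.
scaled_copy_pair <- function(n = 5, scale = 2) {
  va <- matrix(0, n, n)
  va[upper.tri(va)] <- seq(0.3, by = 0.17, length.out = n * (n - 1) / 2)
  va <- va + t(va)
  sp <- paste0("s", seq_len(n))
  list(mat_a = mmm_dist(va, paste0("a", seq_len(n)), species = sp),
       mat_b = mmm_dist(va * scale, paste0("b", seq_len(n)), species = sp))
}
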