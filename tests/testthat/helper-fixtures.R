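# Shared in-code fixtures: small random chains, toy matrices, and the
# brute-force oracles used to cross-check vectorized implementations.

# random bead chain with the given radii (seeded; leaves global RNG alone)
rand_chain <- function(n = 10, radii = runif(n, 5, 20), seed = 1) {
  withr::with_seed(seed, random_walk_chain(radii))
}

# small synthetic fixture: toy chain + accumulated matrix + tracks
toy_fixture <- function(n_beads = 16, loop_pairs = NULL, seed = 1, ...) {
  spec <- synthetic_spec(n_beads = n_beads, loop_pairs = loop_pairs,
                         seed = seed, ...)
  matrix_from_structure(generate_ground_truth(spec), spec)
}

# brute-force double-loop pairwise distances
bf_pairwise <- function(centroids) {
  n <- nrow(centroids)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
  out
}

# brute-force rank-then-Pearson Spearman over the strict upper triangle
bf_spearman <- function(A, B) {
  a <- A[upper.tri(A)]; b <- B[upper.tri(B)]
  cor(rank(a), rank(b), method = "pearson")
}

# brute-force Rodrigues rotation about a unit axis through the origin
bf_rodrigues <- function(p, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  p * cos(angle) + pracma_cross(u, p) * sin(angle) +
    u * sum(u * p) * (1 - cos(angle))
}
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# all intra-bead point-set distances of a chain (in, centroid, out per bead)
bead_shape_distances <- function(chain) {
  n <- chain_length(chain)
  t(vapply(seq_len(n), function(k) {
    p <- rbind(chain$endpoints[k, ], chain$centroids[k, ],
               chain$endpoints[k + 1, ])
    c(dist(p))
  }, numeric(3)))
}

# a two-bead chain at a prescribed normalized centroid distance dt, with
# unit touching distance (radii 0.5 each): psi(chain) equals the pair kernel
psi_pair_chain <- function(dt) {
  new_chain(centroids = rbind(c(0, 0, 0), c(dt, 0, 0)),
            endpoints = rbind(c(-0.5, 0, 0), c(dt / 2, 0, 0), c(dt + 0.5, 0, 0)),
            radii = c(0.5, 0.5))
}
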