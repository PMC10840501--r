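test_that("block decomposition recovers planted diagonal blocks", {
  set.seed(3)
  dense <- function(n) { m <- matrix(rpois(n * n, 20), n); m + t(m) }
  m <- matrix(0, 16, 16)
  m[1:8, 1:8] <- dense(8)
  m[9:16, 9:16] <- dense(8)
  diag(m) <- 0
  part <- decompose_blocks(m, min_block_bins = 3, max_block_bins = 40, tau = 0.1)
  expect_equal(part$starts, c(0L, 8L))
  expect_equal(part$sizes, c(8L, 8L))

  # permuting values within a block leaves the boundary unchanged
  perm <- sample(8)
  m2 <- m
  m2[1:8, 1:8] <- m[perm, perm]
  part2 <- decompose_blocks(m2, 3, 40, 0.1)
  expect_equal(part2$starts, part$starts)

  # uniform matrix: size bounds enforced, blocks cover all bins
  u <- matrix(1, 25, 25); diag(u) <- 0
  pu <- decompose_blocks(u, 3, 10, 0.1)
  expect_true(all(pu$sizes <= 10))
  expect_equal(sum(pu$sizes), 25)
  expect_equal(pu$ends[length(pu$ends)], 25L)

  # matrix smaller than the minimum block size: single block
  tiny <- matrix(1, 2, 2); diag(tiny) <- 0
  expect_equal(decompose_blocks(tiny, 3, 40, 0.1)$sizes, 2L)
})

test_that("matrix binning sums blocks and conserves the total exactly", {
  set.seed(8)
  m <- matrix(rpois(36, 5), 6); m <- m + t(m)
  cm <- contact_matrix(m)
  part <- structure(list(starts = c(0L, 2L, 5L), ends = c(2L, 5L, 6L),
                         sizes = c(2L, 3L, 1L),
                         internal_contacts = c(0, 0, 0),
                         rho_kbp = c(10, 15, 5)),
                    class = "block_partition")
  coarse <- bin_matrix(cm, part)
  # brute-force block-sum oracle
  groups <- rep(1:3, c(2, 3, 1))
  for (a in 1:3) for (b in 1:3)
    expect_equal(coarse$counts[a, b],
                 sum(m[groups == a, groups == b]), tolerance = 1e-12)
  expect_equal(sum(coarse$counts), sum(m))
  # single block: 1x1 total
  p1 <- structure(list(starts = 0L, ends = 6L, sizes = 6L,
                       internal_contacts = 0, rho_kbp = 30),
                  class = "block_partition")
  expect_equal(as.numeric(bin_matrix(cm, p1)$counts), sum(m))
  # a coarse bin is masked only if all its fine bins are masked
  cm$mask <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  expect_equal(bin_matrix(cm, part)$mask, c(TRUE, FALSE, TRUE))
})

test_that("fine-scale radii shrink with internal contacts inside the envelope", {
  dm <- d_min_max(5, 30)
  expect_equal(estimate_radius_fine(5, 0, n_ref = 10), dm[["D_max"]] / 2,
               tolerance = 1e-12)
  expect_equal(estimate_radius_fine(5, 1e9, n_ref = 10), dm[["D_min"]] / 2,
               tolerance = 1e-6)
  r <- estimate_radius_fine(5, 0:50, n_ref = 10)
  expect_true(all(diff(r) < 0))
  expect_true(all(r >= dm[["D_min"]] / 2 - 1e-12 & r <= dm[["D_max"]] / 2 + 1e-12))
  # equal contact counts give equal radii; zero reference gives the loosest
  expect_equal(length(unique(estimate_radius_fine(5, rep(7, 4)))), 1)
  expect_equal(estimate_radius_fine(5, c(0, 0)), rep(dm[["D_max"]] / 2, 2))
})

test_that("reconstruction conserves bin count and is seed-deterministic", {
  fx <- toy_fixture(n_beads = 16, seed = 6)
  r1 <- reconstruct(fx$matrix, seed = 21)
  r2 <- reconstruct(fx$matrix, seed = 21)
  expect_identical(r1$chain$centroids, r2$chain$centroids)
  expect_equal(chain_length(r1$chain), 16)
  # single-block matrix: one level, one block
  expect_equal(unique(r1$levels$level), 0)
  r3 <- reconstruct(fx$matrix, seed = 22)
  expect_false(identical(r1$chain$centroids, r3$chain$centroids))
})

test_that("a multi-block matrix recurses and refines back to input size", {
  fx <- toy_fixture(n_beads = 36, seed = 2)
  cfg <- run_config(max_block_bins = 12)
  rec <- reconstruct(fx$matrix, config = cfg, seed = 5)
  expect_equal(chain_length(rec$chain), 36)
  expect_gt(max(rec$levels$level), 0)          # at least one coarser scale
  expect_gt(sum(rec$levels$level == 0), 1)     # several fine blocks
  # finest chain has contiguous genomic spans
  expect_equal(rec$chain$spans[, 1], seq(0, 35) * 5000)
})

test_that("auxiliary tracks flag blocks only at sufficient coverage", {
  fx <- toy_fixture(n_beads = 12, seed = 3)
  full_cover <- interval_track("chrS", 0, 12 * 5000, kind = "H3K27ME3")
  tiny_cover <- interval_track("chrS", 0, 2000, kind = "H3K27ME3")
  rec_full <- reconstruct(fx$matrix, h3k27me3 = full_cover, seed = 4)
  rec_tiny <- reconstruct(fx$matrix, h3k27me3 = tiny_cover, seed = 4)
  rec_none <- reconstruct(fx$matrix, seed = 4)
  # a fully covered block is packed more tightly than an unflagged one
  expect_lt(max(pairwise_distances(rec_full$chain)),
            max(pairwise_distances(rec_none$chain)))
  # sub-threshold coverage behaves like no track at all
  expect_identical(rec_tiny$chain$centroids, rec_none$chain$centroids)
})
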