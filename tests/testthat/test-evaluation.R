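test_that("single-configuration contacts use a strict distance threshold", {
  # two beads touching exactly: strict inequality keeps them out at factor 1
  two <- new_chain(centroids = rbind(c(0, 0, 0), c(2, 0, 0)),
                   endpoints = rbind(c(-1, 0, 0), c(1, 0, 0), c(3, 0, 0)),
                   radii = c(1, 1))
  expect_equal(contacts_from_configuration(two, 1.0),
               matrix(0, 2, 2))
  # huge factor: everything off-diagonal in contact
  ch <- rand_chain(10, seed = 2)
  all_on <- contacts_from_configuration(ch, 1e9)
  expect_equal(all_on, 1 - diag(10), ignore_attr = TRUE)
  # brute-force oracle
  got <- contacts_from_configuration(ch, 1.2)
  want <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10)
    if (i != j && sqrt(sum((ch$centroids[i, ] - ch$centroids[j, ])^2)) <
          1.2 * (ch$radii[i] + ch$radii[j])) want[i, j] <- 1
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("ensemble contact matrices accumulate per-configuration contacts", {
  ch <- rand_chain(8, seed = 4)
  one <- estimate_contact_matrix(list(ch), 1.3)
  expect_equal(one$counts, contacts_from_configuration(ch, 1.3))
  trip <- estimate_contact_matrix(list(ch, ch, ch), 1.3)
  expect_equal(trip$counts, 3 * one$counts)
  expect_lte(max(trip$counts), trip$n_configurations)
  expect_error(estimate_contact_matrix(list(ch, rand_chain(5, seed = 1))),
               "same number of beads")
})

test_that("Spearman comparison is a rank correlation over the upper triangle", {
  set.seed(19)
  A <- matrix(rpois(36, 6), 6); A <- A + t(A)
  expect_equal(spearman_compare(A, A), 1)
  expect_equal(spearman_compare(A, max(A) - A), -1)
  B <- matrix(rpois(36, 6), 6); B <- B + t(B)
  expect_equal(spearman_compare(A, B), bf_spearman(A, B), tolerance = 1e-12)
  expect_warning(out <- spearman_compare(matrix(1, 4, 4), B[1:4, 1:4]),
                 "constant")
  expect_true(is.nan(out))
  # excluded bins do not contribute
  A2 <- A; A2[1, ] <- 99; A2[, 1] <- 99
  expect_equal(spearman_compare(A2, A, exclude_bins = 1),
               spearman_compare(A[-1, -1], A[-1, -1]))
})

test_that("resampling stability tightens with the ensemble size", {
  spec <- synthetic_spec(n_beads = 20, seed = 12)
  gt <- generate_ground_truth(spec)
  fx <- matrix_from_structure(gt, spec)
  # pool of jittered copies of the truth (cheap stand-in for reconstructions)
  pool <- withr::with_seed(7, lapply(1:120, function(k) {
    ch <- gt
    ch$centroids <- ch$centroids + matrix(rnorm(60, sd = 8), 20, 3)
    ch
  }))
  tab <- stability_analysis(pool, fx$matrix, sizes = c(4, 12), n_resamples = 15,
                            pool_multiplier = 10, seed = 5)
  expect_equal(tab$size, c(4, 12))
  expect_true(all(is.finite(tab$mean)))
  expect_true(all(tab$sd >= 0))
  # degenerate single resample: zero standard deviation by convention
  one <- stability_analysis(pool, fx$matrix, sizes = 4, n_resamples = 1,
                            pool_multiplier = 10, seed = 5)
  expect_equal(one$sd, 0)
  expect_error(stability_analysis(pool[1:10], fx$matrix, sizes = c(4, 12),
                                  n_resamples = 2, pool_multiplier = 10),
               "insufficient")
})

test_that("masking zeroes site neighbourhoods with border clipping", {
  set.seed(23)
  m <- matrix(rpois(256, 5), 16); m <- m + t(m); diag(m) <- 0
  cm <- contact_matrix(m)
  masked <- mask_matrix(cm, 8L, 2L)           # 0-based site 8
  expect_equal(which(masked$mask) - 1, 6:10)  # exactly 5 rows/cols
  expect_true(all(masked$counts[7:11, ] == 0))
  expect_true(all(masked$counts[, 7:11] == 0))
  expect_equal(masked$counts[-(7:11), -(7:11)], m[-(7:11), -(7:11)])

  border <- mask_matrix(cm, 0L, 2L)
  expect_equal(which(border$mask) - 1, 0:2)   # clipped at the border
  expect_equal(which(mask_matrix(cm, 5L, 0L)$mask) - 1, 5)
  expect_error(mask_matrix(cm, 40L, 2L), "range")

  # masking then TF-augmenting restores signal exactly at the anchor pair
  aug <- augment_with_tf(masked, cbind(8L, 14L), 100)
  expect_equal(aug$counts[9, 15], 100)
  other_masked <- aug$counts[7:11, ]
  other_masked[3, 15] <- 0
  expect_true(all(other_masked == 0))
})
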