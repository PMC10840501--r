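test_that("polymer-scaling distance bounds follow the stated power law", {
  dm <- d_min_max(1, 30)
  expect_equal(dm[["D_min"]], 30 / (6 * pi), tolerance = 1e-12)
  expect_equal(dm[["D_max"]], 30 / (3 * pi), tolerance = 1e-12)
  for (rho in c(0.3, 1, 5, 85, 400)) {
    dm <- d_min_max(rho)
    expect_equal(dm[["D_max"]] / dm[["D_min"]], 2, tolerance = 1e-12)
    expect_equal(d_min_max(32 * rho)[["D_min"]] / dm[["D_min"]], 64,
                 tolerance = 1e-9)
  }
  expect_error(d_min_max(0), "rho")
  expect_error(d_min_max(1, -2), "Dc")
})

test_that("contact sets keep exactly the above-threshold pairs", {
  cs <- build_contact_set(matrix(c(0, 5, 5, 0), 2), c(1, 2), 1)
  expect_equal(cs$i, 1L)
  expect_equal(cs$j, 2L)
  expect_equal(cs$n, 5)
  expect_equal(cs$dmin, 3)
  expect_length(build_contact_set(matrix(c(0, 5, 5, 0), 2), c(1, 2), 5)$i, 0)
  set.seed(13)
  m <- matrix(rpois(64, 4), 8); m <- m + t(m); diag(m) <- 0
  radii <- runif(8, 1, 3)
  cs <- build_contact_set(m, radii, 6)
  want <- NULL
  for (i in 1:7) for (j in (i + 1):8)
    if (m[i, j] > 6) want <- rbind(want, c(i, j, m[i, j], radii[i] + radii[j]))
  expect_equal(cbind(cs$i, cs$j, cs$n, cs$dmin), want, ignore_attr = TRUE)
})

test_that("CTCF augmentation adds pseudo-counts, also on masked bins", {
  set.seed(2)
  m <- matrix(rpois(64, 6), 8); m <- m + t(m); diag(m) <- 0
  cm <- contact_matrix(m)
  aug <- augment_with_tf(cm, cbind(2L, 5L), 100)
  expect_equal(aug$counts[3, 6], cm$counts[3, 6] + 100)
  expect_equal(aug$counts[6, 3], cm$counts[6, 3] + 100)
  expect_equal(aug$counts[1, 2], cm$counts[1, 2])
  # empty pair set: bitwise unchanged (the pure Hi-C reduction)
  expect_identical(augment_with_tf(cm, NULL)$counts, cm$counts)
  expect_identical(augment_with_tf(cm, matrix(integer(), 0, 2))$counts, cm$counts)
  # the rescue mechanism: masked bins still receive the pseudo-count
  masked <- mask_matrix(cm, 2L, 1L)
  aug2 <- augment_with_tf(masked, cbind(2L, 5L), 100)
  expect_true(masked$mask[3])
  expect_equal(aug2$counts[3, 6], 100)
  expect_true(all(aug2$counts[masked$mask, -6] == 0))
  expect_error(augment_with_tf(cm, cbind(0L, 99L)), "range")
})

test_that("Hi-C data fit penalizes deviations from the touching distance", {
  mk2 <- function(d, r = 1) new_chain(
    centroids = rbind(c(0, 0, 0), c(d, 0, 0)),
    endpoints = rbind(c(-r, 0, 0), c(d / 2, 0, 0), c(d + r, 0, 0)),
    radii = c(r, r))
  cs <- structure(list(i = 1L, j = 2L, n = 5, dmin = 2), class = "contact_set")
  expect_equal(phi_hic(mk2(2), cs), 0)
  expect_equal(phi_hic(mk2(4), cs), 5 * (1 / 2 - 1)^2)  # = 1.25
  cs2 <- cs; cs2$n <- 10
  expect_equal(phi_hic(mk2(4), cs2), 2 * phi_hic(mk2(4), cs))
  # coincident restrained centroids: infinite-cost sentinel
  expect_equal(phi_hic(mk2(0), cs), Inf)

  # brute-force oracle on random 10-bead chains, and rigid invariance
  set.seed(17)
  for (k in 1:5) {
    ch <- rand_chain(10, seed = k)
    m <- matrix(rpois(100, 3), 10); m <- m + t(m); diag(m) <- 0
    cs <- build_contact_set(m, ch$radii, 2)
    want <- 0
    for (p in seq_along(cs$i)) {
      d <- sqrt(sum((ch$centroids[cs$i[p], ] - ch$centroids[cs$j[p], ])^2))
      want <- want + cs$n[p] * (cs$dmin[p] / d - 1)^2
    }
    expect_equal(phi_hic(ch, cs), want, tolerance = 1e-12)
    chr <- ch
    chr$centroids <- rotate_about_axis(ch$centroids, c(1, 2, 3), c(0, 1, 1), 0.8)
    expect_equal(phi_hic(chr, cs), want, tolerance = 1e-9)
  }
})

test_that("packing terms hit their stated minima", {
  two_at <- function(d) new_chain(centroids = rbind(c(0, 0, 0), c(d, 0, 0)),
                                  endpoints = rbind(c(-1, 0, 0), c(d / 2, 0, 0), c(d + 1, 0, 0)),
                                  radii = c(1, 1))
  expect_equal(phi_chip(two_at(50), FALSE, 10), 0)
  expect_equal(phi_chip(two_at(10), TRUE, 10), 0)
  expect_equal(phi_rna(two_at(50), FALSE, 20), 0)
  expect_equal(phi_rna(two_at(20), TRUE, 20), 0)
  # three beads, max pairwise distance D_min + 10 -> 100
  tri <- new_chain(centroids = rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)),
                   endpoints = matrix(0, 4, 3), radii = rep(1, 3))
  expect_equal(phi_chip(tri, TRUE, 10), (20 - 10)^2)
  expect_equal(phi_rna(tri, TRUE, 14), (10 - 14)^2)
})

test_that("non-interpenetration prior shows the three stated behaviours", {
  # exactly 1/2 at the touching distance
  expect_equal(psi(psi_pair_chain(1)), 0.5, tolerance = 1e-15)
  # vanishes rapidly for far pairs (b = 5, c = 1)
  expect_lt(abs(psi(psi_pair_chain(100))), 1e-3)
  # behaves as 1/d for deeply interpenetrating pairs
  dt <- 1e-3
  expect_lt(abs(psi(psi_pair_chain(dt)) * dt - 1), 0.05)
  # coincident centroids: infinite sentinel
  expect_equal(psi(psi_pair_chain(0)), Inf)
  # decreasing tail on [3, Inf)
  tail_vals <- vapply(c(3, 5, 10, 30, 100, 1000), function(d)
    psi(psi_pair_chain(d)), 0)
  expect_true(all(diff(tail_vals) < 0))
  # moderate-penalty plateau near 1 follows 1/(2d)
  for (d in c(0.9, 1, 1.1))
    expect_equal(psi(psi_pair_chain(d)), 1 / (2 * d), tolerance = 0.06)
  expect_error(psi(psi_pair_chain(1), b = 4), "odd")
})

test_that("the total objective is the stated weighted sum", {
  ch <- rand_chain(8, seed = 9)
  m <- matrix(rpois(64, 3), 8); m <- m + t(m); diag(m) <- 0
  cs <- build_contact_set(m, ch$radii, 2)
  flags <- list(chip = TRUE, rna = TRUE, D_min = 15, D_max = 60)
  params <- cost_params(mu1 = 0.7, mu2 = 1.3, lambda = 2.1)
  tc <- total_cost(ch, cs, flags, params)
  expect_equal(tc$total,
               tc$hic + 0.7 * tc$chip + 1.3 * tc$rna + 2.1 * tc$psi,
               tolerance = 1e-12)
  expect_equal(tc$hic, phi_hic(ch, cs), tolerance = 1e-12)
  # zeroed weights reduce to the data fit alone
  p0 <- cost_params(mu1 = 0, mu2 = 0, lambda = 0)
  p0$lambda <- 0
  expect_equal(total_cost(ch, cs, flags, p0)$total, phi_hic(ch, cs),
               tolerance = 1e-12)
})

test_that("lambda tuning fixes the data:prior ratio on the initial chain", {
  ch <- psi_pair_chain(2)  # d = 2, radii 0.5: dt = 2
  cs <- structure(list(i = 1L, j = 2L, n = 8, dmin = 1), class = "contact_set")
  params <- cost_params()
  # hand-computed parts: data = 8*(1/2 - 1)^2 = 2; psi kernel at dt = 2
  u <- 2 - 1 / 2
  psi_hand <- (1 / 4) * (1 - u^5 / (1 + u^5))
  expect_equal(tune_lambda(ch, cs, list(), params, ratio = 1), 2 / psi_hand,
               tolerance = 1e-12)
  expect_equal(tune_lambda(ch, cs, list(), params, ratio = 0), 0)
  # homogeneity: scaling the counts scales lambda
  cs2 <- cs; cs2$n <- 3 * cs$n
  expect_equal(tune_lambda(ch, cs2, list(), params),
               3 * tune_lambda(ch, cs, list(), params), tolerance = 1e-12)
  # zero prior: warned fallback to the ratio itself
  one_far <- structure(list(i = integer(), j = integer(), n = numeric(),
                            dmin = numeric()), class = "contact_set")
  single <- new_chain(centroids = matrix(0, 1, 3), endpoints = matrix(0, 2, 3),
                      radii = 1)
  expect_warning(lam <- tune_lambda(single, one_far, list(), params, ratio = 0.5))
  expect_equal(lam, 0.5)
})
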