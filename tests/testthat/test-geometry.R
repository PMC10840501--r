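test_that("quaternion rotation matches the Rodrigues-formula oracle", {
  expect_equal(rotate_about_axis(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), pi / 2),
               c(0, 1, 0), tolerance = 1e-9)
  expect_equal(rotate_about_axis(c(0.3, -2, 5), c(1, 1, 1), c(2, 0, 1), 0),
               c(0.3, -2, 5), tolerance = 1e-12)
  set.seed(11)
  for (k in 1:100) {
    p <- rnorm(3); ap <- rnorm(3); ax <- rnorm(3); ang <- runif(1, -2 * pi, 2 * pi)
    got <- rotate_about_axis(p, ap, ax, ang)
    want <- bf_rodrigues(p - ap, ax, ang) + ap
    expect_equal(got, want, tolerance = 1e-9)
    # rotation preserves distance to the axis point
    expect_equal(sum((got - ap)^2), sum((p - ap)^2), tolerance = 1e-9)
  }
  expect_error(rotate_about_axis(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0), 1),
               "zero axis")
  q <- quaternion_from_axis_angle(c(1, 2, 3), 0.7)
  expect_equal(sum(q^2), 1, tolerance = 1e-12)
})

test_that("summarize_chain_as_bead reduces a chain to its coarse bead", {
  # degenerate single-bead chain: radius floor active
  b <- modified_bead(c(0, 0, 0), c(-1, 0, 0), c(1, 0, 0), 2)
  ch1 <- new_chain(beads = list(b))
  cb <- summarize_chain_as_bead(ch1)
  expect_equal(cb$centroid, c(0, 0, 0))
  expect_equal(cb$radius, 2)

  # four collinear centroids at 0,1,2,3: radius = sqrt(population variance)
  cent <- cbind(0:3, 0, 0)
  endp <- cbind(c(-0.5, 0.5, 1.5, 2.5, 3.5), 0, 0)
  ch4 <- new_chain(centroids = cent, endpoints = endp, radii = rep(0.01, 4))
  cb4 <- summarize_chain_as_bead(ch4)
  expect_equal(cb4$centroid, c(1.5, 0, 0))
  expect_equal(cb4$radius, sqrt(1.25), tolerance = 1e-12)
  expect_equal(cb4$endpoint_in, c(-0.5, 0, 0))
  expect_equal(cb4$endpoint_out, c(3.5, 0, 0))

  # equivariance: rotating the chain rotates the summarized bead identically
  ch <- rand_chain(7, seed = 2)
  cb0 <- summarize_chain_as_bead(ch)
  rot <- function(m) rotate_about_axis(m, c(5, -1, 2), c(1, 2, -1), 0.9)
  chr <- ch
  chr$centroids <- rot(chr$centroids)
  chr$endpoints <- rot(chr$endpoints)
  cbr <- summarize_chain_as_bead(chr)
  expect_equal(cbr$centroid, as.numeric(rot(matrix(cb0$centroid, 1))), tolerance = 1e-9)
  expect_equal(cbr$radius, cb0$radius, tolerance = 1e-9)
  expect_error(summarize_chain_as_bead(new_chain(centroids = matrix(numeric(), 0, 3),
                                                 endpoints = matrix(0, 1, 3),
                                                 radii = numeric())),
               "empty")
})

test_that("place_bead realizes the requested pose and keeps bead shape", {
  set.seed(21)
  mk <- function() {
    p <- matrix(rnorm(9, sd = 2), 3)
    modified_bead(p[1, ], p[2, ], p[3, ], runif(1, 0.5, 2))
  }
  prev <- place_bead(mk(), c(0, 0, 0), list(zeta = 0, xi = 0), NULL)

  # zero pose with a coplanar previous bead: all defining points stay in P1
  flat <- place_bead(mk(), prev$endpoint_out, list(zeta = 0, xi = 0), prev)
  n1 <- pracma_cross(prev$centroid - prev$endpoint_in,
                     prev$endpoint_out - prev$endpoint_in)
  n1 <- n1 / sqrt(sum(n1^2))
  for (pt in list(flat$centroid, flat$endpoint_out))
    expect_lt(abs(sum((pt - prev$endpoint_in) * n1)), 1e-6)

  # inverse measurement recovers the pose; shape distances unchanged
  for (k in 1:50) {
    pose <- list(zeta = runif(1, -3, 3), xi = runif(1, -3, 3))
    bend <- runif(1, 0.3, pi - 0.1)
    b0 <- mk()
    b <- place_bead(b0, prev$endpoint_out, pose, prev, bend = bend)
    m <- measure_pose(prev, b)
    expect_equal(m$zeta, pose$zeta, tolerance = 1e-6)
    expect_equal(m$xi, pose$xi, tolerance = 1e-6)
    expect_equal(m$bend, bend, tolerance = 1e-6)
    shape <- function(x) c(dist(rbind(x$endpoint_in, x$centroid, x$endpoint_out)))
    expect_equal(shape(b), shape(b0), tolerance = 1e-9)
    expect_equal(b$endpoint_in, prev$endpoint_out, tolerance = 1e-12)
    prev <- b
  }

  # chained placement: new_chain accepts the beads (shared endpoints coincide)
  set.seed(22)
  beads <- list(place_bead(mk(), c(0, 0, 0), list(zeta = 0, xi = 0), NULL))
  for (k in 2:4)
    beads[[k]] <- place_bead(mk(), beads[[k - 1]]$endpoint_out,
                             list(zeta = runif(1, -3, 3), xi = runif(1, -3, 3)),
                             beads[[k - 1]])
  expect_s3_class(new_chain(beads = beads), "bead_chain")
})

test_that("refine_chain re-expands payloads rigidly", {
  spec <- synthetic_spec(n_beads = 6, seed = 4)
  ch <- generate_ground_truth(spec)
  coarse <- new_chain(beads = list(summarize_chain_as_bead(ch)), scale_level = 1L)

  # unmoved: identity within tolerance
  back <- refine_chain(coarse)
  expect_equal(back$centroids, ch$centroids, tolerance = 1e-6)
  expect_equal(back$endpoints, ch$endpoints, tolerance = 1e-6)

  # bead count conservation and rigidity after a random rigid move
  set.seed(31)
  beads <- lapply(1:3, function(i)
    summarize_chain_as_bead(generate_ground_truth(synthetic_spec(n_beads = 5, seed = i))))
  cc <- random_place_chain(beads, scale_level = 1L)
  fine <- refine_chain(cc)
  expect_equal(chain_length(fine), 15)
  for (i in 1:3) {
    idx <- ((i - 1) * 5 + 1):(i * 5)
    d0 <- pairwise_distances(beads[[i]]$payload$chain)
    d1 <- as.matrix(dist(fine$centroids[idx, ]))
    expect_lt(max(abs(d0 - d1)), 1e-6)
  }
  # missing payload is a state error
  expect_error(refine_chain(rand_chain(3, seed = 1)), "payload")
})

test_that("pairwise distances are metric and match brute force", {
  two <- new_chain(centroids = rbind(c(0, 0, 0), c(5, 0, 0)),
                   endpoints = rbind(c(-1, 0, 0), c(2.5, 0, 0), c(6, 0, 0)),
                   radii = c(1, 1))
  expect_equal(pairwise_distances(two), matrix(c(0, 5, 5, 0), 2), ignore_attr = TRUE)
  ch <- rand_chain(10, seed = 7)
  d <- pairwise_distances(ch)
  expect_equal(d, bf_pairwise(ch$centroids), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # translation invariance
  cht <- ch; cht$centroids <- sweep(cht$centroids, 2, c(3, -4, 10), `+`)
  expect_equal(pairwise_distances(cht), d, tolerance = 1e-9)
})
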