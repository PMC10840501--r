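test_that("chain moves are rigid and preserve shared-endpoint continuity", {
  ch <- rand_chain(8, seed = 5)
  shape0 <- bead_shape_distances(ch)
  set.seed(42)
  types <- character()
  cur <- ch
  for (k in 1:300) {
    mv <- propose_move(cur)
    cur <- mv$chain
    types <- c(types, mv$move$type)
    expect_equal(bead_shape_distances(cur), shape0, tolerance = 1e-6)
  }
  expect_setequal(unique(types), c("pivot", "crankshaft"))
  # single-bead chain: identity move
  single <- new_chain(centroids = matrix(1:3, 1), endpoints = rbind(c(0, 0, 0), c(2, 2, 2)),
                      radii = 1)
  expect_identical(propose_move(single)$move$type, "identity")
})

test_that("annealing improves the cost, reproducibly per seed", {
  ch0 <- rand_chain(6, radii = rep(10, 6), seed = 3)
  m <- matrix(0, 6, 6); m[1, 5] <- m[5, 1] <- 40; m[2, 6] <- m[6, 2] <- 25
  cs <- build_contact_set(m, ch0$radii, 1)
  params <- cost_params()
  params$lambda <- tune_lambda(ch0, cs, list(), params)
  a1 <- anneal(ch0, cs, list(), params, anneal_schedule(stages = 30), seed = 9)
  a2 <- anneal(ch0, cs, list(), params, anneal_schedule(stages = 30), seed = 9)
  expect_identical(a1$chain$centroids, a2$chain$centroids)  # bit-reproducible
  expect_true(all(diff(a1$trace) <= 0))                     # best-seen trace
  expect_lte(a1$best_cost, a1$initial_cost)
  # returned cost agrees with the R reference implementation of the objective
  expect_equal(a1$best_cost, total_cost(a1$chain, cs, list(), params)$total,
               tolerance = 1e-9)
  # acceptance at the calibrated starting temperature is moderate
  expect_gt(a1$acceptance_rate, 0.2)
  expect_lt(a1$acceptance_rate, 0.95)
  # distinct seeds explore distinct near-optima
  a3 <- anneal(ch0, cs, list(), params, anneal_schedule(stages = 30), seed = 10)
  expect_false(identical(a1$chain$centroids, a3$chain$centroids))
})

test_that("a zero-temperature anneal never accepts uphill moves", {
  ch0 <- rand_chain(5, radii = rep(8, 5), seed = 4)
  cs <- structure(list(i = 1L, j = 5L, n = 20, dmin = 16), class = "contact_set")
  params <- cost_params(); params$lambda <- 0.1
  cold <- anneal(ch0, cs, list(), params,
                 anneal_schedule(t0 = 1e-12, stages = 10), seed = 2)
  # with T ~ 0 the current cost can only decrease, so best == last == monotone
  expect_true(all(diff(cold$trace) <= 0))
  expect_lte(cold$best_cost, cold$initial_cost)
})

test_that("a restrained pair anneals to its touching distance", {
  r <- 15
  ok <- 0
  for (s in 1:30) {
    ch <- withr::with_seed(s, random_walk_chain(rep(r, 3)))
    cs <- structure(list(i = 1L, j = 3L, n = 50, dmin = 2 * r),
                    class = "contact_set")
    p <- cost_params()
    p$lambda <- tune_lambda(ch, cs, list(), p)
    a <- anneal(ch, cs, list(), p, seed = s)
    dr <- pairwise_distances(a$chain)[1, 3] / (2 * r)
    if (dr >= 0.8 && dr <= 1.3) ok <- ok + 1
  }
  expect_gte(ok, 29)
})

test_that("non-finite initial cost triggers re-initialization", {
  # two coincident restrained centroids: initial cost is Inf
  bad <- new_chain(centroids = rbind(c(0, 0, 0), c(0, 0, 0), c(30, 0, 0)),
                   endpoints = matrix(0, 4, 3), radii = rep(15, 3))
  cs <- structure(list(i = 1L, j = 2L, n = 10, dmin = 30), class = "contact_set")
  params <- cost_params(); params$lambda <- 0.5
  a <- anneal(bad, cs, list(), params, anneal_schedule(stages = 10), seed = 6)
  expect_true(is.finite(a$best_cost))
})
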