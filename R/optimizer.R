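# Approximated simulated annealing: a fixed-budget Metropolis scheme with
# geometric cooling over quaternion pivot/crankshaft chain moves. One full
# anneal generates one individual of the configuration population; distinct
# seeds land in distinct near-optima, which is the point.

#' Annealing schedule
#'
#' @param t0 Initial temperature in cost units; `NA` (default) calibrates it
#'   so the median uphill move from the initial chain is accepted with
#'   probability about 0.8.
#' @param cooling Geometric cooling factor per stage, in (0, 1).
#' @param stages Number of temperature stages.
#' @param moves_per_stage Moves per stage; `NA` uses `10 * n_beads`.
#' @param theta_max Maximum move rotation angle (radians).
#' @return A list of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t0 = NA_real_, cooling = 0.95, stages = 60L,
                            moves_per_stage = NA_integer_, theta_max = pi / 4) {
  if (!is.na(t0) && t0 <= 0) stop("t0 must be > 0")
  if (cooling <= 0 || cooling >= 1) stop("cooling must be in (0, 1)")
  if (stages < 1) stop("stages must be >= 1")
  structure(list(t0 = t0, cooling = cooling, stages = as.integer(stages),
                 moves_per_stage = moves_per_stage, theta_max = theta_max),
            class = "anneal_schedule")
}

#' Propose one random quaternion chain move
#'
#' Chooses uniformly between a pivot (rotate the chain tail from a random
#' bead onward about a random axis through the preceding shared endpoint)
#' and a crankshaft (rotate the beads strictly between two random beads
#' about the axis joining the flanking shared endpoints). Both moves are
#' rigid on every bead and preserve shared-endpoint continuity exactly.
#' Uses R's RNG stream.
#'
#' @param chain A `bead_chain`.
#' @param theta_max Maximum rotation angle (radians).
#' @return List with the moved `chain` and a `move` descriptor.
#' @export
propose_move <- function(chain, theta_max = pi / 4) {
  n <- chain_length(chain)
  if (n < 2) return(list(chain = chain, move = list(type = "identity")))
  type <- if (n < 3 || runif(1) < 0.5) "pivot" else "crankshaft"
  angle <- runif(1, -theta_max, theta_max)
  if (type == "pivot") {
    k <- sample.int(n - 1, 1) + 1  # bead k..n rotate (1-based)
    origin <- chain$endpoints[k, ]
    z <- runif(1, -1, 1); phi <- runif(1, 0, 2 * pi)
    axis <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
    idx_c <- k:n; idx_e <- (k + 1):(n + 1)
  } else {
    p <- sample.int(n - 2, 1)              # beads p+1..q-1 rotate (1-based)
    q <- p + 1 + sample.int(n - p - 1, 1)
    origin <- chain$endpoints[p + 1, ]
    axis <- chain$endpoints[q, ] - origin
    if (sqrt(sum(axis^2)) < 1e-9)
      return(list(chain = chain, move = list(type = "identity")))
    idx_c <- (p + 1):(q - 1); idx_e <- if (q - 1 >= p + 2) (p + 2):(q - 1) else integer()
  }
  chain$centroids[idx_c, ] <- rotate_about_axis(chain$centroids[idx_c, , drop = FALSE],
                                                origin, axis, angle)
  if (length(idx_e))
    chain$endpoints[idx_e, ] <- rotate_about_axis(chain$endpoints[idx_e, , drop = FALSE],
                                                  origin, axis, angle)
  list(chain = chain, move = list(type = type, angle = angle))
}

#' Random-walk initial placement of a leaf chain
#'
#' Builds a self-avoiding random walk with straight beads: bead `k` runs
#' from its in-endpoint through its centroid to its out-endpoint along a
#' random direction, with `|E - C| = r_k`. Steps that bring two centroids
#' closer than `min_sep_factor * (r_i + r_j)` are retried up to `max_tries`
#' times (then the best candidate is kept). Uses R's RNG stream.
#'
#' @param radii Bead radii (nm).
#' @param spans Optional `n x 2` genomic spans.
#' @param payloads Optional payload list.
#' @param scale_level Scale level tag.
#' @param step_scale Per-bead multiplier on the step length (default 1).
#' @param min_sep_factor Self-avoidance clearance factor.
#' @param max_tries Retry budget per step.
#' @param confine_radius Optional confinement sphere radius (nm) around the
#'   walk origin: candidates outside it are avoided, yielding the compact,
#'   domain-like initial configurations the reconstruction assumes.
#'   `NULL` (default) leaves the walk unconfined.
#' @return A `bead_chain`.
#' @export
random_walk_chain <- function(radii, spans = NULL, payloads = NULL,
                              scale_level = 0L, step_scale = 1,
                              min_sep_factor = 0.8, max_tries = 30L,
                              confine_radius = NULL) {
  n <- length(radii)
  step_scale <- rep_len(step_scale, n)
  centroids <- matrix(0, n, 3)
  endpoints <- matrix(0, n + 1, 3)
  for (k in seq_len(n)) {
    start <- endpoints[k, ]
    best <- NULL; best_score <- -Inf
    for (try in seq_len(max_tries)) {
      z <- runif(1, -1, 1); phi <- runif(1, 0, 2 * pi)
      u <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
      cen <- start + radii[k] * step_scale[k] * u
      eout <- cen + radii[k] * step_scale[k] * u
      clear <- Inf
      if (k > 1) {
        prev <- centroids[seq_len(k - 1), , drop = FALSE]
        d <- sqrt(rowSums(sweep(prev, 2, cen)^2))
        clear <- min(d / (radii[seq_len(k - 1)] + radii[k]))
      }
      confined <- is.null(confine_radius) || sqrt(sum(cen^2)) <= confine_radius
      if (confined && clear >= min_sep_factor) { best <- list(cen, eout); break }
      score <- min(clear, min_sep_factor) - (!confined) * 1
      if (score > best_score) { best_score <- score; best <- list(cen, eout) }
    }
    centroids[k, ] <- best[[1]]
    endpoints[k + 1, ] <- best[[2]]
  }
  new_chain(centroids = centroids, endpoints = endpoints, radii = radii,
            spans = spans, payloads = payloads, scale_level = scale_level)
}

#' Random sequential placement of summarized beads
#'
#' Places beads one after the other with random poses via [place_bead()],
#' preserving each bead's fixed internal geometry (and payload). Uses R's
#' RNG stream.
#'
#' @param beads List of [modified_bead()]s.
#' @param scale_level Scale level tag.
#' @param confine_radius Optional confinement sphere radius (nm): among the
#'   sampled poses, ones keeping the bead centroid inside are preferred.
#' @return A `bead_chain`.
#' @export
random_place_chain <- function(beads, scale_level = 0L,
                               confine_radius = NULL) {
  placed <- vector("list", length(beads))
  target <- c(0, 0, 0)
  prev <- NULL
  for (k in seq_along(beads)) {
    best <- NULL; best_excess <- Inf
    for (try in 1:15) {
      pose <- list(zeta = runif(1, -pi, pi), xi = runif(1, -pi, pi))
      bend <- runif(1, pi / 2, pi)
      cand <- place_bead(beads[[k]], target, pose, prev, bend = bend)
      excess <- if (is.null(confine_radius)) 0 else
        max(0, sqrt(sum(cand$centroid^2)) - confine_radius)
      if (excess < best_excess) { best_excess <- excess; best <- cand }
      if (excess == 0) break
    }
    placed[[k]] <- best
    target <- placed[[k]]$endpoint_out
    prev <- placed[[k]]
  }
  new_chain(beads = placed, scale_level = scale_level)
}

#' Anneal a block chain under the full objective
#'
#' Fixed-budget Metropolis sampling with geometric cooling; returns the
#' best-seen configuration. If the initial cost is non-finite, the chain is
#' re-initialized once as a random self-avoiding walk before giving up.
#' Bit-reproducible for a fixed `seed`.
#'
#' @param chain0 Initial `bead_chain`.
#' @param contacts A [build_contact_set()] result.
#' @param flags List with `chip`, `rna`, `D_min`, `D_max` (see [total_cost()]).
#' @param params A [cost_params()] (with `lambda` already set).
#' @param schedule An [anneal_schedule()].
#' @param seed Integer seed for the sampler's private RNG.
#' @return List with `chain` (best seen), `trace` (best cost per stage),
#'   `best_cost`, `initial_cost`, `acceptance_rate`, `t0`.
#' @export
anneal <- function(chain0, contacts, flags, params,
                   schedule = anneal_schedule(), seed = 1L) {
  n <- chain_length(chain0)
  cost0 <- total_cost(chain0, contacts, flags, params)$total
  if (!is.finite(cost0)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    chain0 <- random_walk_chain(chain0$radii, chain0$spans, chain0$payloads,
                                chain0$scale_level,
                                confine_radius = domain_confine_radius(chain0$radii))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    cost0 <- total_cost(chain0, contacts, flags, params)$total
    if (!is.finite(cost0)) stop("initial cost non-finite after re-initialization")
  }
  mps <- schedule$moves_per_stage
  if (is.na(mps) || is.null(mps)) mps <- 10L * n
  res <- anneal_cpp(chain0$centroids, chain0$endpoints, chain0$radii,
                    as.integer(contacts$i - 1), as.integer(contacts$j - 1),
                    as.numeric(contacts$n), as.numeric(contacts$dmin),
                    isTRUE(flags$chip), flags$D_min %||% 0,
                    isTRUE(flags$rna), flags$D_max %||% 0,
                    params$mu1, params$mu2, params$lambda,
                    params$b, params$c,
                    if (is.na(schedule$t0)) -1 else schedule$t0,
                    schedule$cooling, schedule$stages, as.integer(mps),
                    schedule$theta_max, as.integer(seed %% .Machine$integer.max))
  out_chain <- chain0
  out_chain$centroids <- res$centroids
  out_chain$endpoints <- res$endpoints
  list(chain = out_chain, trace = res$trace, best_cost = res$best_cost,
       initial_cost = res$initial_cost, acceptance_rate = res$acceptance_rate,
       t0 = res$t0)
}
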