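# Validation machinery: re-simulate contact matrices from configuration
# ensembles, compare with Spearman rank correlation, resampling stability
# analysis, and the missing-data masking used by the CTCF-rescue protocol.

#' Binary contact matrix of a single configuration
#'
#' Bead pair (i, j) is in contact iff its centroid distance is strictly
#' below `threshold_factor * (r_i + r_j)`; the diagonal is zero.
#'
#' @param chain A `bead_chain`.
#' @param threshold_factor Contact distance in units of the touching
#'   distance (default 1.2).
#' @return Symmetric 0/1 matrix.
#' @export
contacts_from_configuration <- function(chain, threshold_factor = 1.2) {
  d <- pairwise_distances(chain)
  thr <- threshold_factor * outer(chain$radii, chain$radii, `+`)
  out <- (d < thr) * 1
  diag(out) <- 0
  out
}

#' Estimated contact matrix (ECM) of a configuration ensemble
#'
#' Simulates a Hi-C experiment over the ensemble: for every configuration,
#' the entries of each bead pair found in contact are incremented by one.
#'
#' @param configs List of `bead_chain`s of equal length (or a list of
#'   `reconstruction`s).
#' @param threshold_factor See [contacts_from_configuration()].
#' @return List of class `estimated_contact_matrix` with integer `counts`,
#'   `n_configurations` and `threshold_factor`.
#' @export
estimate_contact_matrix <- function(configs, threshold_factor = 1.2) {
  configs <- lapply(configs, function(x)
    if (inherits(x, "reconstruction")) x$chain else x)
  lens <- vapply(configs, chain_length, 0L)
  if (length(unique(lens)) != 1)
    stop("all configurations must have the same number of beads")
  acc <- matrix(0, lens[1], lens[1])
  for (ch in configs)
    acc <- acc + contacts_from_configuration(ch, threshold_factor)
  structure(list(counts = acc, n_configurations = length(configs),
                 threshold_factor = threshold_factor),
            class = "estimated_contact_matrix")
}

#' @export
print.estimated_contact_matrix <- function(x, ...) {
  cat(sprintf("<estimated_contact_matrix> %d x %d, %d configurations, factor %.3g\n",
              nrow(x$counts), ncol(x$counts), x$n_configurations,
              x$threshold_factor))
  invisible(x)
}

#' Spearman correlation between two contact matrices
#'
#' Rank correlation over the strictly-upper-triangle entries, with ties
#' mid-ranked. Bins listed in `exclude_bins` (e.g. masked rows) are left out
#' of the comparison.
#'
#' @param A,B Matrices of the same shape ([contact_matrix()],
#'   `estimated_contact_matrix` or plain).
#' @param use_upper_triangle If `FALSE`, all off-diagonal entries are used
#'   (the result is identical for symmetric input).
#' @param exclude_bins Optional 1-based bin indices to drop from both axes.
#' @return Correlation in `[-1, 1]`; `NaN` (with a warning) if either side
#'   is constant.
#' @export
spearman_compare <- function(A, B, use_upper_triangle = TRUE,
                             exclude_bins = NULL) {
  A <- as_counts(A); B <- as_counts(B)
  if (!all(dim(A) == dim(B))) stop("matrices must have the same shape")
  if (!is.null(exclude_bins) && length(exclude_bins)) {
    A <- A[-exclude_bins, -exclude_bins, drop = FALSE]
    B <- B[-exclude_bins, -exclude_bins, drop = FALSE]
  }
  sel <- if (use_upper_triangle) upper.tri(A) else
    upper.tri(A) | lower.tri(A)
  a <- A[sel]; b <- B[sel]
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    warning("constant matrix: Spearman correlation undefined")
    return(NaN)
  }
  cor(a, b, method = "spearman")
}

as_counts <- function(x) {
  if (inherits(x, "contact_matrix") || inherits(x, "estimated_contact_matrix"))
    x$counts
  else as.matrix(x)
}

#' Resampling stability analysis of ensemble contact matrices
#'
#' For each ensemble size `s`, draws `n_resamples` random subsets of `s`
#' configurations from a sub-pool of the first `s * pool_multiplier` pool
#' members, builds each subset's ECM, correlates it with the reference
#' matrix, and reports the mean and standard deviation of the correlations.
#' The standard deviation curve flattening with `s` indicates how many
#' configurations are statistically sufficient.
#'
#' @param pool List of `bead_chain`s (or `reconstruction`s).
#' @param reference The reference contact matrix block.
#' @param sizes Ensemble sizes to probe (default 50 to 350 by 50).
#' @param n_resamples Resamples per size (default 20).
#' @param pool_multiplier Sub-pool size factor (default 10).
#' @param threshold_factor ECM contact factor.
#' @param seed Integer seed for the resampling.
#' @return Data frame with columns `size`, `mean`, `sd`.
#' @export
stability_analysis <- function(pool, reference, sizes = seq(50, 350, by = 50),
                               n_resamples = 20L, pool_multiplier = 10L,
                               threshold_factor = 1.2, seed = 1L) {
  pool <- lapply(pool, function(x)
    if (inherits(x, "reconstruction")) x$chain else x)
  need <- max(sizes) * pool_multiplier
  if (length(pool) < need)
    stop(sprintf("pool of %d configurations is insufficient: need %d (max size %d x multiplier %d)",
                 length(pool), need, max(sizes), pool_multiplier))
  with_preserved_rng({
    set.seed(seed)
    rows <- lapply(sizes, function(s) {
      sub_pool <- pool[seq_len(s * pool_multiplier)]
      rho <- vapply(seq_len(n_resamples), function(r) {
        pick <- sample.int(length(sub_pool), s)
        ecm <- estimate_contact_matrix(sub_pool[pick], threshold_factor)
        spearman_compare(ecm, reference)
      }, 0)
      data.frame(size = s, mean = mean(rho),
                 sd = if (n_resamples > 1) sd(rho) else 0)
    })
    do.call(rbind, rows)
  })
}

#' Mask rows/columns around given sites (artificially missing data)
#'
#' Zeroes the full rows and columns in a neighbourhood of `halfwidth` bins
#' on each side of every site (clipped at the matrix borders) and flags them
#' in the mask — the protocol used to probe CTCF rescue of missing Hi-C.
#'
#' @param cm A [contact_matrix()].
#' @param site_bins 0-based bin indices of the sites.
#' @param halfwidth Bins removed on each side (default 2, i.e. 5 rows/cols
#'   per interior site).
#' @return The masked [contact_matrix()].
#' @export
mask_matrix <- function(cm, site_bins, halfwidth = 2L) {
  stopifnot(inherits(cm, "contact_matrix"))
  n <- nrow(cm$counts)
  if (any(site_bins < 0 | site_bins >= n)) stop("site bin out of range")
  hit <- unique(unlist(lapply(site_bins, function(s)
    max(0, s - halfwidth):min(n - 1, s + halfwidth)))) + 1
  counts <- cm$counts
  counts[hit, ] <- 0
  counts[, hit] <- 0
  mask <- cm$mask
  mask[hit] <- TRUE
  contact_matrix(counts, axis = cm$axis, mask = mask)
}
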