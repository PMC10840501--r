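# Objective function of the reconstruction: Hi-C data fit (optionally
# augmented with CTCF loop anchors), packing terms driven by H3K27me3 and
# expressed-gene tracks, and the soft non-interpenetration prior. All terms
# depend on the chain only through centroid distances, so they are invariant
# under rigid transforms.

#' Cost-function parameters
#'
#' @param mu1,mu2 Weights of the H3K27me3 packing and expressed-gene
#'   anti-packing terms (dimensionless, >= 0; default 1).
#' @param lambda Weight of the non-interpenetration prior; usually set per
#'   scale by [tune_lambda()].
#' @param b Odd positive integer steering the steepness of the prior's
#'   transitions (default 5).
#' @param c Positive constant steering the width of the prior's
#'   moderate-penalty interval around the touching distance (default 1).
#' @param Dc Chromatin filament diameter in nm (default 30).
#' @param tf_factor Pseudo-count added to the contact matrix at CTCF anchor
#'   pairs (default 100).
#' @param lambda_ratio Target data:prior weight ratio used by
#'   [tune_lambda()] (default 1).
#' @return A list of class `cost_params`.
#' @export
cost_params <- function(mu1 = 1, mu2 = 1, lambda = 1, b = 5L, c = 1,
                        Dc = 30, tf_factor = 100, lambda_ratio = 1) {
  b <- as.integer(b)
  if (b <= 0 || b %% 2 == 0) stop("b must be an odd positive integer")
  if (c <= 0) stop("c must be > 0")
  if (Dc <= 0) stop("Dc must be > 0")
  if (mu1 < 0 || mu2 < 0 || lambda < 0) stop("weights must be >= 0")
  structure(list(mu1 = mu1, mu2 = mu2, lambda = lambda, b = b, c = c,
                 Dc = Dc, tf_factor = tf_factor, lambda_ratio = lambda_ratio),
            class = "cost_params")
}

#' Polymer-scaling distance bounds for a chain element
#'
#' For a chain element of genomic size `rho` kbp and filament diameter `Dc`
#' nm, the minimum and maximum plausible physical sizes are
#' `D_min = Dc * rho^(6/5) / (6*pi)` and `D_max = Dc * rho^(6/5) / (3*pi)`,
#' so `D_max = 2 * D_min` always.
#'
#' @param rho Genomic size in kbp (> 0).
#' @param Dc Chromatin filament diameter in nm (> 0, default 30).
#' @return Named numeric vector `c(D_min, D_max)` in nm.
#' @export
d_min_max <- function(rho, Dc = 30) {
  if (any(rho <= 0)) stop("rho must be > 0")
  if (Dc <= 0) stop("Dc must be > 0")
  base <- Dc * rho^(6 / 5) / (6 * pi)
  c(D_min = base, D_max = 2 * base)
}

#' Build the restrained contact set of a block
#'
#' Off-diagonal pairs whose (possibly CTCF-augmented) count exceeds the
#' threshold; each pair is stored with its count and its touching distance
#' `D_min_ij = r_i + r_j`.
#'
#' @param matrix_or_counts A [contact_matrix()] or a plain symmetric matrix.
#' @param radii Bead radii (nm), one per bin.
#' @param threshold Count threshold; strictly exceeded counts are kept.
#' @return A list of class `contact_set` with fields `i`, `j` (1-based,
#'   `i < j`), `n` (counts) and `dmin` (nm).
#' @export
build_contact_set <- function(matrix_or_counts, radii, threshold) {
  m <- if (inherits(matrix_or_counts, "contact_matrix")) matrix_or_counts$counts
       else as.matrix(matrix_or_counts)
  n_bins <- nrow(m)
  if (length(radii) != n_bins) stop("radii length must match matrix dimension")
  idx <- which(upper.tri(m) & m > threshold, arr.ind = TRUE)
  dimnames(idx) <- NULL
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  structure(list(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                 n = m[idx],
                 dmin = radii[idx[, 1]] + radii[idx[, 2]]),
            class = "contact_set")
}

#' Augment a contact matrix with CTCF anchor-pair pseudo-counts
#'
#' Adds `tf_factor` to every entry at a CTCF bin pair (both triangles).
#' Masked (missing-data) bins still receive the pseudo-count: this is the
#' mechanism that rescues reconstructions where Hi-C rows are missing.
#'
#' @param cm A [contact_matrix()].
#' @param tf_pairs 2-column matrix of 0-based bin index pairs (as returned by
#'   [bins_overlapping()] on a pair track), or `NULL`/empty for no change.
#' @param tf_factor Pseudo-count (default 100).
#' @return A [contact_matrix()]; equal to the input when `tf_pairs` is empty.
#' @export
augment_with_tf <- function(cm, tf_pairs, tf_factor = 100) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (is.null(tf_pairs) || nrow(tf_pairs) == 0) return(cm)
  n <- nrow(cm$counts)
  if (any(tf_pairs < 0) || any(tf_pairs >= n))
    stop("CTCF pair index out of matrix range")
  counts <- cm$counts
  for (r in seq_len(nrow(tf_pairs))) {
    i <- tf_pairs[r, 1] + 1; j <- tf_pairs[r, 2] + 1
    counts[i, j] <- counts[i, j] + tf_factor
    counts[j, i] <- counts[j, i] + tf_factor
  }
  out <- cm
  out$counts <- counts
  out
}

#' Hi-C (or Hi-C + CTCF) data-fit cost
#'
#' `sum over restrained pairs of n_ij * (Dmin_ij / d_ij - 1)^2`: zero iff
#' every restrained pair sits exactly at its touching distance, and growing
#' with the contact count of violated pairs. Coincident centroids of a
#' restrained pair yield `Inf`.
#'
#' @param chain A `bead_chain`.
#' @param contacts A [build_contact_set()] result.
#' @return Non-negative cost (possibly `Inf`).
#' @export
phi_hic <- function(chain, contacts) {
  if (length(contacts$i) == 0) return(0)
  cm <- chain$centroids
  d <- sqrt(rowSums((cm[contacts$i, , drop = FALSE] - cm[contacts$j, , drop = FALSE])^2))
  if (any(d == 0)) return(Inf)
  sum(contacts$n * (contacts$dmin / d - 1)^2)
}

#' H3K27me3 packing cost
#'
#' Active only when the block carries the repressive mark: penalizes the
#' squared excess of the chain's maximum pairwise distance over `D_min`
#' (strict packing is favoured).
#'
#' @param chain A `bead_chain` with >= 2 beads.
#' @param active Logical flag (block carries H3K27me3).
#' @param D_min Target in nm (from [d_min_max()] at the element's rho).
#' @return Non-negative cost; 0 when inactive.
#' @export
phi_chip <- function(chain, active, D_min) {
  if (!isTRUE(active)) return(0)
  (max(pairwise_distances(chain)) - D_min)^2
}

#' Expressed-gene anti-packing cost
#'
#' Active only when the block overlaps expressed genes: penalizes the squared
#' deviation of the chain's minimum pairwise distance from `D_max` (loose
#' packing is favoured).
#'
#' @param chain A `bead_chain` with >= 2 beads.
#' @param active Logical flag (block overlaps expressed genes).
#' @param D_max Target in nm.
#' @return Non-negative cost; 0 when inactive.
#' @export
phi_rna <- function(chain, active, D_max) {
  if (!isTRUE(active)) return(0)
  d <- pairwise_distances(chain)
  (min(d[upper.tri(d)]) - D_max)^2
}

# prior kernel on the normalized distance dt = d / (r_i + r_j)
psi_kernel <- function(dt, b, c) {
  out <- numeric(length(dt))
  out[dt == 0] <- Inf
  pos <- dt > 0
  u <- dt[pos] - 1 / dt[pos]
  out[pos] <- (1 / (2 * dt[pos])) * (1 - c * u^b / (1 + c * abs(u)^b))
  out
}

#' Non-interpenetration prior
#'
#' Soft steric term summed over all bead pairs, as a function of the
#' normalized distance `dt = d_ij / (r_i + r_j)`: approximately `1/d` for
#' `dt << 1` (strong penalty on deep interpenetration), exactly `1/2` at
#' `dt = 1` (touching beads are only mildly penalized), and decaying to zero
#' as `O(dt^-(b+1))` for `dt >> 1` (far pairs unconstrained). `c` widens or
#' narrows the moderate-penalty interval around `dt = 1`; `b` steepens its
#' transitions.
#'
#' @param chain A `bead_chain`.
#' @param b Odd positive integer (default 5).
#' @param c Positive constant (default 1).
#' @return The summed prior; `Inf` if any two centroids coincide.
#' @export
psi <- function(chain, b = 5L, c = 1) {
  if (b <= 0 || b %% 2 == 0) stop("b must be an odd positive integer")
  if (c <= 0) stop("c must be > 0")
  n <- chain_length(chain)
  if (n < 2) return(0)
  d <- pairwise_distances(chain)
  dmin <- outer(chain$radii, chain$radii, `+`)
  dt <- (d / dmin)[upper.tri(d)]
  sum(psi_kernel(dt, b, c))
}

#' Full objective of a block reconstruction
#'
#' `phi_hic + mu1 * phi_chip + mu2 * phi_rna + lambda * psi`, with the terms
#' also returned separately for logging.
#'
#' @param chain A `bead_chain`.
#' @param contacts A [build_contact_set()] result (possibly CTCF-augmented).
#' @param flags List with logical `chip`, `rna` and targets `D_min`, `D_max`
#'   in nm (targets may be omitted when the flags are off).
#' @param params A [cost_params()].
#' @return List with `total` and the components `hic`, `chip`, `rna`, `psi`.
#' @export
total_cost <- function(chain, contacts, flags, params) {
  hic <- phi_hic(chain, contacts)
  chip <- phi_chip(chain, flags$chip %||% FALSE, flags$D_min %||% 0)
  rna <- phi_rna(chain, flags$rna %||% FALSE, flags$D_max %||% 0)
  ps <- psi(chain, params$b, params$c)
  list(total = hic + params$mu1 * chip + params$mu2 * rna + params$lambda * ps,
       hic = hic, chip = chip, rna = rna, psi = ps)
}

#' Tune the prior weight on a scale's initial configuration
#'
#' Sets `lambda = ratio * (data part) / |psi|` evaluated on the initial
#' chain, so the data terms and the prior keep a predefined weight ratio;
#' re-evaluated at each change of scale (the cost magnitudes change with the
#' binning). Falls back to `lambda = ratio` when the prior evaluates to 0.
#'
#' @param chain0 The scale's initial `bead_chain`.
#' @param contacts,flags,params As in [total_cost()].
#' @param ratio Target data:prior ratio (default `params$lambda_ratio`).
#' @return The tuned `lambda`.
#' @export
tune_lambda <- function(chain0, contacts, flags, params,
                        ratio = params$lambda_ratio) {
  if (ratio == 0) return(0)
  hic <- phi_hic(chain0, contacts)
  chip <- phi_chip(chain0, flags$chip %||% FALSE, flags$D_min %||% 0)
  rna <- phi_rna(chain0, flags$rna %||% FALSE, flags$D_max %||% 0)
  ps <- psi(chain0, params$b, params$c)
  data_part <- hic + params$mu1 * chip + params$mu2 * rna
  if (!is.finite(ps) || ps == 0) {
    warning("psi is zero or non-finite on the initial chain; lambda = ratio")
    return(ratio)
  }
  ratio * data_part / abs(ps)
}
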