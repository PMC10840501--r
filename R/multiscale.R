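# Multiscale orchestration: the contact matrix is split into TAD-like
# diagonal blocks; each block's bead chain is annealed independently and
# summarized as a single bead of the next coarser chain; the binned matrix
# drives the recursion, which stops when one large block (plus possibly some
# minimum-size ones) remains. The coarsest chain is then annealed and
# re-expanded top-down through the stored payloads.

#' Decompose a contact matrix into contiguous diagonal blocks
#'
#' Greedy boundary scan: a boundary is cut wherever the cross-boundary
#' contact fraction within a sliding window falls below `tau`; block-size
#' bounds are then enforced by merging undersized blocks into their smaller
#' neighbour and splitting oversized blocks evenly. Deterministic for a
#' fixed input.
#'
#' @param cm A [contact_matrix()] or plain symmetric matrix.
#' @param min_block_bins,max_block_bins Block size bounds (bins).
#' @param tau Cross-contact fraction below which a boundary is cut.
#' @return A list of class `block_partition` with 0-based `starts`,
#'   exclusive `ends`, `sizes`, per-block `internal_contacts` (strict upper
#'   triangle) and `rho_kbp` (genomic block size, when an axis is known).
#' @export
decompose_blocks <- function(cm, min_block_bins = 3L, max_block_bins = 40L,
                             tau = 0.1) {
  counts <- if (inherits(cm, "contact_matrix")) cm$counts else as.matrix(cm)
  axis <- if (inherits(cm, "contact_matrix")) cm$axis else NULL
  n <- nrow(counts)
  if (n == 0) stop("empty matrix")
  cuts <- integer()
  if (n > min_block_bins) {
    w0 <- max(min_block_bins, 3L)
    for (k in seq_len(n - 1)) {           # boundary between bins k and k+1
      w <- min(w0, k, n - k)
      left <- (k - w + 1):k
      right <- (k + 1):(k + w)
      cross <- sum(counts[left, right, drop = FALSE])
      ul <- counts[left, left, drop = FALSE]
      ur <- counts[right, right, drop = FALSE]
      intra <- sum(ul[upper.tri(ul)]) + sum(ur[upper.tri(ur)])
      denom <- cross + intra
      frac <- if (denom > 0) cross / denom else 0
      if (frac < tau) cuts <- c(cuts, k)
    }
  }
  sizes <- diff(c(0L, cuts, n))
  # merge undersized blocks into the smaller neighbour (left on ties)
  repeat {
    small <- which(sizes < min_block_bins)
    if (length(small) == 0 || length(sizes) == 1) break
    b <- small[1]
    merge_left <- if (b == 1) FALSE else if (b == length(sizes)) TRUE
                  else sizes[b - 1] <= sizes[b + 1]
    if (merge_left) {
      sizes[b - 1] <- sizes[b - 1] + sizes[b]
    } else {
      sizes[b + 1] <- sizes[b + 1] + sizes[b]
    }
    sizes <- sizes[-b]
  }
  # split oversized blocks evenly
  out_sizes <- integer()
  for (s in sizes) {
    if (s <= max_block_bins) {
      out_sizes <- c(out_sizes, s)
    } else {
      parts <- ceiling(s / max_block_bins)
      base <- s %/% parts
      extra <- s %% parts
      out_sizes <- c(out_sizes, rep(base + 1L, extra), rep(base, parts - extra))
    }
  }
  ends <- cumsum(out_sizes)
  starts <- c(0L, ends[-length(ends)])
  internal <- vapply(seq_along(starts), function(b) {
    idx <- (starts[b] + 1):ends[b]
    sub <- counts[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)])
  }, 0)
  rho <- if (!is.null(axis)) out_sizes * axis$bin_size / 1000 else rep(NA_real_, length(starts))
  structure(list(starts = as.integer(starts), ends = as.integer(ends),
                 sizes = as.integer(out_sizes), internal_contacts = internal,
                 rho_kbp = rho),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("<block_partition> %d blocks, sizes %s\n", length(x$starts),
              paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Bin a contact matrix to the block scale
#'
#' Coarse entry (A, B) is the sum of the fine entries over block A x block
#' B; the grand total is conserved exactly. The coarse diagonal is the full
#' within-block submatrix sum (the strict-upper-triangle internal counts
#' are carried by the partition).
#'
#' @param cm A [contact_matrix()].
#' @param partition A [decompose_blocks()] result.
#' @return A coarse [contact_matrix()] whose axis carries the mean block
#'   width and a `block_spans` attribute with the exact per-block bp spans.
#' @export
bin_matrix <- function(cm, partition) {
  stopifnot(inherits(cm, "contact_matrix"))
  nb <- length(partition$starts)
  groups <- rep(seq_len(nb), partition$sizes)
  coarse <- rowsum(t(rowsum(cm$counts, groups)), groups)
  dimnames(coarse) <- NULL
  ax <- cm$axis
  coarse_axis <- genomic_axis(ax$chromosome, ax$start,
                              max(1, round(ax$n_bins * ax$bin_size / nb)), nb)
  mask <- vapply(seq_len(nb), function(b)
    all(cm$mask[(partition$starts[b] + 1):partition$ends[b]]), TRUE)
  out <- contact_matrix(coarse, axis = coarse_axis, mask = mask)
  attr(out, "block_spans") <- cbind(ax$start + partition$starts * ax$bin_size,
                                    ax$start + partition$ends * ax$bin_size)
  out
}

#' Estimate finest-scale bead radii from internal contact counts
#'
#' The radius interpolates exponentially between the polymer-scaling
#' envelope bounds at the element's genomic size: `D_max / 2` for zero
#' internal contacts (loosest) down towards `D_min / 2` as the count grows
#' (the more internal contacts, the smaller the bead), with the sibling
#' mean count as the decay scale.
#'
#' @param rho Genomic size of the element in kbp.
#' @param internal_contacts Internal contact count(s) of the element.
#' @param Dc Chromatin filament diameter (nm).
#' @param n_ref Decay scale; defaults to `mean(internal_contacts)`. When the
#'   reference is 0 every radius takes the loosest value `D_max / 2`.
#' @return Radii in nm, bounded in `[D_min/2, D_max/2]`.
#' @export
estimate_radius_fine <- function(rho, internal_contacts, Dc = 30,
                                 n_ref = mean(internal_contacts)) {
  dm <- d_min_max(rho, Dc)
  if (!is.finite(n_ref) || n_ref <= 0) {
    return(rep_len(dm[["D_max"]] / 2, length(internal_contacts)))
  }
  0.5 * (dm[["D_min"]] + (dm[["D_max"]] - dm[["D_min"]]) *
           exp(-internal_contacts / n_ref))
}

# fraction of [span_start, span_end) covered by the union of track intervals
coverage_fraction <- function(track, chromosome, span_start, span_end) {
  if (is.null(track) || nrow(track) == 0) return(0)
  keep <- track$chromosome == chromosome &
    track$end > span_start & track$start < span_end
  if (!any(keep)) return(0)
  s <- pmax(track$start[keep], span_start)
  e <- pmin(track$end[keep], span_end)
  o <- order(s)
  s <- s[o]; e <- e[o]
  covered <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (k in seq_along(s)[-1]) {
    if (s[k] <= cur_e) cur_e <- max(cur_e, e[k])
    else { covered <- covered + (cur_e - cur_s); cur_s <- s[k]; cur_e <- e[k] }
  }
  covered <- covered + (cur_e - cur_s)
  covered / (span_end - span_start)
}

# compact-domain confinement radius for initial configurations: a sphere at
# about 20% bead volume fraction, the packing regime of a TAD-like domain
domain_confine_radius <- function(radii) {
  mean(radii) * (5 * length(radii))^(1 / 3)
}

# deterministic per-block seed derived from the run seed (kept below 2^31)
derive_seed <- function(seed, level, block) {
  ((as.double(seed) * 1000003 + level * 10007 + block * 101) %% 2147483629) + 1
}

with_preserved_rng <- function(expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  expr
}

#' Reconstruct one chromatin configuration from a contact matrix
#'
#' Runs the full multiscale scheme: per scale, decompose into diagonal
#' blocks, build each block's contact set (CTCF-augmented at the finest
#' scale only), anneal the block chain, summarize it as a coarser bead;
#' recurse on the binned matrix until one large block (or only minimum-size
#' blocks) remains; anneal the coarsest chain and re-expand top-down to the
#' input resolution. One call returns one individual of the configuration
#' population; distinct seeds give distinct near-optimal configurations.
#'
#' @param cm A [contact_matrix()].
#' @param ctcf CTCF anchors: a `pair_track`, or a 2-column matrix of 0-based
#'   bin pairs, or `NULL`.
#' @param h3k27me3,expressed Optional `interval_track`s (finest scale only).
#' @param config A [run_config()].
#' @param seed Integer seed; the single source of randomness.
#' @return List of class `reconstruction`: `chain` (finest-scale
#'   `bead_chain`), `levels` (per-level diagnostics data frame), `seed`.
#' @export
reconstruct <- function(cm, ctcf = NULL, h3k27me3 = NULL, expressed = NULL,
                        config = run_config(), seed = 1L) {
  stopifnot(inherits(cm, "contact_matrix"))
  tf_pairs <- if (inherits(ctcf, "pair_track")) bins_overlapping(ctcf, cm$axis)
              else if (is.matrix(ctcf)) ctcf else NULL
  params <- cost_params(mu1 = config$mu1, mu2 = config$mu2, b = config$b,
                        c = config$c, Dc = config$Dc,
                        tf_factor = config$tf_factor,
                        lambda_ratio = config$lambda_ratio)
  schedule <- anneal_schedule(t0 = config$t0, cooling = config$cooling,
                              stages = config$stages,
                              theta_max = config$theta_max)
  with_preserved_rng(
    reconstruct_impl(cm, tf_pairs, h3k27me3, expressed, params, schedule,
                     config, seed))
}

reconstruct_impl <- function(cm, tf_pairs, h3k27me3, expressed, params,
                             schedule, config, seed) {
  M <- cm
  level <- 0L
  prev_beads <- NULL
  diag_rows <- list()
  top_chain <- NULL
  fine_axis <- cm$axis
  repeat {
    part <- decompose_blocks(M, config$min_block_bins, config$max_block_bins,
                             config$tau)
    nb <- length(part$starts)
    block_beads <- vector("list", nb)
    block_chains <- vector("list", nb)
    for (b in seq_len(nb)) {
      idx <- (part$starts[b] + 1):part$ends[b]
      res <- reconstruct_block(M, idx, level, prev_beads, tf_pairs,
                               h3k27me3, expressed, params, schedule, config,
                               derive_seed(seed, level, b), fine_axis)
      block_chains[[b]] <- res$chain
      block_beads[[b]] <- summarize_chain_as_bead(res$chain)
      diag_rows[[length(diag_rows) + 1]] <- data.frame(
        level = level, block = b, n_bins = length(idx),
        internal_contacts = part$internal_contacts[b],
        threshold = res$threshold, lambda = res$lambda,
        best_cost = res$best_cost, acceptance = res$acceptance)
    }
    if (nb == 1) {
      top_chain <- block_chains[[1]]
      break
    }
    if (all(part$sizes <= config$min_block_bins)) {
      # coarsest scale: anneal the chain of remaining block-beads jointly
      coarse <- bin_matrix(M, part)
      res <- anneal_bead_list(block_beads, coarse$counts, params, schedule,
                              config, derive_seed(seed, level + 1L, 0L),
                              level + 1L)
      top_chain <- res$chain
      diag_rows[[length(diag_rows) + 1]] <- data.frame(
        level = level + 1L, block = 1L, n_bins = nb,
        internal_contacts = sum(coarse$counts[upper.tri(coarse$counts)]),
        threshold = res$threshold, lambda = res$lambda,
        best_cost = res$best_cost, acceptance = res$acceptance)
      break
    }
    M <- bin_matrix(M, part)
    prev_beads <- block_beads
    level <- level + 1L
  }
  # top-down refinement to the input resolution
  chain <- top_chain
  while (chain_length(chain) > 0 &&
         all(!vapply(chain$payloads, is.null, TRUE))) {
    chain <- refine_chain(chain)
  }
  structure(list(chain = chain, levels = do.call(rbind, diag_rows),
                 seed = seed),
            class = "reconstruction")
}

# reconstruct a single diagonal block at the given level
reconstruct_block <- function(M, idx, level, prev_beads, tf_pairs,
                              h3k27me3, expressed, params, schedule, config,
                              seed, fine_axis) {
  sub <- M$counts[idx, idx, drop = FALSE]
  nb <- length(idx)
  flags <- list(chip = FALSE, rna = FALSE, D_min = 0, D_max = 0)
  if (level == 0L) {
    if (!is.null(tf_pairs) && nrow(tf_pairs) > 0) {
      keep <- tf_pairs[, 1] %in% (idx - 1) & tf_pairs[, 2] %in% (idx - 1)
      if (any(keep)) {
        loc <- cbind(match(tf_pairs[keep, 1], idx - 1),
                     match(tf_pairs[keep, 2], idx - 1))
        for (r in seq_len(nrow(loc))) {
          sub[loc[r, 1], loc[r, 2]] <- sub[loc[r, 1], loc[r, 2]] + params$tf_factor
          sub[loc[r, 2], loc[r, 1]] <- sub[loc[r, 2], loc[r, 1]] + params$tf_factor
        }
      }
    }
    rho_elem <- fine_axis$bin_size / 1000
    radii <- estimate_radius_fine(rho_elem, diag(M$counts)[idx], config$Dc)
    if (nb >= 2) {
      dm <- d_min_max(rho_elem, config$Dc)
      span_bp <- c(fine_axis$start + (idx[1] - 1) * fine_axis$bin_size,
                   fine_axis$start + idx[nb] * fine_axis$bin_size)
      chip_cov <- coverage_fraction(h3k27me3, fine_axis$chromosome,
                                    span_bp[1], span_bp[2])
      rna_cov <- coverage_fraction(expressed, fine_axis$chromosome,
                                   span_bp[1], span_bp[2])
      flags <- list(chip = chip_cov >= config$track_overlap_fraction,
                    rna = rna_cov >= config$track_overlap_fraction,
                    D_min = dm[["D_min"]], D_max = dm[["D_max"]])
    }
    spans <- cbind(fine_axis$start + (idx - 1) * fine_axis$bin_size,
                   fine_axis$start + idx * fine_axis$bin_size)
    set.seed(seed)
    chain0 <- random_walk_chain(radii, spans = spans, scale_level = 0L,
                                confine_radius = domain_confine_radius(radii))
  } else {
    beads <- prev_beads[idx]
    radii <- vapply(beads, `[[`, 0, "radius")
    set.seed(seed)
    chain0 <- random_place_chain(beads, scale_level = level,
                                 confine_radius = domain_confine_radius(radii))
  }
  offdiag <- sub[upper.tri(sub)]
  nz <- offdiag[offdiag > 0]
  threshold <- if (length(nz) == 0) Inf else
    as.numeric(quantile(nz, config$contact_threshold_quantile))
  contacts <- build_contact_set(sub, radii, threshold)
  params$lambda <- tune_lambda(chain0, contacts, flags, params)
  ann <- anneal(chain0, contacts, flags, params, schedule, seed = seed)
  list(chain = ann$chain, threshold = threshold, lambda = params$lambda,
       best_cost = ann$best_cost, acceptance = ann$acceptance_rate)
}

# anneal a chain assembled from already-summarized beads (coarsest scale)
anneal_bead_list <- function(beads, counts, params, schedule, config, seed,
                             level) {
  radii <- vapply(beads, `[[`, 0, "radius")
  set.seed(seed)
  chain0 <- random_place_chain(beads, scale_level = level,
                               confine_radius = domain_confine_radius(radii))
  offdiag <- counts[upper.tri(counts)]
  nz <- offdiag[offdiag > 0]
  threshold <- if (length(nz) == 0) Inf else
    as.numeric(quantile(nz, config$contact_threshold_quantile))
  contacts <- build_contact_set(counts, radii, threshold)
  flags <- list(chip = FALSE, rna = FALSE, D_min = 0, D_max = 0)
  params$lambda <- tune_lambda(chain0, contacts, flags, params)
  ann <- anneal(chain0, contacts, flags, params, schedule, seed = seed)
  list(chain = ann$chain, threshold = threshold, lambda = params$lambda,
       best_cost = ann$best_cost, acceptance = ann$acceptance_rate)
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("<reconstruction> %d beads at finest scale, %d block anneals, seed %s\n",
              chain_length(x$chain), nrow(x$levels), format(x$seed)))
  invisible(x)
}
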