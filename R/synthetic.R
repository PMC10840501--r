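# Synthetic toy chromatin: a ground-truth 3D chain with planted loops,
# packed (H3K27me3-like) and open (expressed-gene-like) regions, and the
# Hi-C-like matrix obtained by accumulating thresholded contacts over many
# jittered copies of the chain — the population-of-cells picture Hi-C sums
# over. Concordant CTCF/H3K27me3/expression tracks are emitted alongside,
# so every pipeline stage is testable without external data.

#' Specification of a synthetic toy-chromatin fixture
#'
#' @param n_beads Number of beads (bins); default 40.
#' @param bead_radius Bead radius in nm (default 15, half the 30 nm
#'   filament diameter).
#' @param n_cells Number of perturbed copies accumulated into the matrix
#'   (default 200).
#' @param loop_pairs 2-column matrix (or list of length-2 vectors) of
#'   1-based bead index pairs pulled into contact, emulating CTCF loops.
#' @param packed_regions,open_regions 2-column matrices of 1-based inclusive
#'   bead ranges that are compacted (step x 0.6) or decompacted (step x 1.6).
#' @param jitter_sd Per-cell Gaussian centroid jitter, nm (default 10).
#' @param contact_factor Contact threshold in units of the touching
#'   distance (default 1.2).
#' @param bin_size Genomic bin size in bp for the emitted axis (default 5000).
#' @param seed Integer seed (default 1).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_beads = 40L, bead_radius = 15, n_cells = 200L,
                           loop_pairs = NULL, packed_regions = NULL,
                           open_regions = NULL, jitter_sd = 10,
                           contact_factor = 1.2, bin_size = 5000L, seed = 1L) {
  as_pairs <- function(x) {
    if (is.null(x)) return(matrix(integer(), 0, 2))
    if (is.list(x)) x <- do.call(rbind, x)
    x <- matrix(as.integer(x), ncol = 2)
    x
  }
  loop_pairs <- as_pairs(loop_pairs)
  packed_regions <- as_pairs(packed_regions)
  open_regions <- as_pairs(open_regions)
  if (nrow(loop_pairs) && any(loop_pairs < 1 | loop_pairs > n_beads))
    stop("loop pair index out of range")
  structure(list(n_beads = as.integer(n_beads), bead_radius = bead_radius,
                 n_cells = as.integer(n_cells), loop_pairs = loop_pairs,
                 packed_regions = packed_regions, open_regions = open_regions,
                 jitter_sd = jitter_sd, contact_factor = contact_factor,
                 bin_size = as.integer(bin_size), seed = as.integer(seed)),
            class = "synthetic_spec")
}

in_regions <- function(k, regions) {
  if (nrow(regions) == 0) return(rep(FALSE, length(k)))
  vapply(k, function(x) any(x >= regions[, 1] & x <= regions[, 2]), TRUE)
}

#' Generate the ground-truth toy chain
#'
#' A confined self-avoiding random walk on the centroids with fixed step
#' (twice the bead radius), compressed within packed regions and expanded
#' within open regions. Confinement to a sphere of radius
#' `bead_radius * (5 * n_beads)^(1/3)` (about 20% volume fraction) makes
#' the chain a compact, TAD-like globule with substantial long-range
#' contact frequency, which is the regime the reconstruction method
#' assumes. Loops are planted during the walk: steps approaching a loop's
#' later anchor are biased so that it stays reachable and finally lands at
#' about the touching distance (2 radii) from its earlier partner.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A `bead_chain` of `n_beads` beads.
#' @export
generate_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_beads; r <- spec$bead_radius
  r_conf <- r * (5 * n)^(1 / 3)
  with_preserved_rng({
    set.seed(spec$seed)
    packed <- in_regions(seq_len(n), spec$packed_regions)
    open_r <- in_regions(seq_len(n), spec$open_regions)
    step_fac <- rep(1, n - 1)
    for (k in seq_len(n - 1)) {
      if (packed[k] && packed[k + 1]) step_fac[k] <- 0.6
      else if (open_r[k] && open_r[k + 1]) step_fac[k] <- 1.6
    }
    # earliest placed partner of each later loop anchor
    loops <- spec$loop_pairs
    if (nrow(loops)) loops <- cbind(pmin(loops[, 1], loops[, 2]),
                                    pmax(loops[, 1], loops[, 2]))
    centroids <- matrix(0, n, 3)
    for (k in seq_len(n - 1)) {
      step <- 2 * r * step_fac[k]
      # guidance: keep the nearest upcoming loop anchor reachable, and land
      # it at ~2r from its partner on the final step
      guide <- NULL; slack <- Inf
      if (nrow(loops)) {
        upcoming <- loops[, 1] <= k & loops[, 2] > k
        if (any(upcoming)) {
          w <- which(upcoming)[which.min(loops[upcoming, 2])]
          guide <- centroids[loops[w, 1], ]
          slack <- (loops[w, 2] - (k + 1)) * 2 * r
        }
      }
      best <- NULL; best_score <- -Inf
      for (try in 1:60) {
        z <- runif(1, -1, 1); phi <- runif(1, 0, 2 * pi)
        u <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
        cand <- centroids[k, ] + step * u
        confined <- sqrt(sum(cand^2)) <= r_conf
        clear <- if (k >= 2) {
          prev <- centroids[seq_len(k - 1), , drop = FALSE]
          min(sqrt(rowSums(sweep(prev, 2, cand)^2)))
        } else Inf
        miss <- if (is.null(guide)) 0 else {
          dg <- sqrt(sum((cand - guide)^2))
          if (slack > 0) max(0, dg - 2 * r - slack) else abs(dg - 2 * r)
        }
        score <- min(clear, 0.75 * step) - (!confined) * step - 2 * miss
        if (score > best_score) { best_score <- score; best <- cand }
        if (confined && clear >= 0.75 * step && miss <= 1e-9 && is.null(guide))
          break
      }
      centroids[k + 1, ] <- best
    }
    endpoints <- matrix(0, n + 1, 3)
    endpoints[2:n, ] <- (centroids[-n, , drop = FALSE] + centroids[-1, , drop = FALSE]) / 2
    endpoints[1, ] <- centroids[1, ] - (centroids[2, ] - centroids[1, ]) / 2
    endpoints[n + 1, ] <- centroids[n, ] + (centroids[n, ] - centroids[n - 1, ]) / 2
    spans <- cbind((seq_len(n) - 1) * spec$bin_size, seq_len(n) * spec$bin_size)
    chain <- new_chain(centroids = centroids, endpoints = endpoints,
                       radii = rep(r, n), spans = spans, scale_level = 0L)
    if (nrow(loops) > 0) {
      d <- pairwise_distances(chain)
      for (p in seq_len(nrow(loops))) {
        dp <- d[loops[p, 1], loops[p, 2]]
        if (dp >= 3 * r)
          warning(sprintf("loop (%d, %d) closure incomplete: d = %.1f nm",
                          loops[p, 1], loops[p, 2], dp))
      }
    }
    chain
  })
}

#' Simulate a Hi-C-like matrix (and concordant tracks) from a structure
#'
#' Accumulates, over `n_cells` jittered copies of the chain (iid Gaussian
#' centroid jitter), the binary contact indicator at threshold
#' `contact_factor * (r_i + r_j)`; emits a CTCF-like pair track at the
#' planted loop anchors, an H3K27me3 track over the packed regions and an
#' expressed-gene track over the open regions.
#'
#' @param chain The ground-truth `bead_chain`.
#' @param spec The [synthetic_spec()] that generated it.
#' @return List with `matrix` (a [contact_matrix()]), `ctcf` (`pair_track`),
#'   `h3k27me3` and `expressed` (`interval_track`s), and `ground_truth`.
#' @export
matrix_from_structure <- function(chain, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- chain_length(chain)
  thr <- spec$contact_factor * outer(chain$radii, chain$radii, `+`)
  with_preserved_rng({
    set.seed(spec$seed + 1L)
    acc <- matrix(0, n, n)
    for (cell in seq_len(spec$n_cells)) {
      pts <- chain$centroids +
        matrix(rnorm(3 * n, sd = spec$jitter_sd), n, 3)
      d <- as.matrix(dist(pts))
      acc <- acc + (d < thr)
    }
    diag(acc) <- 0
    axis <- genomic_axis("chrS", 0, spec$bin_size, n)
    cm <- contact_matrix(acc, axis = axis)
    bs <- spec$bin_size
    ctcf <- if (nrow(spec$loop_pairs) > 0) {
      i <- spec$loop_pairs[, 1] - 1; j <- spec$loop_pairs[, 2] - 1
      pair_track("chrS", i * bs, (i + 1) * bs, "chrS", j * bs, (j + 1) * bs)
    } else pair_track(character(), numeric(), numeric(), character(),
                      numeric(), numeric())
    region_track <- function(regions, kind) {
      if (nrow(regions) == 0)
        return(interval_track(character(), numeric(), numeric(), kind = kind))
      interval_track("chrS", (regions[, 1] - 1) * bs, regions[, 2] * bs,
                     kind = kind)
    }
    list(matrix = cm, ctcf = ctcf,
         h3k27me3 = region_track(spec$packed_regions, "H3K27ME3"),
         expressed = region_track(spec$open_regions, "expressed_gene"),
         ground_truth = chain)
  })
}

#' Generate and write a complete fixture set to disk
#'
#' Emits exactly the formats the readers consume (dense TSV matrix +
#' sidecar, BEDPE, BED), so command-line runs on fixtures look identical to
#' runs on real data.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [synthetic_spec()].
#' @return Invisibly, the list from [matrix_from_structure()] with the file
#'   paths attached as `paths`.
#' @export
write_fixture_set <- function(dir, spec = synthetic_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- matrix_from_structure(generate_ground_truth(spec), spec)
  paths <- list(matrix = file.path(dir, "matrix.tsv"),
                ctcf = file.path(dir, "ctcf.bedpe"),
                h3k27me3 = file.path(dir, "h3k27me3.bed"),
                expressed = file.path(dir, "expressed.bed"),
                ground_truth = file.path(dir, "ground_truth.tsv"))
  write_contact_matrix(fx$matrix, paths$matrix)
  write_pairs <- fx$ctcf
  writeLines(if (nrow(write_pairs) == 0) character() else
    sprintf("%s\t%d\t%d\t%s\t%d\t%d", write_pairs$chrom1,
            as.integer(write_pairs$start1), as.integer(write_pairs$end1),
            write_pairs$chrom2, as.integer(write_pairs$start2),
            as.integer(write_pairs$end2)), paths$ctcf)
  write_bed <- function(track, path) {
    writeLines(if (nrow(track) == 0) character() else
      sprintf("%s\t%d\t%d\t%s", track$chromosome, as.integer(track$start),
              as.integer(track$end), track$label), path)
  }
  write_bed(fx$h3k27me3, paths$h3k27me3)
  write_bed(fx$expressed, paths$expressed)
  write_configuration(fx$ground_truth, paths$ground_truth, "table")
  fx$paths <- paths
  invisible(fx)
}
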