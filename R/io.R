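# Readers/writers for contact matrices, BED/BEDPE tracks, bead-chain
# configurations and run configuration files. All coordinates are 0-based,
# half-open, both internally and on disk (BED convention).

#' Genomic axis of a contact matrix
#'
#' Describes the binning of one chromosomal region: bin `k` (0-based) spans
#' `[start + k*bin_size, start + (k+1)*bin_size)` in base pairs.
#'
#' @param chromosome Chromosome label, e.g. `"chr12"`.
#' @param start 0-based start coordinate of bin 0, in bp.
#' @param bin_size Bin width in bp (> 0).
#' @param n_bins Number of bins (> 0).
#' @return An object of class `genomic_axis`.
#' @export
genomic_axis <- function(chromosome, start, bin_size, n_bins) {
  start <- as.numeric(start); bin_size <- as.numeric(bin_size)
  n_bins <- as.integer(n_bins)
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (n_bins <= 0) stop("n_bins must be > 0")
  if (start < 0) stop("start must be >= 0")
  structure(list(chromosome = as.character(chromosome), start = start,
                 bin_size = bin_size, n_bins = n_bins),
            class = "genomic_axis")
}

#' @export
print.genomic_axis <- function(x, ...) {
  cat(sprintf("<genomic_axis> %s:%d-%d, %d bins of %d bp\n", x$chromosome,
              x$start, x$start + x$n_bins * x$bin_size, x$n_bins, x$bin_size))
  invisible(x)
}

#' Contact matrix with genomic bin coordinates
#'
#' A symmetric non-negative matrix of contact counts between the bins of a
#' [genomic_axis()], plus a per-bin mask flagging missing (all-zero)
#' rows/columns.
#'
#' @param counts Square numeric matrix, symmetric, entries >= 0.
#' @param axis A [genomic_axis()]; defaults to an anonymous axis with 5 kbp
#'   bins starting at 0.
#' @param mask Logical vector of masked bins; by default bins whose whole row
#'   and column are zero are flagged.
#' @return An object of class `contact_matrix` with fields `counts`, `axis`,
#'   `mask`.
#' @export
contact_matrix <- function(counts, axis = NULL, mask = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("contact matrix must be square")
  if (any(counts < 0)) stop("contact matrix entries must be non-negative")
  rel <- max(abs(counts - t(counts))) / max(1, max(abs(counts)))
  if (rel > 1e-6) stop("contact matrix asymmetric beyond tolerance")
  counts <- (counts + t(counts)) / 2
  dimnames(counts) <- NULL
  n <- nrow(counts)
  if (is.null(axis)) axis <- genomic_axis("chrS", 0, 5000, n)
  if (axis$n_bins != n) stop("axis n_bins does not match matrix dimension")
  if (is.null(mask)) {
    mask <- rowSums(counts) == 0 & colSums(counts) == 0
  }
  if (length(mask) != n) stop("mask length must match matrix dimension")
  structure(list(counts = counts, axis = axis, mask = as.logical(mask)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d x %d bins (%s), %d masked, total contacts %g\n",
              nrow(x$counts), ncol(x$counts), x$axis$chromosome,
              sum(x$mask), sum(x$counts)))
  invisible(x)
}

#' Read a dense contact matrix with its coordinate sidecar
#'
#' The matrix file is whitespace/tab-separated dense text; the sidecar (or an
#' explicit [genomic_axis()]) supplies chromosome, start and bin size as
#' `key = value` lines (`chromosome`, `start`, `bin_size`).
#'
#' @param path Matrix file path.
#' @param axis_spec A [genomic_axis()], or the path of a sidecar file; if
#'   `NULL`, `paste0(path, ".axis")` is tried, else an anonymous axis is used.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, axis_spec = NULL) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (!is.numeric(m)) stop(sprintf("non-numeric entries in %s", path))
  if (nrow(m) != ncol(m))
    stop(sprintf("matrix in %s is not square (%d x %d)", path, nrow(m), ncol(m)))
  if (any(m < 0)) stop(sprintf("negative entry in %s", path))
  axis <- NULL
  if (inherits(axis_spec, "genomic_axis")) {
    axis <- axis_spec
    axis$n_bins <- nrow(m)
  } else {
    sidecar <- if (is.character(axis_spec)) axis_spec else paste0(path, ".axis")
    if (file.exists(sidecar)) {
      kv <- read_key_values(sidecar)
      axis <- genomic_axis(kv[["chromosome"]], as.numeric(kv[["start"]]),
                           as.numeric(kv[["bin_size"]]), nrow(m))
    }
  }
  contact_matrix(m, axis = axis)
}

#' Write a contact matrix and its sidecar
#'
#' @param cm A [contact_matrix()].
#' @param path Output matrix path; the sidecar is written to
#'   `paste0(path, ".axis")`.
#' @export
write_contact_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  write.table(cm$counts, path, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  ax <- cm$axis
  writeLines(c(sprintf("chromosome = %s", ax$chromosome),
               sprintf("start = %d", as.integer(ax$start)),
               sprintf("bin_size = %d", as.integer(ax$bin_size))),
             paste0(path, ".axis"))
  invisible(NULL)
}

read_key_values <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop(sprintf("malformed 'key = value' line: %s", ln))
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    val <- gsub('^"|"$', "", val)
    kv[[key]] <- val
  }
  kv
}

#' Read an interval track (BED, 3+ columns)
#'
#' Coordinates are preserved as 0-based half-open. Lines starting with `#`
#' (and BED `track`/`browser` lines) are skipped.
#'
#' @param path BED file path.
#' @param kind Track kind, one of `"H3K27ME3"` or `"expressed_gene"`.
#' @return An object of class `interval_track`: data frame with columns
#'   `chromosome`, `start`, `end`, `label`, plus the `kind` attribute.
#' @export
read_interval_track <- function(path, kind = c("H3K27ME3", "expressed_gene")) {
  kind <- match.arg(kind)
  lines <- read_track_lines(path)
  if (length(lines) == 0) return(interval_track(character(), numeric(), numeric(), kind = kind))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) == 1) f <- strsplit(lines[[i]], "[[:space:]]+")[[1]]
    if (length(f) < 3)
      stop(sprintf("%s line %d: expected >= 3 columns, got %d", path, i, length(f)))
    s <- as.numeric(f[2]); e <- as.numeric(f[3])
    if (is.na(s) || is.na(e)) stop(sprintf("%s line %d: non-numeric coordinates", path, i))
    if (s >= e) stop(sprintf("%s line %d: start %g >= end %g", path, i, s, e))
    list(chromosome = f[1], start = s, end = e,
         label = if (length(f) >= 4) f[4] else ".")
  })
  interval_track(vapply(rows, `[[`, "", "chromosome"),
                 vapply(rows, `[[`, 0, "start"),
                 vapply(rows, `[[`, 0, "end"),
                 vapply(rows, `[[`, "", "label"), kind = kind)
}

#' Construct an interval track in code
#'
#' @param chromosome,start,end,label Parallel vectors (0-based half-open).
#' @param kind `"H3K27ME3"` or `"expressed_gene"`.
#' @return An `interval_track`.
#' @export
interval_track <- function(chromosome, start, end, label = NULL,
                           kind = c("H3K27ME3", "expressed_gene")) {
  kind <- match.arg(kind)
  if (is.null(label)) label <- rep(".", length(start))
  if (any(start >= end)) stop("interval start must be < end")
  df <- data.frame(chromosome = as.character(chromosome),
                   start = as.numeric(start), end = as.numeric(end),
                   label = as.character(label), stringsAsFactors = FALSE)
  structure(df, class = c("interval_track", "data.frame"), kind = kind)
}

#' Read an anchor-pair track (BEDPE, 6+ columns)
#'
#' Pairs are unordered: each pair's anchors are put in canonical order
#' (earlier anchor first) and duplicates are dropped.
#'
#' @param path BEDPE file path.
#' @return An object of class `pair_track`: data frame with columns `chrom1`,
#'   `start1`, `end1`, `chrom2`, `start2`, `end2`.
#' @export
read_pair_track <- function(path) {
  lines <- read_track_lines(path)
  if (length(lines) == 0)
    return(pair_track(character(), numeric(), numeric(), character(), numeric(), numeric()))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) == 1) f <- strsplit(lines[[i]], "[[:space:]]+")[[1]]
    if (length(f) < 6)
      stop(sprintf("%s line %d: expected >= 6 columns, got %d", path, i, length(f)))
    co <- suppressWarnings(as.numeric(f[c(2, 3, 5, 6)]))
    if (any(is.na(co))) stop(sprintf("%s line %d: non-numeric coordinates", path, i))
    if (co[1] >= co[2] || co[3] >= co[4])
      stop(sprintf("%s line %d: anchor start >= end", path, i))
    list(chrom1 = f[1], start1 = co[1], end1 = co[2],
         chrom2 = f[4], start2 = co[3], end2 = co[4])
  })
  pair_track(vapply(rows, `[[`, "", "chrom1"), vapply(rows, `[[`, 0, "start1"),
             vapply(rows, `[[`, 0, "end1"), vapply(rows, `[[`, "", "chrom2"),
             vapply(rows, `[[`, 0, "start2"), vapply(rows, `[[`, 0, "end2"))
}

#' Construct an anchor-pair track in code
#'
#' @param chrom1,start1,end1,chrom2,start2,end2 Parallel anchor coordinates
#'   (0-based half-open).
#' @return A `pair_track` with canonically ordered, deduplicated pairs.
#' @export
pair_track <- function(chrom1, start1, end1, chrom2, start2, end2) {
  df <- data.frame(chrom1 = as.character(chrom1), start1 = as.numeric(start1),
                   end1 = as.numeric(end1), chrom2 = as.character(chrom2),
                   start2 = as.numeric(start2), end2 = as.numeric(end2),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    flip <- df$chrom2 < df$chrom1 |
      (df$chrom2 == df$chrom1 & (df$start2 < df$start1 |
        (df$start2 == df$start1 & df$end2 < df$end1)))
    if (any(flip)) {
      tmp <- df[flip, c("chrom2", "start2", "end2")]
      df[flip, c("chrom2", "start2", "end2")] <- df[flip, c("chrom1", "start1", "end1")]
      df[flip, c("chrom1", "start1", "end1")] <- tmp
    }
    df <- unique(df)
    rownames(df) <- NULL
  }
  structure(df, class = c("pair_track", "data.frame"))
}

read_track_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & !grepl("^(track|browser)\\b", lines) & nzchar(trimws(lines))
  as.list(lines[keep])
}

#' Map a track onto the bins of a genomic axis
#'
#' A bin is included iff its half-open span intersects any interval on the
#' axis chromosome; for a pair track, a bin pair (i, j), i < j, is included
#' iff one anchor hits bin i and the other hits bin j (self-pairs dropped).
#'
#' @param track An `interval_track` or `pair_track`.
#' @param axis A [genomic_axis()].
#' @return For intervals, a sorted integer vector of 0-based bin indices; for
#'   pairs, a 2-column integer matrix of 0-based bin index pairs (i < j).
#' @export
bins_overlapping <- function(track, axis) {
  stopifnot(inherits(axis, "genomic_axis"))
  if (inherits(track, "pair_track")) {
    if (nrow(track) == 0) return(matrix(integer(), ncol = 2))
    out <- matrix(integer(), ncol = 2)
    for (r in seq_len(nrow(track))) {
      b1 <- span_bins(track$chrom1[r], track$start1[r], track$end1[r], axis)
      b2 <- span_bins(track$chrom2[r], track$start2[r], track$end2[r], axis)
      if (length(b1) == 0 || length(b2) == 0) next
      grid <- expand.grid(i = b1, j = b2)
      out <- rbind(out, cbind(pmin(grid$i, grid$j), pmax(grid$i, grid$j)))
    }
    out <- out[out[, 1] != out[, 2], , drop = FALSE]
    out <- unique(out)
    out[order(out[, 1], out[, 2]), , drop = FALSE]
  } else {
    bins <- integer()
    for (r in seq_len(nrow(track)))
      bins <- c(bins, span_bins(track$chromosome[r], track$start[r], track$end[r], axis))
    sort(unique(bins))
  }
}

# bins whose half-open span intersects [s, e) on the axis chromosome (0-based)
span_bins <- function(chrom, s, e, axis) {
  if (chrom != axis$chromosome) {
    warning(sprintf("chromosome %s does not match axis chromosome %s; ignored",
                    chrom, axis$chromosome))
    return(integer())
  }
  lo <- floor((s - axis$start) / axis$bin_size)
  hi <- ceiling((e - axis$start) / axis$bin_size) - 1
  lo <- max(lo, 0); hi <- min(hi, axis$n_bins - 1)
  if (hi < lo) return(integer())
  as.integer(lo:hi)
}

#' Write a bead-chain configuration to disk
#'
#' `"table"` writes a TSV with one row per bead (id, genomic span, centroid,
#' endpoints, radius) that round-trips bit-exactly through
#' [read_configuration()]; `"xyz"` writes a bare point list of centroids.
#'
#' @param chain A `bead_chain`.
#' @param path Output path.
#' @param format `"table"` or `"xyz"`.
#' @export
write_configuration <- function(chain, path, format = c("table", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(chain, "bead_chain"))
  n <- chain_length(chain)
  if (format == "xyz") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(as.character(n), con)
    writeLines("chromatin bead centroids (nm)", con)
    if (n > 0)
      writeLines(sprintf("B %.17g %.17g %.17g", chain$centroids[, 1],
                         chain$centroids[, 2], chain$centroids[, 3]), con)
    return(invisible(NULL))
  }
  header <- paste("bead", "span_start", "span_end", "cx", "cy", "cz",
                  "in_x", "in_y", "in_z", "out_x", "out_y", "out_z",
                  "radius", sep = "\t")
  lines <- header
  if (n > 0) {
    for (k in seq_len(n)) {
      lines <- c(lines, paste(
        k - 1,
        sprintf("%.17g", chain$spans[k, 1]), sprintf("%.17g", chain$spans[k, 2]),
        paste(sprintf("%.17g", chain$centroids[k, ]), collapse = "\t"),
        paste(sprintf("%.17g", chain$endpoints[k, ]), collapse = "\t"),
        paste(sprintf("%.17g", chain$endpoints[k + 1, ]), collapse = "\t"),
        sprintf("%.17g", chain$radii[k]), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(NULL)
}

#' Read a bead-chain configuration table written by [write_configuration()]
#'
#' @param path TSV path.
#' @return A `bead_chain` (payloads are not serialized).
#' @export
read_configuration <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  n <- nrow(df)
  if (n == 0)
    return(new_chain(centroids = matrix(numeric(), 0, 3),
                     endpoints = matrix(numeric(), 1, 3),
                     radii = numeric(), spans = matrix(numeric(), 0, 2)))
  endpoints <- rbind(as.matrix(df[, c("in_x", "in_y", "in_z")]),
                     as.matrix(df[n, c("out_x", "out_y", "out_z"), drop = FALSE]))
  dimnames(endpoints) <- NULL
  new_chain(centroids = unname(as.matrix(df[, c("cx", "cy", "cz")])),
            endpoints = endpoints, radii = df$radius,
            spans = unname(as.matrix(df[, c("span_start", "span_end")])))
}

#' Assemble the full run configuration
#'
#' Collects every tunable of the pipeline with its default. Units: distances
#' nm, genomic sizes bp, `Dc` is the chromatin filament diameter.
#'
#' @param ... Overrides of the defaults, by name.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    # cost function
    mu1 = 1, mu2 = 1, lambda_ratio = 1, b = 5L, c = 1, Dc = 30,
    tf_factor = 100, contact_threshold_quantile = 0.75,
    # multiscale
    min_block_bins = 3L, max_block_bins = 40L, tau = 0.1,
    track_overlap_fraction = 0.5,
    # annealing
    t0 = NA_real_, cooling = 0.95, stages = 60L, moves_per_stage_factor = 10L,
    theta_max = pi / 4,
    # ensemble / evaluation
    n_configurations = 100L, random_seed = 1L, ecm_threshold_factor = 1.2,
    mask_halfwidth = 2L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown run_config fields: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  if (cfg$n_configurations < 1) stop("n_configurations must be >= 1")
  if (cfg$contact_threshold_quantile <= 0 || cfg$contact_threshold_quantile >= 1)
    stop("contact_threshold_quantile must be in (0, 1)")
  if (cfg$ecm_threshold_factor <= 0) stop("ecm_threshold_factor must be > 0")
  structure(cfg, class = "run_config")
}

#' Read a flat key = value configuration file into a [run_config()]
#'
#' @param path Config file (TOML-style flat `key = value` lines; `#` comments).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  kv <- read_key_values(path)
  base <- run_config()
  for (key in names(kv)) {
    if (!key %in% names(base)) stop(sprintf("unknown config key: %s", key))
    val <- type.convert(kv[[key]], as.is = TRUE)
    if (is.integer(base[[key]]) && is.numeric(val)) val <- as.integer(val)
    base[[key]] <- val
  }
  do.call(run_config, unclass(base))
}
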