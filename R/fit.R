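# The model-fit front end: chromfold() fits an ensemble of bead-chain
# configurations to a Hi-C contact matrix and returns a classed object with
# the usual modelling verbs.

#' Fit an ensemble of 3D chromatin configurations to a Hi-C matrix
#'
#' Runs the multiscale reconstruction ([reconstruct()]) once per requested
#' configuration (each run is an independent anneal from its own seed — the
#' objective landscape has many near-optima, and the ensemble samples
#' them), accumulates the estimated contact matrix (ECM) of the ensemble
#' and its Spearman correlation with the input.
#'
#' @param hic A [contact_matrix()], or the path of a dense matrix file.
#' @param ctcf Optional CTCF loop anchors: a `pair_track`, a BEDPE path, or
#'   a 2-column 0-based bin-pair matrix.
#' @param h3k27me3,expressed Optional `interval_track`s or BED paths.
#' @param n_configurations Ensemble size (default from `config`; the
#'   stability analysis motivates 100 as a sufficient default).
#' @param config A [run_config()] collecting all tunables.
#' @param seed Integer seed; every source of randomness derives from it.
#' @param verbose Print per-configuration progress.
#' @return An object of class `chromfold` with components `input`, `tracks`,
#'   `config`, `configurations` (list of finest-scale `bead_chain`s),
#'   `ecm`, `spearman`, `diagnostics` (per-block annealing log of the first
#'   configuration), `seeds` and `call`.
#' @seealso [summary.chromfold()], [simulate.chromfold()],
#'   [stability_analysis()], [mask_matrix()]
#' @export
chromfold <- function(hic, ctcf = NULL, h3k27me3 = NULL, expressed = NULL,
                      n_configurations = config$n_configurations,
                      config = run_config(), seed = config$random_seed,
                      verbose = FALSE) {
  cl <- match.call()
  if (is.character(hic)) hic <- read_contact_matrix(hic)
  if (is.character(ctcf)) ctcf <- read_pair_track(ctcf)
  if (is.character(h3k27me3)) h3k27me3 <- read_interval_track(h3k27me3, "H3K27ME3")
  if (is.character(expressed)) expressed <- read_interval_track(expressed, "expressed_gene")
  seeds <- config_seeds(seed, n_configurations)
  configurations <- vector("list", n_configurations)
  diagnostics <- NULL
  for (k in seq_len(n_configurations)) {
    rec <- reconstruct(hic, ctcf = ctcf, h3k27me3 = h3k27me3,
                       expressed = expressed, config = config,
                       seed = seeds[k])
    configurations[[k]] <- rec$chain
    if (k == 1) diagnostics <- rec$levels
    if (verbose) message(sprintf("configuration %d/%d: %d beads", k,
                                 n_configurations, chain_length(rec$chain)))
  }
  ecm <- estimate_contact_matrix(configurations, config$ecm_threshold_factor)
  rho <- spearman_compare(ecm, hic)
  structure(list(input = hic,
                 tracks = list(ctcf = ctcf, h3k27me3 = h3k27me3,
                               expressed = expressed),
                 config = config, configurations = configurations, ecm = ecm,
                 spearman = rho, diagnostics = diagnostics, seeds = seeds,
                 call = cl),
            class = "chromfold")
}

# per-configuration seeds derived from the run seed, all below 2^31
config_seeds <- function(seed, n) {
  ((as.double(seed) * 3779 + (seq_len(n) - 1) * 7919) %% 2147483629) + 1
}

#' @export
print.chromfold <- function(x, ...) {
  cat("Multiscale bead-chain reconstruction\n")
  cat(sprintf("  input: %d x %d bins (%s), %d masked\n", nrow(x$input$counts),
              ncol(x$input$counts), x$input$axis$chromosome, sum(x$input$mask)))
  cat(sprintf("  ensemble: %d configurations of %d beads\n",
              length(x$configurations), chain_length(x$configurations[[1]])))
  cat(sprintf("  Spearman(ECM, input) = %.3f\n", x$spearman))
  invisible(x)
}

#' Summary of a fitted reconstruction ensemble
#'
#' @param object A `chromfold` fit.
#' @param ... Unused.
#' @return A `summary.chromfold` with the ensemble Spearman, the tracks in
#'   use and the per-block annealing diagnostics of the first configuration.
#' @export
summary.chromfold <- function(object, ...) {
  structure(list(
    n_configurations = length(object$configurations),
    n_beads = chain_length(object$configurations[[1]]),
    spearman = object$spearman,
    ecm_threshold_factor = object$ecm$threshold_factor,
    tracks = vapply(object$tracks, Negate(is.null), TRUE),
    diagnostics = object$diagnostics),
    class = "summary.chromfold")
}

#' @export
print.summary.chromfold <- function(x, ...) {
  cat(sprintf("Ensemble of %d configurations, %d beads each\n",
              x$n_configurations, x$n_beads))
  cat(sprintf("Spearman(ECM, input) = %.3f (contact factor %.2f)\n",
              x$spearman, x$ecm_threshold_factor))
  used <- names(x$tracks)[x$tracks]
  cat("auxiliary tracks:", if (length(used)) paste(used, collapse = ", ")
      else "none", "\n")
  cat("\nPer-block annealing (first configuration):\n")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Fitted estimated contact matrix
#'
#' @param object A `chromfold` fit.
#' @param ... Unused.
#' @return The ECM count matrix (entries in `[0, n_configurations]`).
#' @export
fitted.chromfold <- function(object, ...) object$ecm$counts

#' Residual contact signal
#'
#' Input and ECM are each scaled to `[0, 1]` (counts over their maximum,
#' `"normalized"`) or rank-transformed over the upper triangle (`"rank"`,
#' the scale on which the fit is scored); the residual is input minus fit.
#'
#' @param object A `chromfold` fit.
#' @param type `"normalized"` or `"rank"`.
#' @param ... Unused.
#' @return A symmetric residual matrix with zero diagonal.
#' @export
residuals.chromfold <- function(object, type = c("normalized", "rank"), ...) {
  type <- match.arg(type)
  A <- object$input$counts
  B <- object$ecm$counts
  if (type == "normalized") {
    res <- A / max(A, 1) - B / max(B, 1)
  } else {
    sel <- upper.tri(A)
    res <- matrix(0, nrow(A), ncol(A))
    res[sel] <- (rank(A[sel]) - rank(B[sel])) / length(A[sel])
    res <- res + t(res)
  }
  diag(res) <- 0
  res
}

#' Predicted contact probabilities
#'
#' The ensemble contact frequency of each bead pair, optionally re-evaluated
#' at a different contact threshold factor.
#'
#' @param object A `chromfold` fit.
#' @param threshold_factor Contact factor; default the fitted one.
#' @param ... Unused.
#' @return Matrix of contact probabilities in `[0, 1]`.
#' @export
predict.chromfold <- function(object, threshold_factor = NULL, ...) {
  tf <- threshold_factor %||% object$ecm$threshold_factor
  ecm <- if (is.null(threshold_factor)) object$ecm else
    estimate_contact_matrix(object$configurations, tf)
  ecm$counts / ecm$n_configurations
}

#' Simulate contact matrices implied by the fitted model
#'
#' Each simulation reconstructs a fresh configuration (new seed) and
#' returns its binary contact matrix — the model's view of one more cell in
#' the Hi-C population.
#'
#' @param object A `chromfold` fit.
#' @param nsim Number of simulated configurations.
#' @param seed Integer seed (default: continue after the fitted seeds).
#' @param ... Unused.
#' @return List of `nsim` binary contact matrices (with the underlying
#'   chains attached as the `"chains"` attribute).
#' @export
simulate.chromfold <- function(object, nsim = 1, seed = NULL, ...) {
  base_seed <- seed %||% (max(object$seeds) + 1)
  seeds <- config_seeds(base_seed, nsim)
  chains <- lapply(seeds, function(s)
    reconstruct(object$input, ctcf = object$tracks$ctcf,
                h3k27me3 = object$tracks$h3k27me3,
                expressed = object$tracks$expressed,
                config = object$config, seed = s)$chain)
  out <- lapply(chains, contacts_from_configuration,
                threshold_factor = object$ecm$threshold_factor)
  attr(out, "chains") <- chains
  out
}

#' Plot input matrix against the fitted ECM
#'
#' Two log-scaled image panels sharing the colour ramp.
#'
#' @param x A `chromfold` fit.
#' @param ... Passed to [graphics::image()].
#' @export
plot.chromfold <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(2, 2, 3, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  show <- function(m, main) {
    graphics::image(log1p(m)[, rev(seq_len(ncol(m)))], col = pal,
                    axes = FALSE, main = main, ...)
  }
  show(x$input$counts, "input Hi-C")
  show(x$ecm$counts, sprintf("ECM (%d configs), rho = %.2f",
                             x$ecm$n_configurations, x$spearman))
  invisible(x)
}
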