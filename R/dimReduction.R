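#' @include trajectoryIntegration.R
NULL

# Log10-transform a positive profile table, guarding exact zeros with a
# small floor relative to the smallest positive entry.  With rowCenter,
# each profile's mean log level is removed so the embedding sees the
# trajectory shape, not the disease's incidence amplitude.
.logProfiles <- function(profiles, rowCenter = TRUE) {
  if (any(is.na(profiles)))
    stop("profile table contains missing cells; apply completeColumns() first")
  pos <- profiles[profiles > 0]
  if (!length(pos)) stop("profile table has no positive entries")
  floorVal <- min(pos) / 10
  lp <- log10(pmax(profiles, floorVal))
  if (rowCenter) lp <- lp - rowMeans(lp)
  lp
}

.profileLabels <- function(profiles) {
  if (is.null(rownames(profiles)))
    paste0("profile", seq_len(nrow(profiles)))
  else rownames(profiles)
}

#' PCA embedding of incidence profiles
#'
#' Profiles (one row per dataset or per stratum) are log10-transformed,
#' optionally row-centered, then column-centered and decomposed by SVD.
#' No unit-variance scaling is applied.  The default `rowCenter = TRUE`
#' removes each profile's mean log level, so the embedding reflects the
#' trajectory shape: incidence amplitudes of these diseases span several
#' orders of magnitude, and without row-centering the leading component
#' merely ranks diseases by how common they are, drowning the
#' rising-versus-declining signal that distinguishes a non-multistep
#' profile.  Set `rowCenter = FALSE` to keep amplitude differences.
#' Explained-variance percentages are reported per component.
#'
#' @param profiles numeric matrix, >= 2 rows and >= 2 complete columns;
#'   no missing cells (use [completeColumns()]).
#' @param rowCenter remove each profile's mean log10 level first.
#' @return an [Embedding-class] with `method = "pca"`.
#' @examples
#' p <- generatePanel(defaultPanelSpecs(), seed = 3L)
#' prof <- completeColumns(studyProfiles(p))
#' emb <- pcaEmbed(prof)
#' explainedVariance(emb)[1:2]
#' @export
pcaEmbed <- function(profiles, rowCenter = TRUE) {
  if (nrow(profiles) < 2L || ncol(profiles) < 2L)
    stop("need at least 2 profiles and 2 columns for PCA")
  lp <- .logProfiles(profiles, rowCenter = rowCenter)
  pc <- stats::prcomp(lp, center = TRUE, scale. = FALSE)
  ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  k <- min(ncol(pc$x), max(2L, sum(ev > 1e-12)))
  new("Embedding", method = "pca",
      coordinates = pc$x[, seq_len(k), drop = FALSE],
      explainedVariancePct = ev[seq_len(k)],
      labels = .profileLabels(profiles), seed = NA_integer_,
      params = list(center = TRUE, scale = FALSE, rowCenter = rowCenter,
                    rotation = pc$rotation[, seq_len(k), drop = FALSE],
                    centerVec = pc$center))
}

#' UMAP embedding of incidence profiles
#'
#' Two-dimensional uniform manifold approximation and projection of the
#' log10 profiles, deterministic under a fixed seed (single-threaded,
#' exact nearest neighbours).
#'
#' @inheritParams pcaEmbed
#' @param nNeighbors UMAP neighbourhood size (must be < number of
#'   profiles).
#' @param minDist UMAP minimum embedding distance.
#' @param seed integer seed.
#' @param rowCenter remove each profile's mean log10 level first (see
#'   [pcaEmbed()]).
#' @return an [Embedding-class] with `method = "umap"`.
#' @export
umapEmbed <- function(profiles, nNeighbors = 5, minDist = 0.3, seed = 42L,
                      rowCenter = TRUE) {
  if (nrow(profiles) < 4L)
    stop("need at least 4 profiles for UMAP")
  if (nNeighbors >= nrow(profiles))
    stop("'nNeighbors' must be smaller than the number of profiles")
  lp <- .logProfiles(profiles, rowCenter = rowCenter)
  coords <- .withSeed(as.integer(seed),
    uwot::umap(lp, n_neighbors = nNeighbors, min_dist = minDist,
               n_components = 2, n_threads = 1, n_sgd_threads = 1,
               nn_method = "fnn", verbose = FALSE))
  rownames(coords) <- .profileLabels(profiles)
  new("Embedding", method = "umap", coordinates = coords,
      explainedVariancePct = numeric(0), labels = .profileLabels(profiles),
      seed = as.integer(seed),
      params = list(n_neighbors = nNeighbors, min_dist = minDist))
}

#' Write embedding coordinates to CSV
#'
#' @param embedding an [Embedding-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeEmbedding <- function(embedding, path) {
  co <- embeddingCoords(embedding)
  tab <- data.frame(label = embedding@labels, co, check.names = FALSE)
  ev <- embedding@explainedVariancePct
  if (length(ev))
    names(tab)[-1L] <- sprintf("%s (%.1f%%)", colnames(co),
                               ev[seq_len(ncol(co))])
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Scatter plot of an embedding
#'
#' @param x an [Embedding-class].
#' @param y ignored.
#' @param colorBy optional factor (length = profiles) used for colours;
#'   defaults to the stratum part of the labels.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature(x = "Embedding", y = "missing"),
  function(x, y, colorBy = NULL, ...) {
    co <- x@coordinates[, 1:2, drop = FALSE]
    if (is.null(colorBy))
      colorBy <- factor(sub("/.*$", "", x@labels))
    cols <- grDevices::rainbow(nlevels(colorBy))[as.integer(colorBy)]
    lab <- if (x@method == "pca" && length(x@explainedVariancePct) >= 2)
      sprintf("PC%d (%.0f%%)", 1:2, x@explainedVariancePct[1:2])
    else paste0(toupper(x@method), 1:2)
    graphics::plot(co, col = cols, pch = 19, xlab = lab[1], ylab = lab[2],
                   main = sprintf("%s of incidence profiles",
                                  toupper(x@method)), ...)
    graphics::text(co, labels = x@labels, pos = 3, cex = 0.55, col = cols)
    invisible(x)
  })
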