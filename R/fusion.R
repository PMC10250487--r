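#' Compress a data block by PCA at a cumulative-variance threshold
#'
#' Centers and scales the block, decomposes it (exact singular value
#' decomposition), and retains the smallest number of components whose
#' cumulative explained variance reaches `threshold` (capped at
#' `min(n - 1, p, maxComponents)`); alternatively a fixed component count
#' `k` can be forced. The fitted compression maps held-out samples of the
#' same block into the retained score space via [compressionScores()].
#'
#' @param x numeric samples-by-variables matrix.
#' @param threshold cumulative explained-variance fraction in (0, 1]
#'   (default 0.85).
#' @param scaling "none", "uv" or "pareto" (applied after mean-centering).
#' @param maxComponents hard cap on retained components (default 250).
#' @param k optional fixed component count overriding the threshold.
#' @param blockName stored block name.
#' @return list with `compression` (a [BlockCompression-class]) and
#'   `scores` (n x k matrix).
#' @export
compressBlock <- function(x, threshold = 0.85, scaling = "uv",
                          maxComponents = 250, k = NULL,
                          blockName = "block") {
  stopifnot(threshold > 0, threshold <= 1)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("at least two samples are required")
  cs <- centerScale(x, TRUE, scaling)
  sv <- svd(cs$X)
  tot <- sum(sv$d^2)
  if (tot == 0) stop("degenerate-input error: zero-variance matrix")
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  kmax <- min(rank, nrow(x) - 1L, ncol(x), maxComponents)
  ve <- sv$d^2 / tot
  if (is.null(k)) {
    k <- which(cumsum(ve) >= threshold - 1e-12)[1]
    if (is.na(k)) k <- kmax
    k <- min(k, kmax)
    thr <- threshold
  } else {
    if (k > kmax) stop("k exceeds the usable rank (", kmax, ")")
    thr <- NA_real_
  }
  k <- as.integer(k)
  load <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0(blockName, ".PC", seq_len(k))
  comp <- new("BlockCompression", blockName = blockName, center = cs$center,
              scale = cs$scale, scalingMode = cs$scalingMode,
              loadings = load, varExplained = ve[seq_len(k)], k = k,
              threshold = thr)
  list(compression = comp, scores = scores)
}

#' Project new samples through a fitted block compression
#'
#' @param compression a [BlockCompression-class].
#' @param x new samples on the training variable axis.
#' @return n x k score matrix (stored centering/scaling applied; never
#'   re-fits).
#' @export
compressionScores <- function(compression, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(compression@center))
    stop("alignment error: variable axis differs from the fitted block")
  xc <- sweep(sweep(x, 2, compression@center, "-"), 2,
              compression@scale, "/")
  s <- xc %*% compression@loadings
  colnames(s) <- paste0(compression@blockName, ".PC",
                        seq_len(compression@k))
  s
}

checkAligned <- function(blocks) {
  ns <- vapply(blocks, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop("alignment error: blocks have different sample counts")
  ids <- lapply(blocks, rownames)
  ids <- ids[!vapply(ids, is.null, logical(1))]
  if (length(ids) > 1L && !all(vapply(ids[-1], identical, logical(1), ids[[1]])))
    stop("alignment error: sample IDs differ between blocks")
}

#' Low-level data fusion
#'
#' Column-wise scales each block (min-max by default, so heterogeneous
#' units become comparable) and concatenates the scaled blocks; the fitted
#' per-column transforms are stored so held-out samples can be projected
#' with [projectSamples()].
#'
#' @param blocks named list of samples-by-variables matrices with aligned
#'   rows.
#' @param scaling "minmax" or "none".
#' @return a [FusedMatrix-class] with per-feature provenance.
#' @export
lowLevelFuse <- function(blocks, scaling = c("minmax", "none")) {
  scaling <- match.arg(scaling)
  blocks <- lapply(blocks, as.matrix)
  if (is.null(names(blocks)))
    names(blocks) <- paste0("block", seq_along(blocks))
  checkAligned(blocks)
  transforms <- list(); pieces <- list(); prov <- list()
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (is.null(colnames(b))) colnames(b) <- paste0(nm, ".", seq_len(ncol(b)))
    fit <- if (scaling == "minmax") fitMinMax(b) else NULL
    pieces[[nm]] <- if (is.null(fit)) b else applyMinMax(fit, b)
    transforms[[nm]] <- fit
    prov[[nm]] <- data.frame(block = nm, feature = colnames(b))
  }
  new("FusedMatrix", fused = do.call(cbind, pieces),
      provenance = do.call(rbind, c(prov, make.row.names = FALSE)),
      level = "low", transforms = transforms, weighting = "none")
}

#' Mid-level data fusion
#'
#' Compresses each block by PCA ([compressBlock()]) at the cumulative
#' variance threshold and concatenates the retained scores, so the fused
#' feature count is the sum of per-block component counts (e.g. 226 + 8 =
#' 234 for the published salmon blocks). Fitted compressions are stored for
#' held-out projection.
#'
#' @param blocks named list of aligned samples-by-variables matrices.
#' @param threshold cumulative explained-variance threshold (default 0.85).
#' @param scaling per-block scaling mode, recycled ("pareto" is the usual
#'   choice for spectral blocks, "uv" for element panels).
#' @param maxComponents per-block component cap, recycled.
#' @param k optional per-block fixed component counts (list/vector, NA =
#'   use threshold).
#' @param weighting "none" (raw scores concatenated) or "variance"
#'   (per-block scores divided by the square root of their total retained
#'   variance, equalising block influence).
#' @return a [FusedMatrix-class].
#' @export
midLevelFuse <- function(blocks, threshold = 0.85, scaling = "uv",
                         maxComponents = 250, k = NULL,
                         weighting = c("none", "variance")) {
  weighting <- match.arg(weighting)
  blocks <- lapply(blocks, as.matrix)
  if (is.null(names(blocks)))
    names(blocks) <- paste0("block", seq_along(blocks))
  checkAligned(blocks)
  scaling <- rep_len(scaling, length(blocks))
  maxComponents <- rep_len(maxComponents, length(blocks))
  transforms <- list(); pieces <- list(); prov <- list()
  for (i in seq_along(blocks)) {
    nm <- names(blocks)[i]
    ki <- if (!is.null(k) && !is.na(k[[i]])) k[[i]] else NULL
    cb <- compressBlock(blocks[[i]], threshold = threshold,
                        scaling = scaling[i],
                        maxComponents = maxComponents[i], k = ki,
                        blockName = nm)
    s <- cb$scores
    comp <- cb$compression
    if (weighting == "variance") {
      # fold the block weight into the stored scaling so projection of new
      # samples applies the identical transform
      wfac <- sqrt(sum(colSums(s^2)))
      s <- s / wfac
      comp@scale <- comp@scale * wfac
    }
    pieces[[nm]] <- s
    transforms[[nm]] <- comp
    prov[[nm]] <- data.frame(block = nm, feature = colnames(s))
  }
  new("FusedMatrix", fused = do.call(cbind, pieces),
      provenance = do.call(rbind, c(prov, make.row.names = FALSE)),
      level = "mid", transforms = transforms, weighting = weighting)
}

#' Project held-out samples through a fitted fusion
#'
#' Applies the stored per-block transforms (min-max scalers or PCA
#' compressions) to new blocks and concatenates, never re-fitting; feature
#' axes must match the training blocks.
#'
#' @param fused a [FusedMatrix-class].
#' @param blocks named list of new-sample matrices (same block names and
#'   variable axes as at fit time).
#' @return matrix of fused rows for the new samples.
#' @export
projectSamples <- function(fused, blocks) {
  blocks <- lapply(blocks, as.matrix)
  if (!setequal(names(blocks), names(fused@transforms)))
    stop("alignment error: block names differ from the fitted fusion")
  checkAligned(blocks)
  pieces <- lapply(names(fused@transforms), function(nm) {
    tr <- fused@transforms[[nm]]
    if (is(tr, "BlockCompression")) {
      compressionScores(tr, blocks[[nm]])
    } else if (inherits(tr, "minmaxFit")) {
      applyMinMax(tr, blocks[[nm]])
    } else blocks[[nm]]
  })
  out <- do.call(cbind, pieces)
  colnames(out) <- fused@provenance$feature
  out
}
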