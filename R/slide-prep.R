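#' Read a slide image (PNG or TIFF) as an RGB array
#'
#' @param path image path; `.png` read natively, `.tif`/`.tiff` through the
#'   tiff package when installed.
#' @return An `H x W x 3` numeric array in \[0,1\] (grayscale replicated).
#' @export
readSlideImage <- function(path) {
  stopIfNot(file.exists(path), paste("image file not found:", path))
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext, call. = FALSE)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Read a single-channel ROI mask
#'
#' @param path PNG path; pixel values `> 0.5` mark ROI.
#' @return A 0/1 integer matrix.
#' @export
readMask <- function(path) {
  m <- readSlideImage(path)[, , 1]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' Tile an annotated ROI into a grid of fixed-size patches
#'
#' Enumerates grid-aligned `patchSize`-square boxes (0-based, half-open)
#' that fit entirely inside the image and keeps those whose fraction of
#' ROI pixels is at least `minRoiFraction`. Ordering is row-major (top to
#' bottom, then left to right within a row), which fixes the row order of
#' all downstream feature matrices.
#'
#' @param image `H x W (x 3)` array, or a length-2 integer `c(H, W)`.
#' @param roiMask `H x W` 0/1 matrix; same spatial size as `image`.
#' @param patchSize patch side in pixels (default 512, the tiling used at
#'   40x magnification).
#' @param stride grid step in pixels; defaults to `patchSize`
#'   (non-overlapping).
#' @param minRoiFraction minimum ROI-pixel fraction per kept box, in (0,1].
#' @return A data.frame of class `"PatchGrid"` with 0-based columns `x`
#'   (column offset) and `y` (row offset), and attributes `patchSize` and
#'   `stride`. An empty mask yields zero rows (not an error).
#' @examples
#' g <- tileROI(c(1024, 1024), matrix(1, 1024, 1024), 512)
#' nrow(g)  # 4
#' @export
tileROI <- function(image, roiMask, patchSize = 512L, stride = patchSize,
                    minRoiFraction = 0.5) {
  dims <- if (is.array(image) || is.matrix(image)) dim(image)[1:2] else image[1:2]
  stopIfNot(patchSize > 0 && stride > 0, "patchSize and stride must be > 0")
  stopIfNot(minRoiFraction > 0 && minRoiFraction <= 1,
            "minRoiFraction must be in (0, 1]")
  stopIfNot(all(dim(roiMask) == dims),
            "roiMask must have the same spatial size as the image")
  H <- dims[1]; W <- dims[2]
  out <- if (H < patchSize || W < patchSize) {
    data.frame(x = integer(), y = integer())
  } else {
    ys <- seq(0L, H - patchSize, by = stride)
    xs <- seq(0L, W - patchSize, by = stride)
    # integral image: ii[y+1, x+1] = sum(mask[1:y, 1:x]) for O(1) box sums
    ii <- rbind(0, cbind(0, t(apply(apply(roiMask, 2, cumsum), 1, cumsum))))
    boxSum <- function(y, x)
      ii[y + patchSize + 1L, x + patchSize + 1L] - ii[y + 1L, x + patchSize + 1L] -
      ii[y + patchSize + 1L, x + 1L] + ii[y + 1L, x + 1L]
    keep <- list()
    for (y in ys) for (x in xs) {
      if (boxSum(y, x) / patchSize^2 >= minRoiFraction)
        keep[[length(keep) + 1L]] <- c(x, y)
    }
    if (length(keep)) {
      m <- do.call(rbind, keep)
      data.frame(x = as.integer(m[, 1]), y = as.integer(m[, 2]))
    } else data.frame(x = integer(), y = integer())
  }
  structure(out, patchSize = as.integer(patchSize),
            stride = as.integer(stride), class = c("PatchGrid", "data.frame"))
}

#' Extract the pixel patches named by a grid
#'
#' @param image `H x W x 3` array.
#' @param grid a [tileROI()] result.
#' @return A list of `patchSize x patchSize x 3` arrays in grid order.
#' @export
extractPatches <- function(image, grid) {
  ps <- attr(grid, "patchSize")
  lapply(seq_len(nrow(grid)), function(i) {
    y <- grid$y[i]; x <- grid$x[i]
    image[(y + 1L):(y + ps), (x + 1L):(x + ps), , drop = FALSE]
  })
}

#' Write a patch manifest as CSV
#'
#' @param grids named list of [tileROI()] results (names are patient ids).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writePatchManifest <- function(grids, path) {
  rows <- do.call(rbind, lapply(names(grids), function(id) {
    g <- grids[[id]]
    if (!nrow(g)) return(NULL)
    data.frame(patient_id = id, x = g$x, y = g$y,
               width = attr(g, "patchSize"), height = attr(g, "patchSize"))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# RGB [0,1] image to optical density rows (N x 3); base-10 Beer-Lambert.
rgbToOD <- function(patch) {
  v <- pmax(matrix(patch, ncol = 3L), 1 / 256)
  -log10(v)
}

odToRGB <- function(od, dims) {
  array(pmin(pmax(10^(-od), 0), 1), dims)
}

#' Estimate a stain profile by Macenko optical-density decomposition
#'
#' Converts the patch to optical density, keeps stained pixels (OD norm
#' above `odThreshold`), finds the best-fit plane through the top two
#' principal directions, and takes the robust angular extremes (1st/99th
#' percentile) of the projected pixels as the two stain vectors. Pixel
#' stain concentrations are recovered by least squares and their 99th
#' percentiles stored as the profile's concentration scale. Stains are
#' ordered by decreasing red-channel optical density (hematoxylin first
#' for H&E).
#'
#' @param patch `H x W x 3` RGB array in \[0,1\].
#' @param odThreshold minimum OD norm for a pixel to count as stained.
#' @param angularPercentile tail probability for the angular extremes.
#' @return A list of class `"StainProfile"`: `stainMatrix` (3 x 2,
#'   unit-norm columns), `maxC` (length-2 concentration scale), and
#'   `odThreshold`.
#' @export
fitStainReference <- function(patch, odThreshold = 0.15,
                              angularPercentile = 0.01) {
  od <- rgbToOD(patch)
  tissue <- od[sqrt(rowSums(od^2)) > odThreshold, , drop = FALSE]
  if (nrow(tissue) < 20L)
    stop("degenerate stain: patch contains no stained tissue", call. = FALSE)
  ev <- eigen(stats::cov(tissue), symmetric = TRUE)
  if (ev$values[2] < 1e-10)
    stop("degenerate stain: optical densities are not two-dimensional",
         call. = FALSE)
  V <- ev$vectors[, 1:2]
  # orient the plane so projections fall on the positive half
  proj <- tissue %*% V
  if (sum(proj[, 1]) < 0) { V[, 1] <- -V[, 1]; proj[, 1] <- -proj[, 1] }
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(phi, c(angularPercentile, 1 - angularPercentile))
  mk <- function(a) {
    v <- drop(V %*% c(cos(a), sin(a)))
    if (sum(v) < 0) v <- -v
    v / sqrt(sum(v^2))
  }
  s1 <- mk(qs[1]); s2 <- mk(qs[2])
  S <- if (s1[1] >= s2[1]) cbind(s1, s2) else cbind(s2, s1)
  colnames(S) <- c("stain1", "stain2")
  C <- stainConcentrations(od, S)
  structure(list(stainMatrix = S,
                 maxC = apply(C, 2, stats::quantile, 0.99),
                 odThreshold = odThreshold),
            class = "StainProfile")
}

# Least-squares stain concentrations (N x 2), clipped nonnegative.
stainConcentrations <- function(od, S) {
  pmax(od %*% S %*% solve(crossprod(S)), 0)
}

#' Normalize a patch to a reference stain profile
#'
#' Decomposes the patch with its own Macenko-estimated stain basis, rescales
#' each stain's concentrations so their 99th percentile matches the
#' reference profile, and reconstructs the image using the reference stain
#' vectors. Two patches differing only by a global linear color shift map
#' to (near-)identical outputs.
#'
#' @param patch `H x W x 3` RGB array in \[0,1\].
#' @param profile a [fitStainReference()] result.
#' @return An array of the same shape. If the patch's own stains are
#'   degenerate (e.g. blank tissue), the patch is returned unchanged with
#'   attribute `normFlag = "degenerate"` and a warning.
#' @export
normalizePatch <- function(patch, profile) {
  stopIfNot(inherits(profile, "StainProfile"), "profile must be a StainProfile")
  own <- tryCatch(fitStainReference(patch, profile$odThreshold),
                  error = function(e) NULL)
  if (is.null(own)) {
    warning("degenerate patch: returned un-normalized", call. = FALSE)
    return(structure(patch, normFlag = "degenerate"))
  }
  od <- rgbToOD(patch)
  C <- stainConcentrations(od, own$stainMatrix)
  C <- sweep(C, 2, profile$maxC / pmax(own$maxC, 1e-8), `*`)
  odToRGB(C %*% t(profile$stainMatrix), dim(patch))
}
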