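## Synthetic 16-bit nuclear images with ground truth.
##
## Nuclei are rendered as rotated ellipses with an ellipsoidal intensity
## profile (bright centre falling to the rim), repair foci as small
## Gaussian blobs at recorded coordinates, plus additive Gaussian camera
## noise. Coordinates are 0-based (row, column) pixel indices.

.IMG_BACKGROUND <- 300
.NUCLEUS_AMPLITUDE <- 8000
.FOCUS_AMPLITUDE <- 20000
.FOCUS_SIGMA <- 1.5
.PSF_SIGMA <- 1        # optical point-spread blur, pixels

#' Render a synthetic nuclear image
#'
#' Places \code{nNuclei} non-overlapping elliptical nuclei on a constant
#' background, plants bright Gaussian foci inside them at recorded
#' positions, adds Gaussian noise and clips to the 16-bit range. Foci
#' within one nucleus keep a minimum separation so planted foci are
#' resolvable objects. Returns the image together with the ground-truth
#' label map and focus list, the oracle for segmentation and
#' focus-detection checks.
#'
#' @param nNuclei number of nuclei (may be 0).
#' @param fociPerNucleus foci per nucleus: an exact count
#'   (\code{fociDistribution = "fixed"}, default) or a Poisson mean.
#' @param noiseSd additive Gaussian noise sd in camera units.
#' @param seed RNG seed.
#' @param width,height image size in pixels.
#' @param fociDistribution \code{"fixed"} or \code{"poisson"}.
#' @param minFociSeparation minimum distance in pixels between foci
#'   planted in one nucleus.
#' @param maxTries placement retries before giving up.
#' @return list with \code{image} (height x width numeric matrix, integer
#'   values in [0, 65535]), \code{labelMap} (integer matrix, background 0),
#'   \code{foci} (data.frame label/row/col, 0-based) and \code{nuclei}
#'   (data.frame label/row/col/ra/rb/theta, centres 0-based).
#' @examples
#' syn <- renderNucleusImage(3, fociPerNucleus = 2, noiseSd = 0, seed = 7,
#'                           width = 192, height = 192)
#' table(syn$labelMap > 0)
#' @export
renderNucleusImage <- function(nNuclei, fociPerNucleus = 3, noiseSd = 50,
                               seed = 42L, width = 512L, height = 512L,
                               fociDistribution = c("fixed", "poisson"),
                               minFociSeparation = 6, maxTries = 200L) {
  stopifnot(nNuclei >= 0, width > 0, height > 0, noiseSd >= 0)
  fociDistribution <- match.arg(fociDistribution)
  withr::with_seed(seed, {
    img <- matrix(.IMG_BACKGROUND, nrow = height, ncol = width)
    labelMap <- matrix(0L, nrow = height, ncol = width)
    nuclei <- data.frame(label = integer(), row = numeric(),
                         col = numeric(), ra = numeric(), rb = numeric(),
                         theta = numeric())
    fociList <- list()

    if (nNuclei > 0) {
      margin <- 26
      if (width <= 2 * margin || height <= 2 * margin)
        stop("image too small to place nuclei", call. = FALSE)
      centers <- matrix(NA_real_, nrow = nNuclei, ncol = 2)
      radii <- numeric(nNuclei)
      for (i in seq_len(nNuclei)) {
        placed <- FALSE
        for (try in seq_len(maxTries)) {
          ra <- runif(1, 14, 20); rb <- runif(1, 14, 20)
          cy <- runif(1, margin, height - margin)
          cx <- runif(1, margin, width - margin)
          rmax <- max(ra, rb)
          ok <- TRUE
          if (i > 1) {
            d <- sqrt((centers[seq_len(i - 1), 1] - cy)^2 +
                      (centers[seq_len(i - 1), 2] - cx)^2)
            ## keep clearance beyond the PSF halos so rendered nuclei
            ## stay separable foreground components
            ok <- all(d > radii[seq_len(i - 1)] + rmax + 12)
          }
          if (ok) {
            centers[i, ] <- c(cy, cx); radii[i] <- rmax
            theta <- runif(1, 0, pi)
            nuclei <- rbind(nuclei, data.frame(
              label = i, row = cy - 1, col = cx - 1,
              ra = ra, rb = rb, theta = theta))
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place ", nNuclei,
               " non-overlapping nuclei after ", maxTries, " retries",
               call. = FALSE)
      }

      for (i in seq_len(nNuclei)) {
        nb <- nuclei[i, ]
        cy <- nb$row + 1; cx <- nb$col + 1
        rmax <- max(nb$ra, nb$rb)
        rows <- max(1, floor(cy - rmax)):min(height, ceiling(cy + rmax))
        cols <- max(1, floor(cx - rmax)):min(width, ceiling(cx + rmax))
        dy <- outer(rows - cy, rep(1, length(cols)))
        dx <- outer(rep(1, length(rows)), cols - cx)
        u <- (dx * cos(nb$theta) + dy * sin(nb$theta)) / nb$ra
        v <- (-dx * sin(nb$theta) + dy * cos(nb$theta)) / nb$rb
        d2 <- u^2 + v^2
        inside <- d2 <= 1
        ## flattened ellipsoidal profile: bright centre, still well above
        ## background at the rim so the full rendered extent is separable
        img[rows, cols][inside] <- img[rows, cols][inside] +
          .NUCLEUS_AMPLITUDE * sqrt(1 - 0.4 * d2[inside])
        labelMap[rows, cols][inside] <- i

        nf <- if (fociDistribution == "fixed") as.integer(fociPerNucleus)
              else rpois(1L, fociPerNucleus)
        if (nf > 0) {
          pts <- matrix(NA_real_, nrow = nf, ncol = 2)  # (row, col) 1-based
          placedAll <- FALSE
          for (attempt in 1:10) {            # restart crowded layouts
            okAll <- TRUE
            for (f in seq_len(nf)) {
              done <- FALSE
              for (try in seq_len(maxTries)) {
                repeat {                     # uniform in the unit disk
                  p <- runif(2, -1, 1)
                  if (sum(p^2) <= 1) break
                }
                ## map to the ellipse interior, shrunk so blobs stay inside
                fx <- 0.72 * (p[1] * nb$ra * cos(nb$theta) -
                              p[2] * nb$rb * sin(nb$theta))
                fy <- 0.72 * (p[1] * nb$ra * sin(nb$theta) +
                              p[2] * nb$rb * cos(nb$theta))
                fr <- cy + fy; fc <- cx + fx
                sep <- TRUE
                if (f > 1) {
                  d <- sqrt((pts[seq_len(f - 1), 1] - fr)^2 +
                            (pts[seq_len(f - 1), 2] - fc)^2)
                  sep <- all(d >= minFociSeparation)
                }
                if (sep) { pts[f, ] <- c(fr, fc); done <- TRUE; break }
              }
              if (!done) { okAll <- FALSE; break }
            }
            if (okAll) { placedAll <- TRUE; break }
          }
          if (!placedAll)
            stop("could not place ", nf, " separated foci in nucleus ",
                 i, call. = FALSE)
          for (f in seq_len(nf)) {
            fr <- pts[f, 1]; fc <- pts[f, 2]
            w <- 5
            rr <- max(1, floor(fr - w)):min(height, ceiling(fr + w))
            cc <- max(1, floor(fc - w)):min(width, ceiling(fc + w))
            gy <- outer((rr - fr)^2, rep(1, length(cc)))
            gx <- outer(rep(1, length(rr)), (cc - fc)^2)
            img[rr, cc] <- img[rr, cc] +
              .FOCUS_AMPLITUDE * exp(-(gy + gx) / (2 * .FOCUS_SIGMA^2))
          }
          fociList[[length(fociList) + 1L]] <- data.frame(
            label = i, row = pts[, 1] - 1, col = pts[, 2] - 1)
        }
      }
    }

    ## optical point-spread blur of the noiseless scene, then camera noise
    if (nNuclei > 0) {
      psf <- EBImage::makeBrush(7L, "gaussian", sigma = .PSF_SIGMA)
      img <- matrix(as.numeric(EBImage::imageData(
        EBImage::filter2(EBImage::Image(img / 65535), psf))),
        nrow = height) * 65535
    }
    if (noiseSd > 0)
      img <- img + matrix(rnorm(length(img), 0, noiseSd),
                          nrow = height, ncol = width)
  })
  img <- round(pmin(pmax(img, 0), 65535))
  foci <- if (length(fociList)) do.call(rbind, fociList)
          else data.frame(label = integer(), row = numeric(),
                          col = numeric())
  rownames(foci) <- NULL
  list(image = img, labelMap = labelMap, foci = foci, nuclei = nuclei)
}

#' Read / write a 16-bit single-channel TIFF
#'
#' Images are stored as 16-bit grayscale TIFF; in memory they are numeric
#' matrices with integer values in [0, 65535], indexed [row, column].
#'
#' @param img numeric matrix with values in [0, 65535].
#' @param path file path.
#' @return \code{readNucleusImage} returns the matrix; the writer returns
#'   \code{path} invisibly.
#' @export
writeNucleusImage <- function(img, path) {
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeNucleusImage
#' @export
readNucleusImage <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}

#' Write / read the ground-truth focus list companion CSV
#'
#' Companion to a rendered image: one row per planted focus with its
#' parent nucleus label and 0-based x (column) / y (row) position.
#'
#' @param foci data.frame with columns label, row, col (as returned in
#'   \code{renderNucleusImage()$foci}).
#' @param path file path.
#' @return \code{readFociTruth} returns a data.frame label/row/col.
#' @export
writeFociTruth <- function(foci, path) {
  utils::write.csv(
    data.frame(label = foci$label, x = foci$col, y = foci$row),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFociTruth
#' @export
readFociTruth <- function(path) {
  x <- utils::read.csv(path)
  data.frame(label = x$label, row = x$y, col = x$x)
}
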