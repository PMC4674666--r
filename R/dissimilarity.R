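# Distance-transform dissimilarity between binary clutch silhouettes.
#
# Two masks are first registered (translation to matching foreground
# centroids + isotropic rescaling to matching foreground area, nearest
# neighbour); a pixel of either mask then counts as matched when the other
# mask has foreground within `tolerance_px` of it (Euclidean distance
# transform), and the dissimilarity is the proportion of unmatched pixels
# among the union of both foregrounds.

as_mask <- function(x) {
  if (is.logical(x)) m <- x else m <- x > 0.5
  storage.mode(m) <- "logical"
  if (!is.matrix(m)) stop("mask must be a 2-D matrix")
  m
}

check_mask <- function(m, what = "mask") {
  m <- as_mask(m)
  n_fg <- sum(m)
  if (n_fg == 0) stop(what, " is empty (no foreground pixels)")
  if (n_fg >= 0.9 * length(m))
    stop(what, " foreground covers >= 90% of the frame; not a clutch silhouette")
  m
}

mask_centroid <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  colMeans(idx)  # (row, col)
}

# Pad/crop-free common frame: place both masks on a frame large enough for
# the reference and the transformed moving mask.
register_pair <- function(reference, moving) {
  ref <- check_mask(reference, "reference mask")
  mov <- check_mask(moving, "moving mask")
  c_ref <- mask_centroid(ref)
  c_mov <- mask_centroid(mov)
  s <- sqrt(sum(ref) / sum(mov))  # isotropic scale matching foreground areas

  # bounding box of transformed moving foreground, in reference coordinates
  idx <- which(mov, arr.ind = TRUE)
  tr <- sweep(idx, 2, c_mov) * s
  tr <- sweep(tr, 2, c_ref, FUN = "+")
  r_lo <- min(1, floor(min(tr[, 1])) - 1); r_hi <- max(nrow(ref), ceiling(max(tr[, 1])) + 1)
  c_lo <- min(1, floor(min(tr[, 2])) - 1); c_hi <- max(ncol(ref), ceiling(max(tr[, 2])) + 1)
  nr <- r_hi - r_lo + 1L; nc <- c_hi - c_lo + 1L
  off <- c(1L - r_lo, 1L - c_lo)  # shift applied to reference coords

  ref_pad <- matrix(FALSE, nr, nc)
  ref_pad[cbind(which(ref, arr.ind = TRUE)[, 1] + off[1],
                which(ref, arr.ind = TRUE)[, 2] + off[2])] <- TRUE

  # inverse nearest-neighbour mapping: for each output pixel, sample moving
  out_r <- rep(seq_len(nr), times = nc)
  out_c <- rep(seq_len(nc), each = nr)
  src_r <- round((out_r - off[1] - c_ref[1]) / s + c_mov[1])
  src_c <- round((out_c - off[2] - c_ref[2]) / s + c_mov[2])
  ok <- src_r >= 1 & src_r <= nrow(mov) & src_c >= 1 & src_c <= ncol(mov)
  mov_reg <- matrix(FALSE, nr, nc)
  mov_reg[cbind(out_r[ok], out_c[ok])] <- mov[cbind(src_r[ok], src_c[ok])]

  list(reference = ref_pad, moving = mov_reg, scale = s,
       offset = off)
}

#' Register one clutch mask onto another
#'
#' Translates the moving mask so that the two foreground centroids coincide
#' and rescales it isotropically so that the foreground areas match
#' (nearest-neighbour resampling, re-binarized). No rotation is searched:
#' rotating would cancel genuine arrangement change, and nest photographs
#' share a consistent overhead framing.
#'
#' @param reference,moving logical (or 0/1) matrices; `TRUE`/1 = egg pixels.
#' @return the registered moving mask, a logical matrix on a frame padded
#'   (if needed) to hold both masks; the padded reference is attached as
#'   attribute `"reference"`.
#' @export
register_mask <- function(reference, moving) {
  rp <- register_pair(reference, moving)
  out <- rp$moving
  attr(out, "reference") <- rp$reference
  out
}

#' Distance-transform dissimilarity between two clutch masks
#'
#' After registration, a pixel of either mask is "matched" when the other
#' mask's Euclidean distance transform at that pixel is at most
#' `tolerance_px`; the dissimilarity is the number of unmatched pixels of
#' both masks divided by the number of pixels in the union of the two
#' registered foregrounds. The score is a proportion in \[0, 1\]: 0 for
#' identical masks, 1 when the registered masks are everywhere farther
#' apart than the tolerance. It is symmetric in its arguments and
#' non-increasing in the tolerance.
#'
#' @param before,after logical (or 0/1) mask matrices.
#' @param tolerance_px non-negative match tolerance in pixels; the default
#'   2 px absorbs resampling error at the default synthetic resolution of
#'   2 px/mm.
#' @return an object of class `dissimilarity_score`: a list with `value`,
#'   `tolerance_px`, `n_union`, `n_unmatched`.
#' @export
mask_dissimilarity <- function(before, after, tolerance_px = 2) {
  if (!is.numeric(tolerance_px) || length(tolerance_px) != 1 ||
      is.na(tolerance_px) || tolerance_px < 0)
    stop("tolerance_px must be a single non-negative number")
  # registration resamples the moving mask, which is not exactly symmetric
  # in its arguments; scoring both directions and averaging makes the
  # dissimilarity exactly symmetric
  d1 <- directed_dissimilarity(before, after, tolerance_px)
  d2 <- directed_dissimilarity(after, before, tolerance_px)
  structure(
    list(value = (d1$value + d2$value) / 2,
         tolerance_px = tolerance_px,
         n_union = d1$n_union,
         n_unmatched = d1$n_unmatched),
    class = "dissimilarity_score")
}

directed_dissimilarity <- function(reference, moving, tolerance_px) {
  rp <- register_pair(reference, moving)
  a <- rp$reference; b <- rp$moving
  dt_a <- dist_to_foreground(a)
  dt_b <- dist_to_foreground(b)
  unmatched_a <- sum(a & dt_b > tolerance_px)
  unmatched_b <- sum(b & dt_a > tolerance_px)
  n_union <- sum(a | b)
  list(value = (unmatched_a + unmatched_b) / n_union,
       n_union = n_union, n_unmatched = unmatched_a + unmatched_b)
}

#' @export
print.dissimilarity_score <- function(x, ...) {
  cat(sprintf("dissimilarity = %.4f (tolerance %.3g px, %d/%d unmatched)\n",
              x$value, x$tolerance_px, x$n_unmatched, x$n_union))
  invisible(x)
}

# Euclidean distance from every pixel to the nearest foreground pixel.
# EBImage::distmap(x) gives, within the non-zero region of x, the distance
# to the nearest zero pixel; applied to the complement it yields the
# distance to the nearest foreground pixel (0 on the foreground itself).
dist_to_foreground <- function(m) {
  if (!any(m)) return(matrix(Inf, nrow(m), ncol(m)))
  EBImage::distmap(1 - m, metric = "euclidean")
}

#' Read a binary clutch mask from PNG
#'
#' 8-bit grayscale PNG convention: 0 = background, 255 = foreground.
#' Grayscale values are binarized at 0.5.
#'
#' @param path path to a PNG file.
#' @return logical mask matrix (rows = image rows).
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  as_mask(img)
}

#' Write a binary clutch mask to PNG
#'
#' @param mask logical mask matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as_mask(mask) * 1, path)
  invisible(path)
}
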