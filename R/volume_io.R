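#' Volume and label-map containers
#'
#' A `msca_volume` wraps a 3D scalar intensity array together with its voxel
#' spacing (mm) and 4x4 voxel-to-world affine. A `msca_labels` object holds an
#' integer tissue label map over the classes 0 = background, 1 = CSF,
#' 2 = gray matter, 3 = white matter, with the same geometry fields.
#'
#' @param data 3D numeric (volume) or integer (labels) array.
#' @param spacing numeric length-3, positive voxel sizes in mm.
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(spacing)`.
#' @return An object of class `msca_volume` or `msca_labels`.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("volume data must have exactly 3 spatial axes, got rank ",
         length(dim(data)), call. = FALSE)
  if (any(spacing <= 0)) stop("all spacing components must be > 0", call. = FALSE)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix", call. = FALSE)
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine),
            class = "msca_volume")
}

#' @rdname as_volume
#' @export
as_labelmap <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("label data must have exactly 3 spatial axes, got rank ",
         length(dim(data)), call. = FALSE)
  vals <- unique(as.integer(data))
  if (any(vals < 0L | vals > 3L))
    stop("label values must lie in {0, 1, 2, 3}", call. = FALSE)
  v <- as_volume(array(1, dim(data)), spacing, affine)
  structure(list(data = array(as.integer(data), dim(data)),
                 spacing = v$spacing, affine = v$affine),
            class = "msca_labels")
}

#' @export
print.msca_volume <- function(x, ...) {
  cat("<msca_volume> ", paste(dim(x$data), collapse = "x"),
      " spacing ", paste(signif(x$spacing, 3), collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

#' @export
print.msca_labels <- function(x, ...) {
  cat("<msca_labels> ", paste(dim(x$data), collapse = "x"), " classes: ",
      paste(sort(unique(as.vector(x$data))), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Read a 3D NIfTI volume or label map
#'
#' Loads a NIfTI-1 file and reorients it to canonical RAS axis order (when the
#' header carries an orientation) so that the third axis can be treated as
#' axial downstream. Intensities are returned unmodified.
#'
#' @param path path to a `.nii` or `.nii.gz` file with 3 spatial dimensions.
#' @param labels if `TRUE`, return a `msca_labels` (values coerced to integer).
#' @return A [as_volume()] or [as_labelmap()] object.
#' @export
read_volume <- function(path, labels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd != 3L)
    stop("expected a 3-dimensional image, got rank ", nd, call. = FALSE)
  xf <- RNifti::xform(img)
  if (!is.null(attr(xf, "code")) && attr(xf, "code") != 0)
    try(RNifti::orientation(img) <- "RAS", silent = TRUE)
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))  # drop RNifti header attributes
  sp <- RNifti::pixdim(img)
  aff <- RNifti::xform(img)
  if (is.null(attr(aff, "code")) || attr(aff, "code") == 0)
    aff <- diag(c(sp, 1))
  attributes(aff) <- list(dim = c(4L, 4L))
  if (labels) as_labelmap(dat, sp, aff) else as_volume(dat, sp, aff)
}

#' Write a volume or label map as NIfTI-1
#'
#' Label maps are written with an integer on-disk datatype; volumes with
#' float64 so that round trips are bitwise.
#'
#' @param vol a `msca_volume` or `msca_labels`.
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  is_lab <- inherits(vol, "msca_labels")
  img <- RNifti::asNifti(if (is_lab) array(as.integer(vol$data), dim(vol$data))
                         else vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = if (is_lab) "int16" else "float64")
  invisible(path)
}

#' One-hot encode a label map
#'
#' Expands integer tissue labels into a K-channel probability grid in the
#' channel-first layout `(K, X, Y, Z)` used by the network: channel k is 1
#' exactly where the label equals k.
#'
#' @param labels a `msca_labels` or integer 3D array.
#' @param K number of classes (default 4).
#' @return numeric array of dim `(K, dim(labels))`; channel sums are 1.
#' @export
one_hot_encode <- function(labels, K = 4L) {
  lab <- if (inherits(labels, "msca_labels")) labels$data else labels
  if (any(lab >= K)) stop("label value >= K (", K, ") found", call. = FALSE)
  d <- dim(lab)
  out <- numeric(K * prod(d))
  idx <- K * (seq_along(lab) - 1L) + as.integer(lab) + 1L
  out[idx] <- 1
  ftensor(out, c(K, d))
}

# ambient-RNG patch sampler shared by the exported op and the training loop
.sample_patch_rng <- function(vol, labels, size, fg_bias) {
  d <- dim(vol$data)
  size <- rep_len(as.integer(size), 3L)
  if (any(size > d))
    stop("patch size (", paste(size, collapse = "x"),
         ") exceeds volume shape (", paste(d, collapse = "x"), ")", call. = FALSE)
  use_fg <- fg_bias > 0 && runif(1) < fg_bias
  if (use_fg) {
    # class-balanced: draw a present tissue class uniformly, then one of its
    # voxels, so small classes are sampled as often as large ones
    present <- intersect(1:3, unique(as.integer(labels$data)))
    if (length(present) == 0L) use_fg <- FALSE
  }
  if (use_fg) {
    cls <- present[sample.int(length(present), 1L)]
    fg <- which(labels$data == cls)
    v <- fg[sample.int(length(fg), 1L)] - 1L
    ctr <- c(v %% d[1], (v %/% d[1]) %% d[2], v %/% (d[1] * d[2]))
    origin <- pmin(pmax(ctr - size %/% 2L, 0L), d - size)
  } else {
    origin <- vapply(1:3, function(a) sample.int(d[a] - size[a] + 1L, 1L) - 1L,
                     integer(1))
  }
  ix <- lapply(1:3, function(a) (origin[a] + 1L):(origin[a] + size[a]))
  list(image = vol$data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       labels = labels$data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       origin = as.integer(origin), size = size)
}

#' Sample an aligned image/label training patch
#'
#' Draws a patch of the given size. With probability `fg_bias` the patch is
#' centred on a foreground (non-background-label) voxel, drawn class-balanced
#' (a tissue class present in the map is chosen uniformly, then one of its
#' voxels), clamped to the volume bounds; otherwise the origin is uniform
#' over the valid origin lattice. Extents are half-open
#' `[origin, origin + size)` in 0-based voxel coordinates.
#'
#' @param vol a `msca_volume`.
#' @param labels the paired `msca_labels`.
#' @param size patch extent per axis (scalar or length 3).
#' @param seed integer; the same seed yields the same patch.
#' @param fg_bias probability in `[0, 1]` of foreground-centred sampling.
#' @return list with `image`, `labels`, `origin` (0-based), `size`.
#' @export
sample_patch <- function(vol, labels, size, seed, fg_bias = 0.5) {
  if (fg_bias < 0 || fg_bias > 1) stop("fg_bias must be in [0, 1]", call. = FALSE)
  with_seed(seed, .sample_patch_rng(vol, labels, size, fg_bias))
}
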