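#' Construct a patch specification
#'
#' @param patchSize integer(3) patch dimensions.
#' @param padTo integer(3) padded volume shape, divisible by patchSize.
#' @return a \code{\linkS4class{PatchSpec}}.
#' @examples
#' # full-scale spec: 182x218x182 scans padded to 182x224x182, giving
#' # a 13x14x13 grid of 2,366 patches of 14x16x14 voxels
#' spec <- patchSpec(c(14L, 16L, 14L), c(182L, 224L, 182L))
#' prod(gridDims(spec))
#' @export
patchSpec <- function(patchSize, padTo) {
  new("PatchSpec", patchSize = as.integer(patchSize),
      padTo = as.integer(padTo))
}

#' @rdname patchSpec
#' @param spec a \code{PatchSpec}.
#' @export
gridDims <- function(spec) spec@padTo %/% spec@patchSize

# symmetric zero-pad of a 3-D array to target shape; odd remainders put the
# extra voxel on the high side
padVolume <- function(v, padTo) {
  dm <- dim(v)
  stopIfNot(all(dm <= padTo), "volume dims exceed pad_to dims")
  if (all(dm == padTo)) return(v)
  out <- array(0, dim = padTo)
  lo <- (padTo - dm) %/% 2L
  out[lo[1] + seq_len(dm[1]), lo[2] + seq_len(dm[2]), lo[3] + seq_len(dm[3])] <- v
  out
}

#' Tokenize a volume into non-overlapping patches
#'
#' Zero-pads the volume symmetrically to \code{padTo(spec)} (the extra voxel
#' goes to the high side on odd remainders), then tiles it with
#' non-overlapping patches enumerated x-fastest; voxels within a patch are
#' likewise x-fastest (column-major).
#'
#' @param volume 3-D numeric array.
#' @param spec a \code{\linkS4class{PatchSpec}}.
#' @return matrix n_patches x patch_voxels with attribute \code{grid}
#'   (the patch-grid dimensions).
#' @export
tokenizeVolume <- function(volume, spec) {
  stopifnot(is(spec, "PatchSpec"))
  stopIfNot(length(dim(volume)) == 3L, "volume must be a 3-D array")
  v <- padVolume(volume, spec@padTo)
  tok <- tokenizeBatch(array(v, dim = c(dim(v), 1L)), spec)
  attr(tok, "grid") <- gridDims(spec)
  tok
}

# batched tokenization of a (x, y, z, n) array already at padTo shape:
# returns (n_patches * n) x patch_voxels, subject-major blocks
tokenizeBatch <- function(vols, spec) {
  p <- spec@patchSize
  g <- gridDims(spec)
  dm <- dim(vols)
  stopIfNot(identical(dm[1:3], as.integer(spec@padTo)),
            "volumes must already match padTo")
  n <- dm[4]
  dim(vols) <- c(p[1], g[1], p[2], g[2], p[3], g[3], n)
  ap <- aperm(vols, c(1L, 3L, 5L, 2L, 4L, 6L, 7L))
  t(matrix(ap, nrow = prod(p)))
}

#' Reassemble a volume from its patch tokens
#'
#' Inverse of \code{\link{tokenizeVolume}} up to the zero padding:
#' returns the padded volume.
#'
#' @param tokens n_patches x patch_voxels matrix in tokenizeVolume order.
#' @param spec the \code{PatchSpec} used to tokenize.
#' @return 3-D array of shape \code{padTo(spec)}.
#' @export
detokenizeVolume <- function(tokens, spec) {
  p <- spec@patchSize
  g <- gridDims(spec)
  stopIfNot(nrow(tokens) == prod(g) && ncol(tokens) == prod(p),
            "token matrix does not match spec")
  a <- array(t(tokens), dim = c(p[1], p[2], p[3], g[1], g[2], g[3]))
  a <- aperm(a, c(1L, 4L, 2L, 5L, 3L, 6L))
  array(a, dim = spec@padTo)
}
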