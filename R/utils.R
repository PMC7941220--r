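#' @keywords internal
"_PACKAGE"

## Linear voxel indexing is 1-based, x-fastest (R's native array order), so
## `array(x, grid)[idx]` and coordinate arithmetic always agree.

#' Convert voxel grid coordinates to linear indices
#'
#' @param coords integer matrix with columns x, y, z (1-based).
#' @param grid_shape integer vector of length 3.
#' @return integer vector of 1-based linear indices (x-fastest).
#' @export
coord_to_index <- function(coords, grid_shape) {
  coords <- matrix(as.integer(coords), ncol = 3)
  stopifnot(all(coords >= 1L),
            all(coords[, 1] <= grid_shape[1]),
            all(coords[, 2] <= grid_shape[2]),
            all(coords[, 3] <= grid_shape[3]))
  coords[, 1] + (coords[, 2] - 1L) * grid_shape[1] +
    (coords[, 3] - 1L) * grid_shape[1] * grid_shape[2]
}

#' Convert linear voxel indices to grid coordinates
#'
#' @param idx 1-based linear indices (x-fastest).
#' @param grid_shape integer vector of length 3.
#' @return integer matrix with columns x, y, z.
#' @export
index_to_coord <- function(idx, grid_shape) {
  idx0 <- as.integer(idx) - 1L
  x <- idx0 %% grid_shape[1]
  y <- (idx0 %/% grid_shape[1]) %% grid_shape[2]
  z <- idx0 %/% (grid_shape[1] * grid_shape[2])
  cbind(x = x + 1L, y = y + 1L, z = z + 1L)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Derive a child seed from a base seed and a stream label, staying well below
## .Machine$integer.max so downstream set.seed() never overflows.
child_seed <- function(seed, stream) {
  ## double arithmetic is exact here (< 2^53) and avoids integer overflow
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 101) %%
               2147480000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
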