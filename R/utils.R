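## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## run expr with a fixed RNG state, restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Display rounding, half away from zero
#'
#' Report-time rounding convention: halves round away from zero, so
#' 2.835 displays as 2.84 (base R's `round` rounds half to even).
#' Full-precision values are kept everywhere else.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## world coordinates (mm) of voxel centers along one axis
axis_coords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

## coordinate arrays for a full grid; heavy but vectorized
grid_coords <- function(dim, spacing, origin) {
  x <- axis_coords(dim[1], spacing[1], origin[1])
  y <- axis_coords(dim[2], spacing[2], origin[2])
  z <- axis_coords(dim[3], spacing[3], origin[3])
  list(x = x, y = y, z = z)
}
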