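#' Clipped 3 x 3 box mean
#'
#' Mean of each pixel's 3 x 3 neighborhood, the window clipped at the matrix
#' boundary and, optionally, restricted to a mask (cells outside the mask
#' contribute neither to the sum nor to the count).
#'
#' @param mat Numeric matrix.
#' @param mask Optional logical matrix of the same shape; defaults to all
#'   `TRUE`.
#' @return Numeric matrix of the same shape; `NA` where no in-mask pixel
#'   falls in the window.
#' @keywords internal
box_mean3 <- function(mat, mask = NULL) {
  h <- nrow(mat); w <- ncol(mat)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  vals <- mat
  vals[!mask] <- 0
  cnt <- matrix(0, h, w)
  cnt[mask] <- 1
  pad <- function(m) {
    out <- matrix(0, h + 2L, w + 2L)
    out[2:(h + 1L), 2:(w + 1L)] <- m
    out
  }
  v_p <- pad(vals); c_p <- pad(cnt)
  s <- matrix(0, h, w); n <- matrix(0, h, w)
  for (dy in 0:2) {
    for (dx in 0:2) {
      s <- s + v_p[dy + seq_len(h), dx + seq_len(w)]
      n <- n + c_p[dy + seq_len(h), dx + seq_len(w)]
    }
  }
  out <- s / n
  out[n == 0] <- NA_real_
  out
}

# run code with a temporarily seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
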