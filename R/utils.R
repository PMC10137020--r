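# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic operations in the package
# go through this so that scene generation and rendering are reproducible
# without clobbering the user's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

# Derive a sub-seed for an independent stream (e.g. per timepoint/channel)
# from a base seed; stays inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) h <- (h * 31 + as.numeric(v)) %% 2147483546
  as.integer(h + 1)
}

# Shift a matrix by (dr, dc), filling exposed cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Reflect-padded (edge-mirroring) box sum over a k x k window, via an
# integral image. k must be odd. Used by the focus metric and the
# decision-map median filter.
box_sum <- function(m, k) {
  stopifnot(k %% 2 == 1, k >= 1)
  h <- (k - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ridx <- c(pmin(h:1, nr), seq_len(nr), pmax(nr - seq_len(h) + 1L, 1L))
  cidx <- c(pmin(h:1, nc), seq_len(nc), pmax(nc - seq_len(h) + 1L, 1L))
  p <- m[ridx, cidx, drop = FALSE]
  s <- apply(apply(p, 2, cumsum), 1, cumsum) # s is transposed cumulative sum
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  i1 <- seq_len(nr); j1 <- seq_len(nc)
  s[i1 + k, j1 + k, drop = FALSE] - s[i1, j1 + k, drop = FALSE] -
    s[i1 + k, j1, drop = FALSE] + s[i1, j1, drop = FALSE]
}

# Gaussian blur whose kernel radius is capped to the image size (EBImage's
# default 3-sigma support can exceed small test images).
gblur_safe <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  rmax <- min(dim(img)[1:2])
  if (rmax %% 2L == 0L) rmax <- rmax - 1L
  EBImage::gblur(img, sigma = sigma, radius = min(r, rmax))
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}
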