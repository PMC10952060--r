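# internal helpers: typed conditions and scoped RNG

stop_loxdyn <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "loxdyn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# run `expr` under a fixed seed and RNG kind without disturbing the caller's
# RNG stream; RNG kind is pinned so fixtures are reproducible across platforms
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

rng_kind_label <- "Mersenne-Twister/Inversion/Rejection"

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalize rows of an n x 3 matrix
vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop_loxdyn("cannot normalize zero vector", "loxdyn_degenerate_error")
  v / n
}

# Rodrigues rotation matrix for angle (radians) about unit axis
rotation_about_axis <- function(axis, angle) {
  a <- unit(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
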