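# Internal helpers shared across modules.

# Absolute tolerance used when comparing speeds to classification thresholds.
# Constant-speed positions accumulated step by step carry O(1e-13) rounding
# noise; a 1e-9 guard keeps the stated boundary semantics ("strictly above"
# the motion cutoff, "at or above" the walk threshold) exact for any speed a
# caller can actually intend, while being ~1e4 times larger than the noise.
SPEED_TOL <- 1e-9

stop_vt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_vt("'%s' must be a single finite number", name)
  if (strict_min && x <= min)
    stop_vt("'%s' must be > %g (got %g)", name, min, x)
  if (!strict_min && x < min)
    stop_vt("'%s' must be >= %g (got %g)", name, min, x)
  if (x > max)
    stop_vt("'%s' must be <= %g (got %g)", name, max, x)
  invisible(x)
}

check_probability <- function(x, name) check_scalar_number(x, name, 0, 1)

check_count <- function(x, name, min = 0L) {
  check_scalar_number(x, name, min = min)
  if (x != as.integer(x)) stop_vt("'%s' must be an integer (got %g)", name, x)
  invisible(as.integer(x))
}

# Deterministic child seed: mixes a master seed with a stage label so that
# independent pipeline stages draw from unrelated streams. Kept below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# Evaluate expr with a private RNG stream; the caller's RNG state (if any)
# is untouched.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Otsu's threshold on a vector of intensities binned to 256 levels.
otsu_threshold <- function(x) {
  x <- as.integer(round(pmin(pmax(x, 0), 255)))
  h <- as.numeric(tabulate(x + 1L, nbins = 256L))
  n <- sum(h)
  levels <- 0:255
  w1 <- cumsum(h)
  mu <- cumsum(h * levels)
  mu_t <- mu[256L]
  w2 <- n - w1
  between <- (mu_t * w1 - n * mu)^2 / (as.numeric(w1) * w2 * n^2)
  between[w1 == 0 | w2 == 0] <- -Inf
  levels[which.max(between)] + 0.5
}

# 8-connected component labelling over a sparse set of mask pixels,
# given as a 2-column matrix of (row, col). Returns an integer label per
# pixel. Union-find keeps this linear in the number of mask pixels, which
# for fly-sized blobs is tiny compared with the region area.
label_components <- function(px) {
  n <- nrow(px)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- paste(px[, 1L], px[, 2L])
  idx <- new.env(hash = TRUE, size = n * 2L)
  for (i in seq_len(n)) assign(key[i], i, envir = idx)
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L))
  for (i in seq_len(n)) {
    for (k in 1:4) {
      nb <- paste(px[i, 1L] + offs[k, 1L], px[i, 2L] + offs[k, 2L])
      j <- idx[[nb]]
      if (!is.null(j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Row-wise median of a numeric matrix via one global order(): much faster
# than apply(m, 1, median) at video-frame scale.
row_medians <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nc == 1L) return(as.numeric(m))
  s <- matrix(m[order(row(m), m)], nrow = nr, byrow = TRUE)
  if (nc %% 2L == 1L) s[, (nc + 1L) %/% 2L]
  else (s[, nc %/% 2L] + s[, nc %/% 2L + 1L]) / 2
}
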