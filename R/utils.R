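# Internal helpers: seeded evaluation, seed streams, grid geometry.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL means "use the current stream" (no save/restore).
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' Seed streams for multi-stage computations (landscape variants, design
#' cells, bootstrap) are split by name so every stage is independently
#' replayable. The result is always a valid 32-bit integer seed.
#'
#' @param seed integer master seed.
#' @param label character stage label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(paste(label, collapse = "/"))) h <- (h * 131 + k) %% 1000000007
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483646) + 1L
}

# 4-neighbourhood of a linear index in an nr x nc matrix (column-major).
neighbors4 <- function(lin, nr, nc) {
  r <- (lin - 1L) %% nr + 1L
  cc <- (lin - 1L) %/% nr + 1L
  out <- c(if (r > 1L) lin - 1L, if (r < nr) lin + 1L,
           if (cc > 1L) lin - nr, if (cc < nc) lin + nr)
  out
}

# One binary dilation step with the 4-neighbourhood, repeated `steps` times.
dilate4 <- function(m, steps) {
  if (steps <= 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  for (s in seq_len(steps)) {
    m <- m |
      rbind(FALSE, m[-nr, , drop = FALSE]) |
      rbind(m[-1L, , drop = FALSE], FALSE) |
      cbind(FALSE, m[, -nc, drop = FALSE]) |
      cbind(m[, -1L, drop = FALSE], FALSE)
  }
  m
}

# Label 4-connected components of a logical matrix; 0 where FALSE.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(0L, nr, nc)
  queue <- integer(sum(mask))
  k <- 0L
  for (start in which(mask)) {
    if (comp[start] != 0L) next
    k <- k + 1L
    head <- 1L; tail <- 1L
    queue[1L] <- start
    comp[start] <- k
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      for (nb in neighbors4(cur, nr, nc)) {
        if (mask[nb] && comp[nb] == 0L) {
          comp[nb] <- k
          tail <- tail + 1L
          queue[tail] <- nb
        }
      }
    }
  }
  comp
}

# Round a positive real vector to integers that sum to `total`
# (largest-remainder), each at least `minimum`.
apportion <- function(x, total, minimum = 1L) {
  stopifnot(all(x > 0), total >= length(x) * minimum)
  raw <- x / sum(x) * (total - length(x) * minimum)
  base <- floor(raw)
  rem <- total - length(x) * minimum - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base) + as.integer(minimum)
}
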