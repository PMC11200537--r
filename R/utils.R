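# Internal helpers: seeded evaluation, array plumbing.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so exported deterministic ops do not disturb
# the ambient stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# channel-first feature tensor helpers ------------------------------------

ftensor <- function(x, dims) {
  dim(x) <- dims
  x
}

fdims <- function(x) dim(x)

# Per-voxel softmax over the channel (first) axis of a (K, X, Y, Z) array.
channel_softmax <- function(logits) {
  d <- dim(logits)
  K <- d[1]
  m <- matrix(logits, nrow = K)
  mx <- m[1, ]
  if (K > 1) for (k in 2:K) mx <- pmax(mx, m[k, ])
  e <- exp(sweep(m, 2, mx, "-"))
  s <- .colSums(e, K, ncol(e))
  p <- sweep(e, 2, s, "/")
  ftensor(p, d)
}

# argmax over channels with ties resolved to the lowest class index
channel_argmax <- function(prob) {
  d <- dim(prob)
  K <- d[1]
  m <- matrix(prob, nrow = K)
  best <- rep.int(0L, ncol(m))
  bestv <- m[1, ]
  if (K > 1) for (k in 2:K) {
    better <- m[k, ] > bestv
    best[better] <- k - 1L
    bestv[better] <- m[k, better]
  }
  ftensor(best, d[-1])
}

stopifnot_shape <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
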