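# Shared test fixtures: small deterministic phantoms and helpers.

ftensor <- mscaseg:::ftensor
channel_softmax <- mscaseg:::channel_softmax
channel_argmax <- mscaseg:::channel_argmax
with_seed <- mscaseg:::with_seed

tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- phantom_config(shape = c(48, 48, 48))
      cache <<- generate_phantom(cfg, seed = 7)
    }
    cache
  }
})

# brute-force directed/symmetric HD95 oracle for small masks
hd95_oracle <- function(A, B, spacing = c(1, 1, 1), probs = 0.95) {
  ai <- which(A != 0, arr.ind = TRUE)
  bi <- which(B != 0, arr.ind = TRUE)
  if (nrow(ai) == 0 || nrow(bi) == 0) return(NA_real_)
  as_mm <- function(m) sweep(m - 1, 2, spacing, "*")
  am <- as_mm(ai); bm <- as_mm(bi)
  dmat <- outer(rowSums(am^2), rowSums(bm^2), "+") - 2 * am %*% t(bm)
  dmat[dmat < 0] <- 0
  d_ab <- sqrt(apply(dmat, 1, min))
  d_ba <- sqrt(apply(dmat, 2, min))
  max(quantile(d_ab, probs, names = FALSE, type = 7),
      quantile(d_ba, probs, names = FALSE, type = 7))
}

mean_fg_dice <- function(pred, gt) {
  p <- if (inherits(pred, "msca_labels")) pred$data else pred
  g <- if (inherits(gt, "msca_labels")) gt$data else gt
  mean(vapply(1:3, function(k) dice_coefficient(p == k, g == k), numeric(1))) / 100
}
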