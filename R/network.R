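#' Network architecture configuration
#'
#' Five-stage encoder-decoder for 4-class tissue segmentation. The encoder
#' downsamples by 2 at every stage (overall factors 2, 4, 8, 16, 32); stages
#' 1-2 use plain 3x3x3 convolution blocks, stages 3-5 (including the
#' bottleneck) use multiscale convolutional attention blocks. The decoder
#' mirrors the encoder with strided-deconvolution upsampling, concatenating
#' skip connections, and one deep-supervision head per decoder resolution;
#' the final head sits at full patch resolution. All normalisation is
#' instance normalisation with learnable scale/shift.
#'
#' @param stage_channels per-stage channel widths (length 5); default follows
#'   the common 3D U-Net convention.
#' @param n_classes number of output classes (default 4).
#' @param use_msca if `FALSE`, every attention block is replaced by a plain
#'   convolution block (ablation).
#' @param dw_kernel,branch_kernels attention-block kernels, see
#'   [msca_params()].
#' @param norm_eps instance-norm epsilon.
#' @return an `arch_config` list with `n_stages = 5` and per-stage block
#'   types.
#' @export
arch_config <- function(stage_channels = c(32, 64, 128, 256, 320),
                        n_classes = 4L, use_msca = TRUE,
                        dw_kernel = 5L, branch_kernels = c(5L, 7L, 11L),
                        norm_eps = 1e-5) {
  if (length(stage_channels) != 5L)
    stop("stage_channels must have length 5", call. = FALSE)
  enc_type <- if (use_msca) c("conv", "conv", "msca", "msca", "msca")
              else rep("conv", 5L)
  # decoder levels run deepest-first at factors 16, 8, 4, 2, 1
  dec_type <- if (use_msca) c("msca", "msca", "conv", "conv", "conv")
              else rep("conv", 5L)
  structure(list(n_stages = 5L, stage_channels = as.integer(stage_channels),
                 stage_block_type = enc_type, dec_block_type = dec_type,
                 n_classes = as.integer(n_classes), use_msca = isTRUE(use_msca),
                 dw_kernel = as.integer(dw_kernel),
                 branch_kernels = as.integer(branch_kernels),
                 norm_eps = norm_eps),
            class = "arch_config")
}

#' Desk-scale architecture preset
#'
#' Small channel widths for CPU experiments and tests (32 cubed patches).
#' @param ... overrides passed to [arch_config()].
#' @export
arch_config_tiny <- function(...) {
  arch_config(stage_channels = c(8, 16, 32, 64, 64), ...)
}

.init_block <- function(type, C, cfg) {
  if (type == "msca") {
    list(type = "msca", g = rep(1, C), bt = numeric(C),
         msca = msca_init(msca_params(C, cfg$dw_kernel, cfg$branch_kernels)))
  } else {
    list(type = "conv", w = init_conv_w(C, C, c(3L, 3L, 3L)), b = numeric(C),
         g = rep(1, C), bt = numeric(C))
  }
}

#' Build a segmentation network
#'
#' Instantiates all parameters (He initialisation) deterministically under
#' the given seed.
#'
#' @param cfg an [arch_config()].
#' @param seed integer initialisation seed.
#' @return a `msca_network` object.
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "arch_config"))
  ch <- cfg$stage_channels
  with_seed(seed, {
    enc <- vector("list", 5L)
    cin <- 1L
    for (s in 1:5) {
      enc[[s]] <- list(
        down = list(w = init_conv_w(ch[s], cin, c(3L, 3L, 3L)), b = numeric(ch[s]),
                    g = rep(1, ch[s]), bt = numeric(ch[s])),
        block = .init_block(cfg$stage_block_type[s], ch[s], cfg))
      cin <- ch[s]
    }
    dc <- c(ch[4], ch[3], ch[2], ch[1], ch[1])
    skip_ch <- c(ch[4], ch[3], ch[2], ch[1], 0L)
    dec <- vector("list", 5L)
    prev <- ch[5]
    for (j in 1:5) {
      dec[[j]] <- list(
        up = list(w = init_deconv_w(dc[j], prev), b = numeric(dc[j])),
        fuse = list(w = init_conv_w(dc[j], dc[j] + skip_ch[j], c(3L, 3L, 3L)),
                    b = numeric(dc[j]), g = rep(1, dc[j]), bt = numeric(dc[j])),
        block = .init_block(cfg$dec_block_type[j], dc[j], cfg),
        head = list(w = matrix(rnorm(cfg$n_classes * dc[j],
                                     sd = sqrt(2 / dc[j])), cfg$n_classes, dc[j]),
                    b = numeric(cfg$n_classes)))
      prev <- dc[j]
    }
    structure(list(cfg = cfg, params = list(enc = enc, dec = dec), seed = seed),
              class = "msca_network")
  })
}

#' @export
print.msca_network <- function(x, ...) {
  cat("<msca_network> channels", paste(x$cfg$stage_channels, collapse = "/"),
      if (x$cfg$use_msca) "(attention stages 3-5)" else "(plain conv, ablation)",
      "\n  parameters:", format(n_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

#' Total number of trainable parameters
#' @param net a `msca_network`.
#' @export
n_parameters <- function(net) {
  count <- function(x) {
    if (is.numeric(x)) return(length(x))
    if (is.list(x) && !inherits(x, "msca_params"))
      return(sum(vapply(x, count, numeric(1))))
    0
  }
  count(net$params)
}

# --- forward / backward ----------------------------------------------------

.stage_block_fw <- function(x, blk, eps) {
  if (blk$type == "conv") {
    c1 <- conv_fw(x, blk$w, blk$b, c(3L, 3L, 3L))
    n1 <- instnorm_fw(c1$y, blk$g, blk$bt, eps)
    a1 <- lrelu_fw(n1$y)
    list(y = a1$y, cache = list(c1 = c1$cache, n1 = n1$cache, a1 = a1$cache))
  } else {
    n1 <- instnorm_fw(x, blk$g, blk$bt, eps)
    a1 <- gelu_fw(n1$y)
    m1 <- msca_fw(a1$y, blk$msca)
    list(y = x + m1$y, cache = list(n1 = n1$cache, a1 = a1$cache, m1 = m1$cache))
  }
}

.stage_block_bw <- function(dy, blk, cache) {
  if (blk$type == "conv") {
    da <- lrelu_bw(dy, cache$a1)
    gn <- instnorm_bw(da, blk$g, cache$n1)
    gc <- conv_bw(gn$dx, blk$w, cache$c1)
    list(dx = gc$dx, grads = list(w = gc$dw, b = gc$db, g = gn$dgamma, bt = gn$dbeta))
  } else {
    gm <- msca_bw(dy, blk$msca, cache$m1)
    da <- gelu_bw(gm$dx, cache$a1)
    gn <- instnorm_bw(da, blk$g, cache$n1)
    dx <- dy + gn$dx
    list(dx = dx, grads = list(g = gn$dgamma, bt = gn$dbeta, msca = gm$grads))
  }
}

.cat_channels <- function(u, s) {
  du <- dim(u); ds <- dim(s)
  ftensor(rbind(matrix(u, du[1]), matrix(s, ds[1])), c(du[1] + ds[1], du[-1]))
}

net_forward <- function(net, x, keep_cache = FALSE) {
  cfg <- net$cfg
  eps <- cfg$norm_eps
  P <- net$params
  caches <- if (keep_cache) list(enc = vector("list", 5L),
                                 dec = vector("list", 5L)) else NULL
  h <- x
  skips <- vector("list", 5L)
  for (s in 1:5) {
    dn <- conv_fw(h, P$enc[[s]]$down$w, P$enc[[s]]$down$b, c(3L, 3L, 3L), c(2L, 2L, 2L))
    nn <- instnorm_fw(dn$y, P$enc[[s]]$down$g, P$enc[[s]]$down$bt, eps)
    aa <- lrelu_fw(nn$y)
    bl <- .stage_block_fw(aa$y, P$enc[[s]]$block, eps)
    skips[[s]] <- bl$y
    h <- bl$y
    if (keep_cache)
      caches$enc[[s]] <- list(dn = dn$cache, nn = nn$cache, aa = aa$cache,
                              bl = bl$cache)
  }
  logits <- vector("list", 5L)
  for (j in 1:5) {
    up <- deconv_fw(h, P$dec[[j]]$up$w, P$dec[[j]]$up$b)
    skip <- if (j < 5L) skips[[5L - j]] else NULL
    cat_in <- if (is.null(skip)) up$y else .cat_channels(up$y, skip)
    fz <- conv_fw(cat_in, P$dec[[j]]$fuse$w, P$dec[[j]]$fuse$b, c(3L, 3L, 3L))
    fn <- instnorm_fw(fz$y, P$dec[[j]]$fuse$g, P$dec[[j]]$fuse$bt, eps)
    fa <- lrelu_fw(fn$y)
    bl <- .stage_block_fw(fa$y, P$dec[[j]]$block, eps)
    hd <- pconv_fw(bl$y, P$dec[[j]]$head$w, P$dec[[j]]$head$b)
    logits[[j]] <- hd$y
    h <- bl$y
    if (keep_cache)
      caches$dec[[j]] <- list(up = up$cache, had_skip = !is.null(skip),
                              u_ch = dim(up$y)[1], fz = fz$cache, fn = fn$cache,
                              fa = fa$cache, bl = bl$cache, hd = hd$cache)
  }
  list(logits = logits, caches = caches)
}

net_backward <- function(net, caches, dlogits) {
  cfg <- net$cfg
  P <- net$params
  gdec <- vector("list", 5L)
  dskips <- vector("list", 5L)  # gradient flowing into encoder skips
  dh <- NULL  # gradient w.r.t. decoder carry (block output of current level)
  for (j in 5:1) {
    cc <- caches$dec[[j]]
    ghd <- pconv_bw(dlogits[[j]], P$dec[[j]]$head$w, cc$hd)
    dbl_out <- ghd$dx
    if (!is.null(dh)) dbl_out <- dbl_out + dh
    gb <- .stage_block_bw(dbl_out, P$dec[[j]]$block, cc$bl)
    dfa <- lrelu_bw(gb$dx, cc$fa)
    gfn <- instnorm_bw(dfa, P$dec[[j]]$fuse$g, cc$fn)
    gfz <- conv_bw(gfn$dx, P$dec[[j]]$fuse$w, cc$fz)
    dcat <- gfz$dx
    if (cc$had_skip) {
      dc <- dim(dcat)
      m <- matrix(dcat, dc[1])
      du <- ftensor(m[seq_len(cc$u_ch), , drop = FALSE], c(cc$u_ch, dc[-1]))
      dskips[[5L - j]] <- ftensor(m[-seq_len(cc$u_ch), , drop = FALSE],
                                  c(dc[1] - cc$u_ch, dc[-1]))
    } else du <- dcat
    gup <- deconv_bw(du, P$dec[[j]]$up$w, cc$up)
    dh <- gup$dx
    gdec[[j]] <- list(up = list(w = gup$dw, b = gup$db),
                      fuse = list(w = gfz$dw, b = gfz$db, g = gfn$dgamma,
                                  bt = gfn$dbeta),
                      block = gb$grads,
                      head = list(w = ghd$dw, b = ghd$db))
  }
  genc <- vector("list", 5L)
  for (s in 5:1) {
    cc <- caches$enc[[s]]
    # stage 5 output feeds only the decoder carry; stages 1-4 feed both
    # their skip connection and the next encoder stage's input
    d_out <- if (s == 5L) dh else dskips[[s]] + dh
    gb <- .stage_block_bw(d_out, P$enc[[s]]$block, cc$bl)
    daa <- lrelu_bw(gb$dx, cc$aa)
    gnn <- instnorm_bw(daa, P$enc[[s]]$down$g, cc$nn)
    gdn <- conv_bw(gnn$dx, P$enc[[s]]$down$w, cc$dn)
    dh <- gdn$dx
    genc[[s]] <- list(down = list(w = gdn$dw, b = gdn$db, g = gnn$dgamma,
                                  bt = gnn$dbeta),
                      block = gb$grads)
  }
  list(enc = genc, dec = gdec)
}

#' Run a forward pass and return deep-supervision probability maps
#'
#' @param net a `msca_network`.
#' @param patch 3D numeric array whose extents are divisible by 32 (the
#'   deepest downsampling factor).
#' @return list with `outputs` (five per-voxel-normalised probability arrays
#'   `(K, ...)`, lowest resolution first, the last at input resolution) and
#'   `scale_factors` `c(16, 8, 4, 2, 1)`.
#' @export
forward_pass <- function(net, patch) {
  d <- dim(patch)
  if (length(d) != 3L) stop("patch must be a 3D array", call. = FALSE)
  if (any(d %% 32L != 0L))
    stop("patch extents must be divisible by 32; got ",
         paste(d, collapse = "x"), call. = FALSE)
  x <- ftensor(as.double(patch), c(1L, d))
  fw <- net_forward(net, x, keep_cache = FALSE)
  list(outputs = lapply(fw$logits, channel_softmax),
       scale_factors = c(16L, 8L, 4L, 2L, 1L))
}

#' Architecture summary table
#'
#' One row per encoder stage and decoder level: resolution factor, channels,
#' block type and parameter count.
#'
#' @param net a `msca_network`.
#' @return a data.frame.
#' @export
describe_network <- function(net) {
  cfg <- net$cfg
  cnt <- function(x) {
    if (is.numeric(x)) return(length(x))
    if (is.list(x) && !inherits(x, "msca_params"))
      return(sum(vapply(x, cnt, numeric(1))))
    0
  }
  rows <- lapply(1:5, function(s) data.frame(
    part = "encoder", level = s, factor = 2L^s,
    channels = cfg$stage_channels[s], block = cfg$stage_block_type[s],
    n_params = cnt(net$params$enc[[s]])))
  dc <- with(cfg, c(stage_channels[4], stage_channels[3], stage_channels[2],
                    stage_channels[1], stage_channels[1]))
  rows <- c(rows, lapply(1:5, function(j) data.frame(
    part = "decoder", level = j, factor = 2L^(5L - j),
    channels = dc[j], block = cfg$dec_block_type[j],
    n_params = cnt(net$params$dec[[j]]))))
  do.call(rbind, rows)
}
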