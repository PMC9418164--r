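# Nested-skip attention encoder-decoder with deep supervision.
#
# The network is a UNet++-style grid of nodes X(i, j): level i (0 = full
# resolution) and column j.  Column 0 is the encoder; each decoder node
# concatenates all previous nodes of its level with the transposed-conv
# upsampling of the node one level below in the previous column, then runs a
# double 3x3 conv block followed by a channel-then-spatial attention gate.
# Every full-resolution decoder node X(0, j), j >= 1, carries a deep
# supervision head (1x1 conv + sigmoid); the fused prediction is the
# arithmetic mean of the heads.
#
# Forward and backward passes are written out by hand on top of the compiled
# convolution kernels; parameters live in a flat named list so the
# mean-teacher EMA and Adam updates are simple elementwise operations.

#' Segmentation model configuration
#'
#' @param backbone `"tiny"` (plain double-conv encoder blocks, the CPU-scale
#'   default) or `"efficient_pretrained"` (reserved for an externally supplied
#'   pretrained encoder; not required by any test and currently mapped onto
#'   the same nested topology).
#' @param levels Encoder depth (number of resolution levels), at least 2.
#' @param base_channels Channel width at full resolution; width doubles per
#'   level.
#' @param deep_supervision Keep one sigmoid head per full-resolution decoder
#'   node (`levels - 1` heads) and average them into the fused map.
#' @param attention Insert a channel-then-spatial attention gate after each
#'   node's convolution block.
#' @param input_size `(height, width)` of the network input; both must be
#'   divisible by `2^(levels - 1)`.
#' @param attention_reduction Channel-attention bottleneck ratio; the hidden
#'   width is `max(1, channels / attention_reduction)`.
#' @return A `model_config` list.
#' @export
model_config <- function(backbone = c("tiny", "efficient_pretrained"),
                         levels = 3L, base_channels = 4L,
                         deep_supervision = TRUE, attention = TRUE,
                         input_size = c(64L, 64L),
                         attention_reduction = 8L) {
  backbone <- match.arg(backbone)
  levels <- as.integer(levels)
  if (levels < 2L) stopf("levels must be >= 2, got %d", levels)
  stride <- 2L^(levels - 1L)
  if (any(input_size %% stride != 0L))
    stopf("input_size %dx%d must be divisible by 2^(levels-1) = %d",
          input_size[1], input_size[2], stride)
  structure(list(backbone = backbone, levels = levels,
                 base_channels = as.integer(base_channels),
                 deep_supervision = isTRUE(deep_supervision),
                 attention = isTRUE(attention),
                 input_size = as.integer(input_size),
                 attention_reduction = as.integer(attention_reduction)),
            class = "model_config")
}

# Nodes of the nested grid in forward (topological) order.
segnet_nodes <- function(levels) {
  nodes <- list()
  for (i in seq_len(levels) - 1L) nodes[[length(nodes) + 1L]] <- c(i, 0L)
  for (j in seq_len(levels - 1L))
    for (i in 0L:(levels - 1L - j)) nodes[[length(nodes) + 1L]] <- c(i, j)
  nodes
}

node_name <- function(i, j) sprintf("X%d.%d", i, j)

he_conv <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

#' Build the nested-skip attention segmentation network
#'
#' @param config A [model_config()].
#' @param seed Integer seed for parameter initialisation; the same config and
#'   seed always yield bit-identical parameters.
#' @return A `segnet` object holding the config and a flat named parameter
#'   list.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  L <- config$levels
  ch <- config$base_channels * 2L^(0:(L - 1L))
  params <- list()
  with_seed(seed, {
    for (nd in segnet_nodes(L)) {
      i <- nd[1]; j <- nd[2]
      cin <- if (j == 0L) { if (i == 0L) 3L else ch[i] } else (j + 1L) * ch[i + 1L]
      cout <- ch[i + 1L]
      p <- node_name(i, j)
      params[[paste0(p, ".conv1.w")]] <- he_conv(3L, cin, cout)
      params[[paste0(p, ".conv1.b")]] <- numeric(cout)
      params[[paste0(p, ".in1.g")]] <- rep(1, cout)
      params[[paste0(p, ".in1.b")]] <- numeric(cout)
      params[[paste0(p, ".conv2.w")]] <- he_conv(3L, cout, cout)
      params[[paste0(p, ".conv2.b")]] <- numeric(cout)
      params[[paste0(p, ".in2.g")]] <- rep(1, cout)
      params[[paste0(p, ".in2.b")]] <- numeric(cout)
      if (config$attention) {
        hid <- max(1L, cout %/% config$attention_reduction)
        params[[paste0(p, ".ca.w1")]] <-
          matrix(rnorm(hid * cout, sd = sqrt(2 / cout)), hid, cout)
        params[[paste0(p, ".ca.b1")]] <- numeric(hid)
        params[[paste0(p, ".ca.w2")]] <-
          matrix(rnorm(cout * hid, sd = sqrt(2 / hid)), cout, hid)
        params[[paste0(p, ".ca.b2")]] <- numeric(cout)
        params[[paste0(p, ".sa.w")]] <- he_conv(7L, 2L, 1L)
        params[[paste0(p, ".sa.b")]] <- numeric(1L)
      }
      if (j >= 1L) {
        params[[paste0(p, ".up.w")]] <-
          array(rnorm(4L * ch[i + 2L] * ch[i + 1L], sd = sqrt(2 / (4 * ch[i + 2L]))),
                dim = c(2L, 2L, ch[i + 2L], ch[i + 1L]))
        params[[paste0(p, ".up.b")]] <- numeric(ch[i + 1L])
      }
    }
    n_heads <- if (config$deep_supervision) L - 1L else 1L
    for (j in seq_len(n_heads)) {
      params[[sprintf("head%d.w", j)]] <- he_conv(1L, ch[1], 1L)
      params[[sprintf("head%d.b", j)]] <- numeric(1L)
    }
  })
  structure(list(config = config, params = params, seed = as.integer(seed)),
            class = "segnet")
}

#' Total number of scalar parameters of a network
#' @param net A `segnet` (or any flat parameter list).
#' @return Integer parameter count.
#' @export
count_parameters <- function(net) {
  p <- if (inherits(net, "segnet")) net$params else net
  sum(vapply(p, length, integer(1)))
}

sigmoid <- function(x) plogis(x)

## ---- attention blocks -------------------------------------------------------

# Expand an HW x B map to the (p, c, b) vector layout of a full tensor.
expand_channels <- function(v, HW, C, B) {
  m <- matrix(v, HW, B)
  as.vector(m[, rep(seq_len(B), each = C), drop = FALSE])
}

ca_fwd <- function(h, W1, b1, W2, b2) {
  d <- dim(h); HW <- d[1] * d[2]; C <- d[3]; B <- d[4]
  A <- matrix(.colMeans(h, HW, C * B), C, B)
  cm <- colmax_idx(h, HW)
  Mx <- matrix(cm$max, C, B)
  # linear index of each column's argmax pixel, for the backward scatter
  amax_lin <- (seq_len(C * B) - 1L) * HW + cm$idx
  ha <- pmax(W1 %*% A + b1, 0)
  hm <- pmax(W1 %*% Mx + b1, 0)
  att <- sigmoid(W2 %*% ha + b2 + W2 %*% hm + b2)
  out <- as.vector(h) * rep(as.vector(att), each = HW)
  dim(out) <- d
  list(out = out, cache = list(h = h, A = A, Mx = Mx, amax_lin = amax_lin,
                               ha = ha, hm = hm, att = att, HW = HW,
                               C = C, B = B))
}

ca_bwd <- function(dout, cache, W1, W2) {
  HW <- cache$HW; C <- cache$C; B <- cache$B
  dh <- as.vector(dout) * rep(as.vector(cache$att), each = HW)
  datt <- matrix(.colSums(as.vector(dout) * as.vector(cache$h), HW, C * B),
                 C, B)
  ds <- datt * cache$att * (1 - cache$att)
  dW2 <- ds %*% t(cache$ha) + ds %*% t(cache$hm)
  db2 <- 2 * rowSums(ds)
  dha <- t(W2) %*% ds; dhm <- t(W2) %*% ds
  dza <- dha * (cache$ha > 0); dzm <- dhm * (cache$hm > 0)
  dW1 <- dza %*% t(cache$A) + dzm %*% t(cache$Mx)
  db1 <- rowSums(dza) + rowSums(dzm)
  dA <- t(W1) %*% dza; dMx <- t(W1) %*% dzm
  dh <- dh + rep(as.vector(dA) / HW, each = HW)
  dh[cache$amax_lin] <- dh[cache$amax_lin] + as.vector(dMx)
  dim(dh) <- dim(dout)
  list(dh = dh, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

sa_fwd <- function(h, saw, sab) {
  d <- dim(h); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]; HW <- H * W
  st <- ch_stats(h)
  sin <- array(0, c(H, W, 2L, B))
  sin[, , 1L, ] <- array(st$mean, c(H, W, B))
  sin[, , 2L, ] <- array(st$max, c(H, W, B))
  s <- sigmoid(conv2d_fwd(sin, saw, sab))            # H x W x 1 x B
  sv <- as.vector(s)
  out <- as.vector(h) * expand_channels(sv, HW, C, B)
  dim(out) <- d
  list(out = out, cache = list(h = h, sin = sin, sv = sv, amax = st$amax,
                               H = H, W = W, C = C, B = B))
}

sa_bwd <- function(dout, cache, saw) {
  H <- cache$H; W <- cache$W; C <- cache$C; B <- cache$B; HW <- H * W
  dh <- as.vector(dout) * expand_channels(cache$sv, HW, C, B)
  ds <- ch_dot(dout, cache$h)                        # HW * B
  dslog <- ds * cache$sv * (1 - cache$sv)
  dim(dslog) <- c(H, W, 1L, B)
  g <- conv2d_bwd(cache$sin, saw, dslog)
  dmean <- as.vector(g$dx[, , 1L, , drop = FALSE])
  dmax <- as.vector(g$dx[, , 2L, , drop = FALSE])
  dh <- dh + expand_channels(dmean / C, HW, C, B)
  dh[cache$amax] <- dh[cache$amax] + dmax
  dim(dh) <- dim(dout)
  list(dh = dh, dsaw = g$dw, dsab = g$db)
}
## ---- conv block -------------------------------------------------------------

INSTNORM_EPS <- 1e-5

block_fwd <- function(params, prefix, x, attention) {
  z1 <- conv2d_fwd(x, params[[paste0(prefix, ".conv1.w")]],
                   params[[paste0(prefix, ".conv1.b")]])
  n1 <- instnorm_fwd(z1, params[[paste0(prefix, ".in1.g")]],
                     params[[paste0(prefix, ".in1.b")]], INSTNORM_EPS)
  h1 <- pmax(n1$y, 0)
  z2 <- conv2d_fwd(h1, params[[paste0(prefix, ".conv2.w")]],
                   params[[paste0(prefix, ".conv2.b")]])
  n2 <- instnorm_fwd(z2, params[[paste0(prefix, ".in2.g")]],
                     params[[paste0(prefix, ".in2.b")]], INSTNORM_EPS)
  h2 <- pmax(n2$y, 0)
  cache <- list(x = x, xhat1 = n1$xhat, istd1 = n1$istd, m1 = n1$y > 0,
                h1 = h1, xhat2 = n2$xhat, istd2 = n2$istd, m2 = n2$y > 0,
                h2 = h2)
  out <- h2
  if (attention) {
    ca <- ca_fwd(h2, params[[paste0(prefix, ".ca.w1")]],
                 params[[paste0(prefix, ".ca.b1")]],
                 params[[paste0(prefix, ".ca.w2")]],
                 params[[paste0(prefix, ".ca.b2")]])
    sa <- sa_fwd(ca$out, params[[paste0(prefix, ".sa.w")]],
                 params[[paste0(prefix, ".sa.b")]])
    cache$ca <- ca$cache
    cache$sa <- sa$cache
    out <- sa$out
  }
  list(out = out, cache = cache)
}

block_bwd <- function(params, prefix, dout, cache, attention, grads) {
  if (attention) {
    sb <- sa_bwd(dout, cache$sa, params[[paste0(prefix, ".sa.w")]])
    grads[[paste0(prefix, ".sa.w")]] <- grads[[paste0(prefix, ".sa.w")]] %+0% sb$dsaw
    grads[[paste0(prefix, ".sa.b")]] <- grads[[paste0(prefix, ".sa.b")]] %+0% sb$dsab
    cb <- ca_bwd(sb$dh, cache$ca, params[[paste0(prefix, ".ca.w1")]],
                 params[[paste0(prefix, ".ca.w2")]])
    grads[[paste0(prefix, ".ca.w1")]] <- grads[[paste0(prefix, ".ca.w1")]] %+0% cb$dW1
    grads[[paste0(prefix, ".ca.b1")]] <- grads[[paste0(prefix, ".ca.b1")]] %+0% cb$db1
    grads[[paste0(prefix, ".ca.w2")]] <- grads[[paste0(prefix, ".ca.w2")]] %+0% cb$dW2
    grads[[paste0(prefix, ".ca.b2")]] <- grads[[paste0(prefix, ".ca.b2")]] %+0% cb$db2
    dout <- cb$dh
  }
  dn2 <- dout * cache$m2
  nb2 <- instnorm_bwd(cache$xhat2, cache$istd2,
                      params[[paste0(prefix, ".in2.g")]], dn2)
  grads[[paste0(prefix, ".in2.g")]] <- grads[[paste0(prefix, ".in2.g")]] %+0% nb2$dg
  grads[[paste0(prefix, ".in2.b")]] <- grads[[paste0(prefix, ".in2.b")]] %+0% nb2$db
  g2 <- conv2d_bwd(cache$h1, params[[paste0(prefix, ".conv2.w")]], nb2$dx)
  grads[[paste0(prefix, ".conv2.w")]] <- grads[[paste0(prefix, ".conv2.w")]] %+0% g2$dw
  grads[[paste0(prefix, ".conv2.b")]] <- grads[[paste0(prefix, ".conv2.b")]] %+0% g2$db
  dn1 <- g2$dx * cache$m1
  nb1 <- instnorm_bwd(cache$xhat1, cache$istd1,
                      params[[paste0(prefix, ".in1.g")]], dn1)
  grads[[paste0(prefix, ".in1.g")]] <- grads[[paste0(prefix, ".in1.g")]] %+0% nb1$dg
  grads[[paste0(prefix, ".in1.b")]] <- grads[[paste0(prefix, ".in1.b")]] %+0% nb1$db
  g1 <- conv2d_bwd(cache$x, params[[paste0(prefix, ".conv1.w")]], nb1$dx)
  grads[[paste0(prefix, ".conv1.w")]] <- grads[[paste0(prefix, ".conv1.w")]] %+0% g1$dw
  grads[[paste0(prefix, ".conv1.b")]] <- grads[[paste0(prefix, ".conv1.b")]] %+0% g1$db
  list(dx = g1$dx, grads = grads)
}

`%+0%` <- function(a, b) if (is.null(a)) b else a + b

## ---- full network -----------------------------------------------------------

segnet_forward <- function(net, x, want_cache = FALSE) {
  cfg <- net$config
  p <- net$params
  L <- cfg$levels
  d <- dim(x)
  if (length(d) != 4L) stopf("segnet_forward expects an H x W x C x B array")
  if (d[3] != 3L) stopf("expected 3 input channels, got %d", d[3])
  if (d[1] != cfg$input_size[1] || d[2] != cfg$input_size[2])
    stopf("batch is %dx%d but the model was built for %dx%d",
          d[1], d[2], cfg$input_size[1], cfg$input_size[2])
  outs <- list(); caches <- list(); pools <- list()
  for (i in seq_len(L) - 1L) {
    nm <- node_name(i, 0L)
    if (i == 0L) inp <- x
    else {
      mp <- maxpool2_fwd(outs[[node_name(i - 1L, 0L)]])
      pools[[nm]] <- mp$idx
      inp <- mp$y
    }
    bf <- block_fwd(p, nm, inp, cfg$attention)
    outs[[nm]] <- bf$out
    caches[[nm]] <- bf$cache
  }
  for (j in seq_len(L - 1L)) {
    for (i in 0L:(L - 1L - j)) {
      nm <- node_name(i, j)
      below <- outs[[node_name(i + 1L, j - 1L)]]
      up <- upconv2_fwd(below, p[[paste0(nm, ".up.w")]], p[[paste0(nm, ".up.b")]])
      parts <- lapply(0L:(j - 1L), function(jj) outs[[node_name(i, jj)]])
      parts[[length(parts) + 1L]] <- up
      cin <- sum(vapply(parts, function(a) dim(a)[3], numeric(1)))
      dd <- dim(up)
      inp <- array(0, c(dd[1], dd[2], cin, dd[4]))
      off <- 0L
      for (pt in parts) {
        nc <- dim(pt)[3]
        inp[, , (off + 1L):(off + nc), ] <- pt
        off <- off + nc
      }
      bf <- block_fwd(p, nm, inp, cfg$attention)
      outs[[nm]] <- bf$out
      caches[[nm]] <- bf$cache
    }
  }
  n_heads <- if (cfg$deep_supervision) L - 1L else 1L
  heads <- vector("list", n_heads)
  head_src <- character(n_heads)
  for (j in seq_len(n_heads)) {
    src <- node_name(0L, if (cfg$deep_supervision) j else L - 1L)
    head_src[j] <- src
    logit <- conv2d_fwd(outs[[src]], p[[sprintf("head%d.w", j)]],
                        p[[sprintf("head%d.b", j)]])
    heads[[j]] <- sigmoid(logit)
  }
  fused <- Reduce(`+`, heads) / n_heads
  res <- list(fused = fused, heads = heads)
  if (want_cache)
    res$cache <- list(outs = outs, caches = caches, pools = pools,
                      head_src = head_src, x = x)
  res
}

# Backpropagate d(loss)/d(fused) through the whole grid; returns the flat
# gradient list aligned with net$params.
segnet_backward <- function(net, fwd, dfused) {
  cfg <- net$config
  p <- net$params
  L <- cfg$levels
  cache <- fwd$cache
  heads <- fwd$heads
  K <- length(heads)
  grads <- list()
  nodegrad <- list()
  for (j in seq_len(K)) {
    s <- heads[[j]]
    dlogit <- (dfused / K) * s * (1 - s)
    src <- cache$head_src[j]
    g <- conv2d_bwd(cache$outs[[src]], p[[sprintf("head%d.w", j)]], dlogit)
    grads[[sprintf("head%d.w", j)]] <- grads[[sprintf("head%d.w", j)]] %+0% g$dw
    grads[[sprintf("head%d.b", j)]] <- grads[[sprintf("head%d.b", j)]] %+0% g$db
    nodegrad[[src]] <- nodegrad[[src]] %+0% g$dx
  }
  nodes <- segnet_nodes(L)
  for (k in rev(seq_along(nodes))) {
    i <- nodes[[k]][1]; j <- nodes[[k]][2]
    nm <- node_name(i, j)
    dout <- nodegrad[[nm]]
    if (is.null(dout)) next
    bb <- block_bwd(p, nm, dout, cache$caches[[nm]], cfg$attention, grads)
    grads <- bb$grads
    dinp <- bb$dx
    if (j == 0L) {
      if (i > 0L) {
        prev <- node_name(i - 1L, 0L)
        dprev <- maxpool2_bwd(cache$pools[[nm]], dinp,
                              dim(cache$outs[[prev]])[1],
                              dim(cache$outs[[prev]])[2])
        nodegrad[[prev]] <- nodegrad[[prev]] %+0% dprev
      }
    } else {
      chn <- dim(cache$outs[[node_name(i, 0L)]])[3]
      off <- 0L
      for (jj in 0L:(j - 1L)) {
        seg <- dinp[, , (off + 1L):(off + chn), , drop = FALSE]
        nodegrad[[node_name(i, jj)]] <- nodegrad[[node_name(i, jj)]] %+0% seg
        off <- off + chn
      }
      dup <- dinp[, , (off + 1L):(off + chn), , drop = FALSE]
      below <- node_name(i + 1L, j - 1L)
      ub <- upconv2_bwd(cache$outs[[below]], p[[paste0(nm, ".up.w")]], dup)
      grads[[paste0(nm, ".up.w")]] <- grads[[paste0(nm, ".up.w")]] %+0% ub$dw
      grads[[paste0(nm, ".up.b")]] <- grads[[paste0(nm, ".up.b")]] %+0% ub$db
      nodegrad[[below]] <- nodegrad[[below]] %+0% ub$dx
    }
  }
  grads
}

#' Run the network on a batch of images
#'
#' Inference is deterministic: the model has no stochastic layers.
#'
#' @param object A `segnet`.
#' @param batch An `H x W x 3 x B` array (or a single `H x W x 3` image) with
#'   values in `[0, 1]`.
#' @param ... Unused.
#' @return A list with `fused` (`H x W x B` probability array, the mean of the
#'   supervision heads) and `heads` (list of `H x W x B` per-head probability
#'   arrays).
#' @export
predict.segnet <- function(object, batch, ...) {
  batch <- as_batch(batch)
  fw <- segnet_forward(object, batch)
  squeeze <- function(a) { d <- dim(a); array(a, c(d[1], d[2], d[4])) }
  list(fused = squeeze(fw$fused), heads = lapply(fw$heads, squeeze))
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores student parameters, the teacher shadow state and the
#' model config, so evaluation can be reproduced from the file alone.
#'
#' @param net Student `segnet`.
#' @param teacher A `teacher_state` (or `NULL`).
#' @param path File path.
#' @param extra Optional named list stored verbatim.
#' @export
save_checkpoint <- function(net, teacher, path, extra = list()) {
  saveRDS(list(config = net$config, params = net$params, seed = net$seed,
               teacher = teacher, extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns a list with `net` (student),
#'   `teacher`, and `extra`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("checkpoint not found: %s", path)
  ck <- tryCatch(readRDS(path), error = function(e)
    stopf("unreadable checkpoint %s: %s", path, conditionMessage(e)))
  if (is.null(ck$config) || is.null(ck$params))
    stopf("corrupt checkpoint %s: missing config or params", path)
  net <- structure(list(config = ck$config, params = ck$params,
                        seed = ck$seed), class = "segnet")
  list(net = net, teacher = ck$teacher, extra = ck$extra)
}
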