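# Reverse-mode tape over the fixed network graph. Each forward op pushes its
# value and a backward closure; tape_backward walks the ops in reverse,
# accumulating gradients at shared nodes (the skip connections). Parameter
# gradients are accumulated into a separate environment keyed by name.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list()
  tp$ops <- list()
  tp$n <- 0L
  tp
}

tp_push <- function(tp, val, parents = integer(0), bwd = NULL) {
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- val
  tp$ops[[tp$n]] <- list(parents = parents, bwd = bwd)
  tp$n
}

tape_backward <- function(tp, out_id, gout) {
  grads <- vector("list", tp$n)
  grads[[out_id]] <- gout
  for (id in seq(tp$n, 1L)) {
    g <- grads[[id]]
    op <- tp$ops[[id]]
    if (is.null(g) || is.null(op$bwd)) next
    pg <- op$bwd(g)
    for (j in seq_along(op$parents)) {
      p <- op$parents[j]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
    grads[[id]] <- NULL   # free memory as we go
  }
  invisible(NULL)
}

gacc_add <- function(gacc, name, g) {
  gacc[[name]] <- if (is.null(gacc[[name]])) g else gacc[[name]] + g
}

as_c3 <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

# standard convolution; W has dim (kh, kw, cin, cout)
l_conv <- function(tp, gacc, x_id, params, name, stride = 1L, pad = 1L) {
  force(x_id)   # evaluate before touching tp: pushing layers mutates the tape
  W <- params[[paste0(name, ".W")]]
  b <- params[[paste0(name, ".b")]]
  d <- dim(W)
  cin <- d[3]; cout <- d[4]
  wflat <- array(W, dim = c(d[1], d[2], cin * cout))
  x <- tp$vals[[x_id]]
  y <- conv2d_fwd(x, wflat, b, cin, cout, stride, pad)
  tp_push(tp, y, parents = x_id, bwd = function(g) {
    r <- conv2d_bwd(x, wflat, g, cin, cout, stride, pad)
    gacc_add(gacc, paste0(name, ".W"), array(r$gw, dim = d))
    gacc_add(gacc, paste0(name, ".b"), as.numeric(r$gb))
    list(r$gx)
  })
}

# depthwise convolution; W has dim (kh, kw, C)
l_dwconv <- function(tp, gacc, x_id, params, name, stride = 1L, pad = 1L) {
  force(x_id)
  W <- params[[paste0(name, ".W")]]
  b <- params[[paste0(name, ".b")]]
  x <- tp$vals[[x_id]]
  y <- dwconv2d_fwd(x, W, b, stride, pad)
  tp_push(tp, y, parents = x_id, bwd = function(g) {
    r <- dwconv2d_bwd(x, W, g, stride, pad)
    gacc_add(gacc, paste0(name, ".W"), array(r$gw, dim = dim(W)))
    gacc_add(gacc, paste0(name, ".b"), as.numeric(r$gb))
    list(r$gx)
  })
}

l_relu <- function(tp, x_id) {
  force(x_id)
  x <- tp$vals[[x_id]]
  y <- pmax(x, 0)
  tp_push(tp, y, parents = x_id, bwd = function(g) list(g * (x > 0)))
}

l_up2 <- function(tp, x_id) {
  force(x_id)
  x <- tp$vals[[x_id]]
  y <- upsample2_fwd(x)
  d <- dim(x)
  tp_push(tp, y, parents = x_id,
          bwd = function(g) list(upsample2_bwd(g, d[1], d[2])))
}

l_concat <- function(tp, a_id, b_id) {
  force(a_id); force(b_id)
  a <- tp$vals[[a_id]]
  b <- tp$vals[[b_id]]
  da <- dim(a); db <- dim(b)
  y <- array(c(a, b), dim = c(da[1], da[2], da[3] + db[3]))
  tp_push(tp, y, parents = c(a_id, b_id), bwd = function(g) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

# squeeze-and-excitation: global-average squeeze -> bottleneck (ReLU) ->
# logistic gate -> per-channel rescale
l_se <- function(tp, gacc, x_id, params, name) {
  force(x_id)
  W1 <- params[[paste0(name, ".W1")]]
  b1 <- params[[paste0(name, ".b1")]]
  W2 <- params[[paste0(name, ".W2")]]
  b2 <- params[[paste0(name, ".b2")]]
  x <- tp$vals[[x_id]]
  d <- dim(x)
  npix <- d[1] * d[2]
  z <- apply(x, 3, mean)
  u1 <- as.numeric(W1 %*% z + b1)
  h <- pmax(u1, 0)
  u2 <- as.numeric(W2 %*% h + b2)
  s <- 1 / (1 + exp(-u2))
  y <- x * rep(s, each = npix)
  tp_push(tp, y, parents = x_id, bwd = function(g) {
    gs <- vapply(seq_len(d[3]),
                 function(c) sum(g[, , c] * x[, , c]), numeric(1))
    gu2 <- gs * s * (1 - s)
    gacc_add(gacc, paste0(name, ".W2"), gu2 %o% h)
    gacc_add(gacc, paste0(name, ".b2"), gu2)
    gh <- as.numeric(t(W2) %*% gu2)
    gu1 <- gh * (u1 > 0)
    gacc_add(gacc, paste0(name, ".W1"), gu1 %o% z)
    gacc_add(gacc, paste0(name, ".b1"), gu1)
    gz <- as.numeric(t(W1) %*% gu1)
    gx <- g * rep(s, each = npix) +
      array(rep(gz / npix, each = npix), dim = d)
    list(gx)
  })
}

# numerically stable softmax over the channel dimension of an H x W x C array
softmax_channels <- function(logits) {
  d <- dim(logits)
  mx <- logits[, , 1]
  for (c in seq_len(d[3])[-1]) mx <- pmax(mx, logits[, , c])
  e <- exp(logits - array(rep(mx, d[3]), dim = d))
  tot <- e[, , 1]
  for (c in seq_len(d[3])[-1]) tot <- tot + e[, , c]
  e / array(rep(tot, d[3]), dim = d)
}

# mean per-pixel categorical cross-entropy; labels is an H x W matrix of
# class indices starting at 0. Returns loss and d loss / d logits.
softmax_ce <- function(logits, labels) {
  d <- dim(logits)
  p <- softmax_channels(logits)
  npix <- d[1] * d[2]
  onehot <- array(0, dim = d)
  for (c in seq_len(d[3])) onehot[, , c] <- (labels == c - 1L)
  picked <- pmax(apply(p * onehot, c(1, 2), sum), 1e-12)
  list(loss = -mean(log(picked)), grad = (p - onehot) / npix, prob = p)
}
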