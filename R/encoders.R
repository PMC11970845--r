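# Per-instance encoders: images in, one embedding row per instance out.
# The shipped default is a small convolutional network (input downsampling,
# two 3x3 convolution stages with average pooling, global average pooling,
# one linear layer) trained end to end with the aggregator. An "identity"
# spec passes precomputed embedding vectors through unchanged, and an
# "external" spec wraps any user function.

#' Encoder specification
#'
#' @param name `"tiny_cnn"`, `"identity"` or `"external"`.
#' @param out_dim Embedding width d_E produced by the encoder.
#' @param projection_dim Aggregator width d the embeddings are projected to;
#'   a linear projection is inserted by [set_model()] whenever
#'   `out_dim != projection_dim`.
#' @param channels Image channels (tiny_cnn).
#' @param input_size Spatial side length of the (square) input images.
#' @param fn For `"external"`: a function mapping a list of images to an
#'   M x `out_dim` matrix.
#' @return An `encoder_spec` object.
#' @export
encoder_spec <- function(name = c("tiny_cnn", "identity", "external"),
                         out_dim = 64L, projection_dim = out_dim,
                         channels = 3L, input_size = 64L, fn = NULL) {
  name <- match.arg(name)
  if (out_dim < 1) stop("out_dim must be >= 1")
  if (name == "external" && !is.function(fn)) {
    stop("an external encoder needs a function `fn`")
  }
  structure(list(name = name, out_dim = as.integer(out_dim),
                 projection_dim = as.integer(projection_dim),
                 channels = as.integer(channels),
                 input_size = as.integer(input_size), fn = fn),
            class = "encoder_spec")
}

# tiny CNN geometry: input s x s x C -> fixed 4x avg-pool -> conv3x3(16) ->
# relu -> 2x avg-pool -> conv3x3(32) -> relu -> global avg pool -> linear.
TINY_F1 <- 16L
TINY_F2 <- 32L

encoder_init <- function(spec) {
  switch(spec$name,
    identity = list(),
    external = list(),
    tiny_cnn = {
      c1_in <- 9L * spec$channels
      c2_in <- 9L * TINY_F1
      list(conv1 = list(W = kaiming_matrix(c1_in, TINY_F1, fan_in = c1_in),
                        b = numeric(TINY_F1)),
           conv2 = list(W = kaiming_matrix(c2_in, TINY_F2, fan_in = c2_in),
                        b = numeric(TINY_F2)),
           fc = linear_init(TINY_F2, spec$out_dim))
    })
}

# ---------------------------------------------------------------------------
# batched array helpers (arrays are H x W x C x M, column-major)
# ---------------------------------------------------------------------------

stack_images <- function(images) {
  dims <- lapply(images, dim)
  d1 <- dims[[1]]
  if (length(d1) == 2) d1 <- c(d1, 1L)
  same <- vapply(dims, function(d) {
    if (length(d) == 2) d <- c(d, 1L)
    identical(as.integer(d), as.integer(d1))
  }, logical(1))
  if (!all(same)) stop("all images in a batch must have the same size")
  array(unlist(images, use.names = FALSE), c(d1, length(images)))
}

avg_pool_batch <- function(A, f) {
  d <- dim(A) # H W C M
  x <- A
  dim(x) <- c(f, d[1] / f, d[2], d[3], d[4])
  x <- colMeans(x, dims = 1)          # H/f, W, C, M
  x <- aperm(x, c(2, 1, 3, 4))        # W, H/f, C, M
  dim(x) <- c(f, d[2] / f, d[1] / f, d[3], d[4])
  x <- colMeans(x, dims = 1)          # W/f, H/f, C, M
  aperm(x, c(2, 1, 3, 4))             # H/f, W/f, C, M
}

# The CNN works on a flat layout: a feature map over M images is one matrix
# of (H*W*M) rows (pixel fastest, then image) by C columns. Convolutions are
# im2col + one GEMM; pooling gathers/scatters precomputed row indices. Index
# tables depend only on (H, W, M) and are cached.
.cnn_idx_cache <- new.env(parent = emptyenv())

conv3_rows <- function(H, W, M) {
  key <- paste("c", H, W, M, sep = "x")
  if (!is.null(.cnn_idx_cache[[key]])) return(.cnn_idx_cache[[key]])
  Hp <- H + 2L
  i <- rep(seq_len(H), W)
  j <- rep(seq_len(W), each = H)
  unpad1 <- (i + 1L) + j * Hp             # row of pixel (i, j) in padded plane
  per <- Hp * (W + 2L)
  off <- rep.int((seq_len(M) - 1L) * per, rep.int(H * W, M))
  unpad <- rep.int(unpad1, M) + off
  ri <- vector("list", 9L)
  k <- 0L
  for (dj in 0:2) {
    for (di in 0:2) {
      k <- k + 1L
      ri[[k]] <- rep.int((i + di) + (j + dj - 1L) * Hp, M) + off
    }
  }
  out <- list(unpad = unpad, ri = ri, pad_rows = per * M)
  .cnn_idx_cache[[key]] <- out
  out
}

# X: (H*W*M) x C; weight rows ordered (offset k, then channel): (k-1)*C + c
conv3_fwd <- function(X, H, W, M, p) {
  C <- ncol(X)
  ix <- conv3_rows(H, W, M)
  P <- matrix(0, ix$pad_rows, C)
  P[ix$unpad, ] <- X
  Xcol <- matrix(0, nrow(X), 9L * C)
  for (k in 1:9) Xcol[, ((k - 1L) * C + 1L):(k * C)] <- P[ix$ri[[k]], ]
  Out <- Xcol %*% p$W + rep(p$b, each = nrow(X))
  list(out = Out, Xcol = Xcol, ix = ix, C = C)
}

conv3_bwd <- function(cache, p, dOut, want_dx = TRUE) {
  grads <- list(W = crossprod(cache$Xcol, dOut), b = colSums(dOut))
  dX <- NULL
  if (want_dx) {
    dXcol <- dOut %*% t(p$W)
    C <- cache$C
    dP <- matrix(0, cache$ix$pad_rows, C)
    for (k in 1:9) {
      ii <- cache$ix$ri[[k]]
      dP[ii, ] <- dP[ii, ] + dXcol[, ((k - 1L) * C + 1L):(k * C)]
    }
    dX <- dP[cache$ix$unpad, , drop = FALSE]
  }
  list(grads = grads, dX = dX)
}

pool2_rows <- function(H, W, M) {
  key <- paste("p", H, W, M, sep = "x")
  if (!is.null(.cnn_idx_cache[[key]])) return(.cnn_idx_cache[[key]])
  h <- H %/% 2L
  w <- W %/% 2L
  i <- rep(seq_len(h), w)
  j <- rep(seq_len(w), each = h)
  off <- rep.int((seq_len(M) - 1L) * H * W, rep.int(h * w, M))
  at <- function(di, dj) {
    rep.int((2L * i - 1L + di) + (2L * j - 2L + dj) * H, M) + off
  }
  out <- list(i11 = at(0L, 0L), i21 = at(1L, 0L), i12 = at(0L, 1L),
              i22 = at(1L, 1L))
  .cnn_idx_cache[[key]] <- out
  out
}

pool2_fwd <- function(X, H, W, M) {
  ix <- pool2_rows(H, W, M)
  (X[ix$i11, , drop = FALSE] + X[ix$i21, , drop = FALSE] +
     X[ix$i12, , drop = FALSE] + X[ix$i22, , drop = FALSE]) / 4
}

pool2_bwd <- function(dP, H, W, M) {
  ix <- pool2_rows(H, W, M)
  dX <- matrix(0, H * W * M, ncol(dP))
  q <- dP / 4
  dX[ix$i11, ] <- q
  dX[ix$i21, ] <- q
  dX[ix$i12, ] <- q
  dX[ix$i22, ] <- q
  dX
}

tiny_cnn_fwd <- function(A, params) {
  d <- dim(A) # H W C M
  M <- d[4]
  s1 <- d[1] %/% 4L
  x0a <- avg_pool_batch(A, 4L)                    # s/4, array (fixed, no grad)
  x0 <- aperm(x0a, c(1, 2, 4, 3))
  dim(x0) <- c(s1 * s1 * M, d[3])
  c1 <- conv3_fwd(x0, s1, s1, M, params$conv1)
  r1 <- pmax(c1$out, 0)
  s2 <- s1 %/% 2L
  x1 <- pool2_fwd(r1, s1, s1, M)                  # s/8
  c2 <- conv3_fwd(x1, s2, s2, M, params$conv2)
  r2 <- pmax(c2$out, 0)
  hw2 <- s2 * s2
  feat <- rowsum(r2, rep(seq_len(M), each = hw2)) / hw2 # M x F2 (global avg)
  E <- linear_fwd(feat, params$fc)
  list(E = E, cache = list(c1 = c1, m1 = c1$out > 0, c2 = c2,
                           m2 = c2$out > 0, feat = feat, M = M,
                           s1 = s1, s2 = s2))
}

tiny_cnn_bwd <- function(params, cache, dE) {
  fc <- linear_bwd(cache$feat, params$fc, dE)
  hw2 <- cache$s2^2
  dr2 <- fc$dx[rep(seq_len(cache$M), each = hw2), , drop = FALSE] / hw2
  dr2 <- dr2 * cache$m2
  b2 <- conv3_bwd(cache$c2, params$conv2, dr2, want_dx = TRUE)
  dr1 <- pool2_bwd(b2$dX, cache$s1, cache$s1, cache$M) * cache$m1
  b1 <- conv3_bwd(cache$c1, params$conv1, dr1, want_dx = FALSE)
  list(grads = list(conv1 = b1$grads, conv2 = b2$grads, fc = fc$grads))
}

encoder_fwd <- function(x, spec, params) {
  switch(spec$name,
    identity = {
      E <- if (is.list(x)) do.call(rbind, lapply(x, as.numeric)) else as.matrix(x)
      list(E = E, cache = NULL)
    },
    external = list(E = spec$fn(x), cache = NULL),
    tiny_cnn = {
      A <- if (is.list(x)) stack_images(x) else x
      if (length(dim(A)) == 3) dim(A) <- c(dim(A), 1L)
      tiny_cnn_fwd(A, params)
    })
}

encoder_bwd <- function(spec, params, fwd, dE) {
  switch(spec$name,
    identity = list(grads = list()),
    external = list(grads = list()),
    tiny_cnn = tiny_cnn_bwd(params, fwd$cache, dE))
}

#' Encode a set of instance images into embedding rows
#'
#' One embedding row per image, order-preserving; each row depends only on
#' its own image. The identity spec passes precomputed vectors through
#' unchanged.
#'
#' @param images List of H x W x C arrays (all the same size), or an M x d
#'   matrix for the identity spec.
#' @param spec An [encoder_spec()].
#' @param params Encoder parameters; drawn under `seed` when `NULL`.
#' @param seed Seed used only when `params` is `NULL`.
#' @return An M x `out_dim` numeric matrix.
#' @export
encode_instances <- function(images, spec, params = NULL, seed = 1L) {
  if (is.null(params)) params <- with_seed(seed, encoder_init(spec))
  f <- encoder_fwd(images, spec, params)
  if (!all(is.finite(f$E))) stop("encoder produced non-finite embeddings")
  f$E
}
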