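# Transformer-encoder classifier for multi-modal physiological windows:
# per-modality 1-D convolutional feature extractors, concatenation fusion,
# sinusoidal positional encoding, a stack of multi-head self-attention
# encoder layers, temporal pooling and a softmax head, trained with
# categorical cross-entropy. Forward and backward passes are implemented
# analytically (no autodiff framework); the backward pass is verified against
# finite differences in the test suite.

#' Model architecture configuration
#'
#' @param n_classes Number of affect classes C (2 for the binary tasks, 5 for
#'   valence/arousal).
#' @param modalities Channels the model consumes, a subset of
#'   `c("HR", "GSR", "ACCEL")` in that fixed order. Ablation runs instantiate
#'   only the named branches.
#' @param d_e Per-modality embedding width out of the feature extractor.
#' @param cnn_hidden Hidden channel width of the extractor's first
#'   convolution (default 128).
#' @param d_model Width of the fused representation fed to the encoder
#'   (default 512); the concatenated `length(modalities) * d_e` features are
#'   linearly projected to this width.
#' @param n_layers Number of encoder layers.
#' @param n_heads Number of attention heads h; `d_model` must divide evenly
#'   (per-head key width `d_k = d_model / n_heads`).
#' @param ffn_dim Hidden width of the position-wise feed-forward network.
#' @param dropout Dropout rate applied (during training only) to the input
#'   embedding, attention output and feed-forward output.
#' @param layernorm Apply post-norm layer normalisation around each residual
#'   (default). `FALSE` selects the strict residual form
#'   `H' = FFN(MultiHead(H)) + H` with no normalisation.
#' @param pool Temporal pooling to the classifier input: `"mean"` (default)
#'   or `"cls"` (learned classification token prepended to the sequence).
#' @param kernels,strides Kernel sizes and strides of the two extractor
#'   convolutions; the defaults (7/5, stride 2 each) give `T' = T / 4`.
#' @return A `model_config` list.
#' @export
model_config <- function(n_classes, modalities = c("HR", "GSR", "ACCEL"),
                         d_e = 128L, cnn_hidden = 128L, d_model = 512L,
                         n_layers = 2L, n_heads = 8L, ffn_dim = d_model,
                         dropout = 0.2, layernorm = TRUE,
                         pool = c("mean", "cls"),
                         kernels = c(7L, 5L), strides = c(2L, 2L)) {
  pool <- match.arg(pool)
  modalities <- match.arg(modalities, c("HR", "GSR", "ACCEL"),
                          several.ok = TRUE)
  modalities <- c("HR", "GSR", "ACCEL")[c("HR", "GSR", "ACCEL") %in% modalities]
  if (!is_count(n_classes) || n_classes < 2) stopf("n_classes must be >= 2")
  if (d_model %% n_heads != 0L) {
    stopf("d_model (%d) must be divisible by n_heads (%d)", d_model, n_heads)
  }
  if (d_model %% 2L != 0L) {
    stopf("d_model must be even (sin/cos positional-encoding pairing)")
  }
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1) {
    stopf("dropout must lie in [0, 1)")
  }
  structure(list(n_classes = as.integer(n_classes), modalities = modalities,
                 d_e = as.integer(d_e), cnn_hidden = as.integer(cnn_hidden),
                 d_model = as.integer(d_model), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 d_k = as.integer(d_model / n_heads),
                 ffn_dim = as.integer(ffn_dim), dropout = dropout,
                 layernorm = isTRUE(layernorm), pool = pool,
                 kernels = as.integer(kernels), strides = as.integer(strides)),
            class = "model_config")
}

# Uniform fan-in initialisation: U(-sqrt(1/fan_in), sqrt(1/fan_in)).
init_mat <- function(nr, nc) {
  lim <- sqrt(1 / nr)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise model parameters
#'
#' Weight matrices use uniform fan-in scaling, biases start at zero,
#' layer-norm gains at one. Draws come from the session RNG; seed it (or use
#' `seed`) for reproducible initialisation.
#'
#' @param config A [model_config()].
#' @param seed Optional seed for the initialisation draws.
#' @return Nested parameter list (class `model_params`).
#' @export
init_params <- function(config, seed = NULL) {
  build <- function() {
    k <- config$kernels
    extract <- lapply(config$modalities, function(m) {
      list(W1 = init_mat(k[1L] * 1L, config$cnn_hidden),
           b1 = numeric(config$cnn_hidden),
           W2 = init_mat(k[2L] * config$cnn_hidden, config$d_e),
           b2 = numeric(config$d_e))
    })
    names(extract) <- config$modalities
    layers <- lapply(seq_len(config$n_layers), function(l) {
      lp <- list(Wq = init_mat(config$d_model, config$d_model),
                 Wk = init_mat(config$d_model, config$d_model),
                 Wv = init_mat(config$d_model, config$d_model),
                 Wo = init_mat(config$d_model, config$d_model),
                 ff_W1 = init_mat(config$d_model, config$ffn_dim),
                 ff_b1 = numeric(config$ffn_dim),
                 ff_W2 = init_mat(config$ffn_dim, config$d_model),
                 ff_b2 = numeric(config$d_model))
      if (config$layernorm) {
        lp$ln1_g <- rep(1, config$d_model); lp$ln1_b <- numeric(config$d_model)
        lp$ln2_g <- rep(1, config$d_model); lp$ln2_b <- numeric(config$d_model)
      }
      lp
    })
    p <- list(extract = extract,
              fuse = list(W = init_mat(length(config$modalities) * config$d_e,
                                       config$d_model),
                          b = numeric(config$d_model)),
              layers = layers,
              out = list(W = init_mat(config$d_model, config$n_classes),
                         b = numeric(config$n_classes)))
    if (config$pool == "cls") p$cls_token <- init_mat(1L, config$d_model)
    structure(p, class = "model_params")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

# ---- building blocks -------------------------------------------------------

# im2col 1-D convolution. x: Tin x Cin; W: (k*Cin) x Cout, row order
# (tap-1)*Cin + cin; 'same'-style zero padding for output length
# ceiling(Tin / stride).
conv1d_forward <- function(x, W, b, k, stride) {
  Tin <- nrow(x); Cin <- ncol(x)
  out_len <- ceiling(Tin / stride)
  if (Tin < 1L) stopf("conv input is empty")
  pad_total <- max((out_len - 1L) * stride + k - Tin, 0L)
  pad_left <- pad_total %/% 2L
  t0 <- (seq_len(out_len) - 1L) * stride - pad_left          # 0-based starts
  tmat <- outer(t0, 0:(k - 1L), "+")                          # out_len x k
  valid_t <- tmat >= 0L & tmat <= Tin - 1L
  idx <- matrix(NA_integer_, out_len, k * Cin)
  valid <- matrix(FALSE, out_len, k * Cin)
  for (cin in seq_len(Cin)) {
    cols <- (seq_len(k) - 1L) * Cin + cin
    idx[, cols] <- (cin - 1L) * Tin + tmat + 1L
    valid[, cols] <- valid_t
  }
  X_col <- matrix(0, out_len, k * Cin)
  X_col[valid] <- x[idx[valid]]
  Z <- X_col %*% W
  Z <- Z + rep(b, each = out_len)
  list(out = Z, X_col = X_col, idx = idx, valid = valid,
       dims = c(Tin = Tin, Cin = Cin))
}

conv1d_backward <- function(dZ, W, cache) {
  dW <- crossprod(cache$X_col, dZ)
  db <- colSums(dZ)
  dXcol <- dZ %*% t(W)
  acc <- rowsum(dXcol[cache$valid], cache$idx[cache$valid])
  dx <- numeric(cache$dims[["Tin"]] * cache$dims[["Cin"]])
  dx[as.integer(rownames(acc))] <- acc
  list(dW = dW, db = db,
       dx = matrix(dx, cache$dims[["Tin"]], cache$dims[["Cin"]]))
}

#' Per-modality convolutional feature extraction
#'
#' Two strided 1-D convolutions with ReLU turn a length-T channel into a
#' `T' x d_e` temporal embedding (`T' = T / 4` at the default strides).
#'
#' @param x Numeric vector (one segment column) or `T x 1` matrix.
#' @param modality Which extractor branch to use.
#' @param config,params Model configuration and parameters.
#' @return `T' x d_e` embedding matrix.
#' @export
extract_features <- function(x, modality, config, params) {
  fw <- extractor_forward(as.matrix(x), params$extract[[modality]], config)
  fw$out
}

extractor_forward <- function(x, ep, config) {
  k <- config$kernels; s <- config$strides
  if (nrow(x) < k[1L]) {
    stopf("input length %d is shorter than the extractor's receptive field (%d)",
          nrow(x), k[1L])
  }
  c1 <- conv1d_forward(x, ep$W1, ep$b1, k[1L], s[1L])
  a1 <- pmax(c1$out, 0)
  c2 <- conv1d_forward(a1, ep$W2, ep$b2, k[2L], s[2L])
  a2 <- pmax(c2$out, 0)
  list(out = a2, c1 = c1, z1 = c1$out, c2 = c2, z2 = c2$out)
}

extractor_backward <- function(dE, ep, cache) {
  dz2 <- dE * (cache$z2 > 0)
  b2 <- conv1d_backward(dz2, ep$W2, cache$c2)
  dz1 <- b2$dx * (cache$z1 > 0)
  b1 <- conv1d_backward(dz1, ep$W1, cache$c1)
  list(grads = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db),
       dx = b1$dx)
}

#' Concatenation fusion of modality embeddings
#'
#' Joins per-modality embeddings along the feature axis in the fixed order
#' (HR, GSR, ACCEL): `E_concat = [E_HR; E_GSR; E_ACCEL]`, a `T' x (m * d_e)`
#' matrix for m modalities.
#'
#' @param ... Embedding matrices with equal row counts, or a single list of
#'   them.
#' @return The concatenated matrix.
#' @export
fuse_concat <- function(...) {
  es <- list(...)
  if (length(es) == 1L && is.list(es[[1L]]) && !is.matrix(es[[1L]])) {
    es <- es[[1L]]
  }
  rows <- vapply(es, nrow, integer(1))
  if (length(unique(rows)) != 1L) {
    stopf("embeddings disagree on T': %s", paste(rows, collapse = ", "))
  }
  do.call(cbind, es)
}

#' Sinusoidal positional encoding
#'
#' `P(i, 2j) = sin(i / 10000^(2j/d))`, `P(i, 2j+1) = cos(i / 10000^(2j/d))`
#' with 0-based time step i and dimension pair j; added to the fused
#' embeddings to give the encoder a notion of temporal order.
#'
#' @param n Number of time steps.
#' @param d Embedding width (must be even).
#' @return `n x d` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(n, d) {
  if (d %% 2L != 0L) stopf("positional encoding width d must be even")
  i <- 0:(n - 1L)
  j <- 0:(d / 2L - 1L)
  ang <- outer(i, 10000^(-2 * j / d))
  P <- matrix(0, n, d)
  P[, 2L * j + 1L] <- sin(ang)
  P[, 2L * j + 2L] <- cos(ang)
  P
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = Softmax(Q K^T / sqrt(d_k)) V`; each row of the
#' weight matrix is a probability distribution over key positions.
#'
#' @param Q,K,V Query, key and value matrices (`n_q x d_k`, `n_k x d_k`,
#'   `n_k x d_v`).
#' @return The `n_q x d_v` output; attribute `weights` holds the
#'   row-stochastic attention matrix.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  d_k <- ncol(K)
  if (is.null(d_k) || d_k <= 0L) stopf("d_k must be positive")
  A <- softmax_rows(tcrossprod(Q, K) / sqrt(d_k))
  structure(A %*% V, weights = A)
}

mha_forward <- function(H, lp, config) {
  Q <- H %*% lp$Wq; K <- H %*% lp$Wk; V <- H %*% lp$Wv
  h <- config$n_heads; dk <- config$d_k
  O <- matrix(0, nrow(H), config$d_model)
  heads <- vector("list", h)
  for (hi in seq_len(h)) {
    cols <- ((hi - 1L) * dk + 1L):(hi * dk)
    A <- softmax_rows(tcrossprod(Q[, cols, drop = FALSE],
                                 K[, cols, drop = FALSE]) / sqrt(dk))
    O[, cols] <- A %*% V[, cols, drop = FALSE]
    heads[[hi]] <- A
  }
  list(out = O %*% lp$Wo, Q = Q, K = K, V = V, O = O, heads = heads)
}

mha_backward <- function(dout, H, lp, config, cache) {
  h <- config$n_heads; dk <- config$d_k
  dWo <- crossprod(cache$O, dout)
  dO <- dout %*% t(lp$Wo)
  dQ <- matrix(0, nrow(H), config$d_model)
  dK <- dQ; dV <- dQ
  for (hi in seq_len(h)) {
    cols <- ((hi - 1L) * dk + 1L):(hi * dk)
    A <- cache$heads[[hi]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, cols] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dk)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(dk)
  }
  dH <- dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
  list(dH = dH,
       grads = list(Wq = crossprod(H, dQ), Wk = crossprod(H, dK),
                    Wv = crossprod(H, dV), Wo = dWo))
}

#' Multi-head self-attention
#'
#' Splits the model width into `n_heads` independent scaled dot-product
#' attention heads, concatenates their outputs and projects with `Wo`:
#' `MultiHead(H) = Concat(head_1, ..., head_h) Wo`.
#'
#' @param H `T' x d_model` input.
#' @param params List with projection matrices `Wq`, `Wk`, `Wv`, `Wo`
#'   (`d_model x d_model`).
#' @param n_heads Number of heads; must divide `d_model`.
#' @return `T' x d_model` output matrix.
#' @export
multi_head_attention <- function(H, params, n_heads = 1L) {
  d <- ncol(H)
  if (d %% n_heads != 0L) stopf("width %d not divisible by %d heads", d, n_heads)
  cfg <- list(n_heads = as.integer(n_heads), d_k = as.integer(d / n_heads),
              d_model = d)
  mha_forward(H, params, cfg)$out
}

layernorm_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  istd <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * istd
  list(out = t(t(xhat) * g + b), xhat = xhat, istd = istd)
}

layernorm_backward <- function(dout, g, cache) {
  xhat <- cache$xhat
  dxhat <- t(t(dout) * g)
  dx <- cache$istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dout * xhat), db = colSums(dout))
}

ffn_forward <- function(X, lp) {
  Z1 <- X %*% lp$ff_W1
  Z1 <- Z1 + rep(lp$ff_b1, each = nrow(X))
  A1 <- pmax(Z1, 0)
  out <- A1 %*% lp$ff_W2
  out <- out + rep(lp$ff_b2, each = nrow(X))
  list(out = out, Z1 = Z1, A1 = A1)
}

ffn_backward <- function(dout, X, lp, cache) {
  dA1 <- dout %*% t(lp$ff_W2)
  dZ1 <- dA1 * (cache$Z1 > 0)
  list(dX = dZ1 %*% t(lp$ff_W1),
       grads = list(ff_W1 = crossprod(X, dZ1), ff_b1 = colSums(dZ1),
                    ff_W2 = crossprod(cache$A1, dout), ff_b2 = colSums(dout)))
}

drop_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

encoder_layer_forward <- function(H, lp, config, training = FALSE) {
  rate <- if (training) config$dropout else 0
  att <- mha_forward(H, lp, config)
  mA <- drop_mask(nrow(H), ncol(H), rate)
  A <- if (is.null(mA)) att$out else att$out * mA
  if (config$layernorm) {
    R1 <- H + A
    ln1 <- layernorm_forward(R1, lp$ln1_g, lp$ln1_b)
    ffn <- ffn_forward(ln1$out, lp)
    mF <- drop_mask(nrow(H), ncol(H), rate)
    Fv <- if (is.null(mF)) ffn$out else ffn$out * mF
    R2 <- ln1$out + Fv
    ln2 <- layernorm_forward(R2, lp$ln2_g, lp$ln2_b)
    out <- ln2$out
    cache <- list(att = att, mA = mA, ln1 = ln1, ln1_in = R1, ffn = ffn,
                  mF = mF, ln2 = ln2, ffn_in = ln1$out, H = H)
  } else {
    # strict residual form: H' = FFN(MultiHead(H)) + H
    ffn <- ffn_forward(A, lp)
    mF <- drop_mask(nrow(H), ncol(H), rate)
    Fv <- if (is.null(mF)) ffn$out else ffn$out * mF
    out <- Fv + H
    cache <- list(att = att, mA = mA, ffn = ffn, mF = mF, ffn_in = A, H = H)
  }
  list(out = out, cache = cache)
}

encoder_layer_backward <- function(dout, lp, config, cache) {
  g <- list()
  if (config$layernorm) {
    l2 <- layernorm_backward(dout, lp$ln2_g, cache$ln2)
    g$ln2_g <- l2$dg; g$ln2_b <- l2$db
    dFv <- l2$dx
    dF <- if (is.null(cache$mF)) dFv else dFv * cache$mF
    fb <- ffn_backward(dF, cache$ffn_in, lp, cache$ffn)
    g <- c(g, fb$grads)
    dH1 <- l2$dx + fb$dX
    l1 <- layernorm_backward(dH1, lp$ln1_g, cache$ln1)
    g$ln1_g <- l1$dg; g$ln1_b <- l1$db
    dA <- if (is.null(cache$mA)) l1$dx else l1$dx * cache$mA
    ab <- mha_backward(dA, cache$H, lp, config, cache$att)
    g <- c(g, ab$grads)
    dH <- l1$dx + ab$dH
  } else {
    dF <- if (is.null(cache$mF)) dout else dout * cache$mF
    fb <- ffn_backward(dF, cache$ffn_in, lp, cache$ffn)
    g <- c(g, fb$grads)
    dA <- if (is.null(cache$mA)) fb$dX else fb$dX * cache$mA
    ab <- mha_backward(dA, cache$H, lp, config, cache$att)
    g <- c(g, ab$grads)
    dH <- dout + ab$dH
  }
  list(dH = dH, grads = g)
}

#' One Transformer encoder layer
#'
#' Multi-head self-attention followed by a position-wise feed-forward
#' network, composed residually; with `layernorm = TRUE` in the config,
#' post-norm layer normalisation follows each residual add, otherwise the
#' strict form `H' = FFN(MultiHead(H)) + H`.
#'
#' @param H `T' x d_model` input.
#' @param layer_params One element of `params$layers`.
#' @param config A [model_config()].
#' @return The transformed matrix, same shape as `H`.
#' @export
encoder_layer <- function(H, layer_params, config) {
  encoder_layer_forward(H, layer_params, config, training = FALSE)$out
}

#' Softmax classification head
#'
#' `yhat = Softmax(W_out' e_final + b_out)`: a probability vector over the C
#' affect classes, invariant to constant logit shifts.
#'
#' @param e_final Pooled representation (length `d_model`).
#' @param W,b Classifier weights (`d_model x C`) and bias.
#' @return Probability vector of length C.
#' @export
classify <- function(e_final, W, b) {
  softmax(as.numeric(e_final %*% W) + b)
}

#' Categorical cross-entropy
#'
#' `L = -sum_c y_c log(yhat_c)`; probabilities are clamped at 1e-12 before
#' the log so a confidently wrong prediction yields a large finite loss.
#'
#' @param yhat Predicted probability vector.
#' @param y True label: one-hot vector or 1-based class index.
#' @return Nonnegative scalar; 0 iff `yhat` puts all mass on the true class.
#' @export
cross_entropy <- function(yhat, y) {
  if (length(y) == 1L) {
    yi <- as.integer(y)
    -log(max(yhat[yi], 1e-12))
  } else {
    -sum(y * log(pmax(yhat, 1e-12)))
  }
}

#' Full forward pass
#'
#' Segment matrix to class probabilities: per-modality feature extraction,
#' concatenation fusion, linear projection to `d_model`, positional encoding,
#' the encoder stack, temporal pooling, softmax head.
#'
#' @param x `T x m` segment matrix with columns named by modality (a
#'   `segment` object's matrix). Only `config$modalities` columns are used.
#' @param config,params Model configuration and parameters.
#' @param training Draw dropout masks (uses the session RNG).
#' @return List: `yhat` (length-C probability vector) and `cache` (kept for
#'   [model_backward()]).
#' @export
model_forward <- function(x, config, params, training = FALSE) {
  if (inherits(x, "segment")) x <- x$matrix
  ex <- lapply(config$modalities, function(m) {
    extractor_forward(x[, m, drop = FALSE], params$extract[[m]], config)
  })
  names(ex) <- config$modalities
  E <- fuse_concat(lapply(ex, `[[`, "out"))
  H0 <- E %*% params$fuse$W
  H0 <- H0 + rep(params$fuse$b, each = nrow(H0))
  if (config$pool == "cls") H0 <- rbind(params$cls_token, H0)
  H0 <- H0 + positional_encoding(nrow(H0), config$d_model)
  rate <- if (training) config$dropout else 0
  m0 <- drop_mask(nrow(H0), ncol(H0), rate)
  H <- if (is.null(m0)) H0 else H0 * m0
  layer_caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    lf <- encoder_layer_forward(H, params$layers[[l]], config, training)
    H <- lf$out
    layer_caches[[l]] <- lf$cache
  }
  e_final <- if (config$pool == "cls") H[1L, ] else colMeans(H)
  yhat <- classify(e_final, params$out$W, params$out$b)
  list(yhat = yhat,
       cache = list(ex = ex, E = E, m0 = m0, layers = layer_caches,
                    H_final = H, e_final = e_final, Tprime = nrow(H)))
}

#' Backward pass: gradients of the cross-entropy loss
#'
#' @param y True label (1-based class index or one-hot vector).
#' @param fw Result of [model_forward()].
#' @param config,params As in [model_forward()].
#' @return List: `loss` and `grads` (nested list mirroring `params`).
#' @export
model_backward <- function(y, fw, config, params) {
  yhat <- fw$yhat
  cache <- fw$cache
  C <- config$n_classes
  onehot <- if (length(y) == 1L) {
    v <- numeric(C); v[as.integer(y)] <- 1; v
  } else as.numeric(y)
  loss <- cross_entropy(yhat, onehot)
  dlogits <- yhat - onehot

  grads <- list(out = list(W = outer(cache$e_final, dlogits),
                           b = dlogits))
  de <- as.numeric(params$out$W %*% dlogits)
  Tp <- cache$Tprime
  if (config$pool == "cls") {
    dH <- matrix(0, Tp, config$d_model)
    dH[1L, ] <- de
  } else {
    dH <- matrix(rep(de / Tp, each = Tp), Tp, config$d_model)
  }
  grads$layers <- vector("list", config$n_layers)
  for (l in rev(seq_len(config$n_layers))) {
    lb <- encoder_layer_backward(dH, params$layers[[l]], config,
                                 cache$layers[[l]])
    grads$layers[[l]] <- lb$grads
    dH <- lb$dH
  }
  if (!is.null(cache$m0)) dH <- dH * cache$m0
  if (config$pool == "cls") {
    grads$cls_token <- dH[1L, , drop = FALSE]
    dH <- dH[-1L, , drop = FALSE]
  }
  grads$fuse <- list(W = crossprod(cache$E, dH), b = colSums(dH))
  dE <- dH %*% t(params$fuse$W)
  grads$extract <- vector("list", length(config$modalities))
  names(grads$extract) <- config$modalities
  col0 <- 0L
  for (m in config$modalities) {
    cols <- (col0 + 1L):(col0 + config$d_e)
    eb <- extractor_backward(dE[, cols, drop = FALSE],
                             params$extract[[m]], cache$ex[[m]])
    grads$extract[[m]] <- eb$grads
    col0 <- col0 + config$d_e
  }
  list(loss = loss, grads = grads)
}

# ---- nested-parameter utilities -------------------------------------------

# Apply f elementwise over one or two parallel nested parameter structures.
param_map <- function(p, f) {
  if (is.list(p)) lapply(p, param_map, f = f) else f(p)
}

# Pairs by name where both levels are named (gradient lists are not built in
# the same field order as the parameter list), positionally otherwise.
param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    nm <- names(a)
    if (!is.null(nm) && !is.null(names(b))) {
      stopifnot(setequal(nm, names(b)))
      b <- b[nm]
    }
    out <- vector("list", length(a))
    names(out) <- nm
    for (i in seq_along(a)) out[[i]] <- param_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

#' Flatten / restore a nested parameter list
#'
#' Developer utilities used by the finite-difference gradient checks: the
#' nested parameter structure becomes a single numeric vector and back.
#'
#' @param params Nested parameter list.
#' @param flat Numeric vector from `flatten_params`.
#' @return `flatten_params`: numeric vector; `unflatten_params`: the nested
#'   list with the original shapes.
#' @export
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

#' @rdname flatten_params
#' @export
unflatten_params <- function(flat, params) {
  pos <- 0L
  refill <- function(p) {
    if (is.list(p)) return(lapply(p, refill))
    n <- length(p)
    v <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(p)) matrix(v, nrow(p), ncol(p)) else v
  }
  out <- refill(params)
  class(out) <- class(params)
  out
}
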