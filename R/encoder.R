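#' A small bidirectional self-attention encoder
#'
#' A pre-norm transformer encoder (token + learned positional embeddings,
#' multi-head scaled dot-product self-attention, GELU feed-forward blocks,
#' residual connections, final layer norm) implemented directly on R
#' matrices, with hand-derived backpropagation and an Adam optimizer. The
#' default configuration (2 layers, 64 hidden units, 4 heads) is a
#' desk-scale stand-in for a full-size masked-LM encoder; every size
#' parameter is configurable so the same code scales.
#'
#' @name encoder
NULL

#' Encoder configuration
#'
#' @param layers number of transformer blocks.
#' @param hidden hidden size (must be divisible by `heads`).
#' @param heads number of attention heads.
#' @param max_tokens maximum sequence length incl. any CLS token.
#' @param ff_mult feed-forward width as a multiple of `hidden`.
#' @param dropout dropout rate (default 0; training at desk scale is short
#'   enough that regularization is not the binding constraint).
#' @param pooling classification pooling: `"mean"` averages the final hidden
#'   states over all positions (default; gives every token a direct gradient
#'   path, which stabilizes optimization of very small models), `"cls"` uses
#'   the first-token representation only.
#' @return an `encoder_config`.
#' @export
encoder_config <- function(layers = 2, hidden = 64, heads = 4,
                           max_tokens = 608, ff_mult = 2, dropout = 0,
                           pooling = c("mean", "cls")) {
  if (hidden %% heads != 0) {
    stop_promtok("hidden size must be divisible by heads", "promtok_config_error")
  }
  structure(list(layers = as.integer(layers), hidden = as.integer(hidden),
                 heads = as.integer(heads), max_tokens = as.integer(max_tokens),
                 ff_mult = as.integer(ff_mult), dropout = dropout,
                 pooling = match.arg(pooling)),
            class = "encoder_config")
}

#' Training configuration
#'
#' @param batch_size sequences per optimizer step (default 8).
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param mask_rate MLM masking rate (default 0.15, with the standard
#'   80/10/10 mask/random/keep corruption).
#' @param seed integer seed; training is deterministic given it.
#' @param patience early-stopping patience on validation loss (fine-tuning).
#' @return a `train_config`.
#' @export
train_config <- function(batch_size = 8, lr = 1e-3, epochs = 5,
                         mask_rate = 0.15, seed = 1, patience = 3) {
  stopifnot(mask_rate > 0, mask_rate < 1, batch_size >= 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs), mask_rate = mask_rate,
                 seed = as.integer(seed), patience = as.integer(patience)),
            class = "train_config")
}

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xh <- xc * inv
  list(Y = sweep(xh, 2, g, `*`) + rep(b, each = nrow(X)),
       xh = xh, inv = inv)
}

layernorm_bwd <- function(dY, cache, g) {
  xh <- cache$xh; inv <- cache$inv
  dxh <- sweep(dY, 2, g, `*`)
  m1 <- rowMeans(dxh)
  m2 <- rowMeans(dxh * xh)
  dX <- (dxh - m1 - xh * m2) * inv
  list(dX = dX, dg = colSums(dY * xh), db = colSums(dY))
}

#' Initialize encoder parameters
#'
#' @param config an `encoder_config`.
#' @param vocab_size total vocabulary size (specials included).
#' @param seed integer seed for the Gaussian init (sd 0.02).
#' @return a flat named list of parameter arrays.
#' @export
init_encoder <- function(config, vocab_size, seed = 1) {
  h <- config$hidden; f <- h * config$ff_mult
  rnd <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
  with_seed(seed, {
    p <- list(E = rnd(vocab_size, h), P = rnd(config$max_tokens, h))
    for (l in seq_len(config$layers)) {
      pre <- sprintf("L%d.", l)
      p[[paste0(pre, "Wq")]] <- rnd(h, h); p[[paste0(pre, "bq")]] <- numeric(h)
      p[[paste0(pre, "Wk")]] <- rnd(h, h); p[[paste0(pre, "bk")]] <- numeric(h)
      p[[paste0(pre, "Wv")]] <- rnd(h, h); p[[paste0(pre, "bv")]] <- numeric(h)
      p[[paste0(pre, "Wo")]] <- rnd(h, h); p[[paste0(pre, "bo")]] <- numeric(h)
      p[[paste0(pre, "ln1_g")]] <- rep(1, h); p[[paste0(pre, "ln1_b")]] <- numeric(h)
      p[[paste0(pre, "W1")]] <- rnd(h, f); p[[paste0(pre, "b1")]] <- numeric(f)
      p[[paste0(pre, "W2")]] <- rnd(f, h); p[[paste0(pre, "b2")]] <- numeric(h)
      p[[paste0(pre, "ln2_g")]] <- rep(1, h); p[[paste0(pre, "ln2_b")]] <- numeric(h)
    }
    p$lnf_g <- rep(1, h); p$lnf_b <- numeric(h)
    p$Wm <- rnd(h, vocab_size); p$bm <- numeric(vocab_size)
    p$Wp <- rnd(h, h); p$bp <- numeric(h)
    p$wc <- rnorm(h, sd = 0.02); p$bc <- 0
    p
  })
}

row_softmax <- function(S) {
  m <- apply(S, 1, max)
  e <- exp(S - m)
  e / rowSums(e)
}

# Forward pass over one id sequence. Returns final hidden states Y (T x h)
# and, when `cache = TRUE`, everything backward needs.
encoder_forward <- function(params, ids, config, cache = FALSE) {
  T_ <- length(ids); h <- config$hidden
  nh <- config$heads; hd <- h %/% nh
  if (T_ > config$max_tokens) {
    stop_promtok("sequence exceeds max_tokens", "promtok_config_error")
  }
  X <- params$E[ids, , drop = FALSE] + params$P[seq_len(T_), , drop = FALSE]
  caches <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    pre <- sprintf("L%d.", l)
    X0 <- X
    ln1 <- layernorm_fwd(X0, params[[paste0(pre, "ln1_g")]],
                         params[[paste0(pre, "ln1_b")]])
    A_in <- ln1$Y
    Q <- A_in %*% params[[paste0(pre, "Wq")]] +
      rep(params[[paste0(pre, "bq")]], each = T_)
    K <- A_in %*% params[[paste0(pre, "Wk")]] +
      rep(params[[paste0(pre, "bk")]], each = T_)
    V <- A_in %*% params[[paste0(pre, "Wv")]] +
      rep(params[[paste0(pre, "bv")]], each = T_)
    H <- matrix(0, T_, h)
    attn <- vector("list", nh)
    for (j in seq_len(nh)) {
      cols <- ((j - 1L) * hd + 1L):(j * hd)
      S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(hd)
      A <- row_softmax(S)
      attn[[j]] <- A
      H[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    O <- H %*% params[[paste0(pre, "Wo")]] +
      rep(params[[paste0(pre, "bo")]], each = T_)
    X1 <- X0 + O
    ln2 <- layernorm_fwd(X1, params[[paste0(pre, "ln2_g")]],
                         params[[paste0(pre, "ln2_b")]])
    F_in <- ln2$Y
    U <- F_in %*% params[[paste0(pre, "W1")]] +
      rep(params[[paste0(pre, "b1")]], each = T_)
    G <- gelu(U)
    FF <- G %*% params[[paste0(pre, "W2")]] +
      rep(params[[paste0(pre, "b2")]], each = T_)
    X <- X1 + FF
    if (cache) {
      caches[[l]] <- list(ln1 = ln1, A_in = A_in, Q = Q, K = K, V = V,
                          attn = attn, H = H, X1 = X1, ln2 = ln2,
                          F_in = F_in, U = U, G = G)
    }
  }
  lnf <- layernorm_fwd(X, params$lnf_g, params$lnf_b)
  out <- list(Y = lnf$Y, ids = ids)
  if (cache) { out$caches <- caches; out$lnf <- lnf }
  out
}

# Backward from dY (gradient on final hidden states) to all parameters.
# Returns a flat named list of gradients matching `params` (encoder part;
# head parameters are handled by the loss-specific wrappers).
encoder_backward <- function(params, fwd, dY, config) {
  T_ <- length(fwd$ids); h <- config$hidden
  nh <- config$heads; hd <- h %/% nh
  g <- list()
  lb <- layernorm_bwd(dY, fwd$lnf, params$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dX <- lb$dX
  for (l in rev(seq_len(config$layers))) {
    pre <- sprintf("L%d.", l)
    cc <- fwd$caches[[l]]
    # feed-forward block
    dFF <- dX
    dG <- dFF %*% t(params[[paste0(pre, "W2")]])
    g[[paste0(pre, "W2")]] <- t(cc$G) %*% dFF
    g[[paste0(pre, "b2")]] <- colSums(dFF)
    dU <- dG * gelu_grad(cc$U)
    g[[paste0(pre, "W1")]] <- t(cc$F_in) %*% dU
    g[[paste0(pre, "b1")]] <- colSums(dU)
    dF_in <- dU %*% t(params[[paste0(pre, "W1")]])
    lb2 <- layernorm_bwd(dF_in, cc$ln2, params[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- lb2$dg; g[[paste0(pre, "ln2_b")]] <- lb2$db
    dX1 <- dX + lb2$dX
    # attention block
    dO <- dX1
    dH <- dO %*% t(params[[paste0(pre, "Wo")]])
    g[[paste0(pre, "Wo")]] <- t(cc$H) %*% dO
    g[[paste0(pre, "bo")]] <- colSums(dO)
    dQ <- matrix(0, T_, h); dK <- matrix(0, T_, h); dV <- matrix(0, T_, h)
    for (j in seq_len(nh)) {
      cols <- ((j - 1L) * hd + 1L):(j * hd)
      A <- cc$attn[[j]]
      dHj <- dH[, cols, drop = FALSE]
      Vj <- cc$V[, cols, drop = FALSE]
      dA <- dHj %*% t(Vj)
      dV[, cols] <- t(A) %*% dHj
      dS <- (dA - rowSums(dA * A)) * A
      dQ[, cols] <- (dS %*% cc$K[, cols, drop = FALSE]) / sqrt(hd)
      dK[, cols] <- (t(dS) %*% cc$Q[, cols, drop = FALSE]) / sqrt(hd)
    }
    g[[paste0(pre, "Wq")]] <- t(cc$A_in) %*% dQ
    g[[paste0(pre, "bq")]] <- colSums(dQ)
    g[[paste0(pre, "Wk")]] <- t(cc$A_in) %*% dK
    g[[paste0(pre, "bk")]] <- colSums(dK)
    g[[paste0(pre, "Wv")]] <- t(cc$A_in) %*% dV
    g[[paste0(pre, "bv")]] <- colSums(dV)
    dA_in <- dQ %*% t(params[[paste0(pre, "Wq")]]) +
      dK %*% t(params[[paste0(pre, "Wk")]]) +
      dV %*% t(params[[paste0(pre, "Wv")]])
    lb1 <- layernorm_bwd(dA_in, cc$ln1, params[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- lb1$dg; g[[paste0(pre, "ln1_b")]] <- lb1$db
    dX <- dX1 + lb1$dX
  }
  # embeddings
  dE <- matrix(0, nrow(params$E), h)
  acc <- rowsum(dX, group = fwd$ids)
  dE[as.integer(rownames(acc)), ] <- acc
  dP <- matrix(0, nrow(params$P), h)
  dP[seq_len(T_), ] <- dX
  g$E <- dE; g$P <- dP
  g
}

# ---- losses -----------------------------------------------------------------

# Masked-LM loss and gradients for one corrupted sequence.
# `mask_pos` are positions whose original ids are in `targets`.
mlm_loss_grad <- function(params, config, ids_in, mask_pos, targets,
                          want_grad = TRUE) {
  fwd <- encoder_forward(params, ids_in, config, cache = want_grad)
  Ym <- fwd$Y[mask_pos, , drop = FALSE]
  logits <- Ym %*% params$Wm + rep(params$bm, each = length(mask_pos))
  pr <- row_softmax(logits)
  n <- length(mask_pos)
  eps <- 1e-12
  loss <- -mean(log(pr[cbind(seq_len(n), targets)] + eps))
  if (!want_grad) return(list(loss = loss))
  dlogits <- pr
  dlogits[cbind(seq_len(n), targets)] <-
    dlogits[cbind(seq_len(n), targets)] - 1
  dlogits <- dlogits / n
  g_head <- list(Wm = t(Ym) %*% dlogits, bm = colSums(dlogits))
  dY <- matrix(0, length(ids_in), config$hidden)
  dY[mask_pos, ] <- dlogits %*% t(params$Wm)
  g <- encoder_backward(params, fwd, dY, config)
  g$Wm <- g_head$Wm; g$bm <- g_head$bm
  list(loss = loss, grads = g)
}

# Binary classification head: pooled hidden state -> tanh pooler -> logistic.
cls_forward <- function(params, config, ids_in) {
  fwd <- encoder_forward(params, ids_in, config, cache = TRUE)
  pooled <- if (identical(config$pooling, "cls")) fwd$Y[1, ] else colMeans(fwd$Y)
  z <- drop(pooled %*% params$Wp) + params$bp
  pl <- tanh(z)
  logit <- sum(pl * params$wc) + params$bc
  list(fwd = fwd, pooled = pooled, z = z, pl = pl, logit = logit,
       prob = 1 / (1 + exp(-logit)))
}

cls_loss_grad <- function(params, config, ids_in, y, want_grad = TRUE) {
  cf <- cls_forward(params, config, ids_in)
  eps <- 1e-12
  loss <- -(y * log(cf$prob + eps) + (1 - y) * log(1 - cf$prob + eps))
  if (!want_grad) return(list(loss = loss, prob = cf$prob))
  dlogit <- cf$prob - y
  g_head <- list(wc = dlogit * cf$pl, bc = dlogit)
  dpl <- dlogit * params$wc
  dz <- dpl * (1 - cf$pl^2)
  g_head$Wp <- outer(cf$pooled, dz)
  g_head$bp <- dz
  dpooled <- drop(params$Wp %*% dz)
  T_ <- length(ids_in)
  dY <- matrix(0, T_, config$hidden)
  if (identical(config$pooling, "cls")) {
    dY[1, ] <- dpooled
  } else {
    dY[] <- rep(dpooled / T_, each = T_)
  }
  g <- encoder_backward(params, cf$fwd, dY, config)
  g[c("Wp", "bp", "wc", "bc")] <- g_head[c("Wp", "bp", "wc", "bc")]
  list(loss = loss, prob = cf$prob, grads = g)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (is.null(params[[nm]])) next
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

accumulate_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) {
    total[[nm]] <- if (is.null(total[[nm]])) g[[nm]] else total[[nm]] + g[[nm]]
  }
  total
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)
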