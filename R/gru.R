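# Internal GRU machinery for the recurrent rollout policy.
#
# A small, dependency-free recurrent language model: token embedding, a stack
# of GRU layers (tanh candidate activation), and a linear softmax output.
# Gradients are computed by full backpropagation through time; the update
# rule is Adam.  Shapes: batches are row-major matrices (B x dim), weight
# matrices map by right-multiplication (x %*% W).
#
# Gate equations (per layer, h is the previous hidden state):
#   r = sigmoid(x Wr + h Ur + br)
#   z = sigmoid(x Wz + h Uz + bz)
#   n = tanh(x Wn + (r * h) Un + bn)
#   h' = (1 - z) * h + z * n
# Correctness of the hand-written backward pass is enforced by a numerical
# gradient check in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_init_params <- function(V, D, H, L, seed) {
  set.seed(seed)
  rmat <- function(nr, nc, k) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    Din <- if (l == 1L) D else H
    k <- 1 / sqrt(H)
    layers[[l]] <- list(
      Wr = rmat(Din, H, k), Wz = rmat(Din, H, k), Wn = rmat(Din, H, k),
      Ur = rmat(H, H, k), Uz = rmat(H, H, k), Un = rmat(H, H, k),
      br = stats::runif(H, -k, k), bz = stats::runif(H, -k, k),
      bn = stats::runif(H, -k, k))
  }
  list(E = rmat(V, D, 1 / sqrt(D)),
       layers = layers,
       Wout = rmat(H, V, 1 / sqrt(H)),
       bout = numeric(V))
}

gru_cell_forward <- function(lp, x, h) {
  pr <- x %*% lp$Wr + h %*% lp$Ur
  pz <- x %*% lp$Wz + h %*% lp$Uz
  r <- sigmoid(sweep(pr, 2, lp$br, "+"))
  z <- sigmoid(sweep(pz, 2, lp$bz, "+"))
  rh <- r * h
  nn <- tanh(sweep(x %*% lp$Wn + rh %*% lp$Un, 2, lp$bn, "+"))
  hn <- (1 - z) * h + z * nn
  list(h = hn, cache = list(x = x, hprev = h, r = r, z = z, nn = nn, rh = rh))
}

gru_cell_backward <- function(lp, cache, dh, grad) {
  x <- cache$x; h <- cache$hprev
  r <- cache$r; z <- cache$z; nn <- cache$nn; rh <- cache$rh
  dz <- dh * (nn - h)
  dnn <- dh * z
  dhprev <- dh * (1 - z)
  dpn <- dnn * (1 - nn^2)
  grad$Wn <- grad$Wn + crossprod(x, dpn)
  grad$Un <- grad$Un + crossprod(rh, dpn)
  grad$bn <- grad$bn + colSums(dpn)
  drh <- dpn %*% t(lp$Un)
  dr <- drh * h
  dhprev <- dhprev + drh * r
  dpr <- dr * r * (1 - r)
  dpz <- dz * z * (1 - z)
  grad$Wr <- grad$Wr + crossprod(x, dpr)
  grad$Ur <- grad$Ur + crossprod(h, dpr)
  grad$br <- grad$br + colSums(dpr)
  grad$Wz <- grad$Wz + crossprod(x, dpz)
  grad$Uz <- grad$Uz + crossprod(h, dpz)
  grad$bz <- grad$bz + colSums(dpz)
  dx <- dpr %*% t(lp$Wr) + dpz %*% t(lp$Wz) + dpn %*% t(lp$Wn)
  dhprev <- dhprev + dpr %*% t(lp$Ur) + dpz %*% t(lp$Uz)
  list(dx = dx, dh = dhprev, grad = grad)
}

# Forward pass over a padded batch.
# ids: B x (T+1) integer matrix of token indices (start-prefixed,
#      end-terminated, padded on the right with the end token).
# lens: true sequence lengths (number of prediction targets per row).
# Returns loss and, if wanted, caches for the backward pass.
gru_forward <- function(params, ids, lens, keep_cache = FALSE) {
  B <- nrow(ids); Tm <- ncol(ids) - 1L
  L <- length(params$layers)
  H <- ncol(params$layers[[1]]$Ur)
  V <- nrow(params$E)
  h <- replicate(L, matrix(0, B, H), simplify = FALSE)
  caches <- if (keep_cache) vector("list", Tm) else NULL
  loss <- 0
  nmask <- sum(pmin(lens, Tm))
  dlogits_all <- if (keep_cache) vector("list", Tm) else NULL
  hs_top <- NULL
  for (t in seq_len(Tm)) {
    x <- params$E[ids[, t], , drop = FALSE]
    step_caches <- vector("list", L)
    for (l in seq_len(L)) {
      fw <- gru_cell_forward(params$layers[[l]], x, h[[l]])
      h[[l]] <- fw$h
      step_caches[[l]] <- fw$cache
      x <- fw$h
    }
    logits <- sweep(h[[L]] %*% params$Wout, 2, params$bout, "+")
    m <- logits - apply(logits, 1, max)
    em <- exp(m)
    probs <- em / rowSums(em)
    tgt <- ids[, t + 1L]
    active <- t <= lens
    if (any(active)) {
      pick <- probs[cbind(which(active), tgt[active])]
      loss <- loss - sum(log(pmax(pick, 1e-300)))
    }
    if (keep_cache) {
      dl <- probs
      dl[cbind(seq_len(B), tgt)] <- dl[cbind(seq_len(B), tgt)] - 1
      dl[!active, ] <- 0
      dlogits_all[[t]] <- dl / nmask
      caches[[t]] <- step_caches
    }
  }
  list(loss = loss / nmask, caches = caches, dlogits = dlogits_all,
       h_final = h)
}

gru_zero_grad <- function(params) {
  zl <- function(m) if (is.matrix(m)) matrix(0, nrow(m), ncol(m)) else numeric(length(m))
  list(E = zl(params$E),
       layers = lapply(params$layers, function(lp) lapply(lp, zl)),
       Wout = zl(params$Wout), bout = zl(params$bout))
}

gru_backward <- function(params, ids, fw) {
  B <- nrow(ids); Tm <- ncol(ids) - 1L
  L <- length(params$layers)
  H <- ncol(params$layers[[1]]$Ur)
  grad <- gru_zero_grad(params)
  dh_carry <- replicate(L, matrix(0, B, H), simplify = FALSE)
  for (t in rev(seq_len(Tm))) {
    dl <- fw$dlogits[[t]]
    htop <- fw$caches[[t]][[L]]
    # recompute the top hidden state from the cache of step t
    htop_val <- (1 - htop$z) * htop$hprev + htop$z * htop$nn
    grad$Wout <- grad$Wout + crossprod(htop_val, dl)
    grad$bout <- grad$bout + colSums(dl)
    dh <- dl %*% t(params$Wout) + dh_carry[[L]]
    for (l in rev(seq_len(L))) {
      bw <- gru_cell_backward(params$layers[[l]], fw$caches[[t]][[l]], dh,
                              grad$layers[[l]])
      grad$layers[[l]] <- bw$grad
      dh_carry[[l]] <- bw$dh
      if (l > 1L) dh <- bw$dx + dh_carry[[l - 1L]]
    }
    dx_emb <- bw$dx
    for (b in seq_len(B)) {
      id <- ids[b, t]
      grad$E[id, ] <- grad$E[id, ] + dx_emb[b, ]
    }
  }
  grad
}

adam_init <- function(params) {
  zl <- gru_zero_grad(params)
  list(m = zl, v = zl, t = 0L)
}

adam_step <- function(params, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^tt)
    vh <- v / (1 - beta2^tt)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else upd(p, g, m, v)
  }
  res <- walk(params, grad, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = tt))
}

# Single-step inference: advance hidden states by one token id, return the
# next-token probability vector.
gru_step <- function(params, id, hidden) {
  x <- params$E[id, , drop = FALSE]
  L <- length(params$layers)
  for (l in seq_len(L)) {
    fw <- gru_cell_forward(params$layers[[l]], x, hidden[[l]])
    hidden[[l]] <- fw$h
    x <- fw$h
  }
  logits <- as.numeric(x %*% params$Wout) + params$bout
  m <- max(logits)
  p <- exp(logits - m)
  list(probs = p / sum(p), hidden = hidden)
}

gru_init_hidden <- function(params) {
  L <- length(params$layers)
  H <- ncol(params$layers[[1]]$Ur)
  replicate(L, matrix(0, 1, H), simplify = FALSE)
}
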