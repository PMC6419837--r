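# The generative sequence model: embedding -> stacked GRU layers -> linear +
# softmax. Trained by teacher forcing on the summed per-token cross entropy
# (the sequence NLL), with ADAM and a geometric learning-rate decay.
# Implemented directly in base R matrix algebra; sequences are processed in
# padded batches with padded positions masked out of the loss.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.addb <- function(m, b) m + rep(b, each = nrow(m))

# Parameter initialization: small uniform weights so that the untrained
# softmax is near-uniform (every token has probability ~ 1/V).
lm_init_params <- function(vocab_size, embedding_dim, hidden_dim, num_layers,
                           init_scale = 0.08) {
  ru <- function(nr, nc) matrix(stats::runif(nr * nc, -init_scale, init_scale), nr, nc)
  layers <- vector("list", num_layers)
  for (l in seq_len(num_layers)) {
    din <- if (l == 1) embedding_dim else hidden_dim
    layers[[l]] <- list(
      Wz = ru(din, hidden_dim), Uz = ru(hidden_dim, hidden_dim), bz = numeric(hidden_dim),
      Wr = ru(din, hidden_dim), Ur = ru(hidden_dim, hidden_dim), br = numeric(hidden_dim),
      Wh = ru(din, hidden_dim), Uh = ru(hidden_dim, hidden_dim), bh = numeric(hidden_dim))
  }
  list(E = ru(vocab_size, embedding_dim), layers = layers,
       Wo = ru(hidden_dim, vocab_size), bo = numeric(vocab_size))
}

# One GRU cell step for a whole batch. h' = z*h + (1-z)*c with update gate z
# acting as the "keep previous state" gate.
.gru_step <- function(ly, inp, hp) {
  z <- .sigmoid(.addb(inp %*% ly$Wz + hp %*% ly$Uz, ly$bz))
  r <- .sigmoid(.addb(inp %*% ly$Wr + hp %*% ly$Ur, ly$br))
  cc <- tanh(.addb(inp %*% ly$Wh + (r * hp) %*% ly$Uh, ly$bh))
  list(h = z * hp + (1 - z) * cc, z = z, r = r, cc = cc, inp = inp, hp = hp)
}

.softmax_rows <- function(logits) {
  mx <- do.call(pmax, c(as.data.frame(logits), list(0)))
  p <- exp(logits - mx)
  p / rowSums(p)
}

# Teacher-forced forward pass over a padded batch.
# ids_in, targets: B x T integer matrices; mask: B x T logical.
# Returns per-sequence NLL and (optionally) the caches needed for BPTT.
lm_forward <- function(params, ids_in, targets, mask, keep_cache = FALSE) {
  B <- nrow(ids_in); Tn <- ncol(ids_in)
  L <- length(params$layers)
  h <- lapply(seq_len(L), function(l) matrix(0, B, ncol(params$layers[[l]]$Uz)))
  caches <- if (keep_cache) vector("list", Tn) else NULL
  logp <- matrix(0, B, Tn)
  for (t in seq_len(Tn)) {
    inp <- params$E[ids_in[, t], , drop = FALSE]
    steps <- if (keep_cache) vector("list", L) else NULL
    for (l in seq_len(L)) {
      st <- .gru_step(params$layers[[l]], inp, h[[l]])
      h[[l]] <- st$h
      inp <- st$h
      if (keep_cache) steps[[l]] <- st
    }
    probs <- .softmax_rows(.addb(inp %*% params$Wo, params$bo))
    lp <- log(probs[cbind(seq_len(B), targets[, t])])
    logp[, t] <- ifelse(mask[, t], lp, 0)
    if (keep_cache) caches[[t]] <- list(steps = steps, probs = probs, h_top = inp)
  }
  list(nll = -rowSums(logp), caches = caches)
}

# Backpropagation through time. Loss = mean over sequences of summed
# per-token NLL. Returns gradients with the same shape as params.
lm_backward <- function(params, caches, ids_in, targets, mask) {
  B <- nrow(ids_in); Tn <- ncol(ids_in)
  L <- length(params$layers)
  zero_like <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  grads <- rapply(params, zero_like, how = "replace")
  dh_next <- lapply(seq_len(L), function(l) matrix(0, B, ncol(params$layers[[l]]$Uz)))
  scale <- 1 / B
  for (t in rev(seq_len(Tn))) {
    cache <- caches[[t]]
    dlogits <- cache$probs
    idx <- cbind(seq_len(B), targets[, t])
    dlogits[idx] <- dlogits[idx] - 1
    dlogits <- dlogits * (mask[, t] * scale)
    grads$Wo <- grads$Wo + crossprod(cache$h_top, dlogits)
    grads$bo <- grads$bo + colSums(dlogits)
    dx_above <- tcrossprod(dlogits, params$Wo)  # gradient flowing into top h
    for (l in rev(seq_len(L))) {
      st <- cache$steps[[l]]
      ly <- params$layers[[l]]
      dh <- dh_next[[l]] + dx_above
      dz <- dh * (st$hp - st$cc)
      dcc <- dh * (1 - st$z)
      dhp <- dh * st$z
      dac <- dcc * (1 - st$cc^2)
      grads$layers[[l]]$Wh <- grads$layers[[l]]$Wh + crossprod(st$inp, dac)
      grads$layers[[l]]$Uh <- grads$layers[[l]]$Uh + crossprod(st$r * st$hp, dac)
      grads$layers[[l]]$bh <- grads$layers[[l]]$bh + colSums(dac)
      drh <- tcrossprod(dac, ly$Uh)
      dr <- drh * st$hp
      dhp <- dhp + drh * st$r
      dar <- dr * st$r * (1 - st$r)
      grads$layers[[l]]$Wr <- grads$layers[[l]]$Wr + crossprod(st$inp, dar)
      grads$layers[[l]]$Ur <- grads$layers[[l]]$Ur + crossprod(st$hp, dar)
      grads$layers[[l]]$br <- grads$layers[[l]]$br + colSums(dar)
      dhp <- dhp + tcrossprod(dar, ly$Ur)
      daz <- dz * st$z * (1 - st$z)
      grads$layers[[l]]$Wz <- grads$layers[[l]]$Wz + crossprod(st$inp, daz)
      grads$layers[[l]]$Uz <- grads$layers[[l]]$Uz + crossprod(st$hp, daz)
      grads$layers[[l]]$bz <- grads$layers[[l]]$bz + colSums(daz)
      dhp <- dhp + tcrossprod(daz, ly$Uz)
      dh_next[[l]] <- dhp
      dx_above <- tcrossprod(dac, ly$Wh) + tcrossprod(dar, ly$Wr) +
        tcrossprod(daz, ly$Wz)
    }
    agg <- rowsum(dx_above, ids_in[, t])
    rows <- as.integer(rownames(agg))
    grads$E[rows, ] <- grads$E[rows, ] + agg
  }
  grads
}

# Flatten/walk helpers for optimizer state.
.nmap2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(.nmap2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    out
  } else f(a, b)
}

.grad_norm <- function(grads) {
  sqrt(sum(unlist(rapply(grads, function(g) sum(g^2), how = "unlist"))))
}

adam_init <- function(params) {
  zero_like <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  list(m = rapply(params, zero_like, how = "replace"),
       v = rapply(params, zero_like, how = "replace"),
       t = 0L)
}

adam_update <- function(params, grads, state, lr, betas = c(0.9, 0.999), eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  state$m <- .nmap2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- .nmap2(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  upd <- .nmap2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps), state$m, state$v)
  params <- .nmap2(`-`, params, upd)
  list(params = params, state = state)
}

# Build a padded batch from a list of id sequences s = (^, tokens, $).
# Inputs are s[1..L-1], targets s[2..L]; padding uses the "$" id and is
# masked out of the loss.
.make_batch <- function(seqs, end_id) {
  lens <- lengths(seqs)
  Tn <- max(lens) - 1L
  B <- length(seqs)
  ids_in <- matrix(end_id, B, Tn)
  targets <- matrix(end_id, B, Tn)
  mask <- matrix(FALSE, B, Tn)
  for (i in seq_len(B)) {
    li <- lens[i] - 1L
    ids_in[i, seq_len(li)] <- seqs[[i]][seq_len(li)]
    targets[i, seq_len(li)] <- seqs[[i]][1L + seq_len(li)]
    mask[i, seq_len(li)] <- TRUE
  }
  list(ids_in = ids_in, targets = targets, mask = mask)
}

#' Fit a SMILES language model
#'
#' Fits the generative sequence model used throughout the package: an
#' embedding layer feeding stacked GRU layers, a linear output layer and a
#' softmax over the token vocabulary. Training is by teacher forcing — each
#' step is conditioned on the true previous token of the training sequence —
#' minimizing the sequence negative log-likelihood (the summed per-token
#' cross entropy, in nats) with the ADAM optimizer. The learning rate decays
#' geometrically from `lr_start` to `lr_end` across the configured epochs
#' (multiplied by the constant `(lr_end/lr_start)^(1/(epochs-1))` after each
#' epoch).
#'
#' Defaults are the desk-scale profile (embedding 32, hidden 64, one GRU
#' layer, 50-token sequences). The full-scale reference profile used for
#' billion-molecule spaces is embedding 256, hidden 512, three GRU layers,
#' and 140-token sequences; see [lm_reference_profile()].
#'
#' @param x character vector of training SMILES.
#' @param validation optional character vector of validation SMILES; must be
#'   disjoint from the training set.
#' @param vocab a [build_vocabulary()] result; defaults to the vocabulary of
#'   `x` plus `validation`.
#' @param embedding_dim,hidden_dim,num_layers network dimensions.
#' @param epochs number of passes over the training set.
#' @param batch_size sequences per gradient step.
#' @param lr_start,lr_end endpoints of the geometric learning-rate decay.
#' @param adam_betas,adam_eps ADAM moment parameters.
#' @param max_sequence_length sampling truncation length (tokens after `^`).
#' @param seed RNG seed; fits are bit-reproducible given the seed.
#' @param keep_checkpoints keep a copy of the weights after every epoch
#'   (retrievable with [checkpoint()]; needed for post-hoc training
#'   diagnostics).
#' @param grad_clip global gradient-norm clip.
#' @param verbose print per-epoch losses.
#' @return an object of class `smiles_lm`: the fitted weights, vocabulary,
#'   configuration, per-epoch `loss_log` (epoch, lr, mean_train_nll,
#'   mean_valid_nll) and optional checkpoints. Supports `print`, `summary`,
#'   `coef`, `predict` (sequence NLLs), `simulate` (multinomial sampling)
#'   and `plot` (loss curves).
#' @examples
#' \donttest{
#' m <- smiles_lm(c("CC", "CCO", "CCC"), epochs = 3, seed = 1)
#' predict(m, "CCO")
#' simulate(m, nsim = 5, seed = 2)
#' }
#' @export
smiles_lm <- function(x, validation = NULL, vocab = NULL,
                      embedding_dim = 32, hidden_dim = 64, num_layers = 1,
                      epochs = 20, batch_size = 128,
                      lr_start = 1e-3, lr_end = 1e-5,
                      adam_betas = c(0.9, 0.999), adam_eps = 1e-8,
                      max_sequence_length = 50, seed = 42,
                      keep_checkpoints = FALSE, grad_clip = 5,
                      verbose = FALSE) {
  stopifnot(is.character(x), length(x) >= 1, epochs >= 1,
            lr_end <= lr_start, embedding_dim > 0, hidden_dim > 0,
            num_layers > 0)
  if (!is.null(validation) && length(intersect(x, validation)) > 0)
    stop("training and validation sets must be disjoint")
  if (is.null(vocab)) vocab <- build_vocabulary(c(x, validation))
  end_id <- unname(vocab$index[TOKEN_END])
  train_seqs <- lapply(x, function(s) encode_smiles(s, vocab)$ids)
  valid_seqs <- if (!is.null(validation))
    lapply(validation, function(s) encode_smiles(s, vocab)$ids)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  params <- lm_init_params(length(vocab$tokens), embedding_dim, hidden_dim, num_layers)
  opt <- adam_init(params)
  decay <- if (epochs > 1) (lr_end / lr_start)^(1 / (epochs - 1)) else 1
  log_rows <- vector("list", epochs)
  checkpoints <- if (keep_checkpoints) vector("list", epochs) else NULL
  mean_nll_of <- function(seqs) {
    tot <- 0
    for (start in seq(1, length(seqs), by = batch_size)) {
      sub <- seqs[start:min(start + batch_size - 1L, length(seqs))]
      b <- .make_batch(sub, end_id)
      tot <- tot + sum(lm_forward(params, b$ids_in, b$targets, b$mask)$nll)
    }
    tot / length(seqs)
  }
  for (epoch in seq_len(epochs)) {
    lr <- lr_start * decay^(epoch - 1)
    ord <- sample.int(length(train_seqs))
    ep_nll <- 0
    for (start in seq(1, length(ord), by = batch_size)) {
      sel <- ord[start:min(start + batch_size - 1L, length(ord))]
      b <- .make_batch(train_seqs[sel], end_id)
      fw <- lm_forward(params, b$ids_in, b$targets, b$mask, keep_cache = TRUE)
      loss <- mean(fw$nll)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d (lr %.2e): aborting", epoch, lr))
      ep_nll <- ep_nll + sum(fw$nll)
      grads <- lm_backward(params, fw$caches, b$ids_in, b$targets, b$mask)
      gn <- .grad_norm(grads)
      if (gn > grad_clip)
        grads <- rapply(grads, function(g) g * (grad_clip / gn), how = "replace")
      res <- adam_update(params, grads, opt, lr, adam_betas, adam_eps)
      params <- res$params
      opt <- res$state
    }
    mean_train <- ep_nll / length(train_seqs)
    mean_valid <- if (!is.null(valid_seqs)) mean_nll_of(valid_seqs) else NA_real_
    log_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                    mean_train_nll = mean_train,
                                    mean_valid_nll = mean_valid)
    if (keep_checkpoints) checkpoints[[epoch]] <- params
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  train NLL %.3f  valid NLL %s",
                      epoch, lr, mean_train,
                      if (is.na(mean_valid)) "-" else sprintf("%.3f", mean_valid)))
  }
  structure(list(
    params = params,
    vocab = vocab,
    config = list(embedding_dim = embedding_dim, hidden_dim = hidden_dim,
                  num_layers = num_layers, epochs = epochs,
                  batch_size = batch_size, lr_start = lr_start, lr_end = lr_end,
                  adam_betas = adam_betas, adam_eps = adam_eps,
                  max_sequence_length = max_sequence_length, seed = seed,
                  n_train = length(x), n_valid = length(validation %||% character(0))),
    loss_log = do.call(rbind, log_rows),
    checkpoints = checkpoints,
    epoch = epochs
  ), class = "smiles_lm")
}

#' Full-scale reference model profile
#'
#' The network/training profile used for billion-molecule reference spaces:
#' embedding 256, hidden 512, three GRU layers, batch 128, learning rate
#' decaying 1e-3 to 1e-5, 140-token sequences. Pass these to [smiles_lm()]
#' via `do.call` when fitting at full scale.
#' @return named list of `smiles_lm` arguments.
#' @export
lm_reference_profile <- function() {
  list(embedding_dim = 256, hidden_dim = 512, num_layers = 3,
       batch_size = 128, lr_start = 1e-3, lr_end = 1e-5,
       max_sequence_length = 140)
}
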