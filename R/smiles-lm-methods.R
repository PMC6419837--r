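# Methods on fitted smiles_lm objects.

#' @export
print.smiles_lm <- function(x, ...) {
  cf <- x$config
  cat(sprintf("SMILES GRU language model (epoch %d)\n", x$epoch))
  cat(sprintf("  vocabulary: %d tokens; embedding %d; %d x GRU(%d)\n",
              length(x$vocab$tokens), cf$embedding_dim, cf$num_layers, cf$hidden_dim))
  cat(sprintf("  trained on %d sequences (%d validation), batch %d, lr %.1e -> %.1e\n",
              cf$n_train, cf$n_valid, cf$batch_size, cf$lr_start, cf$lr_end))
  last <- x$loss_log[nrow(x$loss_log), ]
  cat(sprintf("  final mean NLL: train %.3f%s nats\n", last$mean_train_nll,
              if (is.na(last$mean_valid_nll)) "" else
                sprintf(", valid %.3f", last$mean_valid_nll)))
  invisible(x)
}

#' @export
summary.smiles_lm <- function(object, ...) {
  out <- list(config = object$config, loss_log = object$loss_log,
              n_parameters = sum(unlist(rapply(object$params, length, how = "unlist"))),
              has_checkpoints = !is.null(object$checkpoints))
  class(out) <- "summary.smiles_lm"
  out
}

#' @export
print.summary.smiles_lm <- function(x, ...) {
  cat(sprintf("smiles_lm with %d parameters over %d epochs\n",
              x$n_parameters, nrow(x$loss_log)))
  print(utils::head(x$loss_log, 3))
  if (nrow(x$loss_log) > 6) cat("  ...\n")
  print(utils::tail(x$loss_log, 3))
  if (x$has_checkpoints) cat("per-epoch checkpoints retained\n")
  invisible(x)
}

#' @export
coef.smiles_lm <- function(object, ...) object$params

#' Retrieve the model as of a given training epoch
#'
#' Requires the fit to have been run with `keep_checkpoints = TRUE`.
#' @param model a fitted [smiles_lm()].
#' @param epoch epoch number (1-based).
#' @return a `smiles_lm` carrying that epoch's weights.
#' @export
checkpoint <- function(model, epoch) {
  stopifnot(inherits(model, "smiles_lm"))
  if (is.null(model$checkpoints))
    stop("model was fitted without keep_checkpoints = TRUE")
  if (epoch < 1 || epoch > length(model$checkpoints))
    stop("no checkpoint for epoch ", epoch)
  out <- model
  out$params <- model$checkpoints[[epoch]]
  out$epoch <- epoch
  out$checkpoints <- NULL
  out
}

#' Score sequences under the model
#'
#' Computes each sequence's negative log-likelihood (nats): the sum of
#' per-step conditional token negative log-probabilities under teacher
#' forcing, including the terminal end-token step. Deterministic for a
#' fixed model.
#'
#' @param object a fitted `smiles_lm`.
#' @param newdata character vector of SMILES; all tokens must be in the
#'   model vocabulary.
#' @param ... unused.
#' @return data.frame with columns `smiles` and `nll`.
#' @export
predict.smiles_lm <- function(object, newdata, ...) {
  stopifnot(is.character(newdata), length(newdata) >= 1)
  vocab <- object$vocab
  end_id <- unname(vocab$index[TOKEN_END])
  seqs <- lapply(newdata, function(s) encode_smiles(s, vocab)$ids)
  bs <- object$config$batch_size
  nll <- numeric(length(seqs))
  for (start in seq(1, length(seqs), by = bs)) {
    sel <- start:min(start + bs - 1L, length(seqs))
    b <- .make_batch(seqs[sel], end_id)
    nll[sel] <- lm_forward(object$params, b$ids_in, b$targets, b$mask)$nll
  }
  data.frame(smiles = newdata, nll = nll)
}

#' Per-step conditional token distributions
#'
#' Teacher-forced forward pass of a single sequence exposing the full
#' softmax distribution at every step. Row `i` is the distribution over the
#' next token given the first `i` tokens (starting from `^`); each row sums
#' to one.
#'
#' @param model a fitted `smiles_lm`.
#' @param smiles a single SMILES string.
#' @return numeric matrix (steps x vocabulary), with the realized target
#'   token of each step in `attr(, "targets")`.
#' @export
token_probabilities <- function(model, smiles) {
  stopifnot(inherits(model, "smiles_lm"), length(smiles) == 1)
  enc <- encode_smiles(smiles, model$vocab)
  ids <- enc$ids
  Tn <- length(ids) - 1L
  params <- model$params
  L <- length(params$layers)
  h <- lapply(seq_len(L), function(l) matrix(0, 1, ncol(params$layers[[l]]$Uz)))
  probs <- matrix(0, Tn, length(model$vocab$tokens),
                  dimnames = list(enc$tokens[seq_len(Tn)], model$vocab$tokens))
  for (t in seq_len(Tn)) {
    inp <- params$E[ids[t], , drop = FALSE]
    for (l in seq_len(L)) {
      st <- .gru_step(params$layers[[l]], inp, h[[l]])
      h[[l]] <- st$h
      inp <- st$h
    }
    probs[t, ] <- .softmax_rows(.addb(inp %*% params$Wo, params$bo))
  }
  attr(probs, "targets") <- enc$tokens[-1]
  probs
}

#' Sample SMILES from the model
#'
#' Generates sequences by multinomial sampling from the per-step softmax:
#' starting after the begin token, each sampled token is fed back as the
#' next input until the end token is produced or `max_length` tokens have
#' been emitted (truncated sequences are flagged and should be counted as
#' invalid downstream). Each sequence is returned with its NLL. Reproducible
#' given `seed`.
#'
#' @param object a fitted `smiles_lm`.
#' @param nsim number of sequences to sample.
#' @param seed RNG seed (`NULL` continues the current RNG stream).
#' @param max_length truncation length; defaults to the fit's
#'   `max_sequence_length`.
#' @param batch internal batch size for the sampler.
#' @param ... unused.
#' @return data.frame with columns `smiles`, `nll`, `truncated`.
#' @export
simulate.smiles_lm <- function(object, nsim = 1, seed = NULL,
                               max_length = NULL, batch = 1024, ...) {
  stopifnot(nsim >= 1)
  max_length <- max_length %||% object$config$max_sequence_length
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
  }
  vocab <- object$vocab
  begin_id <- unname(vocab$index[TOKEN_BEGIN])
  end_id <- unname(vocab$index[TOKEN_END])
  params <- object$params
  L <- length(params$layers)
  V <- length(vocab$tokens)
  out_smiles <- character(nsim)
  out_nll <- numeric(nsim)
  out_trunc <- logical(nsim)
  done <- 0L
  while (done < nsim) {
    B <- min(batch, nsim - done)
    h <- lapply(seq_len(L), function(l) matrix(0, B, ncol(params$layers[[l]]$Uz)))
    last <- rep(begin_id, B)
    nll <- numeric(B)
    toks <- matrix(NA_integer_, B, max_length)
    active <- rep(TRUE, B)
    nemit <- integer(B)
    for (step in seq_len(max_length)) {
      inp <- params$E[last, , drop = FALSE]
      for (l in seq_len(L)) {
        st <- .gru_step(params$layers[[l]], inp, h[[l]])
        h[[l]] <- st$h
        inp <- st$h
      }
      probs <- .softmax_rows(.addb(inp %*% params$Wo, params$bo))
      cs <- probs
      for (j in 2:V) cs[, j] <- cs[, j - 1] + cs[, j]
      u <- stats::runif(B)
      pick <- max.col(cs >= u, ties.method = "first")
      act <- which(active)
      nll[act] <- nll[act] - log(probs[cbind(act, pick[act])])
      ended <- active & pick == end_id
      emit <- active & pick != end_id
      if (any(emit)) {
        toks[cbind(which(emit), nemit[emit] + 1L)] <- pick[emit]
        nemit[emit] <- nemit[emit] + 1L
      }
      active[ended] <- FALSE
      last <- pick
      if (!any(active)) break
    }
    for (i in seq_len(B)) {
      ids <- toks[i, seq_len(nemit[i])]
      out_smiles[done + i] <- if (nemit[i] == 0) "" else
        paste(vocab$tokens[ids], collapse = "")
    }
    out_nll[done + seq_len(B)] <- nll
    out_trunc[done + seq_len(B)] <- active
    done <- done + B
  }
  data.frame(smiles = out_smiles, nll = out_nll, truncated = out_trunc)
}

#' Plot training curves
#'
#' Mean training and validation NLL per epoch, with the learning-rate decay
#' overlaid on a log axis.
#' @param x a fitted `smiles_lm`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.smiles_lm <- function(x, ...) {
  ll <- x$loss_log
  graphics::matplot(ll$epoch, cbind(ll$mean_train_nll, ll$mean_valid_nll),
                    type = "l", lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "mean NLL (nats)", ...)
  graphics::legend("topright", c("training", "validation"),
                   col = c("black", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
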