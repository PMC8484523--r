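# Gated recurrent unit mapping unfolding phonological inputs to static
# aggregated targets: forward pass, hand-derived backpropagation through
# time, and full-batch gradient descent with Nesterov momentum.

sigm <- function(x) 1 / (1 + exp(-x))

#' Initialize GRU parameters
#'
#' Six weight matrices: `W_u`, `H_u` (update gate), `W_r`, `H_r` (reset
#' gate), `W`, `U` (candidate state). Input-facing matrices are
#' `hidden_dim` by `input_dim`; recurrent matrices are `hidden_dim` by
#' `hidden_dim`. Entries are drawn uniformly in `±1/sqrt(hidden_dim)`.
#'
#' @param input_dim input dimensionality (20 for the phonological feature
#'   code).
#' @param hidden_dim hidden/output dimensionality; the hidden state is the
#'   model output, so this equals the aggregated target length (450 at full
#'   scale).
#' @param seed RNG seed for reproducible initialization.
#' @return An object of class `gru_params`.
#' @export
init_params <- function(input_dim, hidden_dim, seed = 1L) {
  stopifnot(input_dim >= 1L, hidden_dim >= 1L)
  set.seed(seed)
  lim <- 1 / sqrt(hidden_dim)
  rmat <- function(nr, nc) matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  structure(
    list(W_u = rmat(hidden_dim, input_dim), H_u = rmat(hidden_dim, hidden_dim),
         W_r = rmat(hidden_dim, input_dim), H_r = rmat(hidden_dim, hidden_dim),
         W   = rmat(hidden_dim, input_dim), U   = rmat(hidden_dim, hidden_dim),
         input_dim = as.integer(input_dim),
         hidden_dim = as.integer(hidden_dim)),
    class = "gru_params")
}

weight_names <- c("W_u", "H_u", "W_r", "H_r", "W", "U")

#' One GRU timestep
#'
#' Computes the update gate `u = sigma(W_u x + H_u h_prev)`, the reset gate
#' `r = sigma(W_r x + H_r h_prev)`, the candidate state
#' `h' = tanh(W x + r * (U h_prev))` (elementwise product), and the new
#' state `h = u * h_prev + (1 - u) * h'`.
#'
#' Inputs may be vectors (one item) or matrices with one column per item.
#'
#' @param p a [init_params()] object.
#' @param x_t input vector (`input_dim`) or matrix (`input_dim` x n).
#' @param h_prev previous hidden state, conformable with `x_t`.
#' @return List with `h`, and gate/candidate diagnostics `u`, `r`, `h_cand`.
#' @export
gru_step <- function(p, x_t, h_prev) {
  x_t <- as.matrix(x_t); h_prev <- as.matrix(h_prev)
  if (nrow(x_t) != p$input_dim || nrow(h_prev) != p$hidden_dim)
    stop("gru_step: dimension mismatch with parameters")
  u <- sigm(p$W_u %*% x_t + p$H_u %*% h_prev)
  r <- sigm(p$W_r %*% x_t + p$H_r %*% h_prev)
  h_cand <- tanh(p$W %*% x_t + r * (p$U %*% h_prev))
  h <- u * h_prev + (1 - u) * h_cand
  list(h = h, u = u, r = r, h_cand = h_cand)
}

#' Run the GRU over an unfolding input
#'
#' Iterates [gru_step()] from `h0` (all zeros by default) over every row of
#' the unfolding matrix.
#'
#' @param p a [init_params()] object.
#' @param m unfolding matrix, timesteps by `input_dim`.
#' @param h0 initial hidden state (default zeros).
#' @return Matrix of hidden states, timesteps by `hidden_dim`.
#' @export
gru_forward <- function(p, m, h0 = NULL) {
  m <- as.matrix(m)
  if (nrow(m) == 0L) return(matrix(0, 0L, p$hidden_dim))
  if (ncol(m) != p$input_dim) stop("gru_forward: input dimension mismatch")
  h <- if (is.null(h0)) matrix(0, p$hidden_dim, 1L) else as.matrix(h0)
  out <- matrix(0, nrow(m), p$hidden_dim)
  for (t in seq_len(nrow(m))) {
    h <- gru_step(p, m[t, ], h)$h
    out[t, ] <- h
  }
  out
}

# split a T x input_dim x N array into a list of input_dim x N matrices
# (precomputed once per training run; array slicing each step is costly)
input_slices <- function(X) {
  Tn <- dim(X)[1L]
  lapply(seq_len(Tn), function(t)
    matrix(X[t, , ], dim(X)[2L], dim(X)[3L]))
}

# Batched forward over X (T x input_dim x N array, or a precomputed list
# of input_dim x N matrices); returns per-step caches needed by the
# backward pass. h columns index items.
gru_forward_batch <- function(p, X, keep_cache = TRUE) {
  Xl <- if (is.list(X)) X else input_slices(X)
  Tn <- length(Xl); N <- ncol(Xl[[1L]])
  H_prev <- matrix(0, p$hidden_dim, N)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  H_all <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Xt <- Xl[[t]]
    u <- sigm(p$W_u %*% Xt + p$H_u %*% H_prev)
    r <- sigm(p$W_r %*% Xt + p$H_r %*% H_prev)
    Uh <- p$U %*% H_prev
    cnd <- tanh(p$W %*% Xt + r * Uh)
    H <- u * H_prev + (1 - u) * cnd
    if (keep_cache)
      cache[[t]] <- list(u = u, r = r, Uh = Uh, cnd = cnd, H_prev = H_prev)
    H_all[[t]] <- H
    H_prev <- H
  }
  list(H = H_all, cache = cache)
}

#' Loss of one training trial
#'
#' The target stays active at every timestep, so the loss is the mean over
#' all timesteps and output dimensions of the pointwise discrepancy between
#' the hidden state and the (constant) aggregated binary target. The
#' default is squared error; `"bce"` applies binary cross-entropy to the
#' state rescaled from `(-1, 1)` to `(0, 1)`.
#'
#' @param outputs timesteps-by-`hidden_dim` matrix of hidden states.
#' @param target binary target vector of length `hidden_dim`.
#' @param loss_kind `"mse"` (default) or `"bce"`.
#' @return Scalar loss.
#' @export
trial_loss <- function(outputs, target, loss_kind = c("mse", "bce")) {
  loss_kind <- match.arg(loss_kind)
  outputs <- as.matrix(outputs)
  if (nrow(outputs) == 0L) stop("trial_loss: empty output sequence")
  if (ncol(outputs) != length(target)) stop("trial_loss: dimension mismatch")
  Y <- matrix(target, nrow(outputs), length(target), byrow = TRUE)
  if (loss_kind == "mse") {
    mean((outputs - Y)^2)
  } else {
    s <- pmin(pmax((outputs + 1) / 2, 1e-12), 1 - 1e-12)
    mean(-(Y * log(s) + (1 - Y) * log(1 - s)))
  }
}

# Full-batch loss and analytic gradients by backpropagation through time.
# X: T x input_dim x N array (or precomputed input_slices list);
# Y: hidden_dim x N (targets held constant over time).
gru_loss_grad <- function(p, X, Y, loss_kind = "mse") {
  if (!is.list(X)) X <- input_slices(X)
  Tn <- length(X); N <- ncol(X[[1L]])
  fw <- gru_forward_batch(p, X)
  norm <- Tn * p$hidden_dim * N
  loss <- 0
  grads <- lapply(p[weight_names], function(w) w * 0)
  dH_carry <- matrix(0, p$hidden_dim, N)
  # accumulate direct loss first (cheap), then backward pass
  dH_direct <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    H <- fw$H[[t]]
    if (loss_kind == "mse") {
      loss <- loss + sum((H - Y)^2)
      dH_direct[[t]] <- 2 * (H - Y) / norm
    } else {
      s <- pmin(pmax((H + 1) / 2, 1e-12), 1 - 1e-12)
      loss <- loss + sum(-(Y * log(s) + (1 - Y) * log(1 - s)))
      dH_direct[[t]] <- (s - Y) / (2 * s * (1 - s)) / norm
    }
  }
  loss <- loss / norm
  for (t in rev(seq_len(Tn))) {
    ch <- fw$cache[[t]]
    tXt <- t(X[[t]])
    tHp <- t(ch$H_prev)
    dH <- dH_direct[[t]] + dH_carry
    du <- dH * (ch$H_prev - ch$cnd)
    dc <- dH * (1 - ch$u)
    dH_prev <- dH * ch$u
    dac <- dc * (1 - ch$cnd^2)
    grads$W <- grads$W + dac %*% tXt
    dr <- dac * ch$Uh
    dUh <- dac * ch$r
    grads$U <- grads$U + dUh %*% tHp
    dH_prev <- dH_prev + crossprod(p$U, dUh)
    dau <- du * ch$u * (1 - ch$u)
    grads$W_u <- grads$W_u + dau %*% tXt
    grads$H_u <- grads$H_u + dau %*% tHp
    dH_prev <- dH_prev + crossprod(p$H_u, dau)
    dar <- dr * ch$r * (1 - ch$r)
    grads$W_r <- grads$W_r + dar %*% tXt
    grads$H_r <- grads$H_r + dar %*% tHp
    dH_prev <- dH_prev + crossprod(p$H_r, dar)
    dH_carry <- dH_prev
  }
  list(loss = loss, grads = grads, H = fw$H)
}

#' Training configuration
#'
#' Defaults follow the model's stated optimization regime: full-batch
#' gradient descent with learning rate 0.4, momentum 0.4, and Nesterov
#' momentum enabled.
#'
#' @param learning_rate step size (> 0).
#' @param momentum momentum coefficient.
#' @param nesterov use the Nesterov formulation?
#' @param epochs maximum number of epochs (one epoch = one full-batch pass
#'   over all items).
#' @param eval_every evaluate recognition and log every this many epochs.
#' @param seed seed for weight initialization.
#' @param loss_kind `"mse"` or `"bce"`.
#' @param converge_pct stop early once the percentage of items with both
#'   constituents recognized reaches this level...
#' @param converge_k ...for this many consecutive evaluations.
#' @param converge_loss additionally require the training loss to fall to
#'   this level before stopping early (default `Inf`: recognition only).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.4, momentum = 0.4, nesterov = TRUE,
                         epochs = 2000L, eval_every = 25L, seed = 1L,
                         loss_kind = c("mse", "bce"),
                         converge_pct = 100, converge_k = 2L,
                         converge_loss = Inf) {
  loss_kind <- match.arg(loss_kind)
  stopifnot(learning_rate > 0, epochs >= 1L, eval_every >= 1L)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 nesterov = nesterov, epochs = as.integer(epochs),
                 eval_every = as.integer(eval_every), seed = as.integer(seed),
                 loss_kind = loss_kind, converge_pct = converge_pct,
                 converge_k = as.integer(converge_k),
                 converge_loss = converge_loss),
            class = "train_config")
}

#' Train the GRU on a prepared dataset
#'
#' Full-batch gradient descent on the mean trial loss over all items, with
#' (Nesterov) momentum in the standard deep-learning formulation: with
#' gradient `g`, velocity `v <- momentum * v + g` and update step
#' `g + momentum * v` (plain momentum uses `v` as the step). All inputs are
#' zero-padded to a common trial length and the targets stay active at
#' every timestep. Recognition is evaluated every `eval_every` epochs at
#' each item's word offset; training stops early when the both-constituent
#' recognition percentage holds at `converge_pct` for `converge_k`
#' consecutive evaluations.
#'
#' @param data a dataset from [prepare_dataset()] (or a list with fields
#'   `X`, `Y`, `segments`, `vocab`).
#' @param cfg a [train_config()].
#' @param params optional warm-start parameters (otherwise initialized from
#'   `cfg$seed`).
#' @param backend `"cpp"` (default, compiled loop) or `"r"` (reference
#'   implementation); both compute identical updates.
#' @return An object of class `gru_model`: parameters, segments, config,
#'   epoch counter, and a training log (`log` data frame plus per-item
#'   correctness matrices `lex_correct`, `semvis_correct`).
#' @export
train_gru <- function(data, cfg = train_config(), params = NULL,
                      backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  X <- data$X; Y <- data$Y
  stopifnot(length(dim(X)) == 3L)
  if (is.null(params))
    params <- init_params(dim(X)[2L], nrow(Y), seed = cfg$seed)
  offsets <- data$vocab$offset_row
  loss_code <- if (cfg$loss_kind == "mse") 0L else 1L
  Xl <- if (backend == "r") input_slices(X) else NULL
  Xc <- if (backend == "cpp") aperm(X, c(2L, 3L, 1L)) else NULL
  vel <- lapply(params[weight_names], function(w) w * 0)
  log_rows <- list(); lex_hist <- list(); sv_hist <- list()
  streak <- 0L; epoch_done <- 0L
  eval_points <- if (cfg$eval_every <= cfg$epochs)
    unique(c(seq(cfg$eval_every, cfg$epochs, by = cfg$eval_every),
             cfg$epochs))
  else cfg$epochs
  for (ev in eval_points) {
    if (backend == "cpp") {
      chunk <- gru_train_epochs_cpp(params[weight_names], vel, Xc, Y,
                                    cfg$learning_rate, cfg$momentum,
                                    cfg$nesterov, ev - epoch_done, loss_code)
      params[weight_names] <- chunk$params
      vel <- chunk$vel
      last_loss <- chunk$loss
      Hcube <- gru_forward_cpp(params[weight_names], Xc)
      H_off <- vapply(seq_along(offsets), function(i)
        Hcube[, i, offsets[i]], numeric(params$hidden_dim))
    } else {
      for (epoch in (epoch_done + 1L):ev) {
        lg <- gru_loss_grad(params, Xl, Y, cfg$loss_kind)
        for (nm in weight_names) {
          g <- lg$grads[[nm]]
          vel[[nm]] <- cfg$momentum * vel[[nm]] + g
          step <- if (cfg$nesterov) g + cfg$momentum * vel[[nm]] else vel[[nm]]
          params[[nm]] <- params[[nm]] - cfg$learning_rate * step
        }
        last_loss <- lg$loss
      }
      fw <- gru_forward_batch(params, Xl, keep_cache = FALSE)
      H_off <- offset_states(fw$H, offsets)
    }
    epoch_done <- ev
    snap <- learning_snapshot_states(H_off, Y, data$segments)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      epoch = ev, loss = last_loss,
      pct_both = 100 * snap$fractions[["both"]],
      pct_semvis_only = 100 * snap$fractions[["semvis_only"]],
      pct_lex_only = 100 * snap$fractions[["lexical_only"]],
      pct_neither = 100 * snap$fractions[["neither"]])
    lex_hist[[length(lex_hist) + 1L]] <- snap$lexical_correct
    sv_hist[[length(sv_hist) + 1L]] <- snap$semvis_correct
    loss_ok <- is.null(cfg$converge_loss) || !is.finite(cfg$converge_loss) ||
      last_loss <= cfg$converge_loss
    if (100 * snap$fractions[["both"]] >= cfg$converge_pct && loss_ok) {
      streak <- streak + 1L
      if (streak >= cfg$converge_k) break
    } else streak <- 0L
  }
  log_df <- do.call(rbind, log_rows)
  structure(
    list(params = params, segments = data$segments, config = cfg,
         epochs_trained = epoch_done,
         vocab = data$vocab,
         log = log_df,
         lex_correct = do.call(rbind, lex_hist),
         semvis_correct = do.call(rbind, sv_hist)),
    class = "gru_model")
}

# collect the hidden state at each item's offset row from a list of
# per-step state matrices
offset_states <- function(H_list, offsets) {
  N <- ncol(H_list[[1L]])
  out <- matrix(0, nrow(H_list[[1L]]), N)
  for (i in seq_len(N)) out[, i] <- H_list[[offsets[i]]][, i]
  out
}

#' @export
print.gru_model <- function(x, ...) {
  cat(sprintf("GRU model: %d -> %d, trained %d epochs", x$params$input_dim,
              x$params$hidden_dim, x$epochs_trained))
  if (!is.null(x$log) && nrow(x$log))
    cat(sprintf("; final loss %.4g, both-constituent recognition %.1f%%",
                x$log$loss[nrow(x$log)], x$log$pct_both[nrow(x$log)]))
  cat("\n")
  invisible(x)
}

#' Write a training log as TSV
#'
#' Columns: `epoch`, `loss`, `pct_both`, `pct_semvis_only`,
#' `pct_lex_only`, `pct_neither`.
#'
#' @param model a trained `gru_model`.
#' @param path output TSV path.
#' @export
write_training_log <- function(model, path) {
  utils::write.table(model$log, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
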