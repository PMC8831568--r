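# Shallow pattern-recognition networks: a single sigmoid hidden layer
# between the 4096-d feature input and a softmax output (two classes with 9
# hidden units for seizure-risk prediction; 14 classes with 120 hidden
# units for drug identification). Trained full-batch by Adam on the
# cross-entropy loss with early stopping on a validation partition; fully
# deterministic given the seed.

#' Pattern-network specification
#'
#' @param input_dim Input dimension (4096 for fc7-style features).
#' @param hidden_units Sigmoid hidden units (9 for the risk net, 120 for
#'   the drug-identification net).
#' @param n_classes Output classes (>= 2).
#' @param max_iterations Maximum full-batch iterations (default 400).
#' @param min_iterations Iterations trained before early stopping may
#'   trigger (default 75), so that the transient loss oscillation of the
#'   first optimizer steps cannot freeze the network at its initial
#'   weights; the best-validation weights are still tracked from the
#'   first iteration.
#' @param learning_rate Adam step size (default 0.01).
#' @param patience Early-stopping patience: training stops after this many
#'   validation checks without improvement and the best-validation weights
#'   are restored (default 20).
#' @param l2 L2 weight-decay strength on `w1` and `w2` (default 0.02).
#'   Substantial decay keeps the decision regions smooth, which matters for
#'   generalizing to unlearned wells rather than memorizing well-specific
#'   window patterns.
#' @param seed Seed controlling weight initialization (default 1).
#' @return An object of class `pattern_net_spec`.
#' @export
pattern_net_spec <- function(input_dim = 4096, hidden_units = 9,
                             n_classes = 2, max_iterations = 400,
                             min_iterations = 75,
                             learning_rate = 0.01, patience = 20, l2 = 0.02,
                             seed = 1) {
  .assert(hidden_units >= 1, "hidden_units must be >= 1")
  .assert(n_classes >= 2, "n_classes must be >= 2")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_units = as.integer(hidden_units),
                 n_classes = as.integer(n_classes),
                 hidden_activation = "sigmoid", loss = "cross-entropy",
                 max_iterations = as.integer(max_iterations),
                 min_iterations = as.integer(min_iterations),
                 learning_rate = learning_rate,
                 patience = as.integer(patience), l2 = l2,
                 seed = as.integer(seed)),
            class = "pattern_net_spec")
}

#' Specification of the seizure-risk network (4096 -> 9 -> 2)
#' @param seed Seed (see [pattern_net_spec()]).
#' @param ... Overrides passed to [pattern_net_spec()].
#' @return A `pattern_net_spec`.
#' @export
risk_net_spec <- function(seed = 1, ...) {
  pattern_net_spec(hidden_units = 9, n_classes = 2, seed = seed, ...)
}

#' Specification of the drug-identification network (4096 -> 120 -> 14)
#' @param n_classes Number of compound classes (default 14: 13 compounds
#'   plus one pooled seizure-free class).
#' @param seed Seed.
#' @param l2 Weight decay; the multi-class net defaults lower (0.002) than
#'   the risk net because separating 13 mechanism signatures needs more of
#'   the hidden layer's capacity than the binary deviation call.
#' @param ... Overrides passed to [pattern_net_spec()].
#' @return A `pattern_net_spec`.
#' @export
drugid_net_spec <- function(n_classes = 14, seed = 1, l2 = 0.002, ...) {
  pattern_net_spec(hidden_units = 120, n_classes = n_classes, seed = seed,
                   l2 = l2, ...)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

.net_forward <- function(x, w) {
  h <- .sigmoid(sweep(x %*% w$w1, 2, w$b1, "+"))
  p <- .softmax_rows(sweep(h %*% w$w2, 2, w$b2, "+"))
  list(h = h, p = p)
}

.xent <- function(p, y_onehot) -mean(rowSums(y_onehot * log(pmax(p, 1e-12))))

#' Train a pattern-recognition network
#'
#' Full-batch Adam on the softmax cross-entropy (plus L2 weight decay) with
#' Glorot-uniform initialization. The validation partition is evaluated every iteration;
#' training stops once `spec$patience` checks pass without improvement, and
#' the weights of the best validation loss are restored. Two runs with the
#' same data, split and seed produce identical weights.
#'
#' @param x Feature matrix (rows = windows, `spec$input_dim` columns).
#' @param y Class labels (factor or coercible; every class must appear in
#'   the training partition).
#' @param split A [make_dataset_split()] (its `train_idx` / `val_idx` are
#'   used).
#' @param spec A [pattern_net_spec()].
#' @return An object of class `trained_classifier`: weights `w1`
#'   (input x hidden), `b1`, `w2` (hidden x classes), `b2`, the class
#'   `levels`, the `spec`, and a training `log` (iterations run, best
#'   iteration, final train/validation losses).
#' @export
train_pattern_net <- function(x, y, split, spec) {
  .assert(inherits(spec, "pattern_net_spec"), "pattern_net_spec required")
  .assert(is.matrix(x) && ncol(x) == spec$input_dim,
          "x must have %d columns", spec$input_dim)
  .assert(all(is.finite(x)), "non-finite features")
  y <- factor(y)
  .assert(nlevels(y) == spec$n_classes,
          "labels have %d classes but spec declares %d", nlevels(y),
          spec$n_classes)
  tr <- split$train_idx; va <- split$val_idx
  .assert(length(tr) > 0 && length(va) > 0, "empty train or validation partition")
  miss <- setdiff(levels(y), unique(as.character(y[tr])))
  .assert(length(miss) == 0, "class(es) absent from training data: %s",
          paste(miss, collapse = ", "))

  d <- spec$input_dim; h <- spec$hidden_units; k <- spec$n_classes
  w <- withr::with_seed(spec$seed, {
    r1 <- sqrt(6 / (d + h)); r2 <- sqrt(6 / (h + k))
    list(w1 = matrix(stats::runif(d * h, -r1, r1), d, h), b1 = numeric(h),
         w2 = matrix(stats::runif(h * k, -r2, r2), h, k), b2 = numeric(k))
  })
  y1 <- diag(k)[as.integer(y), , drop = FALSE]
  xtr <- x[tr, , drop = FALSE]; ytr <- y1[tr, , drop = FALSE]
  xva <- x[va, , drop = FALSE]; yva <- y1[va, , drop = FALSE]
  ntr <- nrow(xtr)

  m <- lapply(w, function(z) z * 0); v <- m  # Adam moments
  b1t <- 1; b2t <- 1
  beta1 <- 0.9; beta2 <- 0.999; epsa <- 1e-8
  best <- list(loss = Inf, w = w, iter = 0L)
  stall <- 0L
  iter <- 0L
  tr_loss <- NA_real_
  while (iter < spec$max_iterations) {
    iter <- iter + 1L
    fw <- .net_forward(xtr, w)
    tr_loss <- .xent(fw$p, ytr)
    # backprop
    dz2 <- (fw$p - ytr) / ntr
    g <- list(w1 = NULL, b1 = NULL,
              w2 = crossprod(fw$h, dz2) + spec$l2 * w$w2,
              b2 = colSums(dz2))
    dh <- tcrossprod(dz2, w$w2) * fw$h * (1 - fw$h)
    g$w1 <- crossprod(xtr, dh) + spec$l2 * w$w1
    g$b1 <- colSums(dh)
    b1t <- b1t * beta1; b2t <- b2t * beta2
    for (nm in names(w)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- m[[nm]] / (1 - b1t)
      vhat <- v[[nm]] / (1 - b2t)
      w[[nm]] <- w[[nm]] - spec$learning_rate * mhat / (sqrt(vhat) + epsa)
    }
    va_loss <- .xent(.net_forward(xva, w)$p, yva)
    if (va_loss < best$loss - 1e-9) {
      best <- list(loss = va_loss, w = w, iter = iter)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= spec$patience && iter >= spec$min_iterations) break
    }
  }
  structure(list(spec = spec, w1 = best$w$w1, b1 = best$w$b1,
                 w2 = best$w$w2, b2 = best$w$b2, levels = levels(y),
                 log = list(iterations = iter, best_iter = best$iter,
                            train_loss = tr_loss, val_loss = best$loss)),
            class = "trained_classifier")
}

#' Per-window class probabilities of a trained network
#'
#' @param model A [train_pattern_net()] result.
#' @param x Feature matrix with `model$spec$input_dim` columns.
#' @return Probability matrix (rows sum to 1) with one column per class,
#'   named by the class levels.
#' @export
predict_windows <- function(model, x) {
  .assert(inherits(model, "trained_classifier"), "trained_classifier required")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  .assert(ncol(x) == model$spec$input_dim,
          "feature dimension %d does not match the model input %d",
          ncol(x), model$spec$input_dim)
  p <- .net_forward(x, model)$p
  colnames(p) <- model$levels
  p
}
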