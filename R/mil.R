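# Gated attention-based multiple instance learning, trained from scratch.
#
# For a bag with instance features h_k, gated attention scores are
#   s_k = w' ( tanh(V h_k) * sigmoid(U h_k) ),   a = softmax(s),
# the pooled vector is z = sum_k a_k h_k and the slide probability is
# logistic(c'z + b). Training minimizes cross-entropy with hand-derived
# gradients and an Adam optimizer; everything is deterministic given a seed.

#' Initialize a gated-attention MIL model
#'
#' @param D feature dimension.
#' @param hidden attention hidden size (default 64).
#' @param seed seed of the random initialization.
#' @param initSd standard deviation of the Gaussian init of V, U, w; the
#'   classification head starts at zero (probability 0.5).
#' @return An [AttentionMILModel-class].
#' @export
milInit <- function(D, hidden = 64L, seed = 1L, initSd = 0.1) {
  set.seed(seed)
  new("AttentionMILModel",
      V = matrix(stats::rnorm(hidden * D, 0, initSd), hidden, D),
      U = matrix(stats::rnorm(hidden * D, 0, initSd), hidden, D),
      w = stats::rnorm(hidden, 0, initSd),
      headW = rep(0, D), headB = 0, hidden = as.integer(hidden))
}

#' Gated attention weights over a bag
#'
#' @param model an [AttentionMILModel-class].
#' @param bag a [milBag()] or a plain instance matrix (n x D).
#' @return Nonnegative per-instance weights summing to 1, invariant to
#'   instance order.
#' @export
attentionWeights <- function(model, bag) {
  H <- if (is(bag, "Bag")) bag@instances else as.matrix(bag)
  if (nrow(H) < 1L) stop("empty bag")
  Tm <- tanh(H %*% t(model@V))
  Gm <- stats::plogis(H %*% t(model@U))
  s <- as.numeric((Tm * Gm) %*% model@w)
  softmax(s)
}

#' Forward pass of the MIL model
#'
#' Attention-pools the bag and applies the logistic head.
#'
#' @inheritParams attentionWeights
#' @return The slide-level probability in (0, 1).
#' @export
milForward <- function(model, bag) {
  H <- if (is(bag, "Bag")) bag@instances else as.matrix(bag)
  a <- attentionWeights(model, H)
  z <- as.numeric(crossprod(H, a))
  as.numeric(stats::plogis(sum(model@headW * z) + model@headB))
}

# Gradients of the cross-entropy loss of one bag w.r.t. all parameters.
.milBagGrad <- function(model, H, y) {
  Tm <- tanh(H %*% t(model@V))          # n x hidden
  Gm <- stats::plogis(H %*% t(model@U)) # n x hidden
  s <- as.numeric((Tm * Gm) %*% model@w)
  a <- softmax(s)
  z <- as.numeric(crossprod(H, a))
  p <- as.numeric(stats::plogis(sum(model@headW * z) + model@headB))
  g <- p - y                            # dL/dlogit
  dz <- g * model@headW                 # D
  da <- as.numeric(H %*% dz)            # n
  ds <- a * (da - sum(a * da))          # softmax backprop
  dw <- as.numeric(crossprod(Tm * Gm, ds))
  dT <- (ds %o% model@w) * Gm * (1 - Tm^2)   # n x hidden
  dG <- (ds %o% model@w) * Tm * Gm * (1 - Gm)
  list(V = crossprod(dT, H), U = crossprod(dG, H), w = dw,
       headW = g * z, headB = g,
       loss = -(y * log(p + 1e-12) + (1 - y) * log(1 - p + 1e-12)))
}

#' Train the gated-attention MIL model
#'
#' Minimizes bag-level cross-entropy with Adam on shuffled mini-batches of
#' bags. Deterministic given `seed`.
#'
#' @param bags list of [milBag()] objects; both labels must be present.
#' @param epochs training epochs (default 30).
#' @param lr Adam learning rate (default 1e-3).
#' @param batchSize bags per gradient step (default 8).
#' @param hidden attention hidden size (default 64).
#' @param seed seed for initialization and shuffling.
#' @return A trained [AttentionMILModel-class].
#' @export
trainMIL <- function(bags, epochs = 30L, lr = 1e-3, batchSize = 8L,
                     hidden = 64L, seed = 1L) {
  y <- vapply(bags, function(b) b@label, integer(1))
  if (length(unique(y)) < 2L)
    stop("both bag labels must be present to train the MIL model")
  D <- ncol(bags[[1]]@instances)
  model <- milInit(D, hidden = hidden, seed = seed)
  pars <- c("V", "U", "w", "headW", "headB")
  m1 <- lapply(pars, function(p) slot(model, p) * 0)
  m2 <- m1
  names(m1) <- names(m2) <- pars
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  nB <- length(bags)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nB)
    for (start in seq(1L, nB, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, nB)]
      grads <- NULL
      for (i in idx) {
        gi <- .milBagGrad(model, bags[[i]]@instances, y[i])
        if (is.null(grads)) grads <- gi
        else for (p in pars) grads[[p]] <- grads[[p]] + gi[[p]]
      }
      step <- step + 1L
      for (p in pars) {
        gp <- grads[[p]] / length(idx)
        m1[[p]] <- b1 * m1[[p]] + (1 - b1) * gp
        m2[[p]] <- b2 * m2[[p]] + (1 - b2) * gp^2
        mh <- m1[[p]] / (1 - b1^step)
        vh <- m2[[p]] / (1 - b2^step)
        slot(model, p) <- slot(model, p) - lr * mh / (sqrt(vh) + eps)
      }
    }
  }
  model
}

#' Predicted probabilities of a MIL model over bags
#' @param model an [AttentionMILModel-class].
#' @param bags list of bags.
#' @return numeric vector of probabilities.
#' @export
milPredict <- function(model, bags) {
  vapply(bags, function(b) milForward(model, b), numeric(1))
}
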