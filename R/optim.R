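# Minimal Adam optimizer over named lists of parameter arrays. Weight
# decay is applied as classic L2 regularization added to the gradient
# before the moment updates.
adam_init <- function(params, lr, weight_decay = 0, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  zeros <- lapply(params, function(p) p * 0)
  list(lr = lr, wd = weight_decay, beta1 = beta1, beta2 = beta2, eps = eps,
       m = zeros, v = zeros, t = 0L)
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + state$wd * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - state$lr * mh / (sqrt(vh) + state$eps)
  }
  list(state = state, params = params)
}
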