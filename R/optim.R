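# Adam optimiser on the flattened parameter vector.

adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  if (weight_decay > 0) grad <- grad + weight_decay * theta
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad * grad
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(state = state, theta = theta)
}

cosine_lr <- function(base_lr, epoch, epochs, min_frac = 0.01) {
  base_lr * (min_frac + (1 - min_frac) * 0.5 * (1 + cos(pi * (epoch - 1) / max(epochs - 1, 1))))
}
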