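# Adam optimiser over nested lists of parameter arrays.
#
# Parameters are stored as (possibly nested) named lists of numeric
# matrices/vectors; gradients mirror that structure. One optimiser state is
# kept per parameter group.

adam_init <- function(params) {
  list(m = nl_zeros(params), v = nl_zeros(params), t = 0L)
}

#' One Adam update
#'
#' @param params nested list of parameter arrays.
#' @param grads matching nested list of gradients of the loss (the step
#'   moves parameters in the negative gradient direction).
#' @param state optimiser state from [adam_init()].
#' @param lr learning rate.
#' @return list with updated `params` and `state`.
#' @keywords internal
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nl_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- nl_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- nl_map2(state$m, state$v,
                 function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- nl_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}
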