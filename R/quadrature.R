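# Gauss-Hermite nodes and log-weights for weight function exp(-x^2),
# by Golub-Welsch on the Jacobi matrix of the Hermite recurrence.
gauss_hermite <- function(order) {
  stopifnot(order >= 1L)
  if (order == 1L) return(list(nodes = 0, logw = 0.5 * log(pi)))
  off <- sqrt(seq_len(order - 1L) / 2)
  J <- matrix(0, order, order)
  J[cbind(seq_len(order - 1L), seq_len(order - 1L) + 1L)] <- off
  J[cbind(seq_len(order - 1L) + 1L, seq_len(order - 1L))] <- off
  eg <- eigen(J, symmetric = TRUE)
  ord <- order(eg$values)
  list(nodes = eg$values[ord],
       logw = 0.5 * log(pi) + 2 * log(abs(eg$vectors[1L, ord])))
}
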