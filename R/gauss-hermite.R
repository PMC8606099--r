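# Gauss-Hermite quadrature nodes and weights (physicists' convention:
# integral of exp(-z^2) f(z) dz ~ sum w_i f(z_i)), via the Golub-Welsch
# symmetric-tridiagonal eigenproblem. Cached per node count.

gh_cache <- new.env(parent = emptyenv())

gauss_hermite <- function(nodes) {
  nodes <- as.integer(nodes)
  if (nodes < 2L) pm_validation_error("need at least 2 quadrature nodes")
  key <- as.character(nodes)
  if (!is.null(gh_cache[[key]])) return(gh_cache[[key]])
  i <- seq_len(nodes - 1L)
  off <- sqrt(i / 2)
  J <- matrix(0, nodes, nodes)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  z <- e$values[ord]
  w <- sqrt(pi) * e$vectors[1L, ord]^2
  res <- list(nodes = z, weights = w)
  gh_cache[[key]] <- res
  res
}
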