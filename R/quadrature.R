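# Gauss-Legendre rules on (0, 1), cached by node count. Nodes are strictly
# interior, so integrands singular at the lower endpoint (Weibull baseline
# with shape < 1) are never evaluated there.

.gl_cache <- new.env(parent = emptyenv())

gl_rule <- function(n_nodes) {
  key <- as.character(n_nodes)
  rule <- .gl_cache[[key]]
  if (is.null(rule)) {
    rule <- pracma::gaussLegendre(n_nodes, 0, 1)
    names(rule) <- c("x", "w")
    .gl_cache[[key]] <- rule
  }
  rule
}

# single-panel integral of f over [a, b]
gl_integrate <- function(f, a, b, n_nodes) {
  if (b <= a) return(0)
  rule <- gl_rule(n_nodes)
  (b - a) * sum(rule$w * f(a + (b - a) * rule$x))
}
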