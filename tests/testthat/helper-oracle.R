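# independent brute-force oracle for the exact signed-rank p-value:
# literal enumeration of all 2^N sign assignments (N <= ~12)
wilcoxon_brute_force <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  t_plus <- sum(ranks[d > 0])
  t_minus <- sum(ranks[d < 0])
  t_obs <- min(t_plus, t_minus)
  total <- n * (n + 1) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  tp <- as.vector(signs %*% ranks)
  p <- mean(tp <= t_obs + 1e-9) + mean(tp >= total - t_obs - 1e-9)
  list(statistic = t_obs, n = n, p.value = min(1, p))
}

# direct hand evaluation of the BPH equation (substitute, exponentiate,
# ratio) -- kept independent of back_calculate_length()
bph_direct <- function(d, d_final, l_final,
                       l_op = 5.1, d_op = 2.6, b = 3.127, cc = 0.928) {
  (l_op + b * (d - d_op)^cc) * l_final / (l_op + b * (d_final - d_op)^cc)
}

# published Table-style difference vector for the ten Hawaiian turtles
hawaii_differences <- c(0.0, -0.2, -0.4, 0.6, 0.4, -0.8, 0.0, -0.3, -1.5, 0.0)
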