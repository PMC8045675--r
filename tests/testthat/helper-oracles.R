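# Independent brute-force oracles used to cross-check the implementation.

# Benjamini-Hochberg step-up, written directly from the procedure:
# order p ascending, q_(k) = p_(k) * m / k, enforce monotonicity from the
# largest rank down, cap at 1.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (k in (m - 1):1) {
    if (m == 1) break
    q[k] <- min(q[k], q[k + 1])
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# 4-connectivity connected components by explicit flood fill
flood_fill_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (r0 in seq_len(nrow(mask))) for (c0 in seq_len(ncol(mask))) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0))
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      r <- cur[1]; cc <- cur[2]
      if (r < 1 || cc < 1 || r > nrow(mask) || cc > ncol(mask)) next
      if (!mask[r, cc] || lab[r, cc] > 0L) next
      lab[r, cc] <- nxt
      stack <- c(stack, list(c(r - 1, cc), c(r + 1, cc),
                             c(r, cc - 1), c(r, cc + 1)))
    }
  }
  nxt
}

# shipped Turing-capable parameter fixture (spotted regime of the petal
# model at basal drive 0.15)
turing_fixture <- function(sigma_a = 0.15, f = 1) {
  petal_params(sigma_a = sigma_a, f_knockdown = f)
}

# random valid parameter draw for property tests
random_params <- function() {
  network_params(
    sigma_a = stats::runif(1, 0, 1),
    sigma_i = stats::runif(1, 0, 1),
    rho_a = exp(stats::runif(1, log(0.2), log(5))),
    rho_i = exp(stats::runif(1, log(0.2), log(5))),
    mu_a = exp(stats::runif(1, log(0.2), log(5))),
    mu_i = exp(stats::runif(1, log(0.2), log(5))),
    kappa = stats::runif(1, 0, 1),
    n_coop = stats::runif(1, 1, 3),
    f_knockdown = 1
  )
}
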