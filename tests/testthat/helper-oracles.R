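# Independent naive oracles: plain loops over Sigma p*log(p/q), kept free
# of any package internals so they can arbitrate the vectorised code.

naive_entropy <- function(p) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi)
  unname(h)
}

naive_kl <- function(p, q) {
  d <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) d <- d + p[i] * log(p[i] / q[i])
  }
  unname(d)
}

# sample FR via the oracle: -KL(shares || uniform)
naive_fr_sample <- function(f) {
  sh <- f / sum(f)
  -naive_kl(sh, rep(1 / length(f), length(f)))
}

# random positive community + profile on the same species set
random_case <- function(n, n_producers = sample(seq_len(n), 1)) {
  ids <- paste0("sp", seq_len(n))
  a <- as.numeric(stats::runif(n, 0.01, 1))
  com <- community(a, ids)
  f <- numeric(n)
  idx <- sample.int(n, n_producers)
  f[idx] <- stats::runif(n_producers, 0.1, 5)
  list(com = com, prof = functional_profile(f, ids, "F"),
       producers = sort(idx))
}
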