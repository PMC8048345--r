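# Independent oracles and small fixtures, built in code.

# log GAK by exhaustive enumeration of all monotone alignment paths
# (steps right / down / diagonal), summed in log space.  Independent of
# the DP implementation.
enum_gak_logk <- function(xi, xj, sigma, order = 0) {
  lk <- function(q, r) {
    d2 <- sum((xi[q, ] - xj[r, ])^2)
    u <- d2 / (2 * sigma^2)
    v <- -(u + log(2 - exp(-u)))
    if (order > 0) {
      tri <- 1 - abs(q - r) / order
      v <- if (tri > 0) v + log(tri) else -Inf
    }
    v
  }
  m <- nrow(xi); n <- nrow(xj)
  terms <- c()
  rec <- function(q, r, acc) {
    acc <- acc + lk(q, r)
    if (q == m && r == n) {
      terms <<- c(terms, acc)
      return(invisible())
    }
    if (q < m) rec(q + 1, r, acc)
    if (r < n) rec(q, r + 1, acc)
    if (q < m && r < n) rec(q + 1, r + 1, acc)
  }
  rec(1, 1, 0)
  mx <- max(terms)
  if (!is.finite(mx)) return(-Inf)
  mx + log(sum(exp(terms - mx)))
}

# Harrell c-index by brute-force double loop over all ordered pairs.
brute_cindex <- function(time, event, score) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (time[i] < time[j]) {
        den <- den + 1
        num <- num + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
      }
    }
  }
  unname(num / den)
}

# -l(beta) by naive risk-set summation (Breslow ties).
naive_neg_loglik <- function(beta, X, time, event) {
  eta <- drop(X %*% beta)
  s <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1)
      s <- s + eta[i] - log(sum(exp(eta[time >= time[i]])))
  }
  -s
}

# random survival table
rand_surv <- function(n, cens_frac = 0.3, seed = 1) {
  withr::local_seed(seed)
  tt <- rexp(n)
  ev <- as.integer(runif(n) > cens_frac)
  data.frame(patient_id = sprintf("p%03d", seq_len(n)),
             time_days = tt, event = ev, stringsAsFactors = FALSE)
}

surv_table <- function(time, event) {
  data.frame(patient_id = sprintf("p%03d", seq_along(time)),
             time_days = time, event = event, stringsAsFactors = FALSE)
}

# small well-separated series set: n patients, two blobs in gene space
blob_series_set <- function(n = 8, nq = 4, ng = 2, gap = 6, seed = 1) {
  withr::local_seed(seed)
  half <- n %/% 2
  v <- array(rnorm(n * nq * ng, sd = 0.3), dim = c(n, nq, ng))
  v[seq_len(half), , ] <- v[seq_len(half), , ] + gap
  structure(list(values = v,
                 provenance = array("observed", dim = dim(v)),
                 grid = seq_len(nq) - 1,
                 patients = sprintf("p%03d", seq_len(n)),
                 genes = sprintf("g%02d", seq_len(ng))),
            class = "series_set")
}
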