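# Brute-force reference implementations, independent of the package's
# closed-form path: adjusted O_k is recomputed by enumerating every k-subset
# of time steps and summing, over sites, the minimum count within the
# subset; M_k and DC are rebuilt from first principles on top of that.

brute_adjusted <- function(m, k) {
  subs <- utils::combn(nrow(m), k)
  sum(apply(subs, 2, function(idx) {
    sum(apply(m[idx, , drop = FALSE], 2, min))
  }))
}

brute_M <- function(m, k) {
  pop <- rowSums(m)
  sum(utils::combn(nrow(m), k, FUN = function(idx) min(pop[idx])))
}

brute_dc <- function(m) {
  ks <- 2:nrow(m)
  M <- vapply(ks, function(k) brute_M(m, k), numeric(1))
  Oa <- vapply(ks, function(k) brute_adjusted(m, k), numeric(1))
  keep <- M > 0
  mean(Oa[keep] / M[keep])
}

random_survey <- function(y, s, max_count) {
  matrix(sample(0:max_count, y * s, replace = TRUE), nrow = y, ncol = s)
}

# a random matrix with a defined DC (at least two occupied time steps)
random_nonzero_survey <- function(y, s, max_count) {
  repeat {
    m <- random_survey(y, s, max_count)
    if (sum(rowSums(m) > 0) >= 2) return(m)
  }
}
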