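# Independent oracles shared between the module tests and the acceptance
# suite.  Each is written against the contract, not the implementation.

# Second, flat-loop traversal of the recursive model score.
oracle_score <- function(model, test, distance_winner = NA, eps = 1e-6) {
  total <- log(model$prior)
  for (key in names(test)) {
    tn <- test[[key]]
    mn <- model$nodes[[key]]
    if (is.null(mn)) {
      total <- total + log(eps)
    } else {
      tm <- as.numeric(identical(mn$type_key, tn$type_key))
      dt <- exp(-abs(tn$mu_d - mn$mu_d) / sqrt(mn$sigma2_d))
      xt <- if (tn$level == 1L && !is.na(distance_winner))
        as.numeric(distance_winner) else 1
      total <- total + log(max(tm * dt * xt, eps))
    }
  }
  total
}

# Exhaustive-permutation assignment optimum for a counts matrix.
brute_best_assignment <- function(m) {
  n <- max(dim(m))
  sq <- matrix(0L, n, n)
  sq[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  max(vapply(perms(seq_len(n)), function(p)
    sum(sq[cbind(seq_len(n), p)]), numeric(1)))
}
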