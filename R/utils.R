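# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Seeded, deterministic k-means with multiple restarts.  Falls back to the
# trivial partition when k equals the number of distinct rows.
seeded_kmeans <- function(x, k, seed, nstart = 10L, iter.max = 100L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds the number of points (", n, ")")
  ux <- unique(x)
  if (k > nrow(ux)) {
    stop("k (", k, ") exceeds the number of distinct points (", nrow(ux), ")")
  }
  if (k == 1L) {
    centers <- matrix(colMeans(x), 1L, ncol(x))
    cl <- rep(1L, n)
    return(list(centers = centers, cluster = cl,
                tot.withinss = sum(sweep(x, 2L, centers[1L, ])^2)))
  }
  with_seed(seed, {
    fit <- suppressWarnings(
      stats::kmeans(x, centers = k, nstart = nstart, iter.max = iter.max)
    )
    list(centers = unname(fit$centers), cluster = fit$cluster,
         tot.withinss = fit$tot.withinss)
  })
}

# Per-axis standard deviation (population, denominator n) of rows of x.
pop_sd <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sqrt(colMeans(sweep(x, 2L, mu)^2))
}

# Population variance with denominator n (expectation form).
pop_var <- function(v) {
  mean((v - mean(v))^2)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)
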