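#' Sample-splitting configuration
#'
#' Holds the cross-fitting layout: the number of test folds \code{K}, the
#' fractions \code{c = (c1, c2, c3)} by which each fold's complement is split
#' into the screening, score-combination and orthogonalization parts, and the
#' seed that makes the split reproducible.
#'
#' @param K integer number of test folds, at least 2. Default 4.
#' @param fractions numeric triple of positive fractions summing to 1
#'   (default \code{c(1/3, 1/3, 1/3)}).
#' @param seed integer seed for the permutation.
#' @param floor minimum viable part size; \code{make_fold_plan} refuses plans
#'   whose smallest part would fall below it. Default 50.
#' @return An object of class \code{"split_config"}.
#' @export
split_config <- function(K = 4, fractions = c(1/3, 1/3, 1/3), seed = 1,
                         floor = 50) {
  K <- as.integer(K)
  if (K < 2) stop("K must be at least 2")
  if (length(fractions) != 3 || any(fractions <= 0))
    stop("fractions must be 3 positive numbers")
  if (abs(sum(fractions) - 1) > 1e-12)
    stop("fractions must sum to 1")
  structure(list(K = K, fractions = fractions, seed = as.integer(seed),
                 floor = as.integer(floor)),
            class = "split_config")
}

# Largest-remainder apportionment of `total` into parts proportional to
# `fractions`; ties in the remainders go to the lower part index.
apportion <- function(total, fractions) {
  quota <- total * fractions
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    rem <- quota - base
    # order(): ties broken by position, i.e. lower index wins
    give <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Build the cross-fitting fold plan
#'
#' Randomly permutes the \code{n} samples (under the config seed), cuts them
#' into \code{K} test folds \eqn{I_k} of size \eqn{\lfloor n/K\rfloor} or
#' \eqn{\lceil n/K\rceil}, and partitions each fold's complement into three
#' disjoint parts \eqn{C1_k, C2_k, C3_k} sized by largest-remainder
#' apportionment of the fractions (remainder ties to the lower part index).
#' Every sample lands in exactly one test fold, so each contributes exactly
#' once to the final statistic.
#'
#' @param n number of samples.
#' @param config a \code{\link{split_config}}.
#' @return An object of class \code{"fold_plan"}: list with \code{K},
#'   \code{n}, and \code{folds}, each fold holding integer index vectors
#'   \code{test}, \code{c1}, \code{c2}, \code{c3}.
#' @export
make_fold_plan <- function(n, config = split_config()) {
  K <- config$K
  min_need <- K * config$floor
  if (n < min_need)
    stop("n = ", n, " too small for K = ", K,
         " folds with floor ", config$floor, "; need at least ", min_need)
  perm <- with_seed(config$seed, sample.int(n))
  # contiguous blocks of the permutation, sizes floor(n/K) or ceiling(n/K)
  sizes <- apportion(n, rep(1 / K, K))
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1) + 1L)
  folds <- vector("list", K)
  for (k in seq_len(K)) {
    test_k <- sort(perm[starts[k]:stops[k]])
    comp <- sort(perm[-(starts[k]:stops[k])])
    part_sizes <- apportion(length(comp), config$fractions)
    # permute the complement (deterministically per fold) before cutting
    cperm <- with_seed(config$seed + k, sample(comp))
    cstop <- cumsum(part_sizes)
    cstart <- c(1L, head(cstop, -1) + 1L)
    part <- function(i) {
      if (part_sizes[i] == 0) return(integer(0))
      sort(cperm[cstart[i]:cstop[i]])
    }
    folds[[k]] <- list(test = test_k, c1 = part(1), c2 = part(2), c3 = part(3))
  }
  structure(list(K = K, n = n, folds = folds, config = config),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold plan: n = %d, K = %d; test fold sizes %s\n", x$n, x$K,
              paste(vapply(x$folds, function(f) length(f$test), 1L),
                    collapse = ", ")))
  invisible(x)
}

#' Serialize a fold plan to JSON
#'
#' Writes the index lists of every fold for audit.
#' @param plan a \code{\link{make_fold_plan}} result.
#' @param path output path.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(list(
    n = plan$n, K = plan$K,
    folds = lapply(plan$folds, function(f)
      list(test = f$test, c1 = f$c1, c2 = f$c2, c3 = f$c3))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Run `expr` under a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child seed for a named substream, kept within 32-bit range.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
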