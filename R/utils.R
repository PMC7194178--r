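#' @import data.table
#' @importFrom stats phyper rbinom rnorm runif setNames cor ks.test p.adjust
#' @importFrom utils combn head packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable integer hash of a seed and a label
#'
#' Derives a reproducible sub-seed from a master seed and a character label,
#' so that independent RNG streams (one per phenotype combination, one per
#' generator stage) do not depend on evaluation order. Polynomial rolling
#' hash modulo the Mersenne prime 2^31 - 1; the result is always a valid
#' `set.seed()` argument.
#'
#' @param seed Integer master seed.
#' @param label Character scalar.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
stable_hash <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  h <- as.double(abs(as.integer(seed))) %% 2147483647
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' All phenotype combinations of a minimum size
#'
#' @param labels Character vector of phenotype labels.
#' @param min_size Smallest combination size (default 2).
#' @return List of character vectors, in the order of `labels`.
#' @export
all_combinations <- function(labels, min_size = 2L) {
  stopifnot(length(labels) >= min_size)
  out <- list()
  for (k in seq.int(min_size, length(labels))) {
    out <- c(out, combn(labels, k, simplify = FALSE))
  }
  out
}

#' Canonical combination label, "A:B:C"
#' @param members Character vector of phenotype labels.
#' @export
combo_label <- function(members) paste(members, collapse = ":")

#' Split a combination label back into its members
#' @param label A label like "GS:MS".
#' @export
parse_combo <- function(label) strsplit(label, ":", fixed = TRUE)[[1L]]

# canonical fragment-pair orientation: lexicographically smaller id first
canonical_pair <- function(a, b) {
  list(a = pmin(a, b), b = pmax(a, b))
}

assert_prob <- function(x, name, open_zero = TRUE) {
  bad <- if (open_zero) any(x <= 0 | x > 1) else any(x < 0 | x > 1)
  if (any(!is.finite(x)) || bad) {
    rng <- if (open_zero) "(0, 1]" else "[0, 1]"
    stop(sprintf("`%s` must lie in %s", name, rng), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x != round(x))) {
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  }
  invisible(x)
}
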