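#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor rnorm runif sd median quantile pt t.test kruskal.test
#'   wilcox.test aggregate
#' @importFrom utils head tail write.csv
NULL

# Clip values into [0, 1]; images throughout the package live on a normalized
# brightness scale so a fixed threshold like 0.4 is image-independent.
clamp01 <- function(x) pmin(pmax(x, 0), 1)

stop_if_not_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix (row, col)", name), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  as.integer(seed)
}

# Linear index <-> (row, col) helpers for column-major matrices.
idx_to_rc <- function(idx, nr) {
  cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
}
rc_to_idx <- function(row, col, nr) {
  (col - 1L) * nr + row
}
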