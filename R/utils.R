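#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange mutate filter select group_by summarise ungroup
#'   bind_rows left_join n across all_of row_number
#' @importFrom stats dgamma sd var pt rnorm runif uniroot convolve p.adjust
#'   lm.fit setNames
NULL

#' The six experimental condition labels
#'
#' Conditions cross three actions (precision grasp PG, whole-hand grasp WHG,
#' reaching-only R) with two object sizes (S small, L large).
#'
#' @return Character vector `c("PGS", "PGL", "WHGS", "WHGL", "RS", "RL")`.
#' @export
grasp_conditions <- function() {
  c("PGS", "PGL", "WHGS", "WHGL", "RS", "RL")
}

#' Derive a child seed from a master seed
#'
#' Hierarchical seeding: one master seed spawns deterministic per-subject and
#' per-run streams, so adding subjects or regions never perturbs the draws of
#' earlier ones. Pure 32-bit-safe integer arithmetic (Lehmer-style mixing).
#'
#' @param seed Integer master seed.
#' @param ... Further integer keys (subject index, run index, ...), folded in
#'   order.
#' @return A single integer in `[1, 2^31 - 2]`, or `NULL` if `seed` is `NULL`.
#' @export
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  keys <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in keys) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s) + 1L
}

# Run a draw under a temporary seed when one is supplied; otherwise use the
# ambient RNG state.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x) && x >= 1
}
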