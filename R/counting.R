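# Exact combinatorial counts of discrete optical layouts. The products grow
# far beyond 2^53, so they are carried in exact arbitrary precision (base-1e4
# digit vectors); base R has no big-integer type.

big_from_int <- function(n) {
  stopifnot(n >= 0, n == floor(n))
  if (n == 0) return(0L)
  d <- integer(0)
  while (n > 0) { d <- c(d, n %% 10000L); n <- n %/% 10000L }
  d
}

big_mul_small <- function(b, m) {
  carry <- 0
  out <- integer(length(b))
  for (i in seq_along(b)) {
    v <- b[i] * m + carry
    out[i] <- v %% 10000L
    carry <- v %/% 10000L
  }
  while (carry > 0) { out <- c(out, carry %% 10000L); carry <- carry %/% 10000L }
  out
}

big_to_string <- function(b) {
  n <- length(b)
  paste0(b[n], paste(sprintf("%04d", rev(b[-n])), collapse = ""))
}

big_to_double <- function(b) sum(b * 10000^(seq_along(b) - 1))

#' Number of discrete optical layouts of a grid ansatz
#'
#' Counts the discrete arrangements reachable by snapping the continuous
#' parameters of a grid ansatz to extreme settings: each beam splitter may
#' transmit, reflect, or split (`bs_states` choices, default 3), and every
#' SLM panel and wave plate may be switched on or off (2 choices each). The
#' exact value `bs_states^n_bs * 2^n_slm * 2^n_wp` is returned in arbitrary
#' precision, since it overflows doubles already for the default 3 x 3
#' ansatz (9 splitters, 48 panels, 24 plates).
#'
#' @param n_bs,n_slm,n_wp Non-negative element counts (beam splitter nodes,
#'   SLM panels, wave plates).
#' @param bs_states Discrete settings per beam splitter (default 3).
#' @return An `ol_layout_count`: list with the exact decimal `string`, a
#'   double `approx`, and `log10`.
#' @examples
#' count_discrete_layouts(1, 1, 1)  # 12
#' @export
count_discrete_layouts <- function(n_bs, n_slm, n_wp, bs_states = 3L) {
  stopifnot(n_bs >= 0, n_slm >= 0, n_wp >= 0, bs_states >= 1)
  b <- big_from_int(1)
  for (i in seq_len(n_bs)) b <- big_mul_small(b, bs_states)
  for (i in seq_len(n_slm + n_wp)) b <- big_mul_small(b, 2L)
  layout_count(b)
}

#' Number of discrete arrangements of typed optical elements
#'
#' The elementary search-space count for a table of `n_elements` element
#' slots, each chosen from `n_types` component types:
#' `n_types ^ n_elements`. Ten elements over five types already gives
#' about ten million arrangements.
#'
#' @param n_elements Number of element slots.
#' @param n_types Number of available component types.
#' @return An `ol_layout_count`.
#' @export
count_arrangements <- function(n_elements, n_types) {
  stopifnot(n_elements >= 0, n_types >= 1)
  b <- big_from_int(1)
  for (i in seq_len(n_elements)) b <- big_mul_small(b, n_types)
  layout_count(b)
}

layout_count <- function(b) {
  s <- big_to_string(b)
  structure(list(string = s, approx = big_to_double(b),
                 log10 = log10(big_to_double(b))),
            class = "ol_layout_count")
}

#' @export
print.ol_layout_count <- function(x, ...) {
  cat(sprintf("<layout count> %s (~%.3g)\n", x$string, x$approx))
  invisible(x)
}

#' @export
as.numeric.ol_layout_count <- function(x, ...) x$approx
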