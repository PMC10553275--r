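#' Public goods payoffs for one group
#'
#' Every cooperator in the group invests `cost`; the pooled investment is
#' multiplied by the enhancement factor `r` and shared equally among all
#' `k` group members (cooperators and defectors alike). An individual playing
#' alone still "plays": a lone cooperator nets `cost * (r - 1)`, a lone
#' defector nets 0.
#'
#' The net production of a group is `(r - 1) * cost * k_C` where `k_C` is the
#' cooperator count; the within-group cooperator-defector gap is
#' `cost * (1 - r / k)`, positive whenever `k > r`.
#'
#' @param strategies Character vector of `"C"` / `"D"` (or a logical vector,
#'   `TRUE` = cooperator), one entry per group member. Must be non-empty.
#' @param r Enhancement factor (> 1).
#' @param cost Cooperator investment per round (positive).
#' @return Numeric vector of payoffs, same order as `strategies`.
#' @examples
#' pgg_payoffs(c("C", "D"), r = 3, cost = 0.1) # 0.05, 0.15
#' @export
pgg_payoffs <- function(strategies, r, cost) {
  if (length(strategies) == 0L) stop("empty group: no payoffs defined",
                                     call. = FALSE)
  is_c <- as_cooperator(strategies)
  k <- length(is_c)
  k_c <- sum(is_c)
  r * cost * k_c / k - cost * is_c
}

#' Payoff of a focal individual given its co-players
#'
#' Vectorised closed form of the same game as [pgg_payoffs()], parameterised
#' the way the Poisson theory uses it: a focal cooperator with `n_C`
#' cooperators and `n_D` defectors *besides itself* earns
#' `r * cost * (1 + n_C) / (1 + n_C + n_D) - cost`; a focal defector earns
#' `r * cost * n_C / (1 + n_C + n_D)`.
#'
#' @param cooperator Logical vector: is the focal individual a cooperator?
#' @param n_C,n_D Non-negative integer vectors: other cooperators / defectors
#'   sharing the focal individual's site.
#' @inheritParams pgg_payoffs
#' @return Numeric vector of focal payoffs.
#' @export
pgg_focal_payoff <- function(cooperator, n_C, n_D, r, cost) {
  if (any(n_C < 0) || any(n_D < 0)) stop("negative co-player counts",
                                         call. = FALSE)
  k <- 1 + n_C + n_D
  r * cost * (n_C + cooperator) / k - cost * cooperator
}

# Accept "C"/"D", factor, or logical encodings of strategies.
as_cooperator <- function(strategies) {
  if (is.logical(strategies)) return(strategies)
  s <- as.character(strategies)
  bad <- !s %in% c("C", "D")
  if (any(bad)) stop("strategies must be \"C\" or \"D\"", call. = FALSE)
  s == "C"
}
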