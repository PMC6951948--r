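#' Structural constraints on the transition generator
#'
#' Builds the permitted-transition structure of a progression model. The
#' structure determines which instantaneous transitions between hidden
#' disease states are allowed:
#'
#' * `"full"`: any state can move to any other (progression and recovery);
#' * `"forward"`: only transitions to strictly later states (no recovery);
#' * `"forward_chain"`: only jumps to the next `order` states, i.e.
#'   transitions `i -> j` with `i < j <= i + order`.
#'
#' With `absorbing_last = TRUE` the last state has no outgoing transitions:
#' once entered it is never left, which models a terminal disease stage.
#'
#' @param num_states number of hidden states `M` (at least 2).
#' @param kind one of `"full"`, `"forward"`, `"forward_chain"`.
#' @param order for `"forward_chain"`, the chain order `L`
#'   (`1 <= L <= M - 1`); ignored otherwise.
#' @param absorbing_last make the last state absorbing.
#'
#' @return An object of class `cthmm_mask` with components `num_states`,
#'   `kind`, `order`, `allowed` (an `M x M` logical matrix, diagonal always
#'   `FALSE`) and `absorbing` (logical vector of length `M`).
#'
#' @examples
#' structure_mask(9, "forward_chain", order = 2, absorbing_last = TRUE)
#' @export
structure_mask <- function(num_states,
                           kind = c("forward_chain", "forward", "full"),
                           order = 2L,
                           absorbing_last = FALSE) {
  kind <- match.arg(kind)
  if (!is.numeric(num_states) || length(num_states) != 1L ||
      num_states != round(num_states) || num_states < 2) {
    stop("'num_states' must be a single integer >= 2", call. = FALSE)
  }
  M <- as.integer(num_states)
  if (kind == "forward_chain") {
    if (!is.numeric(order) || length(order) != 1L ||
        order != round(order) || order < 1 || order > M - 1) {
      stop("'order' must be an integer in [1, num_states - 1]",
           call. = FALSE)
    }
    order <- as.integer(order)
  } else {
    order <- NA_integer_
  }

  i <- row(diag(M))
  j <- col(diag(M))
  allowed <- switch(kind,
    full          = i != j,
    forward       = j > i,
    forward_chain = j > i & j <= i + order
  )
  absorbing <- rep(FALSE, M)
  if (isTRUE(absorbing_last)) {
    absorbing[M] <- TRUE
  }
  allowed[absorbing, ] <- FALSE

  structure(
    list(num_states = M, kind = kind, order = order,
         allowed = allowed, absorbing = absorbing),
    class = "cthmm_mask"
  )
}

#' @export
print.cthmm_mask <- function(x, ...) {
  ord <- if (is.na(x$order)) "" else sprintf(" (order %d)", x$order)
  cat(sprintf("CTHMM structure mask: %d states, %s%s\n",
              x$num_states, x$kind, ord))
  if (any(x$absorbing)) {
    cat("  absorbing state(s):", which(x$absorbing), "\n")
  }
  cat(sprintf("  %d allowed instantaneous transitions\n", sum(x$allowed)))
  invisible(x)
}

is_cthmm_mask <- function(x) inherits(x, "cthmm_mask")

stopifnot_mask <- function(mask) {
  if (!is_cthmm_mask(mask)) {
    stop("expected a 'cthmm_mask' object (see structure_mask())",
         call. = FALSE)
  }
  invisible(mask)
}
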