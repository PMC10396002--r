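# Necklace table: circular doubly linked ring over the occupied bins of a
# histogram column, so traversal skips empty bins entirely. The C++ filter
# backend embeds the same structure; this R version is the testable
# reference of its invariants (insert/delete O(1), traversal visits exactly
# the occupied bins).

#' Create an empty necklace table over `n` bins
#'
#' @param n number of bins (ring capacity).
#' @return a `necklace` object (environment with ring state).
#' @keywords internal
#' @export
necklace_new <- function(n) {
  nt <- new.env(parent = emptyenv())
  nt$n <- as.integer(n)
  sent <- n + 1L # sentinel node
  nt$nxt <- c(rep(NA_integer_, n), sent)
  nt$prv <- c(rep(NA_integer_, n), sent)
  nt$member <- rep(FALSE, n)
  class(nt) <- "necklace"
  nt
}

#' Insert a bin (1-based) into the ring
#' @param nt a [necklace_new()] object.
#' @param f bin index.
#' @keywords internal
#' @export
necklace_insert <- function(nt, f) {
  stopifnot(f >= 1L, f <= nt$n)
  if (nt$member[f]) return(invisible(nt))
  sent <- nt$n + 1L
  h <- nt$nxt[sent]
  nt$nxt[sent] <- f; nt$prv[f] <- sent
  nt$nxt[f] <- h;    nt$prv[h] <- f
  nt$member[f] <- TRUE
  invisible(nt)
}

#' Delete a bin from the ring
#' @inheritParams necklace_insert
#' @keywords internal
#' @export
necklace_delete <- function(nt, f) {
  stopifnot(f >= 1L, f <= nt$n)
  if (!nt$member[f]) return(invisible(nt))
  nt$nxt[nt$prv[f]] <- nt$nxt[f]
  nt$prv[nt$nxt[f]] <- nt$prv[f]
  nt$nxt[f] <- NA_integer_; nt$prv[f] <- NA_integer_
  nt$member[f] <- FALSE
  invisible(nt)
}

#' Traverse the ring, returning the member bins in ring order
#' @inheritParams necklace_insert
#' @return integer vector of occupied bin indices.
#' @keywords internal
#' @export
necklace_traverse <- function(nt) {
  sent <- nt$n + 1L
  out <- integer(0)
  f <- nt$nxt[sent]
  while (f != sent) {
    out <- c(out, f)
    f <- nt$nxt[f]
  }
  out
}
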