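#' Build the forbidden-order machinery for a repeat problem
#'
#' The order between the two regions of two co-selected repeats is
#' constrained: direct repeats may interleave but not nest, inverted repeats
#' may nest but not cross.  The ILP encodes the *forbidden* orders.  For
#' every ordered fragment pair `((i, j), (k, l))` the comparison set `Alpha`
#' holds the vertex couples whose relative circuit positions must be
#' compared — 6 couples for DR (`(i,j), (k,l), (i,k), (j,l), (i,l), (j,k)`),
#' 4 for IR (`(i,k), (i,l), (j,k), (j,l)`) — and the `Forbid` set holds the
#' vertex quartets realising a forbidden total order.  The quartet patterns
#' are `(i,k,l,j)`/`(k,i,j,l)` for DR (nesting) and `(i,k,j,l)`/`(k,i,l,j)`
#' for IR (crossing), instantiated for both within-fragment assignments of
#' `(i, j)` and of `(k, l)` — the circuit is free to traverse either side of
#' a fragment first, so all eight orders per pair must be excluded.
#'
#' A comparison `alpha[v, u]` that is not stored is expressed as
#' `1 - alpha[u, v]` when constraints are emitted.
#'
#' @param fs a [fragment_sets][build_fragment_sets] object.
#' @return An object of class `order_sets`: list with `alpha` (data frame
#'   `u`, `v`) and `forbid` (data frame `a`, `b`, `c`, `d`, `pair` — the
#'   quartet, in forbidden order, and the index of the generating fragment
#'   pair in `fs$pairs`).
#' @export
build_order_sets <- function(fs) {
  stopifnot(inherits(fs, "fragment_sets"))
  empty <- structure(list(alpha = data.frame(u = integer(), v = integer()),
                          forbid = data.frame(a = integer(), b = integer(),
                                              c = integer(), d = integer(),
                                              pair = integer())),
                     class = "order_sets")
  if (nrow(fs$pairs) == 0) return(empty)
  i <- fs$frags$v1[fs$pairs$a]
  j <- fs$frags$v2[fs$pairs$a]
  k <- fs$frags$v1[fs$pairs$b]
  l <- fs$frags$v2[fs$pairs$b]

  if (fs$kind == "DR") {
    alpha <- data.frame(u = c(i, k, i, j, i, j),
                        v = c(j, l, k, l, l, k))
  } else {
    alpha <- data.frame(u = c(i, i, j, j),
                        v = c(k, l, k, l))
  }
  alpha <- alpha[!duplicated(paste(alpha$u, alpha$v)), , drop = FALSE]
  rownames(alpha) <- NULL

  np <- length(i)
  pair_id <- seq_len(np)
  quartets <- vector("list", 8L)
  qi <- 0L
  for (asn in list(list(i, j), list(j, i))) {
    for (bsn in list(list(k, l), list(l, k))) {
      ii <- asn[[1]]; jj <- asn[[2]]; kk <- bsn[[1]]; ll <- bsn[[2]]
      if (fs$kind == "DR") {
        q1 <- data.frame(a = ii, b = kk, c = ll, d = jj, pair = pair_id)
        q2 <- data.frame(a = kk, b = ii, c = jj, d = ll, pair = pair_id)
      } else {
        q1 <- data.frame(a = ii, b = kk, c = jj, d = ll, pair = pair_id)
        q2 <- data.frame(a = kk, b = ii, c = ll, d = jj, pair = pair_id)
      }
      quartets[[qi + 1L]] <- q1
      quartets[[qi + 2L]] <- q2
      qi <- qi + 2L
    }
  }
  forbid <- do.call(rbind, quartets)
  forbid <- forbid[!duplicated(forbid), , drop = FALSE]
  rownames(forbid) <- NULL
  structure(list(alpha = alpha, forbid = forbid), class = "order_sets")
}
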