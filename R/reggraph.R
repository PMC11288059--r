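## Region multidigraph and Eulerian-circuit enumeration of genome forms.

#' Build the region graph of a decomposition
#'
#' The region graph is a directed multigraph with one vertex per oriented
#' region (both orientations of every COR entry, so `|Vreg| = 2 |COR|`)
#' and, for every circular adjacency in `SOR`, one edge plus its reverse
#' (`|Ereg| = 2 |SOR|`): the reverse of an edge `(u, v)` runs from the
#' reverse of `v` to the reverse of `u`.  The reverse pairing is a perfect
#' matching on the edge multiset.
#'
#' @param d a [region_decomposition][extract_regions].
#' @return An object of class `region_graph`: list with `nreg`, `vertices`
#'   (data frame `rid`, `ror`), `edges` (data frame `from`, `to` vertex
#'   ids, `pair` reverse-pair id) and `start` (vertex id of region 1
#'   forward).
#' @export
build_region_graph <- function(d) {
  q <- length(d$COR)
  n <- nrow(d$SOR)
  # vertex id: rid forward = rid, reverse = q + rid
  vx <- function(rid, ror) ifelse(ror == "f", rid, q + rid)
  vertices <- data.frame(rid = rep(seq_len(q), 2),
                         ror = rep(c("f", "r"), each = q))
  nxt <- c(seq_len(n)[-1], 1L)
  from <- vx(d$SOR$rid, d$SOR$ror)
  to <- vx(d$SOR$rid[nxt], d$SOR$ror[nxt])
  rfrom <- vx(d$SOR$rid[nxt], flip_orient(d$SOR$ror[nxt]))
  rto <- vx(d$SOR$rid, flip_orient(d$SOR$ror))
  edges <- data.frame(from = c(from, rfrom), to = c(to, rto),
                      pair = rep(seq_len(n), 2))
  structure(list(nreg = q, vertices = vertices, edges = edges,
                 start = vx(1L, "f"), decomposition = d),
            class = "region_graph")
}

#' Enumerate all genome forms of a region graph
#'
#' A genome form is an Eulerian circuit of the region graph that starts
#' and ends at the starter's region in forward orientation and uses
#' exactly one member of every reverse edge pair.  All such circuits are
#' enumerated by deterministic backtracking (edges tried in sorted target
#' order), and circuits yielding an identical oriented-region sequence are
#' reported once.  The number of forms is bounded by `2^m'` with `m'` the
#' number of inverted repeats; the decomposition's own `SOR` is always
#' among the results.
#'
#' @param rg a [region_graph][build_region_graph].
#' @return List of data frames (`rid`, `ror`), one per genome form, each
#'   of length `nrow(SOR)`.
#' @export
enumerate_genome_forms <- function(rg) {
  q <- rg$nreg
  n <- max(rg$edges$pair)
  # order candidate edges deterministically by (target rid, target ror)
  ord <- order(rg$edges$to, rg$edges$pair, method = "radix")
  edges <- rg$edges[ord, , drop = FALSE]
  out_by_vertex <- split(seq_len(nrow(edges)), factor(edges$from, levels = seq_len(2L * q)))

  forms <- list()
  used <- rep(FALSE, n)
  path <- integer(n)  # path[t]: vertex reached after t edges

  walk <- function(v, nused) {
    if (nused == n) {
      if (v == rg$start) forms[[length(forms) + 1L]] <<- path
      return(invisible())
    }
    for (ei in out_by_vertex[[v]]) {
      p <- edges$pair[ei]
      if (used[p]) next
      used[p] <<- TRUE
      path[nused + 1L] <<- edges$to[ei]
      walk(edges$to[ei], nused + 1L)
      used[p] <<- FALSE
    }
  }
  walk(rg$start, 0L)
  # a form is the vertex sequence (start, path[1..n-1]); path[n] == start
  decode <- function(p) {
    vids <- c(rg$start, p[-n])
    data.frame(rid = ifelse(vids > q, vids - q, vids),
               ror = ifelse(vids > q, "r", "f"),
               stringsAsFactors = FALSE)
  }
  res <- lapply(forms, decode)
  keys <- vapply(res, function(f) paste(f$rid, f$ror, collapse = ";"),
                 character(1))
  res[!duplicated(keys)]
}

#' Oriented-contig sequence of a genome form
#'
#' Concatenates the regions of a form into a full oriented-contig
#' sequence; regions referenced in reverse are reversed (contig order
#' flipped, orientations flipped).
#'
#' @param form one element of [enumerate_genome_forms] (data frame
#'   `rid`, `ror`).
#' @param COR the forward regions of the decomposition, or the
#'   decomposition itself.
#' @return Data frame with columns `contig`, `or`.
#' @export
form_to_contigs <- function(form, COR) {
  if (inherits(COR, "region_decomposition")) {
    return(flatten_regions(COR, SOR = form))
  }
  flatten_regions(list(COR = COR), SOR = form)
}

#' @export
print.region_graph <- function(x, ...) {
  cat("Region graph: |Vreg| =", 2L * x$nreg, ", |Ereg| =", nrow(x$edges), "\n")
  invisible(x)
}
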