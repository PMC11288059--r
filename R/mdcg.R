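#' Build the multiplied doubled contig graph (MDCG)
#'
#' The MDCG has one vertex per (contig, orientation, occurrence) triple —
#' every contig `c` contributes `2 * mult(c)` vertices — and one edge per
#' multiplied link: a link between oriented contigs `(c, d)` expands to
#' `mult(c) * mult(d)` edges over all occurrence pairs, keeping the link's
#' orientations.  Hence `|V| = 2 * sum(mult)` and
#' `|E| = sum over links of mult(c) * mult(d)`.  The edge set is closed
#' under the reversal `(u, v) -> (rev(v), rev(u))` because the link set is.
#'
#' Occurrence numbers are 0-based.  The starter vertex is the starter
#' contig's forward occurrence 0; its reverse is banned from every circuit.
#'
#' @param input a [scaffold_input] object.
#' @return An object of class `mdcg`: a list with the vertex table `vdf`
#'   (columns `contig`, `cidx`, `or` (0 = forward, 1 = reverse), `occ`,
#'   `wex`), the edge table `edges` (vertex indices `u`, `v`), the reverse
#'   vertex map `rev`, adjacency lists `out_edges` / `in_edges`, the
#'   starter vertex index `starter_v` and its reverse `starter_rbar`, and
#'   the contig table with the strict total order rank used for repeat
#'   machinery.
#' @examples
#' inp <- generate_perfect(2, 2)
#' g <- build_mdcg(inp)
#' c(nrow(g$vdf), nrow(g$edges))
#' @export
build_mdcg <- function(input) {
  stopifnot(inherits(input, "scaffold_input"))
  contigs <- input$contigs
  # strict total order on contigs: byte-wise (C locale) lexicographic rank
  contigs$rank <- match(contigs$id, sort(contigs$id, method = "radix"))
  m <- contigs$mult
  nc <- nrow(contigs)
  off <- c(0L, cumsum(2L * m))[seq_len(nc)]
  nV <- sum(2L * m)

  cidx <- rep.int(seq_len(nc), 2L * m)
  or <- unlist(lapply(m, function(k) rep(c(0L, 1L), each = k)), use.names = FALSE)
  occ <- unlist(lapply(m, function(k) c(seq_len(k), seq_len(k)) - 1L), use.names = FALSE)
  vdf <- data.frame(contig = contigs$id[cidx], cidx = cidx, or = or, occ = occ,
                    wex = contigs$wex[cidx], stringsAsFactors = FALSE)

  # vertex id arithmetic: off[cidx] + or * mult + occ + 1
  vid <- function(ci, orient, occurrence) {
    off[ci] + orient * m[ci] + occurrence + 1L
  }
  rev_map <- vid(cidx, 1L - or, occ)

  links <- input$links
  lc1 <- match(links$c1, contigs$id)
  lc2 <- match(links$c2, contigs$id)
  lo1 <- as.integer(links$o1 == "r")
  lo2 <- as.integer(links$o2 == "r")
  nmul <- m[lc1] * m[lc2]
  if (nrow(links)) {
    li <- rep.int(seq_len(nrow(links)), nmul)
    occ_u <- unlist(lapply(seq_len(nrow(links)), function(i) {
      rep(seq_len(m[lc1[i]]) - 1L, each = m[lc2[i]])
    }), use.names = FALSE)
    occ_v <- unlist(lapply(seq_len(nrow(links)), function(i) {
      rep(seq_len(m[lc2[i]]) - 1L, times = m[lc1[i]])
    }), use.names = FALSE)
    eu <- vid(lc1[li], lo1[li], occ_u)
    ev <- vid(lc2[li], lo2[li], occ_v)
  } else {
    eu <- ev <- integer()
  }
  edges <- data.frame(u = eu, v = ev)
  nE <- nrow(edges)
  ekey <- (as.double(edges$u) - 1) * nV + as.double(edges$v)
  stopifnot(!anyDuplicated(ekey))

  out_edges <- split(seq_len(nE), factor(edges$u, levels = seq_len(nV)))
  in_edges <- split(seq_len(nE), factor(edges$v, levels = seq_len(nV)))

  sci <- match(input$starter, contigs$id)
  g <- structure(list(
    contigs = contigs, vdf = vdf, edges = edges, rev = rev_map,
    out_edges = out_edges, in_edges = in_edges,
    starter_v = vid(sci, 0L, 0L), starter_rbar = vid(sci, 1L, 0L),
    off = off, mult = m, nV = nV, nE = nE, ekey = ekey,
    bigM = sum(m)
  ), class = "mdcg")
  g
}

# vertex ids for (contig index, orientation, occurrence), vectorised
mdcg_vid <- function(g, cidx, or, occ) {
  g$off[cidx] + or * g$mult[cidx] + occ + 1L
}

# edge ids for vertex pairs (NA when the edge does not exist)
mdcg_eid <- function(g, u, v) {
  match((as.double(u) - 1) * g$nV + as.double(v), g$ekey)
}

#' Reverse a vertex of the MDCG
#'
#' Maps a vertex to its reverse partner: same contig and occurrence,
#' flipped orientation.  An involution: `reverse_vertex(reverse_vertex(v))`
#' is `v`.
#'
#' @param g an `mdcg` object.
#' @param v vertex index (vectorised).
#' @return The reverse vertex index (or indices).
#' @export
reverse_vertex <- function(g, v) g$rev[v]

#' Human-readable vertex labels
#'
#' Formats vertices as `"contig_or,occ"` tokens (e.g. `"c_r1"`), the
#' labelling used for oriented contig occurrences throughout the package
#' output.
#'
#' @param g an `mdcg` object.
#' @param v vertex indices.
#' @return Character vector of labels.
#' @export
vertex_token <- function(g, v) {
  paste0(g$vdf$contig[v], "_", c("f", "r")[g$vdf$or[v] + 1L], g$vdf$occ[v])
}

#' @export
print.mdcg <- function(x, ...) {
  cat("MDCG: |V| =", x$nV, ", |E| =", x$nE,
      "(starter vertex", vertex_token(x, x$starter_v), ")\n")
  invisible(x)
}
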