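#' Build repeated-fragment sets for one repeat kind
#'
#' A repeated fragment is an unordered pair of vertices of the MDCG carrying
#' two distinct occurrences of the same contig — the elementary building
#' block of a repeat.  For every repeat-candidate contig (multiplicity > 1)
#' the occurrences are paired `(2k, 2k+1)` for `k < floor(mult/2)`:
#'
#' * direct fragments (`kind = "DR"`) pair occurrences of the *same*
#'   orientation, one fragment per orientation and per `k`;
#' * inverted fragments (`kind = "IR"`) pair the forward occurrence `2k`
#'   with the reverse occurrence `2k+1`, one fragment per `k`.
#'
#' The set of ordered fragment pairs (`PDirF`/`PInvF`) orders two fragments
#' by the strict total order on contigs (byte-wise lexicographic), ties
#' broken by occurrence, so each unordered couple appears exactly once.
#' The adjacent-fragment edge set (`ADirF`/`AInvF`) holds the canonical
#' edges whose traversal extends the two regions of a repeat in lockstep;
#' `repadj` maps each canonical edge to its partner edge (for DR, both
#' endpoint occurrences shifted to their fragment mates; for IR, the
#' reversed edge between the fragment mates).
#'
#' An odd last occurrence (odd multiplicity) carries no fragment but remains
#' available to single-copy regions.
#'
#' @param g an [mdcg][build_mdcg] object.
#' @param kind `"DR"` for direct fragments or `"IR"` for inverted ones.
#' @return An object of class `fragment_sets`: list with `kind`, `frags`
#'   (data frame `v1`, `v2`, `cidx`, `k`), `repfrag` (vertex to fragment
#'   index, `NA` when none), `mate` (vertex to its fragment partner),
#'   `pairs` (ordered fragment pairs `a`, `b`), and `arep` (data frame
#'   `e` canonical edge id, `partner` its repadj edge id, `fu`, `fv` the
#'   endpoint fragments).
#' @examples
#' inp <- generate_perfect(2, 2)
#' fs <- build_fragment_sets(build_mdcg(inp), "IR")
#' nrow(fs$frags)
#' @export
build_fragment_sets <- function(g, kind = c("DR", "IR")) {
  kind <- match.arg(kind)
  contigs <- g$contigs
  m <- g$mult
  rep_c <- which(m > 1L)
  npairs <- m %/% 2L

  frag_rows <- list()
  for (ci in rep_c) {
    ks <- seq_len(npairs[ci]) - 1L
    if (kind == "DR") {
      for (orient in c(0L, 1L)) {
        frag_rows[[length(frag_rows) + 1L]] <- data.frame(
          v1 = mdcg_vid(g, rep(ci, length(ks)), orient, 2L * ks),
          v2 = mdcg_vid(g, rep(ci, length(ks)), orient, 2L * ks + 1L),
          cidx = ci, k = ks)
      }
    } else {
      frag_rows[[length(frag_rows) + 1L]] <- data.frame(
        v1 = mdcg_vid(g, rep(ci, length(ks)), 0L, 2L * ks),
        v2 = mdcg_vid(g, rep(ci, length(ks)), 1L, 2L * ks + 1L),
        cidx = ci, k = ks)
    }
  }
  frags <- if (length(frag_rows)) do.call(rbind, frag_rows) else
    data.frame(v1 = integer(), v2 = integer(), cidx = integer(), k = integer())

  repfrag <- rep(NA_integer_, g$nV)
  mate <- rep(NA_integer_, g$nV)
  if (nrow(frags)) {
    repfrag[frags$v1] <- seq_len(nrow(frags))
    repfrag[frags$v2] <- seq_len(nrow(frags))
    mate[frags$v1] <- frags$v2
    mate[frags$v2] <- frags$v1
  }

  # ordered pairs: ctg_j < ctg_k, ties broken by occurrence (occ of the
  # first fragment's second vertex vs the second fragment's first vertex)
  pairs <- data.frame(a = integer(), b = integer())
  if (nrow(frags) > 1) {
    idx <- expand.grid(a = seq_len(nrow(frags)), b = seq_len(nrow(frags)))
    ra <- contigs$rank[frags$cidx[idx$a]]
    rb <- contigs$rank[frags$cidx[idx$b]]
    occ_j <- g$vdf$occ[frags$v2[idx$a]]
    occ_k <- g$vdf$occ[frags$v1[idx$b]]
    keep <- ra < rb | (ra == rb & occ_j < occ_k)
    pairs <- idx[keep, , drop = FALSE]
    rownames(pairs) <- NULL
  }

  arep <- adjacent_fragment_edges(g, kind, repfrag, mate)
  structure(list(kind = kind, frags = frags, repfrag = repfrag, mate = mate,
                 pairs = pairs, arep = arep),
            class = "fragment_sets")
}

# Canonical adjacent-fragment edges and their repadj partners.
adjacent_fragment_edges <- function(g, kind, repfrag, mate) {
  empty <- data.frame(e = integer(), partner = integer(),
                      fu = integer(), fv = integer())
  if (g$nE == 0 || all(is.na(repfrag))) return(empty)
  u <- g$edges$u
  v <- g$edges$v
  vd <- g$vdf
  m_u <- g$mult[vd$cidx[u]]
  m_v <- g$mult[vd$cidx[v]]
  occ_u <- vd$occ[u]; occ_v <- vd$occ[v]
  or_u <- vd$or[u]; or_v <- vd$or[v]
  same_c <- vd$cidx[u] == vd$cidx[v]
  rank_u <- g$contigs$rank[vd$cidx[u]]
  rank_v <- g$contigs$rank[vd$cidx[v]]

  if (kind == "DR") {
    in_rng_u <- occ_u %% 2L == 0L & occ_u < 2L * (m_u %/% 2L)
    in_rng_v <- occ_v %% 2L == 0L & occ_v < 2L * (m_v %/% 2L)
    set1 <- !same_c & in_rng_u & in_rng_v
    set2 <- same_c & (or_u == 0L | or_v == 0L) & in_rng_u & in_rng_v &
      occ_u %/% 2L < occ_v %/% 2L
  } else {
    ku <- occ_u - or_u
    kv <- occ_v - or_v
    in_rng_u <- ku %% 2L == 0L & ku >= 0L & ku < 2L * (m_u %/% 2L)
    in_rng_v <- kv %% 2L == 0L & kv >= 0L & kv < 2L * (m_v %/% 2L)
    set1 <- !same_c & rank_u < rank_v & in_rng_u & in_rng_v
    set2 <- same_c & (or_u == 0L | or_v == 0L) & in_rng_u & in_rng_v &
      ku %/% 2L < kv %/% 2L
  }
  canon <- which(set1 | set2)
  if (!length(canon)) return(empty)
  if (kind == "DR") {
    pu <- mate[u[canon]]
    pv <- mate[v[canon]]
    partner <- mdcg_eid(g, pu, pv)
  } else {
    partner <- mdcg_eid(g, mate[v[canon]], mate[u[canon]])
  }
  stopifnot(!anyNA(partner)) # guaranteed by link reverse closure
  data.frame(e = canon, partner = partner,
             fu = repfrag[u[canon]], fv = repfrag[v[canon]])
}

#' @export
print.fragment_sets <- function(x, ...) {
  cat("Fragment sets (", x$kind, "): |RepF| = ", nrow(x$frags),
      ", |PRepF| = ", nrow(x$pairs), ", |ARepF| = ", nrow(x$arep), "\n",
      sep = "")
  invisible(x)
}
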