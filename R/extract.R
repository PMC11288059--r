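## Decomposition of a solution circuit into COR / SOR.

# vertex -> kind ("DR"/"IR"/NA) and fragment bookkeeping from star-sets
star_maps <- function(g, star_sets) {
  vkind <- rep(NA_character_, g$nV)
  vmate <- rep(NA_integer_, g$nV)
  vfrag <- rep(NA_integer_, g$nV)
  fr <- star_sets$frags
  if (!is.null(fr) && nrow(fr)) {
    for (r in seq_len(nrow(fr))) {
      vs <- c(fr$v1[r], fr$v2[r])
      if (any(!is.na(vkind[vs]))) {
        warning("vertex in two selected fragments; keeping the earlier stage")
        next
      }
      vkind[vs] <- fr$kind[r]
      vmate[fr$v1[r]] <- fr$v2[r]
      vmate[fr$v2[r]] <- fr$v1[r]
      vfrag[vs] <- r
    }
  }
  allowed <- list(DR = integer(), IR = integer())
  ar <- star_sets$arep
  if (!is.null(ar) && nrow(ar)) {
    for (k in c("DR", "IR")) {
      rows <- ar$kind == k
      allowed[[k]] <- unique(c(ar$e[rows], ar$partner[rows]))
    }
  }
  list(vkind = vkind, vmate = vmate, vfrag = vfrag, allowed = allowed)
}

#' Region type of a vertex in a solved instance
#'
#' A used vertex belongs to a direct repeat if it is part of a selected
#' direct fragment, to an inverted repeat if part of a selected inverted
#' fragment, and to a single copy otherwise.  The starter is always a
#' single copy (its multiplicity is 1, so it can carry no fragment).
#'
#' @param g an [mdcg][build_mdcg] object.
#' @param v vertex index (vectorised).
#' @param star_sets selected fragments/adjacencies, as accumulated by
#'   [run_succession] (`$star_sets`) or a repeat stage's `fixed_sets_out`.
#' @return `"DR"`, `"IR"` or `"SC"` per vertex.
#' @export
vertex_region_type <- function(g, v, star_sets) {
  vkind <- star_maps(g, star_sets)$vkind
  ifelse(is.na(vkind[v]), "SC", vkind[v])
}

# region-start flags along the circular circuit: position t starts a new
# region when the edge from circuit[t-1] is a type change or a contiguity
# break between two repeat vertices.
region_starts <- function(g, circuit, maps) {
  n <- length(circuit)
  prev <- circuit[c(n, seq_len(n - 1L))]
  cur <- circuit
  kp <- maps$vkind[prev]
  kc <- maps$vkind[cur]
  kp[is.na(kp)] <- "SC"
  kc[is.na(kc)] <- "SC"
  eid <- mdcg_eid(g, prev, cur)
  if (anyNA(eid)) stop("internal: circuit uses a non-edge")
  starts <- kp != kc
  both_rep <- !starts & kp != "SC"
  if (any(both_rep)) {
    idx <- which(both_rep)
    contig_ok <- vapply(idx, function(t) {
      eid[t] %in% maps$allowed[[kc[t]]]
    }, logical(1))
    starts[idx] <- !contig_ok
  }
  starts
}

#' First vertex of the starter's single-copy region
#'
#' Walks backwards from the starter along the circuit until the
#' predecessor's region type changes; a full-loop guard handles the
#' degenerate all-single-copy circuit (the starter itself is returned).
#'
#' @inheritParams vertex_region_type
#' @param circuit integer vertex sequence from [decode_circuit].
#' @return The vertex index opening the starter's region.
#' @export
initial_vertex <- function(g, circuit, star_sets) {
  maps <- star_maps(g, star_sets)
  starts <- region_starts(g, circuit, maps)
  if (!any(starts)) return(circuit[1])
  spos <- match(g$starter_v, circuit)
  at_or_before <- which(starts & seq_along(circuit) <= spos)
  if (length(at_or_before)) circuit[max(at_or_before)] else circuit[max(which(starts))]
}

#' Do two consecutive repeat vertices extend the same repeat region?
#'
#' True when the circuit edge between them is a selected canonical
#' adjacent-fragment edge or the partner of one — i.e. the two fragments
#' are glued by a selected adjacency, so the partner occurrences are
#' consecutive as well and the repeat's two regions grow in lockstep.
#'
#' @inheritParams vertex_region_type
#' @param u,v consecutive circuit vertices, both repeat-typed.
#' @return Logical.
#' @export
repeat_contiguous <- function(g, u, v, star_sets) {
  maps <- star_maps(g, star_sets)
  ku <- maps$vkind[u]
  kv <- maps$vkind[v]
  if (is.na(ku) || is.na(kv) || ku != kv) return(FALSE)
  eid <- mdcg_eid(g, u, v)
  !is.na(eid) && eid %in% maps$allowed[[ku]]
}

#' Decompose a solution circuit into genomic regions
#'
#' Walks the circuit from the first vertex of the starter's region and
#' opens a new region at every type change or repeat-contiguity break.
#' Each repeat's two regions are matched with a FIFO queue for direct
#' repeats (occurrences may interleave, never nest) and a LIFO queue for
#' inverted repeats (occurrences may nest, never cross).  The result is
#' `COR`, the tuple of forward regions (each an oriented-contig sequence,
#' stored once), and `SOR`, the circular sequence of oriented region
#' references: the partner occurrence of an inverted repeat is referenced
#' reversed, that of a direct repeat forward.  A repeat region appears
#' exactly twice in `SOR` and a single copy exactly once, so
#' `length(SOR) = 2 m + n` for `m` repeats and `n` single copies.
#'
#' @inheritParams initial_vertex
#' @return An object of class `region_decomposition`: list with `COR`
#'   (list of data frames `contig`, `or`), `SOR` (data frame `rid`
#'   1-based region index, `ror` `"f"`/`"r"`), `region_types` (per COR
#'   entry, `"DR"`/`"IR"`/`"SC"`), and `circuit_tokens`.
#' @export
extract_regions <- function(g, circuit, star_sets) {
  maps <- star_maps(g, star_sets)
  n <- length(circuit)
  starts <- region_starts(g, circuit, maps)
  init_v <- initial_vertex(g, circuit, star_sets)
  init_pos <- match(init_v, circuit)
  rot <- circuit[c(seq(init_pos, n), if (init_pos > 1) seq_len(init_pos - 1L))]
  starts_rot <- starts[c(seq(init_pos, n), if (init_pos > 1) seq_len(init_pos - 1L))]
  starts_rot[1] <- TRUE
  cuts <- which(starts_rot)
  ends <- c(cuts[-1] - 1L, n)
  regions <- Map(function(a, b) rot[a:b], cuts, ends)

  COR <- list()
  types <- character()
  cor_vertices <- list()
  sor_rid <- integer()
  sor_ror <- character()
  open_dr <- list()  # FIFO of COR indices
  open_ir <- list()  # LIFO of COR indices
  open_frags <- list(DR = integer(), IR = integer())

  region_df <- function(vs) {
    data.frame(contig = g$vdf$contig[vs],
               or = c("f", "r")[g$vdf$or[vs] + 1L],
               stringsAsFactors = FALSE)
  }

  for (vs in regions) {
    k <- maps$vkind[vs[1]]
    if (is.na(k)) {
      COR[[length(COR) + 1L]] <- region_df(vs)
      cor_vertices[[length(COR)]] <- vs
      types[length(COR)] <- "SC"
      sor_rid <- c(sor_rid, length(COR))
      sor_ror <- c(sor_ror, "f")
      next
    }
    frs <- maps$vfrag[vs]
    if (anyNA(frs)) stop("internal: repeat region contains unselected vertex")
    closing <- any(frs %in% open_frags[[k]])
    if (closing) {
      if (k == "IR") {
        if (!length(open_ir)) stop("internal: unmatched inverted region")
        peek <- open_ir[[length(open_ir)]]
        expect <- maps$vmate[rev(vs)]
        if (!identical(as.integer(expect), as.integer(cor_vertices[[peek]]))) {
          stop("internal: inverted repeat partner mismatch (crossing order?)")
        }
        open_ir[[length(open_ir)]] <- NULL
        sor_rid <- c(sor_rid, peek)
        sor_ror <- c(sor_ror, "r")
      } else {
        if (!length(open_dr)) stop("internal: unmatched direct region")
        peek <- open_dr[[1]]
        expect <- maps$vmate[vs]
        if (!identical(as.integer(expect), as.integer(cor_vertices[[peek]]))) {
          stop("internal: direct repeat partner mismatch (nesting order?)")
        }
        open_dr[[1]] <- NULL
        sor_rid <- c(sor_rid, peek)
        sor_ror <- c(sor_ror, "f")
      }
      open_frags[[k]] <- setdiff(open_frags[[k]], frs)
    } else {
      COR[[length(COR) + 1L]] <- region_df(vs)
      cor_vertices[[length(COR)]] <- vs
      types[length(COR)] <- k
      sor_rid <- c(sor_rid, length(COR))
      sor_ror <- c(sor_ror, "f")
      if (k == "IR") open_ir[[length(open_ir) + 1L]] <- length(COR)
      else open_dr[[length(open_dr) + 1L]] <- length(COR)
      open_frags[[k]] <- c(open_frags[[k]], frs)
    }
  }
  if (length(open_dr) || length(open_ir)) {
    stop("internal: unmatched repeat regions at end of walk")
  }
  structure(list(COR = COR, SOR = data.frame(rid = sor_rid, ror = sor_ror),
                 region_types = types,
                 circuit_tokens = vertex_token(g, circuit)),
            class = "region_decomposition")
}

#' Reverse a region (oriented-contig sequence)
#'
#' The reverse of a region reverses the order of its oriented contigs and
#' flips every orientation.
#'
#' @param region data frame with columns `contig`, `or`.
#' @return The reversed region.
#' @export
reverse_region <- function(region) {
  data.frame(contig = rev(region$contig), or = flip_orient(rev(region$or)),
             stringsAsFactors = FALSE)
}

#' Flatten a decomposition back to an oriented-contig sequence
#'
#' Concatenates the regions referenced by `SOR` (reversed where the
#' reference is reverse), reproducing the solution circuit's
#' oriented-contig sequence.
#'
#' @param d a [region_decomposition][extract_regions], or any list with
#'   `COR` and `SOR` in the same layout.
#' @param SOR optional replacement sequence of oriented regions (e.g. one
#'   genome form from [enumerate_genome_forms]).
#' @return Data frame with columns `contig`, `or`.
#' @export
flatten_regions <- function(d, SOR = NULL) {
  if (is.null(SOR)) SOR <- d$SOR
  parts <- Map(function(rid, ror) {
    r <- d$COR[[rid]]
    if (ror == "r") reverse_region(r) else r
  }, SOR$rid, SOR$ror)
  do.call(rbind, parts)
}

#' Repeat lengths of a decomposition
#'
#' The length `replen` of a repeat is the sum of the lengths of its two
#' regions (twice the region length, since the two regions of a repeat
#' have equal length).
#'
#' @param d a [region_decomposition][extract_regions].
#' @return Data frame with one row per repeat: `rid`, `kind`, `replen`.
#' @export
repeat_lengths <- function(d) {
  rep_idx <- which(d$region_types != "SC")
  data.frame(rid = rep_idx,
             kind = d$region_types[rep_idx],
             replen = vapply(rep_idx, function(i) 2L * nrow(d$COR[[i]]),
                             integer(1)))
}

region_token <- function(d, rid, ror) paste0(rid - 1L, "_", ror)

#' @export
print.region_decomposition <- function(x, ...) {
  cat("Region decomposition:", length(x$COR), "regions (",
      sum(x$region_types == "SC"), "SC,",
      sum(x$region_types == "DR"), "DR,",
      sum(x$region_types == "IR"), "IR )\n")
  cat("SOR:", paste(region_token(x, x$SOR$rid, x$SOR$ror), collapse = " -> "),
      "\n")
  for (i in seq_along(x$COR)) {
    cat(sprintf("  region %d [%s]: %s\n", i - 1L, x$region_types[i],
                paste(paste0(x$COR[[i]]$contig, "_", x$COR[[i]]$or),
                      collapse = ",")))
  }
  invisible(x)
}
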