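# Independent brute-force oracle: exhaustive enumeration of all valid
# circuits of an MDCG and direct evaluation of the scaffolding objectives,
# with interval logic (not quartet constraints) for the order rules.

enumerate_valid_circuits <- function(g) {
  s <- g$starter_v
  sbar <- g$starter_rbar
  res <- list()
  used <- rep(FALSE, g$nV)
  path <- integer()
  walk <- function(cur) {
    for (ei in g$out_edges[[cur]]) {
      w <- g$edges$v[ei]
      if (w == s) {
        res[[length(res) + 1L]] <<- c(s, path)
        next
      }
      if (w == sbar || used[w] || used[g$rev[w]]) next
      used[w] <<- TRUE
      path <<- c(path, w)
      walk(w)
      used[w] <<- FALSE
      path <<- path[-length(path)]
    }
  }
  used[s] <- TRUE
  walk(s)
  res
}

# best repeat objective achievable on one fixed circuit: choose a subset of
# fragments (both vertices used, no forbidden pairwise order) maximising
# #fragments + #selected adjacencies present in the circuit
oracle_repeat_best <- function(g, fs, circuit) {
  pos <- integer(g$nV)
  pos[circuit] <- seq_along(circuit)
  cand <- which(pos[fs$frags$v1] > 0 & pos[fs$frags$v2] > 0)
  if (!length(cand)) return(0)
  nc <- length(cand)
  conf <- matrix(FALSE, nc, nc)
  if (nrow(fs$pairs)) {
    for (r in seq_len(nrow(fs$pairs))) {
      ia <- match(fs$pairs$a[r], cand)
      ib <- match(fs$pairs$b[r], cand)
      if (is.na(ia) || is.na(ib)) next
      pa <- sort(pos[c(fs$frags$v1[cand[ia]], fs$frags$v2[cand[ia]])])
      pb <- sort(pos[c(fs$frags$v1[cand[ib]], fs$frags$v2[cand[ib]])])
      bad <- if (fs$kind == "DR") {
        (pa[1] < pb[1] && pb[2] < pa[2]) || (pb[1] < pa[1] && pa[2] < pb[2])
      } else {
        xor(pa[1] < pb[1] && pb[1] < pa[2], pa[1] < pb[2] && pb[2] < pa[2])
      }
      if (bad) conf[ia, ib] <- conf[ib, ia] <- TRUE
    }
  }
  n <- length(circuit)
  edge_in <- rep(FALSE, g$nE)
  edge_in[mdcg_eid(g, circuit, circuit[c(seq_len(n)[-1], 1L)])] <- TRUE
  adj_ok <- edge_in[fs$arep$e] & edge_in[fs$arep$partner]
  best <- 0L
  for (mask in seq_len(2^nc) - 1L) {
    selpos <- which(bitwAnd(mask, 2^(seq_len(nc) - 1L)) > 0)
    if (length(selpos) > 1 && any(conf[selpos, selpos])) next
    sel <- cand[selpos]
    val <- length(sel) +
      sum(adj_ok & fs$arep$fu %in% sel & fs$arep$fv %in% sel)
    best <- max(best, val)
  }
  best
}

# exhaustive optima; NA when no valid circuit exists (infeasible instance)
oracle_repeat_opt <- function(g, kind, circuits = NULL) {
  if (is.null(circuits)) circuits <- enumerate_valid_circuits(g)
  if (!length(circuits)) return(NA_real_)
  fs <- build_fragment_sets(g, kind)
  max(vapply(circuits, function(cp) oracle_repeat_best(g, fs, cp), numeric(1)))
}

oracle_sc_opt <- function(g, circuits = NULL) {
  if (is.null(circuits)) circuits <- enumerate_valid_circuits(g)
  if (!length(circuits)) return(NA_real_)
  max(vapply(circuits, function(cp) {
    sum(g$vdf$wex[setdiff(cp, g$starter_v)])
  }, numeric(1)))
}

# mdcg internals used by the oracle
mdcg_eid <- chloroscaf:::mdcg_eid
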