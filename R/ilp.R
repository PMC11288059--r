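## Solver-agnostic linear model container and the four constraint blocks.
##
## The model is an environment holding variable bounds/types/objective and
## the constraint matrix as triplets with row ranges rlb <= A x <= rub.
## Infinities are encoded as +/- INF_BOUND when serialised.

INF_BOUND <- 1e30

#' Create an empty linear model
#'
#' A mutable container for a mixed-integer linear program: variables with
#' bounds, types and objective coefficients, and ranged linear constraints
#' stored as sparse triplets.  Constraint blocks ([add_circuit_block],
#' [add_repeat_block], [add_symmetry_block], [add_fix_regions_block]) fill
#' it in; [solve_ilp] dispatches it to a MILP backend.
#'
#' @return An object of class `linear_model` (an environment).
#' @export
new_linear_model <- function() {
  m <- new.env(parent = emptyenv())
  m$nvar <- 0L
  m$lb <- numeric()
  m$ub <- numeric()
  m$vtype <- character()   # "B" binary, "C" continuous
  m$obj <- numeric()
  m$chunks <- list()       # each: list(ri, ci, cv) with ri absolute row ids
  m$rlb <- numeric()
  m$rub <- numeric()
  m$nrow <- 0L
  m$blocks <- character()
  m$maximize <- TRUE
  class(m) <- "linear_model"
  m
}

lm_add_vars <- function(model, n, lb = 0, ub = 1, type = "C", obj = 0) {
  if (n == 0L) return(integer())
  cols <- model$nvar + seq_len(n)
  model$nvar <- model$nvar + as.integer(n)
  model$lb <- c(model$lb, rep_len(lb, n))
  model$ub <- c(model$ub, rep_len(ub, n))
  model$vtype <- c(model$vtype, rep_len(type, n))
  model$obj <- c(model$obj, rep_len(obj, n))
  cols
}

# ri are row indices relative to this call (1..max(ri)); rlb/rub have one
# entry per relative row.
lm_add_cons <- function(model, ri, ci, cv, rlb, rub) {
  nr <- length(rlb)
  if (nr == 0L) return(invisible(model))
  stopifnot(length(rub) == nr, length(ri) == length(ci),
            length(ci) == length(cv))
  model$chunks[[length(model$chunks) + 1L]] <-
    list(ri = model$nrow + as.integer(ri), ci = as.integer(ci), cv = cv)
  model$rlb <- c(model$rlb, rlb)
  model$rub <- c(model$rub, rub)
  model$nrow <- model$nrow + as.integer(nr)
  invisible(model)
}

#' Add the valid-circuit constraint block
#'
#' Encodes a single circuit through the starter vertex with a flow
#' formulation: binary edge-use variables `x`, continuous flow `f` coupled
#' to `x` by `x_e <= f_e <= M x_e` with `M = sum(mult)`, exactly one edge
#' leaving and entering the starter with unit outgoing flow, the reverse
#' starter banned, mutual exclusion of each vertex and its reverse,
#' degree/indicator coupling `in(v) <= i_v <= out(v)`, and a unit flow
#' increase at every used vertex — the flow monotonicity that rules out
#' subcircuits.  Vertex indicators `i_v` are continuous in `[0, 1]` but
#' behave as binaries at any optimum.
#'
#' @param model a [new_linear_model] object (empty).
#' @param g an [mdcg][build_mdcg] object.
#' @return The model, invisibly (modified in place).
#' @export
add_circuit_block <- function(model, g) {
  stopifnot(inherits(model, "linear_model"), inherits(g, "mdcg"))
  if ("circuit" %in% model$blocks) stop("circuit block already added")
  nE <- g$nE
  nV <- g$nV
  M <- g$bigM
  s <- g$starter_v
  sbar <- g$starter_rbar

  x <- lm_add_vars(model, nE, 0, 1, "B")
  f <- lm_add_vars(model, nE, 0, M, "C")
  vns <- setdiff(seq_len(nV), c(s, sbar))
  i_col <- rep(NA_integer_, nV)
  i_col[vns] <- lm_add_vars(model, length(vns), 0, 1, "C")
  model$x_col <- x
  model$f_col <- f
  model$i_col <- i_col
  model$g <- g

  # (4)-(5): edges touching the reverse starter are banned (via bounds)
  banned <- which(g$edges$u == sbar | g$edges$v == sbar)
  if (length(banned)) {
    model$ub[x[banned]] <- 0
    model$ub[f[banned]] <- 0
  }

  if (nE) {
    # (1) x_e <= f_e and f_e <= M x_e
    e <- seq_len(nE)
    lm_add_cons(model,
                ri = c(e, e), ci = c(f[e], x[e]), cv = c(rep(1, nE), rep(-1, nE)),
                rlb = rep(0, nE), rub = rep(INF_BOUND, nE))
    lm_add_cons(model,
                ri = c(e, e), ci = c(f[e], x[e]), cv = c(rep(1, nE), rep(-M, nE)),
                rlb = rep(-INF_BOUND, nE), rub = rep(0, nE))
  }

  out_s <- g$out_edges[[s]]
  in_s <- g$in_edges[[s]]
  # (2) exactly one exit and one entry at the starter
  lm_add_cons(model, ri = rep(1L, length(out_s)), ci = x[out_s],
              cv = rep(1, length(out_s)), rlb = 1, rub = 1)
  lm_add_cons(model, ri = rep(1L, length(in_s)), ci = x[in_s],
              cv = rep(1, length(in_s)), rlb = 1, rub = 1)
  # (3) unit flow leaves the starter
  lm_add_cons(model, ri = rep(1L, length(out_s)), ci = f[out_s],
              cv = rep(1, length(out_s)), rlb = 1, rub = 1)

  # (6) i_v + i_vbar <= 1, once per unordered pair
  fwd <- vns[g$vdf$or[vns] == 0L]
  if (length(fwd)) {
    lm_add_cons(model,
                ri = c(seq_along(fwd), seq_along(fwd)),
                ci = c(i_col[fwd], i_col[g$rev[fwd]]),
                cv = rep(1, 2L * length(fwd)),
                rlb = rep(-INF_BOUND, length(fwd)), rub = rep(1, length(fwd)))
  }

  if (length(vns)) {
    n_out <- lengths(g$out_edges[vns])
    n_in <- lengths(g$in_edges[vns])
    out_e <- unlist(g$out_edges[vns], use.names = FALSE)
    in_e <- unlist(g$in_edges[vns], use.names = FALSE)
    rid <- seq_along(vns)
    # (7) sum x_in - i_v <= 0 and i_v - sum x_out <= 0
    lm_add_cons(model,
                ri = c(rep(rid, n_in), rid),
                ci = c(x[in_e], i_col[vns]),
                cv = c(rep(1, length(in_e)), rep(-1, length(vns))),
                rlb = rep(-INF_BOUND, length(vns)), rub = rep(0, length(vns)))
    lm_add_cons(model,
                ri = c(rid, rep(rid, n_out)),
                ci = c(i_col[vns], x[out_e]),
                cv = c(rep(1, length(vns)), rep(-1, length(out_e))),
                rlb = rep(-INF_BOUND, length(vns)), rub = rep(0, length(vns)))
    # (8) flow gain at every used vertex
    lm_add_cons(model,
                ri = c(rep(rid, n_out), rep(rid, n_in), rid),
                ci = c(f[out_e], f[in_e], i_col[vns]),
                cv = c(rep(1, length(out_e)), rep(-1, length(in_e)),
                       rep(-1, length(vns))),
                rlb = rep(0, length(vns)), rub = rep(0, length(vns)))
  }
  model$blocks <- c(model$blocks, "circuit")
  invisible(model)
}

# Resolve ordered vertex couples against the stored alpha variables:
# returns coef (+1 / -1) on the matched variable column and the constant
# (0 / 1), using alpha[v,u] = 1 - alpha[u,v].
alpha_terms <- function(model, u, v) {
  akey <- model$alpha_key
  hit <- match(paste(u, v), akey)
  rhit <- match(paste(v, u), akey)
  if (anyNA(hit) && anyNA(rhit[is.na(hit)])) {
    stop("internal: unresolvable alpha comparison")
  }
  coef <- ifelse(is.na(hit), -1, 1)
  col <- ifelse(is.na(hit), model$alpha_col[rhit], model$alpha_col[hit])
  const <- ifelse(is.na(hit), 1, 0)
  list(col = col, coef = coef, const = const)
}

#' Add the repeated-region constraint block
#'
#' Adds, for a repeat problem (DRP or IRP), the fragment selection
#' variables `m`, the adjacency indicators `isadj`, the pairwise order
#' variables `alpha` and the forbidden-order detectors `forbid`, together
#' with their linking constraints: selected fragments force both vertices
#' into the circuit; `alpha[u, v]` linearises "u precedes v" through vertex
#' positions (the flow leaving a vertex); a `forbid` variable switches on
#' exactly when a forbidden quartet order is realised; a fragment pair
#' cannot be co-selected under a realised forbidden order; and `isadj` is
#' active only when a canonical adjacent edge and its partner are both in
#' the circuit with both endpoint fragments selected.
#'
#' @param model a [new_linear_model] with the circuit block added.
#' @param g an [mdcg][build_mdcg] object.
#' @param fs [fragment_sets][build_fragment_sets] of the problem's kind.
#' @param os [order_sets][build_order_sets] built from `fs`.
#' @return The model, invisibly (modified in place).
#' @export
add_repeat_block <- function(model, g, fs, os) {
  if (!"circuit" %in% model$blocks) stop("add the circuit block first")
  M <- g$bigM
  x <- model$x_col
  f <- model$f_col
  i_col <- model$i_col

  nfrag <- nrow(fs$frags)
  nadj <- nrow(fs$arep)
  m_col <- lm_add_vars(model, nfrag, 0, 1, "B")
  isadj_col <- lm_add_vars(model, nadj, 0, 1, "B")
  alpha_col <- lm_add_vars(model, nrow(os$alpha), 0, 1, "B")
  forbid_col <- lm_add_vars(model, nrow(os$forbid), 0, 1, "B")
  model$m_col <- m_col
  model$isadj_col <- isadj_col
  model$alpha_col <- alpha_col
  model$alpha_key <- paste(os$alpha$u, os$alpha$v)
  model$forbid_col <- forbid_col
  model$fs <- fs
  model$os <- os

  if (nfrag) {
    # (9)-(10) a selected fragment uses both its vertices
    rid <- seq_len(nfrag)
    lm_add_cons(model,
                ri = c(rid, rid), ci = c(m_col, i_col[fs$frags$v1]),
                cv = c(rep(1, nfrag), rep(-1, nfrag)),
                rlb = rep(-INF_BOUND, nfrag), rub = rep(0, nfrag))
    lm_add_cons(model,
                ri = c(rid, rid), ci = c(m_col, i_col[fs$frags$v2]),
                cv = c(rep(1, nfrag), rep(-1, nfrag)),
                rlb = rep(-INF_BOUND, nfrag), rub = rep(0, nfrag))
  }

  na <- nrow(os$alpha)
  if (na) {
    # pos(v) = flow leaving v
    u <- os$alpha$u
    v <- os$alpha$v
    n_out_u <- lengths(g$out_edges[u])
    n_out_v <- lengths(g$out_edges[v])
    fe_u <- f[unlist(g$out_edges[u], use.names = FALSE)]
    fe_v <- f[unlist(g$out_edges[v], use.names = FALSE)]
    rid <- seq_len(na)
    # (11) pos(v) - pos(u) <= M alpha
    lm_add_cons(model,
                ri = c(rep(rid, n_out_v), rep(rid, n_out_u), rid),
                ci = c(fe_v, fe_u, alpha_col),
                cv = c(rep(1, length(fe_v)), rep(-1, length(fe_u)),
                       rep(-M, na)),
                rlb = rep(-INF_BOUND, na), rub = rep(0, na))
    # (12) pos(u) - pos(v) <= M (1 - alpha)
    lm_add_cons(model,
                ri = c(rep(rid, n_out_u), rep(rid, n_out_v), rid),
                ci = c(fe_u, fe_v, alpha_col),
                cv = c(rep(1, length(fe_u)), rep(-1, length(fe_v)),
                       rep(M, na)),
                rlb = rep(-INF_BOUND, na), rub = rep(M, na))
    # (13) pos(u) + pos(v) >= alpha
    lm_add_cons(model,
                ri = c(rep(rid, n_out_u), rep(rid, n_out_v), rid),
                ci = c(fe_u, fe_v, alpha_col),
                cv = c(rep(1, length(fe_u)), rep(1, length(fe_v)),
                       rep(-1, na)),
                rlb = rep(0, na), rub = rep(INF_BOUND, na))
  }

  nf <- nrow(os$forbid)
  if (nf) {
    t1 <- alpha_terms(model, os$forbid$a, os$forbid$b)
    t2 <- alpha_terms(model, os$forbid$b, os$forbid$c)
    t3 <- alpha_terms(model, os$forbid$c, os$forbid$d)
    rid <- seq_len(nf)
    const <- t1$const + t2$const + t3$const
    # (14) 3 forbid <= alpha_ab + alpha_bc + alpha_cd
    lm_add_cons(model,
                ri = rep(rid, 4L),
                ci = c(forbid_col, t1$col, t2$col, t3$col),
                cv = c(rep(3, nf), -t1$coef, -t2$coef, -t3$coef),
                rlb = rep(-INF_BOUND, nf), rub = const)
    # (15) 2 + forbid >= alpha_ab + alpha_bc + alpha_cd
    lm_add_cons(model,
                ri = rep(rid, 4L),
                ci = c(forbid_col, t1$col, t2$col, t3$col),
                cv = c(rep(1, nf), -t1$coef, -t2$coef, -t3$coef),
                rlb = const - 2, rub = rep(INF_BOUND, nf))
    # (16) co-selection excluded under a realised forbidden order
    np <- nrow(fs$pairs)
    rid_p <- os$forbid$pair
    lm_add_cons(model,
                ri = c(seq_len(np), seq_len(np), rid_p),
                ci = c(m_col[fs$pairs$a], m_col[fs$pairs$b], forbid_col),
                cv = rep(1, 2L * np + nf),
                rlb = rep(-INF_BOUND, np), rub = rep(2, np))
  }

  if (nadj) {
    # (17)-(20) adjacency requires both edges chosen and both fragments
    rid <- seq_len(nadj)
    for (other in list(x[fs$arep$e], x[fs$arep$partner],
                       m_col[fs$arep$fu], m_col[fs$arep$fv])) {
      lm_add_cons(model,
                  ri = c(rid, rid), ci = c(isadj_col, other),
                  cv = c(rep(1, nadj), rep(-1, nadj)),
                  rlb = rep(-INF_BOUND, nadj), rub = rep(0, nadj))
    }
  }
  model$blocks <- c(model$blocks, "repeat")
  invisible(model)
}

#' Add the symmetry-breaking (speed-up) constraint block
#'
#' Prevents the solver from enumerating solutions equivalent up to a
#' permutation of contig occurrences: occurrence usage must be monotone in
#' the occurrence number, and — when no repeats are fixed — fragment
#' selection must be monotone over consecutive same-contig fragments.
#' Neither family changes the optimum value.
#'
#' @param model a [new_linear_model] with the circuit block added.
#' @param g an [mdcg][build_mdcg] object.
#' @param fs optional [fragment_sets][build_fragment_sets]; when supplied
#'   (a repeat problem with nothing fixed) the fragment-monotonicity family
#'   is emitted too.
#' @return The model, invisibly (modified in place).
#' @export
add_symmetry_block <- function(model, g, fs = NULL) {
  if (!"circuit" %in% model$blocks) stop("add the circuit block first")
  i_col <- model$i_col
  # (26) over occurrence-consecutive forward vertices
  multi <- which(g$mult > 1L)
  if (length(multi)) {
    us <- vs <- integer()
    for (ci in multi) {
      t <- seq_len(g$mult[ci] - 1L) - 1L
      us <- c(us, mdcg_vid(g, rep(ci, length(t)), 0L, t))
      vs <- c(vs, mdcg_vid(g, rep(ci, length(t)), 0L, t + 1L))
    }
    rid <- seq_along(us)
    lm_add_cons(model,
                ri = rep(rid, 4L),
                ci = c(i_col[vs], i_col[g$rev[vs]], i_col[us], i_col[g$rev[us]]),
                cv = c(rep(1, 2L * length(us)), rep(-1, 2L * length(us))),
                rlb = rep(-INF_BOUND, length(us)), rub = rep(0, length(us)))
  }
  # (27) over consecutive repeated fragments (same contig, same orientation
  # pattern, occurrence pairs shifted by 2)
  if (!is.null(fs) && nrow(fs$frags) > 1) {
    fr <- fs$frags
    or1 <- model$g$vdf$or[fr$v1]
    grp <- paste(fr$cidx, or1)
    ord <- order(grp, fr$k, method = "radix")
    p <- q <- integer()
    for (gname in unique(grp)) {
      idx <- ord[grp[ord] == gname]
      if (length(idx) > 1) {
        p <- c(p, idx[-length(idx)])
        q <- c(q, idx[-1])
      }
    }
    if (length(p)) {
      m_col <- model$m_col
      rid <- seq_along(p)
      lm_add_cons(model,
                  ri = c(rid, rid), ci = c(m_col[q], m_col[p]),
                  cv = c(rep(1, length(p)), rep(-1, length(p))),
                  rlb = rep(-INF_BOUND, length(p)), rub = rep(0, length(p)))
    }
  }
  model$blocks <- c(model$blocks, "symmetry")
  invisible(model)
}

#' Pin previously scaffolded repeat regions into a model
#'
#' Regions found by an earlier stage of the hierarchical succession must be
#' preserved: the vertices of every fixed fragment are forced into the
#' circuit (`i = 1`) and every fixed canonical adjacent edge is forced in
#' together with its repadj partner (`x = 1`).
#'
#' @param model a [new_linear_model] with the circuit block added.
#' @param fixed star-sets from a solved repeat problem: a list with
#'   `frags` (data frame `v1`, `v2`) and `arep` (data frame `e`,
#'   `partner` of MDCG edge ids).  `NULL` or empty leaves the model
#'   unchanged.
#' @return The model, invisibly (modified in place).
#' @export
add_fix_regions_block <- function(model, fixed) {
  if (!"circuit" %in% model$blocks) stop("add the circuit block first")
  if (is.null(fixed)) return(invisible(model))
  g <- model$g
  if (!is.null(fixed$frags) && nrow(fixed$frags)) {
    cols <- model$i_col[c(fixed$frags$v1, fixed$frags$v2)]
    if (anyNA(cols)) stop("fixed fragment uses the starter vertex")
    model$lb[cols] <- 1
  }
  if (!is.null(fixed$arep) && nrow(fixed$arep)) {
    eids <- c(fixed$arep$e, fixed$arep$partner)
    if (anyNA(eids) || any(eids < 1L) || any(eids > g$nE)) {
      stop("fixed adjacent edge absent from the graph")
    }
    cols <- model$x_col[eids]
    if (any(model$ub[cols] < 1)) stop("fixed adjacent edge is banned")
    model$lb[cols] <- 1
  }
  model$blocks <- c(model$blocks, "fix_regions")
  invisible(model)
}

#' Set the objective of a scaffolding model
#'
#' Repeat problems maximise the number of selected fragments plus selected
#' adjacencies (equal to the cumulative repeat length minus the number of
#' repeats); the single-copy problem maximises the total existence weight
#' of the used vertices, the starter and its reverse excluded.
#'
#' @param model a [new_linear_model] with the relevant blocks added.
#' @param type `"repeat"` or `"sc"`.
#' @return The model, invisibly (modified in place).
#' @export
set_scaffold_objective <- function(model, type = c("repeat", "sc")) {
  type <- match.arg(type)
  model$obj[] <- 0
  if (type == "repeat") {
    model$obj[model$m_col] <- 1
    model$obj[model$isadj_col] <- 1
  } else {
    g <- model$g
    has_i <- which(!is.na(model$i_col))
    model$obj[model$i_col[has_i]] <- g$vdf$wex[has_i]
  }
  model$maximize <- TRUE
  invisible(model)
}

#' @export
print.linear_model <- function(x, ...) {
  cat("Linear model:", x$nvar, "variables,", x$nrow, "constraints; blocks:",
      paste(x$blocks, collapse = ", "), "\n")
  invisible(x)
}
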