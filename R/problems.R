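## DRP / IRP / SCP assembly and the hierarchical succession logic.

problem_name <- function(kind) c(DR = "DRP", IR = "IRP")[kind]

#' Solve a repeat scaffolding problem (DRP or IRP)
#'
#' Builds and solves the ILP maximising the number of selected repeated
#' fragments plus selected adjacencies — equivalently, the cumulative
#' repeat length minus the number of repeats.  The model is the circuit
#' block, the repeat block, the occurrence symmetry constraints, and either
#' the fragment-monotonicity symmetry family (when nothing is fixed) or the
#' region-fixing block (when an earlier stage's repeats are passed in).
#'
#' @param g an [mdcg][build_mdcg] object.
#' @param kind `"DR"` or `"IR"`.
#' @param fixed optional star-sets (from a previous stage's
#'   `fixed_sets_out`) to preserve.
#' @param time_limit optional solver limit in seconds.
#' @param backend optional MILP backend (see [solve_ilp]).
#' @return A `problem_result`: list with `problem`, `status`, `objective`
#'   (0 when no repeat is found or the model is infeasible), `solution`,
#'   `circuit` (decoded vertex sequence, `NULL` if unsolved),
#'   `fixed_sets_out` (the selected fragments and adjacencies, as star-sets
#'   for downstream fixing) and the fragment sets `fs`.
#' @export
solve_repeat_problem <- function(g, kind = c("DR", "IR"), fixed = NULL,
                                 time_limit = NULL, backend = NULL) {
  kind <- match.arg(kind)
  fs <- build_fragment_sets(g, kind)
  os <- build_order_sets(fs)
  model <- new_linear_model()
  add_circuit_block(model, g)
  add_repeat_block(model, g, fs, os)
  has_fixed <- !is.null(fixed) &&
    ((!is.null(fixed$frags) && nrow(fixed$frags) > 0) ||
     (!is.null(fixed$arep) && nrow(fixed$arep) > 0))
  add_symmetry_block(model, g, fs = if (has_fixed) NULL else fs)
  if (has_fixed) add_fix_regions_block(model, fixed)
  set_scaffold_objective(model, "repeat")
  sol <- solve_ilp(model, time_limit = time_limit, backend = backend)
  finish_repeat_result(g, kind, fs, sol)
}

finish_repeat_result <- function(g, kind, fs, sol) {
  res <- list(problem = problem_name(kind), kind = kind, status = sol$status,
              solution = sol, fs = fs, circuit = NULL,
              objective = 0,
              fixed_sets_out = list(
                frags = data.frame(v1 = integer(), v2 = integer(),
                                   kind = character()),
                arep = data.frame(e = integer(), partner = integer(),
                                  kind = character())))
  if (identical(sol$status, "optimal") || identical(sol$status, "limit")) {
    if (!is.null(sol$values)) {
      res$objective <- round(sol$objective, 6)
      res$circuit <- decode_circuit(sol, g)
      sel_f <- which(sol$m > 0.5)
      sel_a <- which(sol$isadj > 0.5)
      res$fixed_sets_out <- list(
        frags = if (length(sel_f)) {
          data.frame(v1 = fs$frags$v1[sel_f], v2 = fs$frags$v2[sel_f],
                     kind = kind)
        } else res$fixed_sets_out$frags,
        arep = if (length(sel_a)) {
          data.frame(e = fs$arep$e[sel_a], partner = fs$arep$partner[sel_a],
                     kind = kind)
        } else res$fixed_sets_out$arep)
    }
  }
  class(res) <- "problem_result"
  res
}

#' Solve the single-copy scaffolding problem (SCP)
#'
#' Maximises the total existence weight of the vertices in the circuit
#' (starter and reverse starter excluded), preserving any previously
#' scaffolded repeat regions.
#'
#' @inheritParams solve_repeat_problem
#' @param fixed star-sets of repeats to preserve (may be `NULL`).
#' @return A `problem_result` (see [solve_repeat_problem]); its
#'   `fixed_sets_out` is always empty.
#' @export
solve_sc_problem <- function(g, fixed = NULL, time_limit = NULL,
                             backend = NULL) {
  model <- new_linear_model()
  add_circuit_block(model, g)
  add_symmetry_block(model, g)
  has_fixed <- !is.null(fixed) &&
    ((!is.null(fixed$frags) && nrow(fixed$frags) > 0) ||
     (!is.null(fixed$arep) && nrow(fixed$arep) > 0))
  if (has_fixed) add_fix_regions_block(model, fixed)
  set_scaffold_objective(model, "sc")
  sol <- solve_ilp(model, time_limit = time_limit, backend = backend)
  res <- list(problem = "SCP", kind = "SC", status = sol$status,
              solution = sol, fs = NULL, circuit = NULL, objective = 0,
              fixed_sets_out = list(frags = data.frame(), arep = data.frame()))
  if (!is.null(sol$values) && sol$status %in% c("optimal", "limit")) {
    res$objective <- sol$objective
    res$circuit <- decode_circuit(sol, g)
  }
  class(res) <- "problem_result"
  res
}

combine_star_sets <- function(a, b) {
  list(frags = rbind(a$frags, b$frags), arep = rbind(a$arep, b$arep))
}

#' Run one hierarchical problem succession
#'
#' Runs the three scaffolding stages in the given order — `"h1"` is
#' DRP then IRP then SCP, `"h2"` is IRP then DRP then SCP.  The second
#' repeat stage preserves the first stage's regions; SCP preserves the
#' union of both.  The result records the objective vector `Z` and the
#' problem code (`"sc"`, `"dr-sc"`, `"ir-sc"`, `"dr-ir-sc"`, `"ir-dr-sc"`)
#' derived from which repeat stages found repeats.
#'
#' @param g an [mdcg][build_mdcg] object.
#' @param order `"h1"` or `"h2"`.
#' @inheritParams solve_repeat_problem
#' @return A `succession_result`: list with `order`, `Z` (3 objectives in
#'   stage order), `code`, `stage_results`, `star_sets` (union of the
#'   repeat stages' selections) and `ok` (`FALSE` when a stage failed).
#' @export
run_succession <- function(g, order = c("h1", "h2"), time_limit = NULL,
                           backend = NULL) {
  order <- match.arg(order)
  kinds <- if (order == "h1") c("DR", "IR") else c("IR", "DR")
  res <- list(order = order, Z = rep(NA_real_, 3), stage_results = list(),
              code = NA_character_, ok = TRUE,
              star_sets = list(frags = data.frame(v1 = integer(),
                                                  v2 = integer(),
                                                  kind = character()),
                               arep = data.frame(e = integer(),
                                                 partner = integer(),
                                                 kind = character())))
  class(res) <- "succession_result"

  r1 <- solve_repeat_problem(g, kinds[1], fixed = NULL,
                             time_limit = time_limit, backend = backend)
  res$stage_results[[r1$problem]] <- r1
  res$Z[1] <- r1$objective
  if (!r1$status %in% c("optimal", "limit", "infeasible")) {
    res$ok <- FALSE
    return(res)
  }
  fixed1 <- r1$fixed_sets_out

  r2 <- solve_repeat_problem(g, kinds[2], fixed = fixed1,
                             time_limit = time_limit, backend = backend)
  res$stage_results[[r2$problem]] <- r2
  res$Z[2] <- r2$objective
  if (!r2$status %in% c("optimal", "limit", "infeasible")) {
    res$ok <- FALSE
    return(res)
  }
  star <- combine_star_sets(fixed1, r2$fixed_sets_out)
  res$star_sets <- star

  r3 <- solve_sc_problem(g, fixed = star, time_limit = time_limit,
                         backend = backend)
  res$stage_results[["SCP"]] <- r3
  res$Z[3] <- r3$objective
  if (!r3$status %in% c("optimal", "limit")) res$ok <- FALSE

  stage_tags <- tolower(kinds)
  found <- res$Z[1:2] > 0
  res$code <- paste(c(stage_tags[found], "sc"), collapse = "-")
  res
}

#' Select the optimal problem successions
#'
#' Keeps the successions whose objective vector attains, componentwise, the
#' maximum over both orders.  The result may contain zero, one or two
#' successions; an empty result means the two orders are incomparable.
#'
#' @param r1,r2 `succession_result` objects for the two orders.
#' @return List (possibly empty) of the optimal `succession_result`s.
#' @export
select_successions <- function(r1, r2) {
  cand <- Filter(function(r) r$ok && !anyNA(r$Z), list(r1, r2))
  if (!length(cand)) return(list())
  zmax <- do.call(pmax, lapply(cand, `[[`, "Z"))
  Filter(function(r) all(r$Z >= zmax - 1e-9), cand)
}

#' @export
print.problem_result <- function(x, ...) {
  cat(x$problem, "result: status", x$status, ", objective", x$objective, "\n")
  invisible(x)
}

#' @export
print.succession_result <- function(x, ...) {
  cat("Succession", x$order, "(", x$code, "): Z = (",
      paste(signif(x$Z, 6), collapse = ", "), ")\n")
  invisible(x)
}
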