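## MILP backend interface.
##
## A backend is a function taking a list of serialised model payloads and
## returning a list of results, each a list(status, objective, values).
## The default backend solves with HiGHS through scipy.optimize.milp in a
## Python subprocess; any exact MILP solver can be plugged in by passing a
## function with the same contract.

serialize_model <- function(model, relax = FALSE, time_limit = NULL,
                            mip_gap = 1e-9) {
  ri <- unlist(lapply(model$chunks, `[[`, "ri"), use.names = FALSE)
  ci <- unlist(lapply(model$chunks, `[[`, "ci"), use.names = FALSE)
  cv <- unlist(lapply(model$chunks, `[[`, "cv"), use.names = FALSE)
  list(
    nvar = model$nvar,
    obj = model$obj,
    lb = model$lb,
    ub = pmin(model$ub, INF_BOUND),
    integer = as.integer(model$vtype == "B" & !relax),
    ai = ri, aj = ci, av = cv,
    rlb = pmax(model$rlb, -INF_BOUND),
    rub = pmin(model$rub, INF_BOUND),
    maximize = model$maximize,
    relax = relax,
    time_limit = if (is.null(time_limit)) -1 else time_limit,
    mip_gap = mip_gap
  )
}

#' Default MILP backend: HiGHS via scipy
#'
#' Writes the models to a temporary JSON file, solves them with
#' `scipy.optimize.milp` (the HiGHS solver) in a Python subprocess and
#' reads the solutions back.  Requires a `python` interpreter with scipy
#' on the PATH (or set `options(chloroscaf.python = ...)`).
#'
#' @param payloads list of serialised models (internal format).
#' @return List of results: `status` (`"optimal"`, `"infeasible"`,
#'   `"limit"`, `"unbounded"` or `"failed"`), `objective`, `values`.
#' @export
milp_backend_highs <- function(payloads) {
  python <- getOption("chloroscaf.python", Sys.which("python"))
  if (!nzchar(python)) stop("no python interpreter found for the MILP backend")
  runner <- system.file("python", "milp_runner.py", package = "chloroscaf",
                        mustWork = TRUE)
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payloads, fin, auto_unbox = TRUE, digits = NA,
                       always_decimal = FALSE)
  status <- system2(python, c(shQuote(runner), shQuote(fin), shQuote(fout)),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(fout)) {
    stop("MILP backend failed (exit status ", status, ")")
  }
  jsonlite::fromJSON(fout, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Solve a linear model
#'
#' Dispatches the model to a MILP backend and returns the raw solution.
#' Infeasibility is reported in the status, not raised, so the hierarchical
#' succession logic can react to it.
#'
#' @param model a [new_linear_model] with blocks and objective set.
#' @param time_limit optional wall-clock limit in seconds.
#' @param relax solve the LP relaxation instead of the integer program.
#' @param backend a backend function; default [milp_backend_highs].
#' @return An `ilp_solution`: list with `status`, `objective`, `values`
#'   and decoded component vectors (`x`, `f`, `i`, and for repeat models
#'   `m`, `isadj`).
#' @export
solve_ilp <- function(model, time_limit = NULL, relax = FALSE, backend = NULL) {
  solve_ilp_batch(list(model), time_limit = time_limit, relax = relax,
                  backend = backend)[[1]]
}

#' Solve several linear models in one backend call
#'
#' @param models list of models as in [solve_ilp].
#' @inheritParams solve_ilp
#' @return List of `ilp_solution` objects.
#' @export
solve_ilp_batch <- function(models, time_limit = NULL, relax = FALSE,
                            backend = NULL) {
  if (is.null(backend)) backend <- getOption("chloroscaf.backend",
                                             milp_backend_highs)
  payloads <- lapply(models, serialize_model, relax = relax,
                     time_limit = time_limit)
  raw <- backend(payloads)
  stopifnot(length(raw) == length(models))
  Map(function(res, model) {
    sol <- list(status = res$status,
                objective = if (is.null(res$objective)) NA_real_ else res$objective,
                values = if (is.null(res$values)) NULL else as.numeric(res$values))
    if (!is.null(sol$values)) {
      v <- sol$values
      sol$x <- v[model$x_col]
      sol$f <- v[model$f_col]
      sol$i <- ifelse(is.na(model$i_col), NA_real_, v[pmax(model$i_col, 1L)])
      if (!is.null(model$m_col)) sol$m <- v[model$m_col]
      if (!is.null(model$isadj_col)) sol$isadj <- v[model$isadj_col]
    }
    class(sol) <- "ilp_solution"
    sol
  }, raw, models)
}

#' Decode the circuit of an ILP solution
#'
#' Follows the chosen edges (`x = 1`) from the starter and verifies the
#' result is one valid circuit: it starts and ends at the starter, never
#' uses a vertex together with its reverse, and uses every chosen edge.
#'
#' @param sol an `ilp_solution` with values.
#' @param g the [mdcg][build_mdcg] the model was built on.
#' @return Integer vector of vertex indices along the circuit, starting at
#'   the starter (the closing edge back to the starter is implicit).
#' @export
decode_circuit <- function(sol, g) {
  stopifnot(inherits(sol, "ilp_solution"), !is.null(sol$values))
  chosen <- which(sol$x > 0.5)
  succ <- rep(NA_integer_, g$nV)
  eu <- g$edges$u[chosen]
  ev <- g$edges$v[chosen]
  if (anyDuplicated(eu)) stop("internal: branching circuit decoded")
  succ[eu] <- ev
  s <- g$starter_v
  path <- integer(length(chosen))
  cur <- s
  for (t in seq_along(chosen)) {
    path[t] <- cur
    cur <- succ[cur]
    if (is.na(cur)) stop("internal: broken circuit decoded")
    if (cur == s) {
      path <- path[seq_len(t)]
      break
    }
  }
  if (cur != s) stop("internal: chosen edges do not form one circuit")
  if (length(path) != length(chosen)) {
    stop("internal: chosen edges form more than one circuit")
  }
  if (any(g$rev[path] %in% path)) {
    stop("internal: circuit uses a vertex and its reverse")
  }
  path
}
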