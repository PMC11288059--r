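#' Scaffold a chloroplast genome
#'
#' The main entry point: builds the multiplied doubled contig graph, solves
#' both hierarchical problem successions (direct repeats first or inverted
#' repeats first, single copies last, each stage preserving the previous
#' stages' regions), keeps the succession(s) whose objective vector attains
#' the componentwise maximum, decomposes each retained solution circuit
#' into genomic regions, and enumerates every coexisting genome form as an
#' Eulerian circuit of the region graph.
#'
#' When the two successions are incomparable (neither dominates), both are
#' retained and the result is flagged ambiguous.
#'
#' @param input a [scaffold_input] object.
#' @param time_limit optional per-stage solver limit in seconds.
#' @param backend optional MILP backend function (see [solve_ilp]).
#' @return An object of class `chloroscaf`: list with the `input`, the
#'   graph `g`, both `successions`, the `selected` succession orders,
#'   `ambiguous`, and `results` — one entry per retained succession with
#'   the `decomposition`, the `region_graph` and the enumerated `forms`.
#' @examples
#' \donttest{
#' inp <- generate_perfect(2, 2)
#' fit <- scaffold(inp)
#' print(fit)
#' }
#' @export
scaffold <- function(input, time_limit = NULL, backend = NULL) {
  stopifnot(inherits(input, "scaffold_input"))
  g <- build_mdcg(input)
  h1 <- run_succession(g, "h1", time_limit = time_limit, backend = backend)
  h2 <- run_succession(g, "h2", time_limit = time_limit, backend = backend)
  sel <- select_successions(h1, h2)
  ambiguous <- length(sel) == 0
  if (ambiguous) sel <- Filter(function(r) r$ok, list(h1, h2))
  if (!length(sel)) stop("no succession could be solved (infeasible input?)")

  results <- lapply(sel, function(r) {
    scp <- r$stage_results[["SCP"]]
    if (is.null(scp$circuit)) return(NULL)
    d <- extract_regions(g, scp$circuit, r$star_sets)
    rg <- build_region_graph(d)
    forms <- enumerate_genome_forms(rg)
    list(order = r$order, code = r$code, Z = r$Z,
         decomposition = d, region_graph = rg, forms = forms)
  })
  results <- Filter(Negate(is.null), results)
  structure(list(input = input, g = g,
                 successions = list(h1 = h1, h2 = h2),
                 selected = vapply(sel, `[[`, "", "order"),
                 ambiguous = ambiguous,
                 results = results),
            class = "chloroscaf")
}

#' @export
print.chloroscaf <- function(x, ...) {
  cat("Chloroplast scaffolding of", nrow(x$input$contigs), "contigs",
      "(|V| =", x$g$nV, ", |E| =", x$g$nE, ")\n")
  for (h in c("h1", "h2")) {
    r <- x$successions[[h]]
    cat(sprintf("  %s (%s): Z = (%s)%s\n", h,
                ifelse(is.na(r$code), "failed", r$code),
                paste(signif(r$Z, 6), collapse = ", "),
                if (h %in% x$selected) "  [selected]" else ""))
  }
  if (x$ambiguous) cat("  successions incomparable: both retained\n")
  for (res in x$results) {
    cat(sprintf("  %s: %d regions, %d genome form(s)\n", res$order,
                length(res$decomposition$COR), length(res$forms)))
  }
  invisible(x)
}

#' @export
summary.chloroscaf <- function(object, ...) {
  print(object)
  for (res in object$results) {
    cat("\nSuccession", res$order, "\n")
    print(res$decomposition)
    for (i in seq_along(res$forms)) {
      f <- res$forms[[i]]
      cat(sprintf("  form %d: %s\n", i,
                  paste(paste0(f$rid - 1L, "_", f$ror), collapse = " -> ")))
    }
  }
  invisible(object)
}

#' Plot the region graph of a scaffolding result
#'
#' Draws the region multidigraph (oriented regions as vertices, region
#' adjacencies as edges) of the first retained succession.  Requires the
#' igraph package.
#'
#' @param x a `chloroscaf` object.
#' @param which index of the retained succession to plot.
#' @param ... passed to `plot.igraph`.
#' @export
plot.chloroscaf <- function(x, which = 1L, ...) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("plotting the region graph requires the igraph package")
  }
  rg <- x$results[[which]]$region_graph
  labels <- paste0(rg$vertices$rid - 1L, "_", rg$vertices$ror)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = labels[rg$edges$from], to = labels[rg$edges$to]),
    vertices = data.frame(name = labels))
  plot(ig, ...)
  invisible(x)
}
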