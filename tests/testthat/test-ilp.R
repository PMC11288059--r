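# The circuit / repeat / symmetry constraint blocks and the solver bridge.

toy_irp_model <- function(g) {
  fs <- build_fragment_sets(g, "IR")
  os <- build_order_sets(fs)
  m <- new_linear_model()
  add_circuit_block(m, g)
  add_repeat_block(m, g, fs, os)
  add_symmetry_block(m, g, fs)
  set_scaffold_objective(m, "repeat")
  m
}

test_that("the toy inverted-repeat circuit is optimal and decodes cleanly", {
  g <- build_mdcg(toy_input())
  m <- toy_irp_model(g)
  sol <- solve_ilp(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 3)
  cp <- decode_circuit(sol, g)
  expect_equal(cp[1], g$starter_v)
  expect_token_seq(g, cp, c("a_f0", "c_r1", "b_f0", "d_f0", "b_r1", "c_f0"))
  # chosen-edge multigraph is one circuit: in = out = 1 at used vertices
  chosen <- which(sol$x > 0.5)
  expect_equal(sort(g$edges$u[chosen]), sort(cp))
  expect_equal(sort(g$edges$v[chosen]), sort(cp))
  # vertex indicators are integral at the optimum
  expect_true(all(abs(sol$i - round(sol$i)) < 1e-6, na.rm = TRUE))
  # objective equals the recomputed fragment + adjacency count
  expect_equal(sum(sol$m > 0.5) + sum(sol$isadj > 0.5), sol$objective)
})

test_that("a graph whose only cycles avoid the starter is infeasible", {
  inp <- suppressMessages(scaffold_input(
    data.frame(id = c("s", "x", "y"), mult = 1L, wex = 1),
    data.frame(c1 = c("x", "y"), o1 = "f", c2 = c("y", "x"), o2 = "f"),
    starter = "s"))
  g <- build_mdcg(inp)
  m <- new_linear_model()
  add_circuit_block(m, g)
  add_symmetry_block(m, g)
  set_scaffold_objective(m, "sc")
  sol <- solve_ilp(m)
  expect_equal(sol$status, "infeasible")
})

test_that("symmetry constraints do not change the optimum", {
  g <- build_mdcg(suppressMessages(generate_perfect(2, 2)))
  fs <- build_fragment_sets(g, "IR")
  os <- build_order_sets(fs)
  with_sym <- toy_irp_model(g)
  without <- new_linear_model()
  add_circuit_block(without, g)
  add_repeat_block(without, g, fs, os)
  set_scaffold_objective(without, "repeat")
  sols <- solve_ilp_batch(list(with_sym, without))
  expect_equal(sols[[1]]$objective, sols[[2]]$objective)
  expect_equal(sols[[1]]$objective, 2 * 2 - 1)
})

test_that("fixing a full circuit leaves a unique feasible point", {
  g <- build_mdcg(toy_input())
  m0 <- toy_irp_model(g)
  sol <- solve_ilp(m0)
  cp <- decode_circuit(sol, g)
  eids <- mdcg_eid(g, cp, cp[c(seq_along(cp)[-1], 1L)])
  m1 <- new_linear_model()
  add_circuit_block(m1, g)
  add_symmetry_block(m1, g)
  # pin every edge of the circuit: SCP must return exactly that circuit
  half <- seq_len(floor(length(eids) / 2))
  add_fix_regions_block(m1, list(arep = data.frame(e = eids[half],
                                                   partner = eids[-half])))
  set_scaffold_objective(m1, "sc")
  sol1 <- solve_ilp(m1)
  expect_equal(sol1$status, "optimal")
  expect_equal(decode_circuit(sol1, g), cp)
})

test_that("fixing regions rejects edges absent from the graph", {
  g <- build_mdcg(toy_input())
  m <- new_linear_model()
  add_circuit_block(m, g)
  expect_error(add_fix_regions_block(m, list(arep = data.frame(e = 1L,
                                                               partner = NA))),
               "absent")
})

test_that("an empty fixed set leaves the model unchanged", {
  g <- build_mdcg(toy_input())
  m <- new_linear_model()
  add_circuit_block(m, g)
  nrow0 <- m$nrow
  lb0 <- m$lb
  add_fix_regions_block(m, list(frags = data.frame(), arep = data.frame()))
  expect_equal(m$nrow, nrow0)
  expect_equal(m$lb, lb0)
})

test_that("alpha orders used vertices consistently with their positions", {
  g <- build_mdcg(toy_input())
  m <- toy_irp_model(g)
  sol <- solve_ilp(m)
  cp <- decode_circuit(sol, g)
  pos <- integer(g$nV)
  pos[cp] <- seq_along(cp)
  os <- m$os
  for (r in seq_len(nrow(os$alpha))) {
    u <- os$alpha$u[r]; v <- os$alpha$v[r]
    if (pos[u] > 0 && pos[v] > 0) {
      expect_equal(sol$values[m$alpha_col[r]] > 0.5, pos[u] < pos[v])
    }
  }
})
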