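toy_solution <- function() {
  g <- build_mdcg(toy_input())
  r <- solve_repeat_problem(g, "IR")
  list(g = g, r = r)
}

test_that("the toy solution decomposes into the four expected regions", {
  ts <- toy_solution()
  d <- extract_regions(ts$g, ts$r$circuit, ts$r$fixed_sets_out)
  expect_equal(length(d$COR), 3L)          # 3 distinct regions...
  expect_equal(nrow(d$SOR), 4L)            # ...spanning 4 SOR entries (2m+n)
  expect_equal(d$region_types, c("SC", "IR", "SC"))
  cor_tokens <- lapply(d$COR, function(r) paste0(r$contig, "_", r$or))
  expect_equal(cor_tokens, list("a_f", c("c_r", "b_f"), "d_f"))
  expect_equal(paste0(d$SOR$rid - 1L, "_", d$SOR$ror),
               c("0_f", "1_f", "2_f", "1_r"))
})

test_that("region typing distinguishes repeats from single copies", {
  ts <- toy_solution()
  star <- ts$r$fixed_sets_out
  g <- ts$g
  tok <- vertex_token(g, seq_len(g$nV))
  expect_equal(vertex_region_type(g, match("c_r1", tok), star), "IR")
  expect_equal(vertex_region_type(g, g$starter_v, star), "SC")
  expect_equal(vertex_region_type(g, match("d_f0", tok), star), "SC")
})

test_that("the initial vertex opens the starter's single-copy region", {
  ts <- toy_solution()
  # toy: the starter is its whole region
  expect_equal(initial_vertex(ts$g, ts$r$circuit, ts$r$fixed_sets_out),
               ts$g$starter_v)
  # starter mid-region: rotate a no-repeat circuit so s sits in the middle
  inp <- suppressMessages(scaffold_input(
    data.frame(id = c("s", "x", "y"), mult = 1L, wex = 1),
    data.frame(c1 = c("s", "x", "y"), o1 = "f",
               c2 = c("x", "y", "s"), o2 = "f"),
    starter = "s"))
  g <- build_mdcg(inp)
  r <- solve_sc_problem(g)
  empty_star <- list(frags = data.frame(), arep = data.frame())
  # all-single-copy circuit: full-loop guard returns the starter itself
  expect_equal(initial_vertex(g, r$circuit, empty_star), g$starter_v)
  d <- extract_regions(g, r$circuit, empty_star)
  expect_equal(length(d$COR), 1L)
  expect_equal(paste0(d$SOR$rid - 1L, "_", d$SOR$ror), "0_f")
})

test_that("repeat contiguity follows selected adjacencies", {
  ts <- toy_solution()
  g <- ts$g
  star <- ts$r$fixed_sets_out
  tok <- vertex_token(g, seq_len(g$nV))
  expect_true(repeat_contiguous(g, match("c_r1", tok), match("b_f0", tok), star))
  expect_true(repeat_contiguous(g, match("b_r1", tok), match("c_f0", tok), star))
  # not consecutive partner occurrences: boundary
  expect_false(repeat_contiguous(g, match("b_f0", tok), match("c_r1", tok), star))
  # dropping the adjacency from the star sets breaks contiguity
  no_adj <- list(frags = star$frags, arep = star$arep[0, , drop = FALSE])
  expect_false(repeat_contiguous(g, match("c_r1", tok), match("b_f0", tok),
                                 no_adj))
})

test_that("direct repeats extract one region per side with FIFO matching", {
  g <- build_mdcg(suppressMessages(generate_perfect_dr(2, 3)))
  r <- solve_repeat_problem(g, "DR")
  expect_equal(r$objective, 2 * 3 - 1)
  d <- extract_regions(g, r$circuit, r$fixed_sets_out)
  expect_equal(sum(d$region_types == "DR"), 1L)
  # DR partner referenced forward, twice
  dr_rid <- which(d$region_types == "DR")
  refs <- d$SOR[d$SOR$rid == dr_rid, ]
  expect_equal(nrow(refs), 2L)
  expect_equal(refs$ror, c("f", "f"))
})

test_that("flattening the decomposition reproduces the solution circuit", {
  cases <- list(toy_solution(),
                {
                  g <- build_mdcg(suppressMessages(generate_perfect(3, 2)))
                  list(g = g, r = solve_repeat_problem(g, "IR"))
                })
  for (ts in cases) {
    d <- extract_regions(ts$g, ts$r$circuit, ts$r$fixed_sets_out)
    flat <- flatten_regions(d)
    vd <- ts$g$vdf[ts$r$circuit, ]
    rot <- function(x, k) if (k == 0) x else c(x[-seq_len(k)], x[seq_len(k)])
    # rotation-equivalent to the circuit's oriented contig sequence
    circ_tok <- paste0(vd$contig, "_", c("f", "r")[vd$or + 1L])
    flat_tok <- paste0(flat$contig, "_", flat$or)
    shifts <- vapply(seq_along(circ_tok) - 1L, function(k) {
      identical(rot(circ_tok, k), flat_tok)
    }, logical(1))
    expect_true(any(shifts))
    # region multiset conservation
    expect_equal(nrow(flat), length(ts$r$circuit))
  }
})

test_that("IR partners are exact reverses and DR partners exact copies", {
  cases <- list(
    {
      g <- build_mdcg(suppressMessages(generate_perfect(2, 3)))
      list(g = g, r = solve_repeat_problem(g, "IR"))
    },
    {
      g <- build_mdcg(suppressMessages(generate_perfect_dr(2, 3)))
      list(g = g, r = solve_repeat_problem(g, "DR"))
    })
  for (ts in cases) {
    d <- extract_regions(ts$g, ts$r$circuit, ts$r$fixed_sets_out)
    flat_ref <- function(rid, ror) {
      r <- d$COR[[rid]]
      if (ror == "r") reverse_region(r) else r
    }
    for (rid in which(d$region_types != "SC")) {
      refs <- which(d$SOR$rid == rid)
      expect_equal(length(refs), 2L)
      r1 <- flat_ref(d$SOR$rid[refs[1]], d$SOR$ror[refs[1]])
      r2 <- flat_ref(d$SOR$rid[refs[2]], d$SOR$ror[refs[2]])
      if (d$region_types[rid] == "IR") {
        expect_equal(reverse_region(r1), r2, ignore_attr = TRUE)
      } else {
        expect_equal(r1, r2, ignore_attr = TRUE)
      }
    }
  }
})
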