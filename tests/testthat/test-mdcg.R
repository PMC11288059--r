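test_that("MDCG sizes follow the closed forms", {
  g <- build_mdcg(toy_input())
  expect_equal(g$nV, 12L)   # 2 * (1+2+2+1)
  expect_equal(g$nE, 24L)   # sum over the 10 links of mult(c)*mult(d)
  # one contig, no links
  one <- scaffold_input(data.frame(id = "s", mult = 1, wex = 0),
                        data.frame(), starter = "s")
  g1 <- build_mdcg(one)
  expect_equal(g1$nV, 2L)
  expect_equal(g1$nE, 0L)
})

test_that("edge set is closed under reversal", {
  for (inp in list(toy_input(), random_tiny_input(7))) {
    g <- build_mdcg(inp)
    rev_eids <- mdcg_eid(g, g$rev[g$edges$v], g$rev[g$edges$u])
    expect_false(anyNA(rev_eids))
  }
})

test_that("vertex reversal is an involution flipping only the orientation", {
  g <- build_mdcg(toy_input())
  v <- seq_len(g$nV)
  rv <- reverse_vertex(g, v)
  expect_equal(reverse_vertex(g, rv), v)
  expect_equal(g$vdf$contig[rv], g$vdf$contig[v])
  expect_equal(g$vdf$occ[rv], g$vdf$occ[v])
  expect_equal(g$vdf$or[rv], 1L - g$vdf$or[v])
  expect_equal(g$vdf$wex, g$vdf$wex[g$rev])  # weight equals the contig's
})

test_that("fragment counts match the worked two-contig example", {
  # contigs c (mult 4) and d (mult 2): |DirF| = 6, |PDirF| = 12,
  # |InvF| = 3, |PInvF| = 3
  inp <- suppressMessages(scaffold_input(
    data.frame(id = c("e", "c", "d"), mult = c(1L, 4L, 2L), wex = 1),
    data.frame(c1 = "c", o1 = "f", c2 = "d", o2 = "f"),
    starter = "e"))
  g <- build_mdcg(inp)
  dr <- build_fragment_sets(g, "DR")
  ir <- build_fragment_sets(g, "IR")
  expect_equal(nrow(dr$frags), 6L)
  expect_equal(nrow(dr$pairs), 12L)
  expect_equal(nrow(ir$frags), 3L)
  expect_equal(nrow(ir$pairs), 3L)
  # closed-form counts: sum 2*floor(mult/2) and sum floor(mult/2)
  expect_equal(nrow(dr$frags), sum(2L * (g$mult %/% 2L)[g$mult > 1]))
  expect_equal(nrow(ir$frags), sum((g$mult %/% 2L)[g$mult > 1]))
})

test_that("all fragment sets are empty when every multiplicity is 1", {
  inp <- suppressMessages(scaffold_input(
    data.frame(id = c("s", "x"), mult = 1L, wex = 1),
    data.frame(c1 = "s", o1 = "f", c2 = "x", o2 = "f"), starter = "s"))
  g <- build_mdcg(inp)
  for (kind in c("DR", "IR")) {
    fs <- build_fragment_sets(g, kind)
    expect_equal(nrow(fs$frags), 0L)
    expect_equal(nrow(fs$pairs), 0L)
    expect_equal(nrow(fs$arep), 0L)
    os <- build_order_sets(fs)
    expect_equal(nrow(os$alpha), 0L)
    expect_equal(nrow(os$forbid), 0L)
  }
})

test_that("repadj matches the canonical adjacency examples", {
  # link ((c,f),(d,f)) with mult(c) = mult(d) = 2:
  # diradj(c_f0 -> d_f0) = (c_f1 -> d_f1); invadj(c_f0 -> d_f0) = (d_r1 -> c_r1)
  inp <- suppressMessages(scaffold_input(
    data.frame(id = c("s", "c", "d"), mult = c(1L, 2L, 2L), wex = 1),
    data.frame(c1 = "c", o1 = "f", c2 = "d", o2 = "f"), starter = "s"))
  g <- build_mdcg(inp)
  tok_edge <- function(e) paste(vertex_token(g, g$edges$u[e]),
                                vertex_token(g, g$edges$v[e]))
  dr <- build_fragment_sets(g, "DR")
  canon <- tok_edge(dr$arep$e)
  i <- match("c_f0 d_f0", canon)
  expect_false(is.na(i))
  expect_equal(tok_edge(dr$arep$partner[i]), "c_f1 d_f1")
  ir <- build_fragment_sets(g, "IR")
  canon <- tok_edge(ir$arep$e)
  i <- match("c_f0 d_f0", canon)
  expect_false(is.na(i))
  expect_equal(tok_edge(ir$arep$partner[i]), "d_r1 c_r1")
})

test_that("adjacent fragment edges cover two distinct fragments", {
  for (seed in c(3, 11, 42)) {
    g <- build_mdcg(random_tiny_input(seed))
    for (kind in c("DR", "IR")) {
      fs <- build_fragment_sets(g, kind)
      if (!nrow(fs$arep)) next
      # endpoints of the canonical edge and of its partner cover exactly
      # the two fragments, and repfrag is defined on all four endpoints
      for (r in seq_len(nrow(fs$arep))) {
        u <- g$edges$u[fs$arep$e[r]]; v <- g$edges$v[fs$arep$e[r]]
        pu <- g$edges$u[fs$arep$partner[r]]; pv <- g$edges$v[fs$arep$partner[r]]
        fr <- fs$repfrag[c(u, v, pu, pv)]
        expect_false(anyNA(fr))
        expect_setequal(unique(fr), c(fs$arep$fu[r], fs$arep$fv[r]))
        expect_equal(length(unique(fr)), 2L)
      }
    }
  }
})
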