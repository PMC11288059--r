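toy_valid_d <- function() {
  g <- build_mdcg(toy_input())
  r <- solve_repeat_problem(g, "IR")
  extract_regions(g, r$circuit, r$fixed_sets_out)
}

test_that("the toy decomposition certifies k = 4 with one inverted repeat", {
  d <- toy_valid_d()
  rep <- check_sor(d, k = 4, m_max = 1)
  expect_true(rep$sor_valid)
  expect_equal(rep$cumulative_repeat_length, 4L)
  expect_equal(rep$n_inverted_repeats, 1L)
  # stricter k fails
  expect_false(check_sor(d, k = 6, m_max = 1)$sor_valid)
  expect_false(check_sor(d, k = 4, m_max = 0)$sor_valid)
  # no repeats, k = 0, m' = 0: valid
  d0 <- structure(list(COR = list(data.frame(contig = "s", or = "f")),
                       SOR = data.frame(rid = 1L, ror = "f"),
                       region_types = "SC"), class = "region_decomposition")
  expect_true(check_sor(d0, k = 0, m_max = 0)$sor_valid)
})

test_that("crossing inverted repeats are rejected by the LIFO pass", {
  # SOR 0f 1f 2f 1r 3f 2r 3r: IR pairs (1,1) and (2,2) cross
  reg <- function(id) data.frame(contig = id, or = "f")
  d <- structure(list(
    COR = list(reg("s"), reg("a"), reg("b"), reg("c")),
    SOR = data.frame(rid = c(1L, 2L, 3L, 2L, 4L, 3L, 4L),
                     ror = c("f", "f", "f", "r", "f", "r", "r")),
    region_types = c("SC", "IR", "IR", "IR")), class = "region_decomposition")
  rep <- check_sor(d)
  expect_false(rep$sor_valid)
  expect_match(paste(rep$violations, collapse = " "), "cross")
  # nested instead of crossed: accepted
  d$SOR <- data.frame(rid = c(1L, 2L, 3L, 4L, 3L, 2L),
                      ror = c("f", "f", "f", "f", "r", "r"))
  expect_true(check_sor(d)$sor_valid)
})

test_that("nesting direct repeats are rejected by the FIFO variant", {
  reg <- function(id) data.frame(contig = id, or = "f")
  d <- structure(list(
    COR = list(reg("s"), reg("a"), reg("b")),
    # (a .. b .. b .. a): DR pair a nests DR pair b
    SOR = data.frame(rid = c(1L, 2L, 3L, 3L, 2L), ror = "f"),
    region_types = c("SC", "DR", "DR")), class = "region_decomposition")
  expect_false(check_sor(d, check_dr = TRUE)$sor_valid)
  # interleaved (a .. b .. a .. b): accepted
  d$SOR <- data.frame(rid = c(1L, 2L, 3L, 2L, 3L), ror = "f")
  expect_true(check_sor(d, check_dr = TRUE)$sor_valid)
})

test_that("the flattened contig sequence is checked against links and mult", {
  d <- toy_valid_d()
  inp <- toy_input()
  expect_true(check_soc(d, inp)$soc_valid)
  # lowering mult(b) to 1 breaks the multiplicity condition
  c2 <- toy_contigs(); c2$mult[c2$id == "b"] <- 1L
  inp2 <- suppressMessages(scaffold_input(c2, toy_links(), starter = "a"))
  rep2 <- check_soc(d, inp2)
  expect_false(rep2$soc_valid)
  expect_match(paste(rep2$violations, collapse = " "), "multiplicity")
  # deleting one link breaks an adjacency, which is reported
  l3 <- toy_links()[-1, ]   # drop (a_f, c_r)
  inp3 <- suppressMessages(scaffold_input(toy_contigs(), l3, starter = "a"))
  rep3 <- check_soc(d, inp3)
  expect_false(rep3$soc_valid)
  expect_match(paste(rep3$violations, collapse = " "), "a_f, c_r")
})

test_that("solver-produced decompositions always pass both validators", {
  for (inp in list(generate_perfect(2, 2), generate_perfect_dr(2, 2))) {
    g <- build_mdcg(inp)
    r <- run_succession(g, "h2")
    scp <- r$stage_results[["SCP"]]
    d <- extract_regions(g, scp$circuit, r$star_sets)
    expect_true(check_sor(d, check_dr = TRUE)$sor_valid)
    expect_true(check_soc(d, inp)$soc_valid)
  }
})
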