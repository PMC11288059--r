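test_that("link sets are completed to their reverse closure on load", {
  inp <- toy_input()
  expect_equal(nrow(inp$contigs), 4L)
  expect_equal(inp$contigs$mult[inp$contigs$id == "b"], 2L)
  expect_equal(inp$contigs$wex[inp$contigs$id == "c"], 0.17)
  # 5 listed links complete to 10 with their reverses
  expect_equal(nrow(inp$links), 10L)
  rev <- chloroscaf:::reverse_link_table(inp$links)
  expect_setequal(chloroscaf:::link_key(rev), chloroscaf:::link_key(inp$links))
})

test_that("TSV round trip is the identity on the reverse-closed input", {
  inp <- toy_input()
  cp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".tsv")
  write_scaffold_input(inp, cp, lp)
  back <- suppressMessages(read_scaffold_input(cp, lp, starter_id = "a"))
  expect_equal(back$contigs, inp$contigs)
  expect_equal(back$links, inp$links)
  expect_equal(back$starter, "a")
})

test_that("degenerate and malformed inputs are handled", {
  # single contig, no links: valid
  one <- scaffold_input(data.frame(id = "s", mult = 1, wex = 0),
                        data.frame(), starter = "s")
  expect_equal(nrow(one$links), 0L)
  # link naming an unknown contig
  expect_error(
    scaffold_input(toy_contigs(),
                   data.frame(c1 = "a", o1 = "f", c2 = "z", o2 = "f"),
                   starter = "a"),
    "unknown contig")
  # starter must have multiplicity 1
  expect_error(scaffold_input(toy_contigs(), toy_links(), starter = "b"),
               "multiplicity 1")
  # bad orientation token
  expect_error(
    scaffold_input(toy_contigs(),
                   data.frame(c1 = "a", o1 = "x", c2 = "b", o2 = "f"),
                   starter = "a"),
    "orientation")
  # non-positive multiplicity
  bad <- toy_contigs(); bad$mult[1] <- 0L
  expect_error(suppressMessages(scaffold_input(bad, toy_links(), starter = "a")),
               "positive")
  # missing starter defaults to the first contig with a warning
  expect_warning(suppressMessages(scaffold_input(toy_contigs(), toy_links())),
                 "defaulting")
})

test_that("results artefacts round-trip through write and read", {
  d <- structure(list(
    COR = list(data.frame(contig = c("a", "b"), or = c("f", "r"))),
    SOR = data.frame(rid = 1L, ror = "f"),
    region_types = "SC"), class = "region_decomposition")
  dir <- withr::local_tempdir()
  paths <- write_results(d, forms = list(), out_dir = dir)
  back <- read_region_decomposition(file.path(dir, "regions.tsv"))
  expect_equal(back$COR, d$COR)
  expect_equal(back$SOR$rid, d$SOR$rid)
  expect_equal(back$SOR$ror, d$SOR$ror)
  expect_equal(back$region_types, d$region_types)
  # empty form list: header-only file
  expect_equal(length(read_genome_forms(file.path(dir, "forms.tsv"))), 0L)
})

test_that("toy decomposition writes 3 region rows and 2 form rows", {
  fit <- scaffold(toy_input())
  res <- fit$results[[1]]
  dir <- withr::local_tempdir()
  write_results(res$decomposition, res$forms, dir,
                run_info = data.frame(order = res$order, code = res$code))
  regions <- utils::read.delim(file.path(dir, "regions.tsv"), comment.char = "#")
  forms <- utils::read.delim(file.path(dir, "forms.tsv"))
  expect_equal(nrow(regions), 3L)
  expect_equal(nrow(forms), 2L)
  back <- read_genome_forms(file.path(dir, "forms.tsv"))
  expect_equal(back, lapply(res$forms, function(f) {
    f
  }), ignore_attr = TRUE)
})
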