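# Shared fixtures, built in code.

# The 4-contig toy instance: a and d single-copy, b and c multiplicity 2,
# links listed in one direction only (reverse closure happens on load).
toy_contigs <- function() {
  data.frame(id = c("a", "b", "c", "d"), mult = c(1L, 2L, 2L, 1L),
             wex = c(0.70, 0.83, 0.17, 0.43), stringsAsFactors = FALSE)
}

toy_links <- function() {
  data.frame(c1 = c("a", "a", "b", "b", "b"),
             o1 = c("f", "r", "r", "f", "f"),
             c2 = c("c", "c", "c", "d", "d"),
             o2 = c("r", "r", "f", "f", "r"),
             stringsAsFactors = FALSE)
}

toy_input <- function() {
  suppressMessages(scaffold_input(toy_contigs(), toy_links(), starter = "a"))
}

# random small instance with a guaranteed feasible circuit
# (chain starter -> c1 -> ... -> starter) plus random extra links;
# total multiplicity <= 7 so |V| <= 14
random_tiny_input <- function(seed) {
  set.seed(seed)
  n_extra <- sample(2:4, 1)
  mult <- c(1L, sample(1:2, n_extra, replace = TRUE))
  while (sum(mult) > 7L) mult <- c(1L, sample(1:2, n_extra, replace = TRUE))
  ids <- c("s", paste0("c", seq_len(n_extra)))
  contigs <- data.frame(id = ids, mult = mult,
                        wex = round(stats::runif(n_extra + 1), 2),
                        stringsAsFactors = FALSE)
  chain <- data.frame(c1 = ids, o1 = "f", c2 = c(ids[-1], ids[1]), o2 = "f",
                      stringsAsFactors = FALSE)
  n_rand <- sample(2:4, 1)
  extra <- data.frame(c1 = sample(ids, n_rand, replace = TRUE),
                      o1 = sample(c("f", "r"), n_rand, replace = TRUE),
                      c2 = sample(ids, n_rand, replace = TRUE),
                      o2 = sample(c("f", "r"), n_rand, replace = TRUE),
                      stringsAsFactors = FALSE)
  suppressMessages(scaffold_input(contigs, rbind(chain, extra), starter = "s"))
}

expect_token_seq <- function(g, vertices, tokens) {
  expect_equal(vertex_token(g, vertices), tokens)
}
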