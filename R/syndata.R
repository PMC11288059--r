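## Artificial benchmark instance generators.

chain_links <- function(ids) {
  n <- length(ids)
  if (n < 2) return(data.frame(c1 = character(), o1 = character(),
                               c2 = character(), o2 = character()))
  data.frame(c1 = ids[-n], o1 = "f", c2 = ids[-1], o2 = "f",
             stringsAsFactors = FALSE)
}

#' Generate a perfect artificial instance
#'
#' Builds the smallest contig and link set whose genome architecture is the
#' circular sequence of oriented regions `SC1 - IR - SC2 - rev(IR)` (the
#' classic quadripartite chloroplast layout): `sc_len` multiplicity-1
#' contigs per single copy (the first is the starter), `ir_len`
#' multiplicity-2 contigs for the inverted repeat, forward chain links
#' inside each region and four junction links closing the circle — last
#' SC1 to first IR (f,f), last IR to first SC2 (f,f), last SC2 to last IR
#' reversed (f,r) and first IR reversed to first SC1 (r,f).  All weights
#' are 1 and the emitted link set is reverse-closed.
#'
#' The intended solution circuit is attached as attribute `witness` (a
#' data frame of contig/orientation/occurrence), for use as a constructive
#' test oracle.  The optimal inverted-repeat objective of such an instance
#' is `2 * ir_len - 1` (`ir_len` fragments plus `ir_len - 1` adjacencies).
#'
#' @param sc_len contigs per single-copy region (at least 1).
#' @param ir_len contigs per inverted-repeat region (at least 1).
#' @return A [scaffold_input] with attribute `witness`.
#' @examples
#' inp <- generate_perfect(20, 20)
#' g <- build_mdcg(inp)
#' c(nrow(g$vdf), nrow(g$edges))  # 160, 244
#' @export
generate_perfect <- function(sc_len = 20, ir_len = 20) {
  stopifnot(sc_len >= 1, ir_len >= 1)
  sc1 <- sprintf("sc1_%03d", seq_len(sc_len))
  ir <- sprintf("ir_%03d", seq_len(ir_len))
  sc2 <- sprintf("sc2_%03d", seq_len(sc_len))
  contigs <- data.frame(id = c(sc1, ir, sc2),
                        mult = c(rep(1L, sc_len), rep(2L, ir_len),
                                 rep(1L, sc_len)),
                        wex = 1, stringsAsFactors = FALSE)
  junctions <- data.frame(
    c1 = c(sc1[sc_len], ir[ir_len], sc2[sc_len], ir[1]),
    o1 = c("f", "f", "f", "r"),
    c2 = c(ir[1], sc2[1], ir[ir_len], sc1[1]),
    o2 = c("f", "f", "r", "f"),
    stringsAsFactors = FALSE)
  links <- rbind(chain_links(sc1), chain_links(ir), chain_links(sc2),
                 junctions)
  inp <- suppressMessages(scaffold_input(contigs, links, starter = sc1[1]))
  witness <- data.frame(
    contig = c(sc1, ir, sc2, rev(ir)),
    or = c(rep("f", sc_len + ir_len + sc_len), rep("r", ir_len)),
    occ = c(rep(0L, sc_len + ir_len + sc_len), rep(1L, ir_len)),
    stringsAsFactors = FALSE)
  attr(inp, "witness") <- witness
  inp
}

#' Generate a perfect direct-repeat instance
#'
#' Mirror of [generate_perfect] for the architecture
#' `SC1 - DR - SC2 - DR` (both repeat copies forward): `dr_len`
#' multiplicity-2 contigs for the direct repeat, junctions last SC1 to
#' first DR, last DR to first SC2, last SC2 to first DR, last DR to first
#' SC1 (all forward).  The optimal direct-repeat objective is
#' `2 * dr_len - 1`.
#'
#' @param sc_len contigs per single-copy region.
#' @param dr_len contigs per direct-repeat region.
#' @return A [scaffold_input] with attribute `witness`.
#' @export
generate_perfect_dr <- function(sc_len = 20, dr_len = 20) {
  stopifnot(sc_len >= 1, dr_len >= 1)
  sc1 <- sprintf("sc1_%03d", seq_len(sc_len))
  dr <- sprintf("dr_%03d", seq_len(dr_len))
  sc2 <- sprintf("sc2_%03d", seq_len(sc_len))
  contigs <- data.frame(id = c(sc1, dr, sc2),
                        mult = c(rep(1L, sc_len), rep(2L, dr_len),
                                 rep(1L, sc_len)),
                        wex = 1, stringsAsFactors = FALSE)
  junctions <- data.frame(
    c1 = c(sc1[sc_len], dr[dr_len], sc2[sc_len], dr[dr_len]),
    o1 = "f",
    c2 = c(dr[1], sc2[1], dr[1], sc1[1]),
    o2 = "f",
    stringsAsFactors = FALSE)
  links <- rbind(chain_links(sc1), chain_links(dr), chain_links(sc2),
                 junctions)
  inp <- suppressMessages(scaffold_input(contigs, links, starter = sc1[1]))
  witness <- data.frame(
    contig = c(sc1, dr, sc2, dr),
    or = "f",
    occ = c(rep(0L, sc_len + dr_len + sc_len), rep(1L, dr_len)),
    stringsAsFactors = FALSE)
  attr(inp, "witness") <- witness
  inp
}

#' Generate a noisy artificial instance
#'
#' Starts from the perfect instance of [generate_perfect] and degrades it
#' the way read-derived inputs are degraded: independently for every
#' contig except the starter, the multiplicity is overestimated by one
#' with probability `noise_mult_prob`; independently for every contig, one
#' extra link to another uniformly chosen contig (orientations of both
#' endpoints uniform) is added with probability `noise_link_prob`.  Extra
#' links are reverse-closed and duplicates dropped, so every noisy
#' instance is a well-formed supergraph of the perfect one — in particular
#' the perfect solution stays feasible and the noisy repeat optimum is at
#' least the perfect one.  Fully reproducible from `seed`.
#'
#' @param sc_len,ir_len as in [generate_perfect].
#' @param noise_mult_prob probability of a +1 multiplicity overestimate
#'   (default 0.25).
#' @param noise_link_prob probability of one extra random link per contig
#'   (default 0.25).
#' @param seed integer seed for the random noise.
#' @return A [scaffold_input].
#' @export
generate_noisy <- function(sc_len = 20, ir_len = 20,
                           noise_mult_prob = 0.25, noise_link_prob = 0.25,
                           seed = 1L) {
  stopifnot(noise_mult_prob >= 0, noise_mult_prob <= 1,
            noise_link_prob >= 0, noise_link_prob <= 1)
  base <- generate_perfect(sc_len, ir_len)
  contigs <- base$contigs
  links <- base$links
  set.seed(as.integer(seed))
  bump <- stats::rbinom(nrow(contigs), 1L, noise_mult_prob) == 1L
  bump[contigs$id == base$starter] <- FALSE
  contigs$mult <- contigs$mult + as.integer(bump)
  extra <- stats::rbinom(nrow(contigs), 1L, noise_link_prob) == 1L
  new_links <- list()
  for (i in which(extra)) {
    partner <- sample(setdiff(seq_len(nrow(contigs)), i), 1L)
    new_links[[length(new_links) + 1L]] <- data.frame(
      c1 = contigs$id[i], o1 = sample(c("f", "r"), 1L),
      c2 = contigs$id[partner], o2 = sample(c("f", "r"), 1L),
      stringsAsFactors = FALSE)
  }
  if (length(new_links)) links <- rbind(links, do.call(rbind, new_links))
  suppressMessages(scaffold_input(contigs, links, starter = base$starter))
}
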