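## Polynomial certificate validators for proposed solutions.

#' Validate a sequence of oriented regions
#'
#' Certificate check for the repeat decision problem: identifies the
#' inverted-repeat pairs of `SOR` (a region index appearing twice with
#' opposite orientations), verifies with a LIFO that their occurrences are
#' disjoint or nested but never crossing, and checks that the cumulative
#' repeat length reaches `k` with at most `m_max` inverted repeats.
#' Direct-repeat pairs (same index, same orientation twice) are optionally
#' checked with the symmetric FIFO discipline (interleaving allowed,
#' nesting forbidden).  Linear in `|SOR| + |COR|`.
#'
#' @param d a [region_decomposition][extract_regions] (or compatible list).
#' @param k minimum cumulative inverted-repeat length to certify.
#' @param m_max maximum number of inverted repeats allowed.
#' @param check_dr also check the direct-repeat order discipline.
#' @return An object of class `validation_report`: list with `sor_valid`,
#'   `cumulative_repeat_length`, `n_inverted_repeats` and `violations`.
#' @export
check_sor <- function(d, k = 0, m_max = Inf, check_dr = FALSE) {
  sor <- d$SOR
  q <- length(d$COR)
  violations <- character()
  if (any(sor$rid < 1 | sor$rid > q)) {
    stop("malformed decomposition: region index out of range")
  }
  counts <- table(sor$rid)
  if (any(counts > 2)) {
    violations <- c(violations, "a region index appears more than twice")
  }
  twice <- as.integer(names(counts)[counts == 2])
  ir_idx <- dr_idx <- integer()
  for (rid in twice) {
    ors <- sor$ror[sor$rid == rid]
    if (ors[1] != ors[2]) ir_idx <- c(ir_idx, rid) else dr_idx <- c(dr_idx, rid)
  }
  # LIFO discipline: inverted repeats must not cross
  lifo <- integer()
  seen <- integer()
  for (t in seq_len(nrow(sor))) {
    rid <- sor$rid[t]
    if (rid %in% ir_idx) {
      if (rid %in% seen) {
        if (!length(lifo) || lifo[length(lifo)] != rid) {
          violations <- c(violations,
                          sprintf("inverted repeats cross at region %d", rid - 1L))
        } else {
          lifo <- lifo[-length(lifo)]
        }
      } else {
        lifo <- c(lifo, rid)
        seen <- c(seen, rid)
      }
    }
  }
  if (check_dr) {
    fifo <- integer()
    seen <- integer()
    for (t in seq_len(nrow(sor))) {
      rid <- sor$rid[t]
      if (rid %in% dr_idx) {
        if (rid %in% seen) {
          if (!length(fifo) || fifo[1] != rid) {
            violations <- c(violations,
                            sprintf("direct repeats nest at region %d", rid - 1L))
          } else {
            fifo <- fifo[-1]
          }
        } else {
          fifo <- c(fifo, rid)
          seen <- c(seen, rid)
        }
      }
    }
  }
  cum_len <- sum(vapply(ir_idx, function(i) 2L * nrow(d$COR[[i]]), integer(1)))
  if (cum_len < k) {
    violations <- c(violations,
                    sprintf("cumulative repeat length %d < k = %d", cum_len, k))
  }
  if (length(ir_idx) > m_max) {
    violations <- c(violations,
                    sprintf("%d inverted repeats > m' = %d", length(ir_idx), m_max))
  }
  structure(list(sor_valid = length(violations) == 0,
                 cumulative_repeat_length = cum_len,
                 n_inverted_repeats = length(ir_idx),
                 violations = violations),
            class = "validation_report")
}

#' Validate the flattened sequence of oriented contigs
#'
#' Flattens `SOR` through `COR` and checks the two conditions of a valid
#' oriented-contig sequence: every circular adjacency is a member of the
#' (reverse-closed) link set, and no contig is used more often than its
#' multiplicity.  Linear time with hashed membership.
#'
#' @param d a [region_decomposition][extract_regions] (or compatible list).
#' @param input the [scaffold_input] the solution was computed from.
#' @param SOR optional alternative oriented-region sequence (e.g. a genome
#'   form) to flatten instead of `d$SOR`.
#' @return A `validation_report` with `soc_valid` and `violations`.
#' @export
check_soc <- function(d, input, SOR = NULL) {
  soc <- flatten_regions(d, SOR = SOR)
  violations <- character()
  n <- nrow(soc)
  lk <- link_key(input$links)
  nxt <- c(seq_len(n)[-1], 1L)
  adj <- paste(soc$contig, soc$or, soc$contig[nxt], soc$or[nxt], sep = "\r")
  bad <- which(!(adj %in% lk))
  for (t in bad) {
    violations <- c(violations,
                    sprintf("adjacency (%s_%s, %s_%s) is not a link",
                            soc$contig[t], soc$or[t],
                            soc$contig[nxt[t]], soc$or[nxt[t]]))
  }
  use <- table(soc$contig)
  mult <- input$contigs$mult[match(names(use), input$contigs$id)]
  over <- which(as.integer(use) > mult)
  for (i in over) {
    violations <- c(violations,
                    sprintf("contig %s used %d times (multiplicity %d)",
                            names(use)[i], as.integer(use)[i], mult[i]))
  }
  structure(list(soc_valid = length(violations) == 0, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  ok <- c(x$sor_valid, x$soc_valid)
  cat("Validation:", if (all(ok, na.rm = TRUE) && length(x$violations) == 0)
    "valid" else "INVALID", "\n")
  if (!is.null(x$cumulative_repeat_length)) {
    cat("  cumulative IR length:", x$cumulative_repeat_length,
        "; inverted repeats:", x$n_inverted_repeats, "\n")
  }
  for (v in x$violations) cat("  -", v, "\n")
  invisible(x)
}
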