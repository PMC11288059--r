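#' Assemble a scaffolding input from contig and link tables
#'
#' A scaffolding instance consists of a contig table, a link table and a
#' designated starter contig.  Each contig carries a *multiplicity* (the
#' maximum number of occurrences allowed in the genome) and a non-negative
#' *existence weight* scoring how likely the contig is to belong to the
#' chloroplast genome.  A link is an ordered pair of oriented contigs; the
#' double-strand symmetry of DNA requires the link set to be closed under
#' reversal: whenever `(c, d)` is a link, so is `(rev(d), rev(c))`.  Links
#' supplied without their reverse are completed automatically (with a
#' message) and duplicates are dropped.
#'
#' @param contigs data frame with columns `id` (character), `mult`
#'   (positive integer) and `wex` (non-negative numeric).
#' @param links data frame with columns `c1`, `o1`, `c2`, `o2`: source
#'   contig id and orientation, target contig id and orientation.
#'   Orientations are the literal tokens `"f"` (forward) and `"r"`
#'   (reverse).  May have zero rows.
#' @param starter id of the starter contig.  The starter anchors every
#'   solution circuit and must have multiplicity exactly 1.  Defaults to the
#'   first contig of the table (with a warning).
#'
#' @return An object of class `scaffold_input`: a list with elements
#'   `contigs`, `links` (reverse-closed, deduplicated) and `starter`.
#' @examples
#' contigs <- data.frame(id = c("a", "b"), mult = c(1, 2), wex = c(1, 1))
#' links <- data.frame(c1 = "a", o1 = "f", c2 = "b", o2 = "f")
#' scaffold_input(contigs, links, starter = "a")
#' @export
scaffold_input <- function(contigs, links, starter = NULL) {
  stopifnot(is.data.frame(contigs), is.data.frame(links))
  need <- c("id", "mult", "wex")
  if (!all(need %in% names(contigs))) {
    stop("contig table must have columns id, mult, wex")
  }
  contigs$id <- as.character(contigs$id)
  contigs$mult <- as.integer(contigs$mult)
  contigs$wex <- as.numeric(contigs$wex)
  if (anyDuplicated(contigs$id)) stop("duplicated contig ids")
  if (any(is.na(contigs$mult)) || any(contigs$mult < 1L)) {
    stop("multiplicities must be positive integers")
  }
  if (any(is.na(contigs$wex)) || any(contigs$wex < 0)) {
    stop("existence weights must be non-negative")
  }
  if (nrow(links) > 0) {
    if (!all(c("c1", "o1", "c2", "o2") %in% names(links))) {
      stop("link table must have columns c1, o1, c2, o2")
    }
    for (col in c("c1", "o1", "c2", "o2")) links[[col]] <- as.character(links[[col]])
    bad_or <- setdiff(unique(c(links$o1, links$o2)), c("f", "r"))
    if (length(bad_or)) {
      stop("malformed orientation token(s): ", paste(bad_or, collapse = ", "),
           " (must be 'f' or 'r')")
    }
    unknown <- setdiff(unique(c(links$c1, links$c2)), contigs$id)
    if (length(unknown)) {
      stop("link(s) reference unknown contig(s): ", paste(unknown, collapse = ", "))
    }
  } else {
    links <- data.frame(c1 = character(), o1 = character(),
                        c2 = character(), o2 = character(),
                        stringsAsFactors = FALSE)
  }
  if (is.null(starter)) {
    starter <- contigs$id[1]
    warning("no starter given; defaulting to first contig '", starter, "'")
  }
  starter <- as.character(starter)
  if (!starter %in% contigs$id) stop("starter '", starter, "' not in contig table")
  if (contigs$mult[match(starter, contigs$id)] != 1L) {
    stop("starter '", starter, "' must have multiplicity 1")
  }
  closed <- close_links(links)
  if (nrow(closed) > nrow(unique_links(links))) {
    message("link set completed with ", nrow(closed) - nrow(unique_links(links)),
            " reverse link(s) (", nrow(closed), " total)")
  }
  structure(list(contigs = contigs, links = closed, starter = starter),
            class = "scaffold_input")
}

flip_orient <- function(o) ifelse(o == "f", "r", "f")

reverse_link_table <- function(links) {
  data.frame(c1 = links$c2, o1 = flip_orient(links$o2),
             c2 = links$c1, o2 = flip_orient(links$o1),
             stringsAsFactors = FALSE)
}

link_key <- function(links) paste(links$c1, links$o1, links$c2, links$o2, sep = "\r")

unique_links <- function(links) links[!duplicated(link_key(links)), , drop = FALSE]

# Reverse closure: union of the links and their reverses, deduplicated and
# sorted for a canonical on-disk order.
close_links <- function(links) {
  all <- rbind(links, reverse_link_table(links))
  all <- unique_links(all)
  all <- all[order(all$c1, all$o1, all$c2, all$o2, method = "radix"), , drop = FALSE]
  rownames(all) <- NULL
  all
}

#' Read a scaffolding input from TSV tables
#'
#' Reads the contig and link tables in the tab-separated layout with header
#' rows `contig  mult  wex` and `contig  orient  contig  orient`, with
#' orientation tokens `f`/`r`.  The link table may list each link in one
#' direction only; reverses are completed on load.
#'
#' @param contig_path path to the contig TSV.
#' @param link_path path to the link TSV.
#' @param starter_id starter contig id (defaults to the first contig,
#'   with a warning).
#' @return A [scaffold_input] object.
#' @export
read_scaffold_input <- function(contig_path, link_path, starter_id = NULL) {
  if (!file.exists(contig_path)) stop("contig file not found: ", contig_path)
  if (!file.exists(link_path)) stop("link file not found: ", link_path)
  contigs <- utils::read.delim(contig_path, header = TRUE,
                               colClasses = c("character", "integer", "numeric"),
                               col.names = c("id", "mult", "wex"),
                               comment.char = "#")
  links <- utils::read.delim(link_path, header = TRUE,
                             colClasses = "character",
                             col.names = c("c1", "o1", "c2", "o2"),
                             comment.char = "#")
  scaffold_input(contigs, links, starter = starter_id)
}

#' Write a scaffolding input as TSV tables
#'
#' Writes the reverse-closed link set, so reading the files back yields an
#' identical input.
#'
#' @param input a [scaffold_input] object.
#' @param contig_path,link_path output paths.
#' @param header_comment optional comment line(s) written atop both files.
#' @return Invisibly, the two paths.
#' @export
write_scaffold_input <- function(input, contig_path, link_path,
                                 header_comment = NULL) {
  stopifnot(inherits(input, "scaffold_input"))
  write_tsv_with_comment <- function(df, path, names) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
    writeLines(paste(names, collapse = "\t"), con)
    if (nrow(df)) {
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  write_tsv_with_comment(input$contigs, contig_path, c("contig", "mult", "wex"))
  write_tsv_with_comment(input$links, link_path,
                         c("contig", "orient", "contig", "orient"))
  invisible(c(contig_path, link_path))
}

#' @export
print.scaffold_input <- function(x, ...) {
  cat("Scaffolding input:", nrow(x$contigs), "contigs,",
      nrow(x$links), "links (reverse-closed), starter '", x$starter, "'\n",
      sep = " ")
  invisible(x)
}
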