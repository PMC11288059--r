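## Writing and re-reading result artefacts.

sor_string <- function(SOR) {
  paste(paste0(SOR$rid - 1L, "_", SOR$ror), collapse = ",")
}

contig_string <- function(region) {
  paste(paste0(region$contig, "_", region$or), collapse = ",")
}

#' Write scaffolding results to a directory
#'
#' Emits three tab-separated artefacts: `regions.tsv` (one row per forward
#' region with its type and oriented-contig sequence; the circular
#' oriented-region sequence is kept in a `#sor` comment line so the
#' decomposition round-trips through [read_region_decomposition]),
#' `forms.tsv` (one row per genome form: its oriented-region sequence and
#' the flattened oriented-contig sequence), and `run_report.tsv` (one row
#' per attempted succession with the objective vector and problem code)
#' when `run_info` is supplied.
#'
#' @param decomposition a [region_decomposition][extract_regions].
#' @param forms list of oriented-region sequences
#'   ([enumerate_genome_forms]); may be empty.
#' @param out_dir output directory (created if missing).
#' @param run_info optional data frame with one row per succession
#'   (columns such as `order`, `code`, `Z1`, `Z2`, `Z3`, `status`).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(decomposition, forms, out_dir, run_info = NULL) {
  d <- decomposition
  if (any(d$SOR$rid > length(d$COR))) {
    stop("inconsistent decomposition: SOR references a missing region")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- file.path(out_dir, c("regions.tsv", "forms.tsv", "run_report.tsv"))

  con <- file(paths[1], "w")
  writeLines(paste0("#sor\t", sor_string(d$SOR)), con)
  writeLines("region\ttype\tcontigs", con)
  for (i in seq_along(d$COR)) {
    writeLines(sprintf("%d\t%s\t%s", i - 1L, d$region_types[i],
                       contig_string(d$COR[[i]])), con)
  }
  close(con)

  con <- file(paths[2], "w")
  writeLines("form\tregions\tcontigs", con)
  for (i in seq_along(forms)) {
    writeLines(sprintf("%d\t%s\t%s", i, sor_string(forms[[i]]),
                       contig_string(flatten_regions(d, SOR = forms[[i]]))),
               con)
  }
  close(con)

  if (!is.null(run_info)) {
    utils::write.table(run_info, paths[3], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

parse_oriented_tokens <- function(s, what = c("region", "contig")) {
  what <- match.arg(what)
  toks <- strsplit(s, ",", fixed = TRUE)[[1]]
  m <- regmatches(toks, regexec("^(.*)_([fr])$", toks))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed oriented token(s): ", paste(toks[bad], collapse = ", "))
  id <- vapply(m, `[[`, "", 2L)
  or <- vapply(m, `[[`, "", 3L)
  if (what == "region") {
    data.frame(rid = as.integer(id) + 1L, ror = or, stringsAsFactors = FALSE)
  } else {
    data.frame(contig = id, or = or, stringsAsFactors = FALSE)
  }
}

#' Read a region decomposition back from a regions TSV
#'
#' Inverse of the `regions.tsv` part of [write_results].
#'
#' @param path path to a `regions.tsv` file.
#' @return A `region_decomposition`.
#' @export
read_region_decomposition <- function(path) {
  lines <- readLines(path)
  sor_line <- grep("^#sor\t", lines, value = TRUE)
  if (length(sor_line) != 1) stop("regions file has no single #sor line")
  SOR <- parse_oriented_tokens(sub("^#sor\t", "", sor_line), "region")
  body <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                            colClasses = c("integer", "character", "character"))
  ord <- order(body$region)
  body <- body[ord, , drop = FALSE]
  COR <- lapply(body$contigs, parse_oriented_tokens, what = "contig")
  structure(list(COR = COR, SOR = SOR, region_types = body$type,
                 circuit_tokens = NULL),
            class = "region_decomposition")
}

#' Read genome forms back from a forms TSV
#'
#' Inverse of the `forms.tsv` part of [write_results].
#'
#' @param path path to a `forms.tsv` file.
#' @return List of oriented-region sequences (possibly empty).
#' @export
read_genome_forms <- function(path) {
  body <- utils::read.delim(path, colClasses = c("integer", "character",
                                                 "character"),
                            comment.char = "#")
  lapply(body$regions, parse_oriented_tokens, what = "region")
}
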