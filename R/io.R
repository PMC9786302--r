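#' Read a multi-record FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] with a friendlier
#' error for malformed headers: the first non-empty line must start with
#' `>`, otherwise the offending line number is reported. Line wrapping and
#' surrounding whitespace are tolerated; record ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0) rlang::abort(paste("empty FASTA file:", path))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    rlang::abort(sprintf(
      "malformed FASTA: line %d should be a '>' header", nonblank[1]))
  }
  set <- Biostrings::readDNAStringSet(path)
  s <- as.character(set)
  names(s) <- sub("\\s.*$", "", names(set))
  s
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  seqs <- as_named_seqs(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

output_header <- function(config = list()) {
  cfg <- paste(names(config), unname(unlist(config)), sep = "=",
               collapse = " ")
  c(paste0("# g4cr ", as.character(utils::packageVersion("g4cr"))),
    paste0("# config: ", cfg))
}

#' Write regions as BED6
#'
#' One line per region, 0-based half-open coordinates. The name field is
#' `id:n_tot:n_tand`, the score `min(1000, round(10 * max_tm))`. Two `#`
#' comment lines embed the package version and the run configuration.
#'
#' @param regions A region tibble from [g4_regions()].
#' @param path Output path.
#' @param config Named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path, config = list()) {
  lines <- output_header(config)
  if (nrow(regions) > 0) {
    bed_strand <- ifelse(regions$strand %in% c("-", "noncoding"), "-", "+")
    lines <- c(lines, sprintf(
      "%s\t%d\t%d\t%s\t%d\t%s",
      regions$seq_id, regions$start, regions$end,
      sprintf("%s:%d:%d", regions$seq_id, regions$n_tot, regions$n_tand),
      pmin(1000L, as.integer(round(10 * regions$max_tm))),
      bed_strand
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file written by [write_bed()]
#'
#' @param path Path to the BED file.
#' @return A tibble `seq_id`, `start`, `end`, `name`, `score`, `strand`,
#'   with `n_tot`/`n_tand` re-parsed from the name field.
#' @export
read_bed <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#",
                         col_names = c("seq_id", "start", "end", "name",
                                       "score", "strand"),
                         show_col_types = FALSE)
  parts <- stringr::str_match(tbl$name, "^(.*):(\\d+):(\\d+)$")
  tbl$n_tot <- as.integer(parts[, 3])
  tbl$n_tand <- as.integer(parts[, 4])
  tbl
}

#' Write per-base folding multiplicity as bedGraph
#'
#' One single-base interval per position with non-zero multiplicity (the
#' track is single-residue resolved, so no run merging is applied). One
#' file per strand is conventional since values of the two strands may
#' overlap.
#'
#' @param regions A region tibble (one strand).
#' @param path Output path.
#' @param config Named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(regions, path, config = list()) {
  lines <- output_header(config)
  for (i in seq_len(nrow(regions))) {
    mult <- regions$multiplicity[[i]]
    keep <- which(mult > 0)
    if (length(keep)) {
      pos <- regions$start[i] + keep - 1L
      lines <- c(lines, sprintf("%s\t%d\t%d\t%d", regions$seq_id[i],
                                pos, pos + 1L, mult[keep]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the isomer table as TSV
#'
#' Coordinates are 0-based half-open; core positions are a comma-separated
#' list of absolute 0-based indices. `#` comment lines embed the package
#' version and configuration; [read_isomers()] round-trips the file.
#'
#' @param matches Match tibble from [g4_scan()].
#' @param path Output path.
#' @param config Named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_isomers <- function(matches, path, config = list()) {
  flat <- dplyr::mutate(matches,
    cores = vapply(.data$cores, paste, character(1), collapse = ","))
  con <- file(path, "w")
  writeLines(output_header(config), con)
  close(con)
  readr::write_tsv(flat, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read back an isomer TSV written by [write_isomers()]
#'
#' @param path Path to the TSV.
#' @return The match tibble with the `cores` list column restored.
#' @export
read_isomers <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  tbl$cores <- purrr::map(strsplit(as.character(tbl$cores), ","), as.integer)
  for (col in c("start", "end", "width", "mask_id", "l1", "l2", "l3",
                "bulge_tract", "bulge_gap", "bulge_len")) {
    if (col %in% names(tbl)) tbl[[col]] <- as.integer(tbl[[col]])
  }
  tbl
}
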