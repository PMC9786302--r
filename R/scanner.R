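#' Encode a DNA sequence as a guanine indicator vector
#'
#' Case-insensitive: `G` and `g` encode 1, everything else (including `N`
#' and other IUPAC ambiguity codes) encodes 0.
#'
#' @param sequence A single non-empty character string.
#' @return Integer vector of 0/1, one value per residue.
#' @examples
#' encode_g("GGGTGGG")
#' @export
encode_g <- function(sequence) {
  if (length(sequence) != 1 || is.na(sequence) || nchar(sequence) == 0) {
    rlang::abort("`sequence` must be a single non-empty string")
  }
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  as.integer(ch == "G")
}

#' Split a sequence into candidate G-dense segments
#'
#' Candidate G4-containing regions are found by removing every run of non-G
#' residues longer than `max_loop` from the G indicator vector, trimming the
#' surviving segments so they start and end on a G, and keeping those with
#' at least `min_g` guanines (12 are needed for one three-tetrad core). No
#' stable quadruplex footprint can cross a removed run, so scanning is
#' confined to these segments.
#'
#' @param sequence A single DNA string, or an integer indicator vector from
#'   [encode_g()].
#' @param max_loop Longest non-G run allowed inside a candidate (default 7,
#'   the maximum loop length).
#' @param min_g Minimum guanine count for a candidate to be retained
#'   (default 12). Use `min_g = 0` to see the raw trimmed segments before
#'   the guanine-count filter.
#' @return A tibble with one row per candidate: `start`, `end` (0-based,
#'   half-open, in source coordinates), `width` and `g_count`.
#' @examples
#' split_candidates("TCTACAAAGGGTGGGAGTGGGGTGGGTATCTCATGGAGCTCTTACA")
#' split_candidates("TCTACAAAGGGTGGGAGTGGGGTGGGTATCTCATGGAGCTCTTACA", min_g = 0)
#' @export
split_candidates <- function(sequence, max_loop = 7, min_g = 12) {
  ind <- if (is.character(sequence)) encode_g(sequence) else as.integer(sequence)
  g_pos <- which(ind == 1L)
  if (length(g_pos) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          width = integer(), g_count = integer()))
  }
  # break between consecutive Gs separated by > max_loop non-Gs
  gap <- diff(g_pos) - 1L
  brk <- which(gap > max_loop)
  seg_first <- g_pos[c(1L, brk + 1L)]
  seg_last <- g_pos[c(brk, length(g_pos))]
  out <- tibble::tibble(
    start = seg_first - 1L,
    end = seg_last,
    width = seg_last - seg_first + 1L,
    g_count = vapply(seq_along(seg_first), function(i) {
      sum(ind[seg_first[i]:seg_last[i]])
    }, integer(1))
  )
  dplyr::filter(out, .data$g_count >= min_g)
}

#' Score one window of a G indicator vector against one mask row
#'
#' The dot product of the window with a mask row (cores 1, loops 0, bulges
#' 13) is exactly 12 when all twelve core positions hold guanines and no
#' bulge position does; below 12 some core is not a G, above 12 a bulge
#' column holds a G (bulged guanines are disallowed: the non-bulged variant
#' is always more stable).
#'
#' @param window Integer 0/1 indicator slice.
#' @param row Mask row of the same length, e.g. from [encode_mask()].
#' @return The integer score.
#' @examples
#' match_window(encode_g("GGGTGGGAGTGGGGTGGG"), encode_mask(1, 3, 2))
#' @export
match_window <- function(window, row) {
  if (length(window) != length(row)) {
    rlang::abort("`window` and `row` must have the same length")
  }
  as.integer(sum(window * row))
}

#' Locate every stable quadruplex isomer in DNA sequences
#'
#' Slides every retained motif mask across every candidate G-dense segment
#' of each sequence and reports each placement whose indicator/mask dot
#' product is exactly 12 — i.e. every distinct set of 12 guanines that can
#' form a stable three-tetrad quadruplex core with its loops and at most one
#' bulge. Distinct (mask, offset) placements always correspond to distinct
#' core sets, so no deduplication is needed.
#'
#' @param x Sequences: a named character vector, a single string, a
#'   `Biostrings::DNAStringSet`, or a data frame with columns `seq_id` and
#'   `seq`.
#' @param catalog A stable mask catalog from
#'   `filter_stable(g4_motif_catalog())`; built with `params` if `NULL`.
#' @param params A [tm_params()] object (used only when `catalog` is NULL).
#' @param max_loop,max_bulge Structure caps used when building the catalog
#'   and when splitting candidates.
#' @param strands `"+"` scans the sequences as given; `"-"` scans their
#'   reverse complements, reporting coordinates on the given (source)
#'   sequence; `"both"` does both.
#'
#' @return A tibble of isomer matches: `seq_id`, `strand`, `start`, `end`
#'   (0-based half-open footprint in source coordinates), `width`,
#'   `mask_id`, loop lengths, bulge spec, `tm`, `ambiguous` (does the
#'   footprint contain a non-ACGT character), and `cores`, a list column of
#'   the 12 absolute 0-based core positions.
#' @examples
#' g4_scan("GGGTGGGGTGGGTGGGTG")
#' @seealso [g4_regions()], [g4_analyze()]
#' @export
g4_scan <- function(x, catalog = NULL, params = tm_params(), max_loop = 7,
                    max_bulge = 3, strands = "+") {
  seqs <- as_named_seqs(x)
  strands <- match.arg(strands, c("+", "-", "both"))
  if (is.null(catalog)) {
    catalog <- filter_stable(g4_motif_catalog(max_loop, max_bulge, params),
                             params)
  }
  groups <- mask_groups(catalog)
  want <- if (strands == "both") c("+", "-") else strands
  res <- purrr::map(seq_along(seqs), function(i) {
    purrr::map(want, function(st) {
      s <- if (st == "+") seqs[[i]] else revcomp(seqs[[i]])
      m <- scan_one(s, catalog, groups, max_loop)
      if (nrow(m) == 0) {
        return(dplyr::mutate(m, seq_id = character(), strand = character()))
      }
      if (st == "-") {
        L <- nchar(seqs[[i]])
        new_start <- L - m$end
        m$end <- L - m$start
        m$start <- new_start
        m$cores <- purrr::map(m$cores, function(cp) sort(L - 1L - cp))
      }
      dplyr::mutate(m, seq_id = names(seqs)[i], strand = st)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(res))
  if (nrow(out) == 0) {
    return(empty_match_tibble())
  }
  dplyr::select(out, "seq_id", "strand", "start", "end", "width", "mask_id",
                "l1", "l2", "l3", "bulge_tract", "bulge_gap", "bulge_len",
                "tm", "ambiguous", "cores") |>
    dplyr::arrange(.data$seq_id, .data$strand, .data$start, .data$mask_id)
}

empty_match_tibble <- function() {
  tibble::tibble(
    seq_id = character(), strand = character(), start = integer(),
    end = integer(), width = integer(), mask_id = integer(), l1 = integer(),
    l2 = integer(), l3 = integer(), bulge_tract = integer(),
    bulge_gap = integer(), bulge_len = integer(), tm = double(),
    ambiguous = logical(), cores = list()
  )
}

# group mask encodings into one matrix per width for vectorised scanning
mask_groups <- function(catalog) {
  idx <- split(seq_len(nrow(catalog)), catalog$width)
  purrr::map(idx, function(i) {
    list(rows = i,
         mat = do.call(rbind, catalog$encoding[i]),
         width = catalog$width[i[1]])
  })
}

# scan a single sequence (plus strand as given); returns match tibble
# without seq_id/strand columns
scan_one <- function(s, catalog, groups, max_loop) {
  ind <- encode_g(s)
  ambig <- !(strsplit(toupper(s), "", fixed = TRUE)[[1]] %in%
               c("A", "C", "G", "T"))
  cands <- split_candidates(ind, max_loop = max_loop, min_g = 12)
  acc <- list()
  for (ci in seq_len(nrow(cands))) {
    v <- ind[(cands$start[ci] + 1L):cands$end[ci]]
    L <- length(v)
    for (grp in groups) {
      w <- grp$width
      if (w > L) next
      win <- matrix(v[outer(0:(L - w), seq_len(w), `+`) + 0L], nrow = L - w + 1L)
      scores <- win %*% t(grp$mat)
      hits <- which(scores == 12, arr.ind = TRUE)
      if (nrow(hits) == 0) next
      rows <- grp$rows[hits[, 2]]
      offs <- cands$start[ci] + hits[, 1] - 1L   # 0-based in source
      enc <- catalog$encoding[rows]
      acc[[length(acc) + 1L]] <- tibble::tibble(
        start = as.integer(offs),
        end = as.integer(offs + w),
        width = w,
        mask_id = catalog$mask_id[rows],
        l1 = catalog$l1[rows], l2 = catalog$l2[rows], l3 = catalog$l3[rows],
        bulge_tract = catalog$bulge_tract[rows],
        bulge_gap = catalog$bulge_gap[rows],
        bulge_len = catalog$bulge_len[rows],
        tm = catalog$tm[rows],
        ambiguous = vapply(seq_along(offs), function(k) {
          any(ambig[(offs[k] + 1L):(offs[k] + w)])
        }, logical(1)),
        cores = purrr::map(seq_along(offs), function(k) {
          as.integer(offs[k] + which(enc[[k]] == 1L) - 1L)
        })
      )
    }
  }
  if (length(acc) == 0) {
    tibble::tibble(start = integer(), end = integer(), width = integer(),
                   mask_id = integer(), l1 = integer(), l2 = integer(),
                   l3 = integer(), bulge_tract = integer(),
                   bulge_gap = integer(), bulge_len = integer(),
                   tm = double(), ambiguous = logical(), cores = list())
  } else {
    dplyr::bind_rows(acc)
  }
}

# ---- small sequence utilities ------------------------------------------

as_named_seqs <- function(x) {
  if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet")) {
    s <- as.character(x)
    if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
    return(s)
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("seq_id", "seq") %in% names(x)))
    return(rlang::set_names(as.character(x$seq), x$seq_id))
  }
  nm <- names(x)
  s <- as.character(x)
  names(s) <- nm
  if (is.null(names(s))) {
    names(s) <- if (length(s) == 1) "seq1" else paste0("seq", seq_along(s))
  }
  s
}

#' Reverse complement of a DNA string
#'
#' @param sequence A single DNA string (IUPAC codes supported, case
#'   preserved by complementing through [Biostrings::reverseComplement()]).
#' @return The reverse-complemented string.
#' @examples
#' revcomp("AGGGT")
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}
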