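#' Assemble isomer matches into G4-containing regions (G4CRs)
#'
#' A G4CR is a maximal stretch of DNA in which every residue can take part
#' in at least one stable quadruplex (as core, loop or bulge). Matches from
#' one sequence and strand are grouped into connected components of the
#' footprint-overlap graph (two isomers are connected when their footprints
#' share at least one position); each component's footprint union is a
#' contiguous interval and the intervals of different components are
#' pairwise disjoint.
#'
#' Per region the polymorphism statistics are computed: `n_tot`, the number
#' of member isomers (distinct 12-G core sets); `n_tand`, the maximum number
#' of member isomers with pairwise disjoint footprints (how many quadruplexes
#' can fold simultaneously in tandem; earliest-footprint-end greedy
#' selection, which is optimal for intervals); and the per-base folding
#' `multiplicity`, the number of member isomers whose core includes each
#' position. The multiplicities always sum to `12 * n_tot`.
#'
#' @param matches Isomer matches from [g4_scan()].
#' @param sequences The scanned sequences (same form as for [g4_scan()]);
#'   needed to compute `g_content` on the scanned strand (counting G on the
#'   `+` strand, C on the `-` strand of the source). If omitted,
#'   `g_content` is `NA`.
#'
#' @return A tibble with one region per row: `seq_id`, `strand`, `start`,
#'   `end` (0-based half-open), `length`, `g_content`, `n_tot`, `n_tand`,
#'   `max_tm`, `n_max_tm` (how many isomers tie for the maximal tm),
#'   `isomers` (list column of the member-match tibble, with `is_max_tm`
#'   flags), and `multiplicity` (list column, one integer per base of the
#'   region).
#' @examples
#' g4_regions(g4_scan("GGGTGGGGTGGGTGGGTG"), "GGGTGGGGTGGGTGGGTG")
#' @export
g4_regions <- function(matches, sequences = NULL) {
  if (nrow(matches) == 0) return(empty_region_tibble())
  seqs <- if (is.null(sequences)) NULL else as_named_seqs(sequences)
  grp <- dplyr::group_split(matches, .data$seq_id, .data$strand)
  out <- purrr::map(grp, function(m) {
    m <- dplyr::arrange(m, .data$start, .data$end, .data$mask_id)
    # component break where a footprint starts at/after the running max end
    comp <- cumsum(m$start >= dplyr::lag(cummax(m$end), default = -1L))
    purrr::map(split(seq_len(nrow(m)), comp), function(i) {
      region_from_members(m[i, ], seqs)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  dplyr::arrange(out, .data$seq_id, .data$strand, .data$start)
}

empty_region_tibble <- function() {
  tibble::tibble(
    seq_id = character(), strand = character(), start = integer(),
    end = integer(), length = integer(), g_content = double(),
    n_tot = integer(), n_tand = integer(), max_tm = double(),
    n_max_tm = integer(), isomers = list(), multiplicity = list()
  )
}

region_from_members <- function(m, seqs) {
  start <- min(m$start)
  end <- max(m$end)
  len <- end - start
  mult <- integer(len)
  for (cp in m$cores) {
    idx <- cp - start + 1L
    mult[idx] <- mult[idx] + 1L
  }
  gc <- NA_real_
  if (!is.null(seqs) && m$seq_id[1] %in% names(seqs)) {
    ch <- strsplit(toupper(seqs[[m$seq_id[1]]]), "", fixed = TRUE)[[1]]
    piece <- ch[(start + 1L):end]
    gbase <- if (m$strand[1] == "-") "C" else "G"
    gc <- sum(piece == gbase) / len
  }
  max_tm <- max(m$tm)
  m$is_max_tm <- m$tm == max_tm
  tibble::tibble(
    seq_id = m$seq_id[1], strand = m$strand[1],
    start = start, end = end, length = len, g_content = gc,
    n_tot = nrow(m),
    n_tand = n_tand_greedy(m$start, m$end),
    max_tm = max_tm, n_max_tm = sum(m$is_max_tm),
    isomers = list(m), multiplicity = list(mult)
  )
}

# maximum number of pairwise disjoint [start, end) intervals:
# classic earliest-end-first greedy (optimal for interval scheduling)
n_tand_greedy <- function(start, end) {
  o <- order(end, start)
  n <- 0L
  last_end <- -Inf
  for (i in o) {
    if (start[i] >= last_end) {
      n <- n + 1L
      last_end <- end[i]
    }
  }
  n
}

#' Per-base folding multiplicity of a region
#'
#' Convenience accessor: returns the multiplicity track of one assembled
#' region as a tibble of positions, for plotting or export. The multiplicity
#' of a position is the number of member isomers whose 12-G core includes
#' it; loop, bulge and non-G positions have multiplicity 0, and the track
#' sums to `12 * n_tot`.
#'
#' @param region One row of the tibble returned by [g4_regions()].
#' @return A tibble with `seq_id`, `strand`, `pos` (0-based source
#'   coordinate) and `multiplicity`.
#' @examples
#' r <- g4_regions(g4_scan("GGGTGGGTGGGTGGG"))
#' multiplicity_track(r[1, ])
#' @export
multiplicity_track <- function(region) {
  stopifnot(nrow(region) == 1)
  mult <- region$multiplicity[[1]]
  tibble::tibble(
    seq_id = region$seq_id, strand = region$strand,
    pos = region$start + seq_along(mult) - 1L,
    multiplicity = mult
  )
}
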