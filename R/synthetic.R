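#' Random DNA background of given length and GC fraction
#'
#' @param length Number of residues.
#' @param gc Target GC fraction (bases drawn independently; G and C each
#'   get `gc/2`).
#' @param seed Optional integer seed for reproducibility.
#' @return A single DNA string.
#' @export
random_dna <- function(length, gc = 0.4, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(as.integer(seed))
  }
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Plant a G-tract array in a random background
#'
#' Builds a synthetic test sequence: a G-tract island (tracts of given
#' lengths joined by the given spacers) inserted at a chosen offset into a
#' random background. With `isolate = TRUE` (default) the 8 residues on
#' each side of the island are forced to non-G so that no background G-run
#' can merge with the island across the maximum loop length of 7.
#'
#' @param tracts Integer vector of G-tract lengths, e.g. `c(3, 4, 3, 4)`.
#' @param spacers Character vector of loop sequences between consecutive
#'   tracts (recycled to `length(tracts) - 1`).
#' @param offset 0-based insertion offset of the island in the background.
#' @param background_length Total sequence length before insertion
#'   (island replaces background residues in place).
#' @param gc Background GC fraction.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param isolate Force a non-G buffer of 8 nt around the island.
#' @return A single DNA string of length `background_length`.
#' @examples
#' synth_sequence(c(3, 3, 3, 3), "T", offset = 20, background_length = 60,
#'                seed = 1)
#' @export
synth_sequence <- function(tracts, spacers = "T", offset = 0,
                           background_length = 100, gc = 0.4, seed = 1,
                           isolate = TRUE) {
  stopifnot(length(tracts) >= 1, all(tracts >= 1))
  spacers <- rep_len(spacers, max(length(tracts) - 1, 0))
  island <- paste0(
    paste0(vapply(seq_along(tracts), function(i) {
      paste0(strrep("G", tracts[i]),
             if (i < length(tracts)) spacers[i] else "")
    }, character(1)), collapse = "")
  )
  iw <- nchar(island)
  if (iw > background_length) {
    rlang::abort("planted island is longer than the background")
  }
  if (offset + iw > background_length) {
    rlang::abort("island does not fit at the requested offset")
  }
  bg <- strsplit(random_dna(background_length, gc = gc, seed = seed), "",
                 fixed = TRUE)[[1]]
  bg[(offset + 1):(offset + iw)] <- strsplit(island, "", fixed = TRUE)[[1]]
  if (isolate) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(as.integer(seed) + 1L)
    buf <- function(idx) {
      idx <- idx[idx >= 1 & idx <= background_length]
      bg[idx] <<- sample(c("A", "C", "T"), length(idx), replace = TRUE)
    }
    buf((offset - 7):offset)
    buf((offset + iw + 1):(offset + iw + 8))
  }
  paste(bg, collapse = "")
}

#' Brute-force enumeration of all stable quadruplex core sets
#'
#' Independent reference enumerator used to validate the mask scanner: it
#' shares no code path with the catalog/sliding-window machinery. Every
#' placement of a three-guanine tract (contiguous, or carrying one internal
#' bulge of 1 to `max_bulge` non-G residues between its first/second or
#' second/third G) is listed directly from the sequence; ordered chains of
#' four placements with inter-tract loops of 1 to `max_loop` residues, at
#' most one bulge overall and `tm_est >= threshold` give the stable core
#' sets.
#'
#' @param sequence A DNA string; refuses sequences longer than `max_len`
#'   (the search is combinatorial).
#' @param params A [tm_params()] object.
#' @param max_loop,max_bulge Structure caps.
#' @param max_len Guard on input length (default 60).
#' @return A list of the distinct core sets, each a sorted integer vector
#'   of the 12 0-based core positions, in lexicographic order.
#' @examples
#' length(oracle_enumerate("AGGGTGGGGAGGGTGGGG"))   # 4 register isomers
#' @export
oracle_enumerate <- function(sequence, params = tm_params(), max_loop = 7,
                             max_bulge = 3, max_len = 60) {
  if (nchar(sequence) > max_len) {
    rlang::abort(sprintf("sequence longer than %d nt; refusing brute force",
                         max_len))
  }
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  isg <- ch == "G"
  n <- length(ch)
  # all tract placements: cores (1-based triplet), bulged residue count
  cores <- list(); lbs <- integer()
  add <- function(c3, lb) {
    cores[[length(cores) + 1L]] <<- c3
    lbs[length(lbs) + 1L] <<- lb
  }
  for (i in seq_len(n)) {
    if (!isg[i]) next
    if (i + 2 <= n && isg[i + 1] && isg[i + 2]) add(c(i, i + 1, i + 2), 0L)
    if (max_bulge >= 1) {
      for (g in seq_len(max_bulge)) {
        j <- i + 1 + g
        if (j + 1 <= n && isg[j] && isg[j + 1] && all(!isg[(i + 1):(j - 1)]))
          add(c(i, j, j + 1), g)
        k <- i + 2 + g
        if (k <= n && i + 1 <= n && isg[i + 1] && isg[k] &&
            all(!isg[(i + 2):(k - 1)]))
          add(c(i, i + 1, k), g)
      }
    }
  }
  m <- length(cores)
  if (m < 4) return(list())
  starts <- vapply(cores, `[`, 0, 1)
  ends <- vapply(cores, `[`, 0, 3)
  # successors: placements reachable with a loop of 1..max_loop
  succ <- lapply(seq_len(m), function(i) {
    which(starts - ends[i] - 1 >= 1 & starts - ends[i] - 1 <= max_loop)
  })
  res <- character(0)
  for (i1 in seq_len(m)) {
    for (i2 in succ[[i1]]) {
      b2 <- (lbs[i1] > 0) + (lbs[i2] > 0)
      if (b2 > 1) next
      for (i3 in succ[[i2]]) {
        b3 <- b2 + (lbs[i3] > 0)
        if (b3 > 1) next
        for (i4 in succ[[i3]]) {
          nb <- b3 + (lbs[i4] > 0)
          if (nb > 1) next
          lb <- lbs[i1] + lbs[i2] + lbs[i3] + lbs[i4]
          tm <- params$a -
            params$b * log10((starts[i2] - ends[i1] - 1) *
                               (starts[i3] - ends[i2] - 1) *
                               (starts[i4] - ends[i3] - 1)) -
            params$d * nb - params$f * (lb - nb)
          if (tm < params$threshold) next
          res <- c(res, paste(c(cores[[i1]], cores[[i2]], cores[[i3]],
                                cores[[i4]]) - 1L, collapse = ","))
        }
      }
    }
  }
  res <- sort(unique(res))
  lapply(strsplit(res, ",", fixed = TRUE), as.integer)
}
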