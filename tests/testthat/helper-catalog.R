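# shared fixtures: the default stable catalog is expensive enough to build
# once per test run
stable_catalog <- filter_stable(g4_motif_catalog())

# canonical string keys for sets of core-position tuples
cores_key <- function(matches) {
  sort(vapply(matches$cores, paste, character(1), collapse = ","))
}
oracle_key <- function(sets) {
  sort(vapply(sets, paste, character(1), collapse = ","))
}

# exhaustive maximum independent set over [start, end) intervals; the
# reference against which the greedy tandem count is checked
mis_exhaustive <- function(start, end) {
  n <- length(start)
  best <- 0L
  for (code in 0:(2^n - 1)) {
    idx <- which(bitwAnd(code, bitwShiftL(1L, 0:(n - 1))) != 0L)
    if (length(idx) <= best) next
    ok <- TRUE
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) {
        for (b in (a + 1):length(idx)) {
          if (start[idx[a]] < end[idx[b]] && start[idx[b]] < end[idx[a]]) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
    }
    if (ok) best <- length(idx)
  }
  best
}

# G-skewed random DNA: symmetric-GC backgrounds almost never reach four
# G-tracts, so correctness properties are exercised on G-rich draws
g_rich_dna <- function(length, g = 0.45) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - g) * 0.4, (1 - g) * 0.2, g, (1 - g) * 0.4)),
        collapse = "")
}

# random multi-tract G4 island chain (guaranteed quadruplex content)
random_island_seq <- function(n_islands = 2) {
  islands <- vapply(seq_len(n_islands), function(i) {
    k <- sample(4:6, 1)
    tracts <- vapply(seq_len(k), function(j) {
      strrep("G", sample(3:4, 1))
    }, character(1))
    # spacers capped at 4 nt so the loop product stays under the stability
    # bound and every island is guaranteed to fold
    spacers <- vapply(seq_len(k - 1), function(j) {
      strrep(sample(c("A", "T"), 1), sample(1:4, 1))
    }, character(1))
    paste0(paste0(tracts[-k], spacers, collapse = ""), tracts[k])
  }, character(1))
  paste(islands, collapse = strrep("A", 9))
}

# nested-loop reference count for the unfiltered catalog size
catalog_count_oracle <- function(max_loop, max_bulge) {
  n <- 0L
  for (l1 in seq_len(max_loop)) for (l2 in seq_len(max_loop)) {
    for (l3 in seq_len(max_loop)) {
      n <- n + 1L                                # no bulge
      if (max_bulge >= 1) {
        for (tract in 1:4) for (gap in 1:2) {
          for (len in seq_len(max_bulge)) n <- n + 1L
        }
      }
    }
  }
  n
}
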