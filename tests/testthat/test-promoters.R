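plant_island <- function(chars, at, island = "GGGTGGGTGGGTGGG") {
  # overwrite chars at 1-based position `at`, with non-G buffers either side
  iw <- nchar(island)
  chars[at:(at + iw - 1)] <- strsplit(island, "")[[1]]
  chars[max(1, at - 8):(at - 1)] <- "A"
  chars[(at + iw):min(length(chars), at + iw + 7)] <- "A"
  chars
}

make_genome <- function(tss, plant_at_offset = -100, clen = 10000) {
  ch <- strsplit(random_dna(clen, gc = 0.4, seed = 99), "")[[1]]
  for (t in tss) ch <- plant_island(ch, t + plant_at_offset)
  c(chr1 = paste(ch, collapse = ""))
}

test_that("windows are TSS-centred, oriented and truncation-flagged", {
  genome <- c(chr1 = random_dna(10000, gc = 0.4, seed = 1))
  prom <- tibble::tibble(id = c("a_1", "b_1", "c_1"), chrom = "chr1",
                         tss = c(5000, 1000, 5000),
                         strand = c("+", "+", "-"))
  win <- extract_windows(genome, prom)
  expect_equal(nchar(win$seq[1]), 4000)
  expect_equal(win$seq[1], substr(genome[[1]], 3001, 7000))
  expect_equal(c(win$offset_start[1], win$offset_end[1]), c(-1999, 2000))
  expect_false(win$truncated[1])
  # insufficient upstream: truncated and flagged
  expect_true(win$truncated[2])
  expect_equal(win$offset_start[2], -999)
  # minus strand: reverse complement of the plus-strand slice
  expect_equal(win$seq[3], revcomp(substr(genome[[1]], 3000, 6999)))
})

test_that("missing contigs are skipped with a warning, run continues", {
  genome <- c(chr1 = random_dna(6000, gc = 0.4, seed = 2))
  prom <- tibble::tibble(id = c("a_1", "b_1"), chrom = c("chrX", "chr1"),
                         tss = c(3000, 3000), strand = "+")
  expect_warning(win <- extract_windows(genome, prom), "chrX")
  expect_equal(win$id, "b_1")
})

test_that("coding and non-coding strands are scanned separately", {
  pu18 <- "AGGGTGGGGAGGGTGGGG"
  ch <- strsplit(strrep("AT", 2000), "")[[1]]
  ch[2001:(2000 + nchar(pu18))] <- strsplit(revcomp(pu18), "")[[1]]
  win <- tibble::tibble(id = "w1", chrom = "chr1", tss = 2000, strand = "+",
                        offset_start = -1999L, offset_end = 2000L,
                        truncated = FALSE, seq = paste(ch, collapse = ""))
  regs <- scan_windows(win, catalog = stable_catalog)
  expect_equal(unique(regs$strand), "noncoding")
  expect_equal(nrow(regs), 1)
  expect_equal(regs$n_tot, 4)

  win$seq <- strrep("AT", 2000)
  expect_equal(nrow(scan_windows(win, catalog = stable_catalog)), 0)
})

test_that("planted regions land at the requested TSS offsets", {
  tss <- seq(3000, 7000, by = 1000)
  genome <- make_genome(tss)
  prom <- tibble::tibble(id = paste0("g", seq_along(tss), "_1"),
                         chrom = "chr1", tss = tss, strand = "+")
  win <- extract_windows(genome, prom)
  regs <- scan_windows(win, catalog = stable_catalog)
  planted <- dplyr::filter(regs, strand == "coding", offset_lo == -100)
  expect_equal(nrow(planted), length(tss))
  expect_equal(unique(planted$offset_hi), -86)
})

test_that("positional distributions are normalised per class", {
  tss <- seq(3000, 7000, by = 500)
  genome <- make_genome(tss)
  prom <- tibble::tibble(id = paste0("g", seq_along(tss), "_1"),
                         chrom = "chr1", tss = tss, strand = "+")
  win <- extract_windows(genome, prom)
  regs <- scan_windows(win, catalog = stable_catalog)
  # planted 15-nt regions present in every window: uniform 1/15 profile
  planted <- dplyr::filter(regs, strand == "coding", offset_lo == -100)
  d <- positional_distribution(planted, win)
  inpeak <- d$offset >= -100 & d$offset <= -86
  expect_true(all(abs(d$probability[inpeak] - 1 / 15) < 1e-9))
  expect_true(all(d$probability[!inpeak] == 0))
  expect_equal(sum(d$probability), 1, tolerance = 1e-9)

  cls <- classify_regions(regs, "length")
  dd <- positional_distribution(cls, win)
  sums <- tapply(dd$probability, list(dd$strand, dd$class), sum)
  for (s in rownames(sums)) for (cl in colnames(sums)) {
    key <- paste(s, cl, sep = "/")
    if (key %in% attr(dd, "empty_classes")) {
      expect_equal(sums[s, cl], 0)
    } else {
      expect_equal(unname(sums[s, cl]), 1, tolerance = 1e-9)
    }
  }
})

test_that("a class with no members yields a flagged zero vector", {
  win <- tibble::tibble(id = "w1", offset_start = -1999L, offset_end = 2000L)
  regs <- tibble::tibble(seq_id = character(), strand = character(),
                         offset_lo = integer(), offset_hi = integer())
  d <- positional_distribution(regs, win)
  expect_true(all(d$probability == 0))
  expect_true(length(attr(d, "empty_classes")) > 0)
})

test_that("enrichment ratio is 1 for flat profiles and Inf without far mass", {
  offsets <- -1999:2000
  flat <- tibble::new_tibble(
    tibble::tibble(strand = "coding", class = factor("all"),
                   offset = offsets,
                   fraction = 1 / 4000, probability = 1 / 4000),
    class = "g4_profile")
  er <- enrichment_ratio(flat)
  expect_equal(er$ratio, 1)
  expect_false(er$far_zero)

  near_only <- flat
  near_only$probability <- ifelse(offsets >= -200 & offsets <= 0,
                                  1 / 201, 0)
  er2 <- enrichment_ratio(near_only)
  expect_true(is.infinite(er2$ratio))
  expect_true(er2$far_zero)
})

test_that("a higher planting rate near the TSS raises the ratio", {
  set.seed(21)
  n_win <- 40
  rows <- list()
  for (i in seq_len(n_win)) {
    # plant near (-150..-50) in every window, far (-1500..-1300) in 1 of 10
    rows[[length(rows) + 1]] <- tibble::tibble(
      seq_id = paste0("w", i), strand = "coding",
      offset_lo = sample(-150:-65, 1), offset_hi = 0L)
    if (i %% 10 == 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        seq_id = paste0("w", i), strand = "coding",
        offset_lo = sample(-1500:-1315, 1), offset_hi = 0L)
    }
  }
  regs <- dplyr::bind_rows(rows)
  regs$offset_hi <- regs$offset_lo + 14L
  win <- tibble::tibble(id = paste0("w", seq_len(n_win)),
                        offset_start = -1999L, offset_end = 2000L)
  d <- positional_distribution(regs, win)
  er <- enrichment_ratio(d)
  expect_gt(er$ratio, 5)
})

test_that("quantile classes split a region population as expected", {
  regs <- tibble::tibble(length = 1:200, g_content = runif(200),
                         n_tot = 1:200, n_tand = 1:200)
  cls <- classify_regions(regs, "length")
  expect_equal(as.integer(table(cls$class)), c(100, 50, 48, 2))
  edges <- attr(cls, "class_edges")
  expect_equal(unname(edges), c(100, 150, 198))
  # ties collapse into the lower bin
  tied <- tibble::tibble(length = rep(15L, 50), g_content = 0.8,
                         n_tot = 1L, n_tand = 1L)
  tcls <- classify_regions(tied, "length")
  expect_true(all(tcls$class == "bottom50"))
})

test_that("region summaries use midpoint quantiles and per-gene counts work", {
  regs <- tibble::tibble(seq_id = c("a", "a", "b", "c"),
                         length = c(15, 18, 25, 30),
                         g_content = c(0.8, 0.7, 0.6, 0.75),
                         n_tot = c(1, 4, 2, 8), n_tand = c(1, 1, 1, 2))
  s <- summarize_regions(regs)
  expect_equal(s$value[s$metric == "length" & s$prob == 0.5], 21.5)
  one <- summarize_regions(regs[1, ])
  expect_true(all(one$value[one$metric == "length"] == 15))

  win <- tibble::tibble(id = c("a", "b", "c", "d"))
  cnt <- regions_per_gene(regs, win)
  expect_equal(cnt$n_regions[match(c("a", "b", "c", "d"), cnt$id)],
               c(2, 1, 1, 0))
})

test_that("first-promoter deduplication keeps one promoter per gene", {
  prom <- tibble::tibble(id = c("TP53_1", "TP53_2", "MYC_1"),
                         chrom = "chr1", tss = c(100, 200, 300),
                         strand = "+")
  first <- first_promoter_only(prom)
  expect_equal(first$id, c("TP53_1", "MYC_1"))
  # identical when every gene has a single promoter
  expect_equal(first_promoter_only(prom[c(1, 3), ]), prom[c(1, 3), ])
})

test_that("mononucleotide shuffles preserve composition and are seeded", {
  win <- tibble::tibble(id = c("w1", "w2"),
                        seq = c(random_dna(200, 0.6, seed = 5),
                                random_dna(200, 0.4, seed = 6)))
  s1 <- shuffle_windows(win, 42)
  s2 <- shuffle_windows(win, 42)
  s3 <- shuffle_windows(win, 43)
  expect_identical(s1$seq, s2$seq)
  expect_false(identical(s1$seq, s3$seq))
  for (i in 1:2) {
    expect_equal(sort(strsplit(s1$seq[i], "")[[1]]),
                 sort(strsplit(win$seq[i], "")[[1]]))
  }
})

test_that("shuffling washes out TSS clustering of planted regions", {
  tss <- seq(3000, 7000, by = 500)
  genome <- make_genome(tss)
  prom <- tibble::tibble(id = paste0("g", seq_along(tss), "_1"),
                         chrom = "chr1", tss = tss, strand = "+")
  win <- extract_windows(genome, prom)
  regs <- scan_windows(win, catalog = stable_catalog)
  d <- positional_distribution(regs, win)
  peak <- max(d$probability)
  shuf <- shuffle_windows(win, 7)
  regs_s <- scan_windows(shuf, catalog = stable_catalog)
  if (nrow(regs_s) > 0) {
    ds <- positional_distribution(regs_s, shuf)
    ds <- dplyr::filter(ds, strand == "coding")
    if (sum(ds$probability) > 0) {
      expect_lt(max(ds$probability), peak)
    }
  }
  succeed()
})
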