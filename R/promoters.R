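#' Read a promoter table
#'
#' Tab-separated with header columns `id`, `chrom`, `tss`, `strand`;
#' `tss` is the 1-based genomic coordinate of the transcription start site
#' (the convention of Eukaryotic Promoter Database exports) and `strand` is
#' `+` or `-`.
#'
#' @param path Path to the TSV file.
#' @return A tibble of promoter records.
#' @export
read_promoters <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("id", "chrom", "tss", "strand")
  if (!all(need %in% names(tbl))) {
    rlang::abort(paste("promoter table needs columns:",
                       paste(need, collapse = ", ")))
  }
  if (!all(tbl$strand %in% c("+", "-"))) {
    rlang::abort("promoter strand must be '+' or '-'")
  }
  tbl
}

#' Keep only the first promoter of each gene
#'
#' Region-level statistics are computed over unique promoters to avoid
#' counting the same G4CR once per alternative promoter; positional
#' analyses typically use all promoters. Gene identity is the promoter id
#' stripped of a trailing `_<number>` suffix (EPD style, e.g. `TP53_1`,
#' `TP53_2`); ids without such a suffix are their own gene.
#'
#' @param promoters A promoter tibble (see [read_promoters()]).
#' @return The tibble restricted to each gene's first listed promoter.
#' @export
first_promoter_only <- function(promoters) {
  gene <- sub("_\\d+$", "", promoters$id)
  promoters[!duplicated(gene), , drop = FALSE]
}

#' Extract TSS-centred promoter windows from a genome
#'
#' Cuts a window of `upstream` bases before and `downstream` bases after
#' the transcription start site (offsets `-upstream` .. `+downstream`,
#' offset 0 = the TSS base; 4000 positions with the defaults) out of the
#' genome for each promoter record. Windows of minus-strand genes are
#' reverse-complemented so that offsets always increase in the direction of
#' transcription. Windows running off a contig end are truncated and
#' flagged; records naming absent contigs are skipped with a warning.
#'
#' @param genome A named character vector of contig sequences, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @param promoters A promoter tibble (see [read_promoters()]).
#' @param upstream,downstream Window half-widths in bases (defaults 1999
#'   and 2000).
#' @return A tibble with `id`, `chrom`, `tss`, `strand`, `offset_start`,
#'   `offset_end` (inclusive offsets actually present), `truncated`, `seq`.
#' @export
extract_windows <- function(genome, promoters, upstream = 1999,
                            downstream = 2000) {
  contigs <- if (is.character(genome) && length(genome) == 1 &&
                 file.exists(genome)) {
    read_fasta(genome)
  } else {
    as_named_seqs(genome)
  }
  rows <- purrr::map(seq_len(nrow(promoters)), function(i) {
    p <- promoters[i, ]
    if (!p$chrom %in% names(contigs)) {
      rlang::warn(paste0("contig '", p$chrom, "' not in genome; skipping ",
                         p$id))
      return(NULL)
    }
    contig <- contigs[[p$chrom]]
    clen <- nchar(contig)
    if (p$strand == "+") {
      lo <- p$tss - upstream
      hi <- p$tss + downstream
      from <- max(1L, lo); to <- min(clen, hi)
      s <- substr(contig, from, to)
      off_start <- from - p$tss
      off_end <- to - p$tss
    } else {
      # offset o corresponds to genomic coordinate tss - o
      lo <- p$tss - downstream
      hi <- p$tss + upstream
      from <- max(1L, lo); to <- min(clen, hi)
      s <- revcomp(substr(contig, from, to))
      off_start <- p$tss - to
      off_end <- p$tss - from
    }
    tibble::tibble(
      id = p$id, chrom = p$chrom, tss = p$tss, strand = p$strand,
      offset_start = as.integer(off_start), offset_end = as.integer(off_end),
      truncated = off_start != -upstream || off_end != downstream,
      seq = s
    )
  })
  dplyr::bind_rows(rows)
}

#' Scan promoter windows on both strands and assemble regions
#'
#' The coding strand is the window sequence as oriented (5' to 3' in the
#' direction of transcription); the non-coding (template) strand is its
#' reverse complement, with coordinates mapped back to window offsets so
#' both strands share the same TSS-relative axis.
#'
#' @param windows A window tibble from [extract_windows()].
#' @param catalog A stable mask catalog (built with defaults if `NULL`).
#' @param params,max_loop,max_bulge Passed to the catalog builder when
#'   `catalog` is `NULL`.
#' @param strands `"both"` (default), `"coding"` or `"noncoding"`.
#' @return A region tibble as from [g4_regions()], with `seq_id` the window
#'   id, `strand` labelled `coding`/`noncoding`, window-local 0-based
#'   half-open `start`/`end`, plus inclusive TSS-relative offsets
#'   `offset_lo`/`offset_hi`.
#' @export
scan_windows <- function(windows, catalog = NULL, params = tm_params(),
                         max_loop = 7, max_bulge = 3, strands = "both") {
  strands <- match.arg(strands, c("both", "coding", "noncoding"))
  if (is.null(catalog)) {
    catalog <- filter_stable(g4_motif_catalog(max_loop, max_bulge, params),
                             params)
  }
  want <- switch(strands, both = "both", coding = "+", noncoding = "-")
  seqs <- rlang::set_names(windows$seq, windows$id)
  matches <- g4_scan(seqs, catalog = catalog, max_loop = max_loop,
                     strands = want)
  regs <- g4_regions(matches, seqs)
  if (nrow(regs) == 0) return(regs)
  regs$strand <- ifelse(regs$strand == "+", "coding", "noncoding")
  off0 <- rlang::set_names(windows$offset_start, windows$id)
  regs$offset_lo <- as.integer(off0[regs$seq_id] + regs$start)
  regs$offset_hi <- as.integer(off0[regs$seq_id] + regs$end - 1L)
  regs
}

#' Classify regions into quantile bins of one attribute
#'
#' Bin edges sit at the 50th, 75th and 99th percentiles (nearest-rank
#' method) of the attribute over all supplied regions, giving four classes:
#' the bottom 50%, 50-75%, 76-99% and the top 1%. Values tied with an edge
#' fall in the lower bin, so the classification is deterministic.
#'
#' @param regions A region tibble (e.g. from [scan_windows()]).
#' @param attribute One of `"length"`, `"g_content"`, `"n_tot"`, `"n_tand"`.
#' @return `regions` with an ordered factor column `class` (levels
#'   `bottom50`, `p50_75`, `p76_99`, `top1`) and an attribute
#'   `class_edges` recording the three edges.
#' @export
classify_regions <- function(regions,
                             attribute = c("length", "g_content", "n_tot",
                                           "n_tand")) {
  attribute <- match.arg(attribute)
  x <- regions[[attribute]]
  edges <- nearest_rank(x, c(0.50, 0.75, 0.99))
  lv <- c("bottom50", "p50_75", "p76_99", "top1")
  # manual binning: edges may coincide under heavy ties, and a value tied
  # with an edge always falls in the lower bin
  bin <- 1L + (x > edges[1]) + (x > edges[2]) + (x > edges[3])
  regions$class <- factor(lv[bin], levels = lv, ordered = TRUE)
  attr(regions, "class_edges") <- rlang::set_names(edges,
                                                   c("p50", "p75", "p99"))
  attr(regions, "class_attribute") <- attribute
  regions
}

nearest_rank <- function(x, probs) {
  xs <- sort(x)
  xs[pmax(1L, ceiling(probs * length(xs)))]
}

#' TSS-relative positional distribution of classified regions
#'
#' For every offset in the window, computes the fraction of promoters in
#' which that position lies inside a region of the given class (the
#' denominator at each offset is the number of windows actually covering
#' that offset, so truncated windows contribute only where present). Each
#' class/strand vector is then normalised to sum to 1 over all offsets,
#' which puts common and rare classes on a comparable scale. Classes with
#' no mass are left as all-zero vectors and recorded in the
#' `empty_classes` attribute rather than being normalised.
#'
#' @param regions Regions carrying `seq_id`, `strand`, `offset_lo`,
#'   `offset_hi` and (optionally, from [classify_regions()]) `class`.
#' @param windows The window tibble the regions came from.
#' @param upstream,downstream Offset range of the analysis window.
#' @return A tibble of class `g4_profile`: `strand`, `class`, `offset`,
#'   `fraction` (raw per-offset fraction of covering windows) and
#'   `probability` (normalised to sum 1 per strand/class).
#' @export
positional_distribution <- function(regions, windows, upstream = 1999,
                                    downstream = 2000) {
  offsets <- seq(-upstream, downstream)
  n_off <- length(offsets)
  # per-offset denominator: windows covering the offset
  denom <- integer(n_off)
  for (i in seq_len(nrow(windows))) {
    lo <- max(windows$offset_start[i], -upstream)
    hi <- min(windows$offset_end[i], downstream)
    if (lo <= hi) {
      idx <- (lo + upstream + 1L):(hi + upstream + 1L)
      denom[idx] <- denom[idx] + 1L
    }
  }
  if (!"class" %in% names(regions)) regions$class <- factor("all")
  classes <- levels(regions$class)
  strands <- sort(unique(regions$strand))
  if (length(strands) == 0) strands <- "coding"
  empties <- character()
  out <- purrr::map(strands, function(st) {
    purrr::map(classes, function(cl) {
      rr <- regions[regions$strand == st & regions$class == cl, , drop = FALSE]
      tal <- numeric(n_off)
      for (id in unique(rr$seq_id)) {
        cov <- logical(n_off)
        ri <- which(rr$seq_id == id)
        for (j in ri) {
          lo <- max(rr$offset_lo[j], -upstream)
          hi <- min(rr$offset_hi[j], downstream)
          if (lo <= hi) cov[(lo + upstream + 1L):(hi + upstream + 1L)] <- TRUE
        }
        tal <- tal + cov
      }
      frac <- ifelse(denom > 0, tal / pmax(denom, 1L), 0)
      tot <- sum(frac)
      if (tot > 0) {
        prob <- frac / tot
      } else {
        prob <- rep(0, n_off)
        empties <<- c(empties, paste(st, cl, sep = "/"))
      }
      tibble::tibble(strand = st, class = factor(cl, levels = classes),
                     offset = offsets, fraction = frac, probability = prob)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out <- tibble::new_tibble(out, class = "g4_profile")
  attr(out, "empty_classes") <- empties
  out
}

#' Near/far TSS enrichment ratio of a positional distribution
#'
#' Ratio of the mean probability in a window just upstream of the TSS
#' (default offsets -200..0) to the mean probability in a distal upstream
#' window (default -1500..-1300). A ratio of 1 means no enrichment; an
#' empty far window gives `Inf` and is flagged.
#'
#' @param dist A [positional_distribution()] result.
#' @param near,far Inclusive offset ranges `c(lo, hi)`.
#' @return A tibble per strand/class: `near_mean`, `far_mean`, `ratio`,
#'   `far_zero`.
#' @export
enrichment_ratio <- function(dist, near = c(-200, 0), far = c(-1500, -1300)) {
  dist |>
    dplyr::group_by(.data$strand, .data$class) |>
    dplyr::summarise(
      near_mean = mean(.data$probability[.data$offset >= near[1] &
                                           .data$offset <= near[2]]),
      far_mean = mean(.data$probability[.data$offset >= far[1] &
                                          .data$offset <= far[2]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ratio = ifelse(.data$far_mean > 0, .data$near_mean / .data$far_mean,
                     Inf),
      far_zero = .data$far_mean == 0
    )
}

#' Plot a TSS-relative positional distribution
#'
#' @param object A [positional_distribution()] result.
#' @param ... Unused.
#' @return A ggplot object: probability against TSS offset, coloured by
#'   class, faceted by strand.
#' @export
autoplot.g4_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset,
                                       y = .data$probability,
                                       colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~strand, ncol = 1) +
    ggplot2::labs(x = "position relative to TSS (nt)",
                  y = "normalised probability") +
    ggplot2::theme_minimal()
}

#' Quantile summaries of a region population
#'
#' Empirical percentiles of the region attributes (length, G-content,
#' `n_tot`, `n_tand`) and of the melting scores of all member isomers,
#' using the standard midpoint-interpolating quantile convention.
#'
#' @param regions A region tibble from [g4_regions()] or [scan_windows()].
#' @param probs Quantile probabilities (default 25/50/75/99%).
#' @return A long tibble: `metric`, `prob`, `value`.
#' @export
summarize_regions <- function(regions, probs = c(0.25, 0.5, 0.75, 0.99)) {
  metrics <- list(
    length = regions$length,
    g_content = regions$g_content,
    n_tot = regions$n_tot,
    n_tand = regions$n_tand
  )
  if ("isomers" %in% names(regions)) {
    metrics$tm <- unlist(purrr::map(regions$isomers, "tm"))
  }
  purrr::imap(metrics, function(v, nm) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NULL)
    tibble::tibble(metric = nm, prob = probs,
                   value = unname(stats::quantile(v, probs)))
  }) |> dplyr::bind_rows()
}

#' Number of regions per promoter window
#'
#' @param regions A region tibble whose `seq_id` is the promoter/window id.
#' @param windows Optional window tibble; windows without any region are
#'   then included with a count of 0.
#' @return A tibble `id`, `n_regions`.
#' @export
regions_per_gene <- function(regions, windows = NULL) {
  cnt <- dplyr::count(regions, id = .data$seq_id, name = "n_regions")
  if (!is.null(windows)) {
    cnt <- dplyr::left_join(tibble::tibble(id = unique(windows$id)), cnt,
                            by = "id")
    cnt$n_regions[is.na(cnt$n_regions)] <- 0L
  }
  cnt
}

#' Mononucleotide shuffle of promoter windows
#'
#' Permutes the residues of each window independently, preserving each
#' window's base composition exactly — the null model against which TSS
#' clustering of regions is judged. Deterministic for a given seed.
#'
#' @param windows A window tibble.
#' @param seed Integer RNG seed.
#' @return The window tibble with shuffled `seq`.
#' @export
shuffle_windows <- function(windows, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  windows$seq <- vapply(windows$seq, function(s) {
    paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  windows
}
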