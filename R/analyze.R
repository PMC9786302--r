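#' Full quadruplex-region analysis of a set of sequences
#'
#' One-stop pipeline: build (or reuse) the stable motif catalog, scan every
#' sequence for all quadruplex isomers, and assemble the matches into
#' G4-containing regions with their polymorphism statistics.
#'
#' @inheritParams g4_scan
#' @return An object of class `g4_analysis`: a list with elements `isomers`
#'   (the match tibble from [g4_scan()]), `regions` (from [g4_regions()]),
#'   `sequences` (named character), `params`, and `caps`
#'   (`max_loop`/`max_bulge`/catalog size). Use [tidy()] for the region
#'   table, [glance()] for a one-row summary and [autoplot()] for a
#'   multiplicity profile.
#' @examples
#' fit <- g4_analyze(c(pu18 = "AGGGTGGGGAGGGTGGGG"))
#' tidy(fit)
#' glance(fit)
#' @export
g4_analyze <- function(x, catalog = NULL, params = tm_params(), max_loop = 7,
                       max_bulge = 3, strands = "+") {
  seqs <- as_named_seqs(x)
  if (is.null(catalog)) {
    catalog <- filter_stable(g4_motif_catalog(max_loop, max_bulge, params),
                             params)
  }
  isomers <- g4_scan(seqs, catalog = catalog, max_loop = max_loop,
                     strands = strands)
  regions <- g4_regions(isomers, seqs)
  structure(
    list(isomers = isomers, regions = regions, sequences = seqs,
         params = params,
         caps = list(max_loop = max_loop, max_bulge = max_bulge,
                     n_masks = nrow(catalog))),
    class = "g4_analysis"
  )
}

#' @export
print.g4_analysis <- function(x, ...) {
  cat(sprintf(
    "<g4_analysis> %d sequence(s): %d isomer(s) in %d region(s); %d stable masks, threshold %.1f degC\n",
    length(x$sequences), nrow(x$isomers), nrow(x$regions), x$caps$n_masks,
    x$params$threshold
  ))
  if (nrow(x$regions) > 0) print(tidy(x))
  invisible(x)
}

#' Tidy the regions of a quadruplex analysis
#'
#' @param x A [g4_analyze()] result.
#' @param ... Unused.
#' @return The region tibble without list columns: one row per G4CR with
#'   coordinates, length, G-content, `n_tot`, `n_tand` and melting-score
#'   summaries.
#' @export
tidy.g4_analysis <- function(x, ...) {
  dplyr::select(x$regions, -"isomers", -"multiplicity")
}

#' One-row summary of a quadruplex analysis
#'
#' @param x A [g4_analyze()] result.
#' @param ... Unused.
#' @return A one-row tibble: sequence, region and isomer counts plus median
#'   region length, `n_tot`, `n_tand` and median isomer tm.
#' @export
glance.g4_analysis <- function(x, ...) {
  tibble::tibble(
    n_sequences = length(x$sequences),
    n_regions = nrow(x$regions),
    n_isomers = nrow(x$isomers),
    median_length = if (nrow(x$regions)) stats::median(x$regions$length) else NA_real_,
    median_n_tot = if (nrow(x$regions)) stats::median(x$regions$n_tot) else NA_real_,
    median_n_tand = if (nrow(x$regions)) stats::median(x$regions$n_tand) else NA_real_,
    median_tm = if (nrow(x$isomers)) stats::median(x$isomers$tm) else NA_real_
  )
}

#' Multiplicity profile plot of an analysed sequence
#'
#' Plots the per-base folding multiplicity of every region found in one
#' sequence, one bar per residue, faceted by strand.
#'
#' @param object A [g4_analyze()] result.
#' @param seq_id Which sequence to plot (default: the first with regions).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.g4_analysis <- function(object, seq_id = NULL, ...) {
  regs <- object$regions
  if (nrow(regs) == 0) rlang::abort("no regions to plot")
  if (is.null(seq_id)) seq_id <- regs$seq_id[1]
  regs <- dplyr::filter(regs, .data$seq_id == !!seq_id)
  tracks <- dplyr::bind_rows(
    purrr::map(seq_len(nrow(regs)), function(i) multiplicity_track(regs[i, ]))
  )
  ggplot2::ggplot(tracks, ggplot2::aes(x = .data$pos, y = .data$multiplicity)) +
    ggplot2::geom_col(width = 1, fill = "grey25") +
    ggplot2::facet_wrap(~strand, ncol = 1) +
    ggplot2::labs(x = "position (0-based)", y = "folding multiplicity",
                  title = seq_id) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
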