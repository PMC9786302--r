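#' Enumerate every admissible three-tetrad quadruplex motif mask
#'
#' Generates the full combinatorial catalog of core/loop/bulge layouts for a
#' 12-guanine, three-tetrad quadruplex: four tracts of three core guanines,
#' three loops of 1 to `max_loop` nucleotides, and at most one bulge of 1 to
#' `max_bulge` non-G residues strictly inside one tract (between its first
#' and second, or second and third, core G — two admissible gaps per tract,
#' eight in total). With the defaults this yields
#' `max_loop^3 * (8 * max_bulge + 1) = 8575` masks. Each mask is scored with
#' [tm_est()]; use [filter_stable()] to keep only stable masks.
#'
#' @param max_loop Maximum loop length in nucleotides (default 7).
#' @param max_bulge Maximum bulge length in nucleotides (default 3); 0
#'   disables bulges entirely.
#' @param params A [tm_params()] object used to score each mask.
#'
#' @return A tibble with one row per mask: `mask_id`, loop lengths
#'   `l1`,`l2`,`l3`, `bulge_tract` (1-4 or `NA`), `bulge_gap` (1 = between
#'   core G1 and G2 of that tract, 2 = between G2 and G3, or `NA`),
#'   `bulge_len` (0 when no bulge), `width` (total columns,
#'   `12 + l1 + l2 + l3 + bulge_len`), `tm`, and `encoding`, a list column of
#'   integer rows with core positions coded 1, loops 0 and bulged positions
#'   13 (so that a window's indicator/mask dot product equals 12 exactly when
#'   all cores are G and no bulge column is G).
#'
#' @examples
#' cat <- g4_motif_catalog()
#' nrow(cat)                      # 8575
#' nrow(filter_stable(cat))       # 699
#' @seealso [filter_stable()], [encode_mask()]
#' @export
g4_motif_catalog <- function(max_loop = 7, max_bulge = 3, params = tm_params()) {
  stopifnot(max_loop >= 1, max_bulge >= 0)
  loops <- tidyr::expand_grid(
    l1 = seq_len(max_loop), l2 = seq_len(max_loop), l3 = seq_len(max_loop)
  )
  no_bulge <- dplyr::mutate(loops,
    bulge_tract = NA_integer_, bulge_gap = NA_integer_, bulge_len = 0L
  )
  masks <- no_bulge
  if (max_bulge >= 1) {
    bulged <- tidyr::expand_grid(
      loops,
      bulge_tract = 1:4, bulge_gap = 1:2, bulge_len = seq_len(max_bulge)
    )
    masks <- dplyr::bind_rows(no_bulge, bulged)
  }
  masks <- dplyr::mutate(masks,
    width = 12L + .data$l1 + .data$l2 + .data$l3 + .data$bulge_len,
    n_bulges = as.integer(.data$bulge_len > 0),
    tm = tm_est(.data$l1, .data$l2, .data$l3, .data$n_bulges, .data$bulge_len,
                params = params)
  )
  masks <- dplyr::arrange(masks, .data$l1, .data$l2, .data$l3,
                          .data$bulge_tract, .data$bulge_gap, .data$bulge_len)
  masks$mask_id <- seq_len(nrow(masks))
  masks$encoding <- purrr::pmap(
    masks[c("l1", "l2", "l3", "bulge_tract", "bulge_gap", "bulge_len")],
    encode_mask
  )
  out <- dplyr::select(masks, "mask_id", "l1", "l2", "l3", "bulge_tract",
                       "bulge_gap", "bulge_len", "n_bulges", "width", "tm",
                       "encoding")
  attr(out, "caps") <- list(max_loop = max_loop, max_bulge = max_bulge)
  out
}

#' Retain only masks whose estimated melting temperature passes the cutoff
#'
#' Rescores each mask of a catalog under `params` and keeps those with
#' `tm >= params$threshold` (inclusive). With the default model this reduces
#' the 8575-mask catalog to 699 stable motifs; no mask with two or more
#' bulges could ever survive the default 50 degree cutoff, which is why the
#' enumeration considers at most one bulge.
#'
#' @param catalog A catalog from [g4_motif_catalog()].
#' @param params A [tm_params()] object; both the rescoring and the cutoff
#'   come from it.
#' @return The filtered catalog tibble, `tm` updated under `params`.
#' @examples
#' nrow(filter_stable(g4_motif_catalog()))   # 699
#' @export
filter_stable <- function(catalog, params = tm_params()) {
  caps <- attr(catalog, "caps")
  catalog <- dplyr::mutate(catalog,
    tm = tm_est(.data$l1, .data$l2, .data$l3, .data$n_bulges, .data$bulge_len,
                params = params)
  )
  out <- dplyr::filter(catalog, .data$tm >= params$threshold)
  attr(out, "caps") <- caps
  attr(out, "threshold") <- params$threshold
  out
}

#' Numeric row encoding of a single motif mask
#'
#' Builds the scanning row for one core/loop/bulge layout: core guanine
#' positions are coded 1, loop positions 0, and bulged positions 13. Against
#' a 0/1 G-indicator window of the same width, the dot product is exactly 12
#' when every core position holds a G and no bulge position does.
#'
#' @param l1,l2,l3 Loop lengths (nt), each at least 1.
#' @param bulge_tract Tract carrying the bulge (1-4), or `NA` for none.
#' @param bulge_gap Position of the bulge within its tract: 1 = between the
#'   tract's first and second core G, 2 = between its second and third.
#' @param bulge_len Bulge length in nucleotides (0 for none).
#' @return Integer vector of length `12 + l1 + l2 + l3 + bulge_len`.
#' @examples
#' encode_mask(1, 3, 2)                # the (1,3,2) no-bulge layout
#' encode_mask(1, 1, 2, bulge_tract = 2, bulge_gap = 2, bulge_len = 2)
#' @export
encode_mask <- function(l1, l2, l3, bulge_tract = NA, bulge_gap = NA,
                        bulge_len = 0) {
  stopifnot(l1 >= 1, l2 >= 1, l3 >= 1)
  tract <- function(i) {
    if (!is.na(bulge_tract) && bulge_len > 0 && i == bulge_tract) {
      if (bulge_gap == 1) {
        c(1L, rep(13L, bulge_len), 1L, 1L)
      } else {
        c(1L, 1L, rep(13L, bulge_len), 1L)
      }
    } else {
      c(1L, 1L, 1L)
    }
  }
  c(tract(1), rep(0L, l1), tract(2), rep(0L, l2), tract(3), rep(0L, l3),
    tract(4))
}
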