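#' Homozygosity-enrichment score
#'
#' `HMES = (alpha + rho) / (beta + rho)`, where `alpha` and `beta` are the
#' homozygous and heterozygous variant counts of a fragment and `rho` a
#' small ratio adjustment that avoids division of or by zero. The score is
#' strictly increasing in `alpha`, strictly decreasing in `beta`, and equals
#' 1 when the counts are equal; a fragment enriched in homozygous variants
#' (linked to a selected recessive locus) scores above 1.
#'
#' @param alpha Homozygous variant count (vectorized, non-negative).
#' @param beta Heterozygous variant count (vectorized, non-negative).
#' @param rho Ratio adjustment, strictly positive (default 0.5).
#' @return Numeric vector of scores, all positive.
#' @examples
#' compute_hmes(10, 0)   # 21
#' compute_hmes(5, 2)    # 2.2
#' @export
compute_hmes <- function(alpha, beta, rho = 0.5) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0) {
    stop("rho must be a single positive number")
  }
  stopifnot(all(alpha >= 0), all(beta >= 0))
  (alpha + rho) / (beta + rho)
}

#' Score fragments by homozygosity enrichment
#'
#' Tallies homozygous and heterozygous variants per fragment and computes
#' each fragment's HMES. Fragments with no variants are omitted: their score
#' would be exactly 1 and cannot pass the strict `HMES > 1` enrichment
#' filter.
#'
#' @param variants Classified variant data frame (see
#'   [build_variant_table()]): columns `contig`, `zygosity`.
#' @param fragment_lengths Named integer vector of fragment lengths (bp).
#' @param rho Ratio adjustment (default 0.5).
#' @return Data frame with `contig`, `length`, `alpha`, `beta`, `hmes`,
#'   one row per fragment carrying at least one variant.
#' @export
score_fragments <- function(variants, fragment_lengths, rho = 0.5) {
  unknown <- setdiff(unique(variants$contig), names(fragment_lengths))
  if (length(unknown)) {
    stop("variant(s) on unknown fragment(s): ",
         paste(utils::head(unknown, 10L), collapse = ", "))
  }
  if (nrow(variants) == 0L) {
    return(data.frame(contig = character(), length = integer(),
                      alpha = integer(), beta = integer(), hmes = numeric(),
                      stringsAsFactors = FALSE))
  }
  f <- factor(variants$contig)
  alpha <- as.integer(tapply(variants$zygosity == "homozygous", f, sum))
  beta <- as.integer(tapply(variants$zygosity == "heterozygous", f, sum))
  ids <- levels(f)
  data.frame(contig = ids,
             length = as.integer(unname(fragment_lengths[ids])),
             alpha = alpha, beta = beta,
             hmes = compute_hmes(alpha, beta, rho),
             stringsAsFactors = FALSE)
}

#' Keep only enriched fragments (HMES strictly greater than 1)
#'
#' @param scores Fragment score data frame from [score_fragments()].
#' @return The subset with `hmes > 1`.
#' @export
filter_enriched <- function(scores) {
  scores[scores$hmes > 1, , drop = FALSE]
}

# Deterministic ranking order used everywhere fragments are sorted:
# hmes desc, length desc, contig id asc.
fragment_order <- function(scores) {
  order(-scores$hmes, -scores$length, scores$contig)
}

#' Arrange fragments centre-out by score
#'
#' Places the highest-scoring fragment at the centre, the second to its
#' immediate left, the third to its immediate right, the fourth at the
#' extreme left, the fifth at the extreme right, and so on (even ranks
#' extend the left flank, odd ranks the right). Nearness to the centre of
#' the arrangement estimates nearness to the causative mutation; the result
#' is a rough ordering, not the fragments' original genomic order.
#'
#' @param scores Fragment score data frame.
#' @return The scores reordered left-to-right, with columns `rank` (1 =
#'   highest score) and `position` (1 = leftmost), and attribute
#'   `centre_index` giving the row position of the top fragment.
#' @export
center_out_order <- function(scores) {
  n <- nrow(scores)
  if (n == 0L) {
    out <- cbind(scores, rank = integer(0), position = integer(0))
    attr(out, "centre_index") <- integer(0)
    return(out)
  }
  ranked <- scores[fragment_order(scores), , drop = FALSE]
  evens <- seq_len(n)[seq_len(n) %% 2L == 0L]
  odds <- seq_len(n)[seq_len(n) %% 2L == 1L & seq_len(n) > 1L]
  left_to_right <- c(rev(evens), 1L, odds)
  out <- ranked[left_to_right, , drop = FALSE]
  out$rank <- left_to_right
  out$position <- seq_len(n)
  rownames(out) <- NULL
  attr(out, "centre_index") <- length(evens) + 1L
  out
}

#' Select the top score percentile of enriched variants
#'
#' Takes the `ceiling(percent/100 * N)` variants with the highest fragment
#' HMES among the `N` supplied variants. Ties at the cut are broken
#' deterministically by (hmes desc, fragment length desc, contig id asc,
#' position asc).
#'
#' @param variants Data frame of variants each carrying its fragment's
#'   `hmes` and `length` columns plus `contig`, `pos`.
#' @param percent Percentile size in (0, 100] (default 5).
#' @return The selected subset, sorted by the tie-break order.
#' @export
select_top_percentile <- function(variants, percent = 5) {
  stopifnot(percent > 0, percent <= 100)
  n <- nrow(variants)
  if (n == 0L) return(variants)
  k <- ceiling(percent / 100 * n)
  ord <- order(-variants$hmes, -variants$length, variants$contig, variants$pos)
  out <- variants[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract flanking sequence around a variant position
#'
#' Returns up to `flank_len` bases immediately left and right of a 1-based
#' position, silently truncated at the contig ends; sized for PCR-marker
#' design around candidate variants.
#'
#' @param contigs Named character vector of contig sequences.
#' @param contig_id Contig identifier.
#' @param position 1-based position within the contig.
#' @param flank_len Maximum flank length in bp (default 50).
#' @return A list with elements `left` and `right`.
#' @export
extract_flanks <- function(contigs, contig_id, position, flank_len = 50L) {
  seq <- unname(contigs[contig_id])[1L]
  if (is.na(seq)) stop("unknown contig: ", contig_id)
  L <- nchar(seq)
  if (position < 1L || position > L) {
    stop(sprintf("position %d out of range for contig %s (length %d)",
                 position, contig_id, L))
  }
  left <- if (position == 1L) "" else
    substr(seq, max(1L, position - flank_len), position - 1L)
  right <- if (position == L) "" else
    substr(seq, position + 1L, min(L, position + flank_len))
  list(left = left, right = right)
}
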