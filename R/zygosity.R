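#' Zygosity classification thresholds
#'
#' Bundles the allele-frequency windows and evidence filters used to call a
#' bulk variant homozygous or heterozygous. For a recessive allele under
#' phenotypic selection the mutant bulk is expected near 100% mutant-allele
#' frequency at the causative locus, and a non-mutant outcross F2 bulk near
#' 33.3% (two thirds of it are heterozygotes, half of whose alleles are
#' mutant); the windows absorb binomial read-sampling noise around those
#' ideals at typical 8-50x bulk coverages.
#'
#' @param hom_min_af Minimum allele frequency to call homozygous (default 0.90).
#' @param het_min_af Lower edge of the heterozygous window (default 0.25).
#' @param het_max_af Upper edge of the heterozygous window (default 0.75).
#' @param min_depth Minimum filtered depth to consider a site (default 6).
#' @param min_base_quality Minimum Phred base quality when counting from
#'   pileup evidence (default 15).
#' @return An object of class `zygosity_thresholds`.
#' @export
zygosity_thresholds <- function(hom_min_af = 0.90, het_min_af = 0.25,
                                het_max_af = 0.75, min_depth = 6L,
                                min_base_quality = 15L) {
  stopifnot(hom_min_af > 0, hom_min_af <= 1,
            het_min_af > 0, het_min_af < 1,
            het_max_af > 0, het_max_af < 1,
            min_depth >= 1, min_base_quality >= 0)
  if (!(het_min_af < het_max_af && het_max_af < hom_min_af)) {
    stop("thresholds must satisfy het_min_af < het_max_af < hom_min_af")
  }
  structure(list(hom_min_af = hom_min_af, het_min_af = het_min_af,
                 het_max_af = het_max_af, min_depth = as.integer(min_depth),
                 min_base_quality = as.integer(min_base_quality)),
            class = "zygosity_thresholds")
}

#' Allele frequency from counts
#'
#' @param alt_count Reads carrying the allele.
#' @param depth Filtered depth at the site.
#' @return `alt_count / depth`; `NA` where depth is zero (undefined
#'   frequency; such variants are dropped downstream, not guessed).
#' @export
allele_frequency <- function(alt_count, depth) {
  ifelse(depth > 0, alt_count / depth, NA_real_)
}

#' Classify an allele frequency as homozygous, heterozygous or ambiguous
#'
#' Homozygous iff `af >= hom_min_af`; heterozygous iff
#' `het_min_af <= af <= het_max_af`; otherwise ambiguous. The three ranges
#' partition `[0, 1]`.
#'
#' @param af Allele frequency (vectorized), in `[0, 1]`.
#' @param thresholds A [zygosity_thresholds()] object.
#' @return Character vector in `{"homozygous", "heterozygous", "ambiguous"}`.
#' @export
classify_zygosity <- function(af, thresholds = zygosity_thresholds()) {
  stopifnot(all(is.na(af) | (af >= 0 & af <= 1)))
  out <- rep(NA_character_, length(af))
  out[!is.na(af)] <- "ambiguous"
  out[!is.na(af) & af >= thresholds$hom_min_af] <- "homozygous"
  out[!is.na(af) & af >= thresholds$het_min_af & af <= thresholds$het_max_af] <-
    "heterozygous"
  out
}

#' Subtract background homozygous variants from a mutant-bulk variant set
#'
#' Removes every mutant-bulk variant whose (contig, position, alt allele)
#' key matches a *homozygous* variant in the union of the supplied
#' background sets (background bulks and/or parental lines). Heterozygous
#' background matches are retained: only fixed background polymorphisms are
#' evidence against causation. Matching is allele-aware so that a genuine
#' induced allele is not discarded merely for coinciding with an accession
#' SNP position.
#'
#' @param mut_variants Data frame of mutant-bulk variants with `contig`,
#'   `pos`, `alt` and `zygosity` columns.
#' @param background_sets A single data frame or a list of data frames with
#'   `contig`, `pos`, `alt`, `zygosity`.
#' @return The surviving subset of `mut_variants` (row order preserved).
#' @export
subtract_background <- function(mut_variants, background_sets) {
  if (is.data.frame(background_sets)) background_sets <- list(background_sets)
  keys <- unlist(lapply(background_sets, function(b) {
    if (is.null(b) || nrow(b) == 0L) return(character(0))
    hom <- b[b$zygosity == "homozygous", , drop = FALSE]
    paste(hom$contig, hom$pos, hom$alt, sep = "\r")
  }), use.names = FALSE)
  if (length(keys) == 0L || nrow(mut_variants) == 0L) return(mut_variants)
  mk <- paste(mut_variants$contig, mut_variants$pos, mut_variants$alt, sep = "\r")
  mut_variants[!(mk %in% keys), , drop = FALSE]
}

#' Build the classified variant table for a mutant bulk
#'
#' Applies depth and frequency filters to mutant-bulk allele evidence,
#' classifies each surviving site by its mutant-bulk allele frequency,
#' attaches the background-bulk frequency where background evidence covers
#' the same key, vetoes variants that are homozygous in the background bulk
#' (non-segregating), and subtracts homozygous calls from any parental
#' variant sets. Ambiguous-frequency variants are dropped and counted.
#'
#' @param mut_counts Counts data frame for the mutant bulk (from
#'   [pileup_counts()], [read_vcf_variants()], or the simulator): columns
#'   `contig`, `pos`, `ref`, `alt`, `ref_count`, `alt_count`, `depth`.
#' @param bg_counts Optional counts data frame for the background bulk.
#' @param parental_sets Optional list of variant data frames (e.g. from
#'   [read_vcf_variants()]) whose homozygous calls are subtracted.
#' @param thresholds A [zygosity_thresholds()] object.
#' @param fragment_lengths Optional named lengths of the assembly fragments;
#'   when given, evidence on unknown contigs is an error.
#' @return A data frame of classified variants (`zygosity` in
#'   homozygous/heterozygous), with an attribute `stage_counts` recording
#'   the funnel: sites in, depth-filtered, classified, vetoed, subtracted,
#'   surviving.
#' @export
build_variant_table <- function(mut_counts, bg_counts = NULL,
                                parental_sets = list(),
                                thresholds = zygosity_thresholds(),
                                fragment_lengths = NULL) {
  counts <- list(sites_in = nrow(mut_counts))
  if (!is.null(fragment_lengths)) {
    unknown <- setdiff(unique(mut_counts$contig), names(fragment_lengths))
    if (length(unknown)) {
      stop("evidence on contig(s) absent from the assembly: ",
           paste(utils::head(unknown, 10L), collapse = ", "))
    }
  }
  v <- mut_counts
  # a site must carry an alternative allele to be a variant
  v <- v[!is.na(v$alt) & v$alt_count > 0L, , drop = FALSE]
  if (!is.null(v$freq_unknown)) {
    counts$freq_unknown <- sum(v$freq_unknown)
    v <- v[!v$freq_unknown, , drop = FALSE]
  }
  v <- v[v$depth >= thresholds$min_depth, , drop = FALSE]
  counts$depth_ok <- nrow(v)
  v$af <- allele_frequency(v$alt_count, v$depth)
  v$zygosity <- classify_zygosity(v$af, thresholds)
  counts$ambiguous <- sum(v$zygosity == "ambiguous")
  v <- v[v$zygosity %in% c("homozygous", "heterozygous"), , drop = FALSE]
  counts$classified <- nrow(v)

  v$bg_af <- rep(NA_real_, nrow(v))
  if (!is.null(bg_counts) && nrow(bg_counts) > 0L) {
    bg <- bg_counts[!is.na(bg_counts$alt) & bg_counts$depth > 0L, , drop = FALSE]
    bk <- paste(bg$contig, bg$pos, bg$alt, sep = "\r")
    vk <- paste(v$contig, v$pos, v$alt, sep = "\r")
    m <- match(vk, bk)
    v$bg_af[!is.na(m)] <- allele_frequency(bg$alt_count[m[!is.na(m)]],
                                           bg$depth[m[!is.na(m)]])
    bg_depth <- rep(0L, nrow(v))
    bg_depth[!is.na(m)] <- bg$depth[m[!is.na(m)]]
    # veto: fixed in a well-covered background bulk means non-segregating
    veto <- !is.na(v$bg_af) & v$bg_af >= thresholds$hom_min_af &
      bg_depth >= thresholds$min_depth
    counts$bg_vetoed <- sum(veto)
    v <- v[!veto, , drop = FALSE]
  } else {
    counts$bg_vetoed <- 0L
  }

  if (length(parental_sets)) {
    psets <- lapply(parental_sets, function(p) {
      if (is.null(p$zygosity)) {
        p$af <- allele_frequency(p$alt_count, p$depth)
        p <- p[!is.na(p$af), , drop = FALSE]
        p$zygosity <- classify_zygosity(p$af, thresholds)
      }
      p
    })
    before <- nrow(v)
    v <- subtract_background(v, psets)
    counts$parent_subtracted <- before - nrow(v)
  } else {
    counts$parent_subtracted <- 0L
  }
  counts$surviving <- nrow(v)
  rownames(v) <- NULL
  attr(v, "stage_counts") <- counts
  v
}
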