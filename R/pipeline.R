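candidate_columns <- c("hmes", "allele_frequency", "contig_length",
                       "contig_id", "position_in_contig", "ref_base",
                       "coverage", "read_bases", "base_qualities",
                       "left_flank", "variant_allele", "right_flank")

#' Map candidate causative variants on a fragmented assembly
#'
#' The main entry point. Composes the full mapping workflow for a recessive
#' mutation from bulked segregant sequencing: classify mutant-bulk variants
#' by allele frequency, veto/subtract background- and parent-derived
#' homozygous calls, score every fragment's homozygosity enrichment
#' (`HMES = (alpha + rho) / (beta + rho)`), keep fragments with
#' `HMES > 1`, rank variants by their fragment's score, select the top
#' percentile, and attach flanking sequence for marker design.
#'
#' @param assembly The unordered assembly fragments: a path to a FASTA
#'   file, a named character vector of sequences, or a named integer vector
#'   of fragment lengths (in which case flanking sequences are reported
#'   empty).
#' @param mut_evidence Mutant-bulk evidence: a counts data frame (columns
#'   `contig`, `pos`, `ref`, `alt`, `ref_count`, `alt_count`, `depth`), or
#'   a path to an mpileup/VCF file.
#' @param bg_evidence Optional background-bulk evidence, same forms.
#' @param parental_sets Optional list of parental variant sets (data frames
#'   or VCF paths); their homozygous calls are subtracted.
#' @param thresholds A [zygosity_thresholds()] object.
#' @param rho HMES ratio adjustment (default 0.5).
#' @param top_percent Score percentile of variants to report (default 5).
#' @param flank_len Flanking sequence length in bp (default 50).
#' @param format Evidence format for file inputs: `"auto"` (by extension),
#'   `"pileup"` or `"vcf"`.
#' @return An object of class `hmes_map` with components `candidates`
#'   (the 12-column report, sorted by HMES descending), `scores` (all
#'   fragment scores), `enriched` (scores with HMES > 1), `ordered`
#'   (the centre-out arrangement of enriched fragments), `variants`
#'   (the classified variant table), `stage_counts` and `options`.
#' @examples
#' frags <- c(f1 = "ACGTACGTACGTACGTACGT", f2 = "TTTTACGTACGTACGTCCCC")
#' mut <- data.frame(contig = c("f1", "f1", "f2"), pos = c(5L, 9L, 8L),
#'                   ref = "A", alt = "T",
#'                   ref_count = c(0L, 0L, 5L), alt_count = c(10L, 9L, 5L),
#'                   depth = c(10L, 9L, 10L))
#' fit <- hmes_map(frags, mut)
#' fit$candidates$contig_id
#' @export
hmes_map <- function(assembly, mut_evidence, bg_evidence = NULL,
                     parental_sets = list(),
                     thresholds = zygosity_thresholds(), rho = 0.5,
                     top_percent = 5, flank_len = 50L, format = "auto") {
  contigs <- NULL
  if (is.character(assembly) && length(assembly) == 1L && is.null(names(assembly))) {
    contigs <- read_fasta(assembly)
    fragment_lengths <- nchar(contigs)
  } else if (is.character(assembly)) {
    contigs <- assembly
    fragment_lengths <- nchar(contigs)
  } else if (is.numeric(assembly) && !is.null(names(assembly))) {
    fragment_lengths <- as.integer(assembly)
    names(fragment_lengths) <- names(assembly)
  } else {
    stop("assembly must be a FASTA path, named sequences, or named lengths")
  }

  load_evidence <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.character(x) && length(x) == 1L) {
      fmt <- format
      if (fmt == "auto") {
        fmt <- if (grepl("\\.vcf(\\.gz)?$", x, ignore.case = TRUE)) "vcf" else "pileup"
      }
      if (fmt == "vcf") return(read_vcf_variants(x))
      return(pileup_counts(read_pileup(x), thresholds$min_base_quality))
    }
    stop("evidence must be a counts data frame or a file path")
  }

  mut <- load_evidence(mut_evidence)
  bg <- if (is.null(bg_evidence)) NULL else load_evidence(bg_evidence)
  parents <- lapply(parental_sets, load_evidence)

  variants <- build_variant_table(mut, bg, parents, thresholds,
                                  fragment_lengths = fragment_lengths)
  stage_counts <- attr(variants, "stage_counts")

  scores <- score_fragments(variants, fragment_lengths, rho)
  enriched <- filter_enriched(scores)
  ordered <- center_out_order(enriched)
  stage_counts$fragments_scored <- nrow(scores)
  stage_counts$fragments_enriched <- nrow(enriched)

  # variants on enriched fragments, carrying their fragment's score
  m <- match(variants$contig, enriched$contig)
  ev <- variants[!is.na(m), , drop = FALSE]
  ev$hmes <- enriched$hmes[m[!is.na(m)]]
  ev$length <- enriched$length[m[!is.na(m)]]
  stage_counts$variants_enriched <- nrow(ev)

  sel <- select_top_percentile(ev, top_percent)
  stage_counts$variants_selected <- nrow(sel)

  flanks <- lapply(seq_len(nrow(sel)), function(i) {
    if (is.null(contigs)) return(list(left = "", right = ""))
    extract_flanks(contigs, sel$contig[i], sel$pos[i], flank_len)
  })
  candidates <- data.frame(
    hmes = sel$hmes,
    allele_frequency = sel$af,
    contig_length = sel$length,
    contig_id = sel$contig,
    position_in_contig = sel$pos,
    ref_base = sel$ref,
    coverage = if (!is.null(sel$coverage)) sel$coverage else sel$depth,
    read_bases = if (!is.null(sel$bases)) sel$bases else rep(".", nrow(sel)),
    base_qualities = if (!is.null(sel$quals)) sel$quals else rep(".", nrow(sel)),
    left_flank = vapply(flanks, `[[`, "", "left"),
    variant_allele = sel$alt,
    right_flank = vapply(flanks, `[[`, "", "right"),
    stringsAsFactors = FALSE
  )
  if (nrow(candidates) == 0L) {
    candidates <- candidates[, candidate_columns, drop = FALSE]
  }

  structure(list(candidates = candidates, scores = scores,
                 enriched = enriched, ordered = ordered, variants = variants,
                 stage_counts = stage_counts,
                 options = list(thresholds = thresholds, rho = rho,
                                top_percent = top_percent,
                                flank_len = flank_len)),
            class = "hmes_map")
}

#' @export
print.hmes_map <- function(x, ...) {
  sc <- x$stage_counts
  cat("Homozygosity-enrichment mapping (HMES)\n")
  cat(sprintf("  sites in evidence:      %d\n", sc$sites_in))
  cat(sprintf("  classified variants:    %d (%d ambiguous dropped)\n",
              sc$classified, sc$ambiguous))
  cat(sprintf("  background-vetoed:      %d; parent-subtracted: %d\n",
              sc$bg_vetoed, sc$parent_subtracted))
  cat(sprintf("  fragments scored:       %d (%d with HMES > 1)\n",
              sc$fragments_scored, sc$fragments_enriched))
  cat(sprintf("  candidates reported:    %d of %d enriched variants (top %g%%)\n",
              sc$variants_selected, sc$variants_enriched, x$options$top_percent))
  if (nrow(x$candidates)) {
    top <- x$candidates[1L, ]
    cat(sprintf("  top candidate:          %s:%d %s>%s  HMES %.4f  AF %.4f\n",
                top$contig_id, top$position_in_contig, top$ref_base,
                top$variant_allele, top$hmes, top$allele_frequency))
  }
  invisible(x)
}

#' @export
summary.hmes_map <- function(object, ...) {
  s <- list(stage_counts = object$stage_counts,
            hmes_summary = if (nrow(object$scores)) summary(object$scores$hmes),
            candidates = object$candidates)
  class(s) <- "summary.hmes_map"
  s
}

#' @export
print.summary.hmes_map <- function(x, ...) {
  cat("Stage counts:\n")
  print(unlist(x$stage_counts))
  if (!is.null(x$hmes_summary)) {
    cat("\nFragment HMES distribution:\n")
    print(x$hmes_summary)
  }
  cat(sprintf("\n%d candidate variant(s)\n", nrow(x$candidates)))
  invisible(x)
}

#' Write the candidate report
#'
#' Tab-delimited text, UTF-8, LF line endings: a header row then one line
#' per candidate with the 12 columns HMES, allele frequency, contig length,
#' contig id, position in contig, reference base, coverage, read bases,
#' base qualities, left flanking sequence, variant allele, right flanking
#' sequence. Floating-point fields are rendered with 4 decimal places.
#'
#' @param records Candidate data frame (the `candidates` component of an
#'   [hmes_map()] fit), already sorted by the caller.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_candidates <- function(records, path) {
  df <- records[, candidate_columns, drop = FALSE]
  df$hmes <- sprintf("%.4f", df$hmes)
  df$allele_frequency <- sprintf("%.4f", df$allele_frequency)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(candidate_columns, collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    lines <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a candidate report written by [write_candidates()]
#'
#' @param path Path to the report.
#' @return Data frame with the 12 report columns, numeric fields parsed.
#' @export
read_candidates <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!identical(names(df), candidate_columns)) {
    stop("not a candidate report: unexpected column set in ", path)
  }
  df$hmes <- as.numeric(df$hmes)
  df$allele_frequency <- as.numeric(df$allele_frequency)
  df$contig_length <- as.integer(df$contig_length)
  df$position_in_contig <- as.integer(df$position_in_contig)
  df$coverage <- as.integer(df$coverage)
  for (col in c("left_flank", "right_flank", "read_bases", "base_qualities")) {
    df[[col]][is.na(df[[col]])] <- ""
  }
  df
}
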