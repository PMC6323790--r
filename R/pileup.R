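#' Read samtools mpileup text
#'
#' Parses the 6-column single-sample mpileup format produced by
#' `samtools mpileup` (contig, 1-based position, reference base, coverage,
#' read bases, base qualities). Mapping-quality columns are not expected;
#' mapping-quality filtering is assumed applied upstream.
#'
#' @param path Path to an mpileup text file, or a character vector of
#'   mpileup lines when `text = TRUE`.
#' @param text Logical; if `TRUE`, `path` is treated as the lines themselves.
#' @return A data frame with columns `contig`, `pos`, `ref`, `coverage`,
#'   `bases`, `quals`, one row per pileup record.
#' @examples
#' read_pileup("c1\t100\tA\t4\t..,,\tIIII", text = TRUE)
#' @export
read_pileup <- function(path, text = FALSE) {
  lines <- if (text) path else readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      coverage = integer(), bases = character(),
                      quals = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 6L)
  if (length(bad)) {
    stop(sprintf("mpileup format error: line %d has %d columns (expected 6)",
                 bad[1L], nf[bad[1L]]))
  }
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  cov <- suppressWarnings(as.integer(m[, 4L]))
  bad <- which(is.na(pos) | is.na(cov) | pos < 1L | cov < 0L)
  if (length(bad)) {
    stop(sprintf("mpileup format error: line %d has non-numeric or out-of-range position/coverage",
                 bad[1L]))
  }
  data.frame(contig = m[, 1L], pos = pos, ref = m[, 3L], coverage = cov,
             bases = m[, 5L], quals = m[, 6L], stringsAsFactors = FALSE)
}

#' Count alleles in one mpileup base column
#'
#' Walks the mpileup read-base grammar: `.`/`,` match the reference;
#' `ACGTacgt` are substitutions; `^X` marks a read start (the following
#' mapping-quality character is skipped and consumes no base quality);
#' `$` marks a read end; `+n<seq>`/`-n<seq>` record an indel attached to the
#' preceding base (keyed as `+SEQ`/`-SEQ`, no quality consumed); `*` is a
#' deletion placeholder and `<`/`>` are reference skips, all carrying no
#' allele evidence. Each scored base consumes exactly one character of the
#' quality string; only bases with Phred quality at or above
#' `min_base_quality` are counted.
#'
#' `filtered_depth` is the number of quality-passing base calls (reference
#' matches plus substitutions), so it never exceeds the raw coverage. Indel
#' alleles are recorded in `alt_counts` in addition to their anchor base and
#' are gated by the anchor base's quality.
#'
#' @param bases The mpileup read-base column for one site.
#' @param quals The matching base-quality string (Phred+33).
#' @param ref Reference base at the site (single character).
#' @param min_base_quality Minimum Phred base quality to count a base
#'   (default 15, matching a typical `samtools mpileup -Q 15` run).
#' @return A list with `ref_count`, `alt_counts` (named integer vector, may
#'   be empty), and `filtered_depth`.
#' @examples
#' count_bases(",.TT,t", "IIIIII", ref = "A")
#' count_bases(".+2AT.", "II", ref = "A")
#' @export
count_bases <- function(bases, quals, ref, min_base_quality = 15L) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1L]]
  qv <- utf8ToInt(quals) - 33L
  n <- length(ch)
  ref_count <- 0L
  alt <- integer(0)
  i <- 1L
  qi <- 1L
  bump <- function(key) {
    if (is.na(match(key, names(alt)))) alt[key] <<- 1L else alt[key] <<- alt[key] + 1L
  }
  take_qual <- function() {
    if (qi > length(qv)) {
      stop("mpileup format error: quality string shorter than scored bases")
    }
    q <- qv[qi]
    qi <<- qi + 1L
    q
  }
  last_scored <- NA  # whether the most recent scored base passed the filter
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "^") {
      i <- i + 2L                     # caret + mapping-quality char, no quality
    } else if (c0 == "$") {
      i <- i + 1L
    } else if (c0 == "+" || c0 == "-") {
      j <- i + 1L
      while (j <= n && ch[j] >= "0" && ch[j] <= "9") j <- j + 1L
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      seq <- toupper(paste(ch[j:(j + len - 1L)], collapse = ""))
      if (isTRUE(last_scored)) bump(paste0(c0, seq))
      i <- j + len
    } else if (c0 == "." || c0 == ",") {
      ok <- take_qual() >= min_base_quality
      if (ok) ref_count <- ref_count + 1L
      last_scored <- ok
      i <- i + 1L
    } else if (c0 %in% c("A", "C", "G", "T", "a", "c", "g", "t")) {
      ok <- take_qual() >= min_base_quality
      if (ok) bump(toupper(c0))
      last_scored <- ok
      i <- i + 1L
    } else if (c0 %in% c("N", "n", "*", "<", ">")) {
      # consumes a quality slot but carries no allele evidence
      if (c0 %in% c("<", ">")) {
        last_scored <- FALSE
      } else {
        invisible(take_qual())
        last_scored <- FALSE
      }
      i <- i + 1L
    } else {
      stop(sprintf("mpileup format error: unexpected character '%s' in base column", c0))
    }
  }
  snv <- if (length(alt)) {
    alt[!startsWith(names(alt), "+") & !startsWith(names(alt), "-")]
  } else integer(0)
  list(ref_count = ref_count,
       alt_counts = alt,
       filtered_depth = ref_count + sum(snv))
}

#' Tabulate allele counts across a pileup data frame
#'
#' Applies [count_bases()] to every record and keeps, per site, the
#' reference count and the single most-supported alternative allele
#' (ties broken alphabetically). Sites with no alternative evidence get
#' `alt = NA` and `alt_count = 0`.
#'
#' @param pileup Data frame from [read_pileup()].
#' @param min_base_quality Minimum Phred base quality (see [count_bases()]).
#' @return Data frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count`, `depth` (filtered depth), plus the raw
#'   `coverage`, `bases`, `quals` columns carried through for reporting.
#' @export
pileup_counts <- function(pileup, min_base_quality = 15L) {
  n <- nrow(pileup)
  alt <- character(n); altc <- integer(n); refc <- integer(n); dep <- integer(n)
  for (k in seq_len(n)) {
    cb <- count_bases(pileup$bases[k], pileup$quals[k], pileup$ref[k],
                      min_base_quality)
    refc[k] <- cb$ref_count
    dep[k] <- cb$filtered_depth
    if (length(cb$alt_counts)) {
      ord <- order(-cb$alt_counts, names(cb$alt_counts))
      alt[k] <- names(cb$alt_counts)[ord[1L]]
      altc[k] <- cb$alt_counts[[ord[1L]]]
    } else {
      alt[k] <- NA_character_
      altc[k] <- 0L
    }
  }
  data.frame(contig = pileup$contig, pos = pileup$pos, ref = pileup$ref,
             alt = alt, ref_count = refc, alt_count = altc, depth = dep,
             coverage = pileup$coverage, bases = pileup$bases,
             quals = pileup$quals, stringsAsFactors = FALSE)
}

#' Write per-site allele counts as mpileup text
#'
#' Serializes a counts table (as produced by [pileup_counts()] or the bulk
#' simulator) into 6-column mpileup lines: reference reads as `.`, reads
#' carrying the alternative allele as the allele base, all base qualities
#' `I` (Phred 40).
#'
#' @param counts Data frame with `contig`, `pos`, `ref`, `alt`, `ref_count`,
#'   `alt_count`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_mpileup <- function(counts, path) {
  depth <- counts$ref_count + counts$alt_count
  alt <- ifelse(is.na(counts$alt), "", counts$alt)
  bases <- paste0(strrep(".", counts$ref_count),
                  strrep(alt, counts$alt_count))
  quals <- strrep("I", depth)
  bases[depth == 0L] <- "*"
  quals[depth == 0L] <- "!"
  lines <- paste(counts$contig, counts$pos, counts$ref,
                 pmax(depth, 0L), bases, quals, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
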