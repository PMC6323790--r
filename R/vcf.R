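#' Read variant evidence from a VCF file
#'
#' Loads a VCF 4.x file (plain or bgzipped) and expands every record into
#' one row per alternative allele. Per-allele depths are taken, in order of
#' preference, from the first sample's `AD` genotype field, then from an
#' `DP4` INFO field (ref = fwd+rev reference reads, alt = fwd+rev variant
#' reads, attributed to the first alternative allele), then reconstructed
#' from `INFO/DP` with `INFO/AF`. Rows with no usable depth evidence are
#' flagged `freq_unknown` and carry zero counts.
#'
#' @param path Path to the VCF file.
#' @return Data frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count`, `depth`, `freq_unknown`.
#' @export
read_vcf_variants <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  nrec <- nrow(fix)
  if (nrec == 0L) {
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), ref_count = integer(),
                      alt_count = integer(), depth = integer(),
                      freq_unknown = logical(), stringsAsFactors = FALSE))
  }
  alts <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",", fixed = TRUE)
  ad <- rep(NA_character_, nrec)
  if (ncol(v@gt) >= 2L) {
    adm <- try(vcfR::extract.gt(v, element = "AD"), silent = TRUE)
    if (!inherits(adm, "try-error") && !is.null(adm)) ad <- adm[, 1L]
  }
  info <- fix[, "INFO"]
  info_field <- function(info, key) {
    info <- ifelse(is.na(info), "", info)
    has <- grepl(paste0("(^|;)", key, "="), info)
    out <- rep(NA_character_, length(info))
    out[has] <- sub(paste0(".*(^|;)", key, "=([^;]*).*"), "\\2", info[has])
    out
  }
  dp4 <- info_field(info, "DP4")
  dp <- suppressWarnings(as.numeric(info_field(info, "DP")))
  af <- info_field(info, "AF")

  rows <- vector("list", nrec)
  for (i in seq_len(nrec)) {
    aa <- alts[[i]]
    aa <- aa[nzchar(aa) & aa != "."]
    if (length(aa) == 0L) next
    pos <- as.integer(fix[i, "POS"])
    refb <- fix[i, "REF"]
    nall <- length(aa)
    rc <- rep(NA_integer_, nall); ac <- rep(NA_integer_, nall)
    if (!is.na(ad[i])) {
      adv <- suppressWarnings(as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1L]]))
      if (length(adv) >= nall + 1L && !anyNA(adv[seq_len(nall + 1L)])) {
        rc <- rep(adv[1L], nall)
        ac <- adv[1L + seq_len(nall)]
      }
    }
    if (anyNA(ac) && !is.na(dp4[i])) {
      d4 <- suppressWarnings(as.integer(strsplit(dp4[i], ",", fixed = TRUE)[[1L]]))
      if (length(d4) == 4L && !anyNA(d4)) {
        rc <- rep(d4[1L] + d4[2L], nall)
        ac <- rep(NA_integer_, nall)
        ac[1L] <- d4[3L] + d4[4L]
      }
    }
    if (anyNA(ac) && !is.na(dp[i]) && !is.na(af[i])) {
      afv <- suppressWarnings(as.numeric(strsplit(af[i], ",", fixed = TRUE)[[1L]]))
      if (length(afv) >= nall && !anyNA(afv[seq_len(nall)])) {
        miss <- is.na(ac)
        ac[miss] <- as.integer(round(dp[i] * afv[seq_len(nall)][miss]))
        rc[miss] <- as.integer(round(dp[i])) - ac[miss]
      }
    }
    unk <- is.na(ac)
    rc[unk] <- 0L; ac[unk] <- 0L
    rows[[i]] <- data.frame(contig = unname(fix[i, "CHROM"]), pos = pos,
                            ref = unname(refb), alt = aa, ref_count = rc,
                            alt_count = ac, depth = rc + ac,
                            freq_unknown = unk, row.names = NULL,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), ref_count = integer(),
                      alt_count = integer(), depth = integer(),
                      freq_unknown = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write a minimal single-sample VCF
#'
#' Serializes a counts table as VCF 4.2 with an `AD` genotype field, the
#' inverse of [read_vcf_variants()] for round-tripping synthetic evidence.
#'
#' @param counts Data frame with `contig`, `pos`, `ref`, `alt`, `ref_count`,
#'   `alt_count`.
#' @param path Output path.
#' @param sample Sample name in the header.
#' @return Invisibly, the path.
#' @export
write_vcf <- function(counts, path, sample = "bulk") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", sample, sep = "\t"))
  body <- paste(counts$contig, counts$pos, ".", counts$ref, counts$alt, ".",
                "PASS", ".", "GT:AD",
                paste0("./.:", counts$ref_count, ",", counts$alt_count),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
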