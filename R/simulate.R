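#' Arabidopsis-like default chromosome lengths (bp)
#'
#' Five chromosomes totalling about 119 Mb, the scale at which the
#' fragmentation and cross simulations operate by default.
#'
#' @return Named numeric vector of chromosome lengths.
#' @export
default_chrom_lengths <- function() {
  c(chr1 = 30.4e6, chr2 = 19.7e6, chr3 = 23.5e6, chr4 = 18.6e6, chr5 = 27.0e6)
}

#' Fragment a genome with log-normally distributed piece lengths
#'
#' Draws fragment lengths from exp(Normal(log_mean, log_sd)), rounds them to
#' integers, floors them at `min_fragment_bp`, and lays them down
#' left-to-right per chromosome; the final fragment of each chromosome is
#' truncated at the chromosome end, so fragments tile each chromosome
#' exactly. The default parameters (log-length mean 7.88, spread 1.56,
#' floor 300 bp) emulate a short-read de novo assembly of an
#' Arabidopsis-sized genome: mean fragment about exp(7.88 + 1.56^2/2) ~
#' 8.9 kb, while the fragment containing a fixed locus is size-biased with
#' median about exp(7.88 + 1.56^2) ~ 30 kb.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param log_mean Mean of natural-log fragment lengths (default 7.88).
#' @param log_sd Standard deviation of natural-log lengths (default 1.56).
#' @param min_fragment_bp Minimum fragment length (default 300).
#' @param seed Integer seed; the fragmentation is deterministic given it.
#' @return An object of class `sim_assembly`: a data frame with columns
#'   `chrom`, `start`, `end` (1-based inclusive), `fragment_id`, `length`.
#' @export
fragment_genome <- function(chrom_lengths, log_mean = 7.88, log_sd = 1.56,
                            min_fragment_bp = 300L, seed = NULL) {
  stopifnot(all(chrom_lengths > 0), log_sd > 0, min_fragment_bp >= 1)
  if (!is.null(seed)) set.seed(seed)
  per_chrom <- lapply(names(chrom_lengths), function(ch) {
    L <- as.numeric(chrom_lengths[[ch]])
    starts <- numeric(0)
    ends <- numeric(0)
    at <- 1
    # draw in chunks until the chromosome is covered
    expect <- ceiling(L / exp(log_mean + log_sd^2 / 2)) + 10L
    while (at <= L) {
      lens <- pmax(round(exp(stats::rnorm(expect, log_mean, log_sd))),
                   min_fragment_bp)
      cum <- at + cumsum(lens) - 1
      keep <- which(cum - lens + 1 <= L)
      if (length(keep)) {
        starts <- c(starts, (cum - lens + 1)[keep])
        ends <- c(ends, pmin(cum[keep], L))
        at <- ends[length(ends)] + 1
      }
    }
    data.frame(chrom = ch, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  frags <- do.call(rbind, per_chrom)
  frags$fragment_id <- sprintf("frag%05d", seq_len(nrow(frags)))
  frags$length <- as.integer(frags$end - frags$start + 1)
  class(frags) <- c("sim_assembly", "data.frame")
  frags
}

#' Locate the fragment containing a genomic position
#'
#' @param assembly A `sim_assembly` from [fragment_genome()].
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @return The matching assembly row (one-row data frame).
#' @export
fragment_at <- function(assembly, chrom, pos) {
  hit <- assembly$chrom == chrom & assembly$start <= pos & assembly$end >= pos
  if (!any(hit)) stop(sprintf("position %s:%d outside the assembly", chrom, pos))
  assembly[which(hit)[1L], , drop = FALSE]
}

#' Assign genome-coordinate variants to assembly fragments
#'
#' Each variant lands in exactly the fragment whose interval contains it;
#' positions are re-expressed in 1-based fragment coordinates.
#'
#' @param assembly A `sim_assembly`.
#' @param variants Data frame with `chrom` and `pos` (genome coordinates).
#' @return `variants` with `fragment_id` and `fragment_pos` columns added.
#' @export
assign_variants <- function(assembly, variants) {
  n <- nrow(variants)
  frag_id <- character(n)
  frag_pos <- integer(n)
  for (ch in unique(variants$chrom)) {
    rows <- which(variants$chrom == ch)
    fr <- assembly[assembly$chrom == ch, , drop = FALSE]
    if (nrow(fr) == 0L) stop("variant chromosome absent from assembly: ", ch)
    idx <- findInterval(variants$pos[rows], fr$start)
    bad <- idx < 1L | variants$pos[rows] > fr$end[pmax(idx, 1L)]
    if (any(bad)) {
      stop(sprintf("variant at %s:%d outside all fragments", ch,
                   variants$pos[rows][which(bad)[1L]]))
    }
    frag_id[rows] <- fr$fragment_id[idx]
    frag_pos[rows] <- as.integer(variants$pos[rows] - fr$start[idx] + 1)
  }
  variants$fragment_id <- frag_id
  variants$fragment_pos <- frag_pos
  variants
}

#' Describe a bulk-segregant cross design
#'
#' Parameters of the generative model behind [simulate_bulks()]. In an
#' outcross, the mutagenized line (carrying induced mutations) is crossed to
#' a polymorphic accession and F2 individuals are pooled by phenotype; the
#' accession supplies dense natural SNP markers. In a backcross, the F1 is
#' crossed back to the mutant parent, so only the sparse induced mutations
#' segregate. Variant evidence is expressed against a reference matching
#' the non-mutant (accession) haplotype, so the mutant-parent allele is the
#' alternative allele at every marker.
#'
#' @param cross_type `"outcross"` or `"backcross"`.
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param causative_chrom,causative_pos The planted recessive causative
#'   locus (defaults: chr4:6852405, within the default genome).
#' @param recomb_rate Recombination rate in cM/Mb (default 4,
#'   Arabidopsis-like; crossovers per gamete follow a no-interference
#'   Haldane model).
#' @param n_mutant_pool,n_background_pool Individuals per pool (default 80).
#' @param coverage Mean sequencing depth per site (Poisson; default 20).
#' @param induced_density Induced-mutation density per Mb (default 10).
#' @param snp_density Accession-SNP density per Mb (default 500 for an
#'   outcross; forced to 0 for a backcross, where parents share a
#'   background).
#' @param seed Integer seed governing every stochastic draw.
#' @return An object of class `cross_design`.
#' @export
cross_design <- function(cross_type = c("outcross", "backcross"),
                         chrom_lengths = default_chrom_lengths(),
                         causative_chrom = "chr4", causative_pos = 6852405L,
                         recomb_rate = 4, n_mutant_pool = 80L,
                         n_background_pool = 80L, coverage = 20,
                         induced_density = 10, snp_density = 500,
                         seed = 1L) {
  cross_type <- match.arg(cross_type)
  if (cross_type == "backcross") snp_density <- 0
  if (!causative_chrom %in% names(chrom_lengths)) {
    stop("causative chromosome not in chrom_lengths")
  }
  if (causative_pos < 1 || causative_pos > chrom_lengths[[causative_chrom]]) {
    stop("causative position outside its chromosome")
  }
  stopifnot(recomb_rate > 0, n_mutant_pool >= 1, n_background_pool >= 1,
            coverage > 0, induced_density > 0, snp_density >= 0)
  structure(list(cross_type = cross_type, chrom_lengths = chrom_lengths,
                 causative_chrom = causative_chrom,
                 causative_pos = as.integer(causative_pos),
                 recomb_rate = recomb_rate,
                 n_mutant_pool = as.integer(n_mutant_pool),
                 n_background_pool = as.integer(n_background_pool),
                 coverage = coverage, induced_density = induced_density,
                 snp_density = snp_density, seed = as.integer(seed)),
            class = "cross_design")
}

# Uniformly placed markers at a per-Mb density (Poisson count per chromosome).
place_markers <- function(chrom_lengths, density_per_Mb) {
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- as.numeric(chrom_lengths[[ch]])
    k <- stats::rpois(1L, density_per_Mb * L / 1e6)
    if (k == 0L) return(NULL)
    data.frame(chrom = ch, pos = sort(sample.int(as.integer(L), k)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# One recombinant gamete from a heterozygous F1: per chromosome, a crossover
# mosaic of the two parental haplotypes (Haldane: Poisson crossover count,
# uniform breakpoints). Returned as list(chrom -> list(start_origin, bps));
# origin 1 = mutant-parent haplotype, 0 = accession haplotype.
sim_gamete <- function(chrom_lengths, morgans_per_bp) {
  lapply(chrom_lengths, function(L) {
    k <- stats::rpois(1L, morgans_per_bp * L)
    list(start = sample(0:1, 1L),
         bps = if (k > 0L) sort(stats::runif(k, 1, L)) else numeric(0))
  })
}

# Haplotype origin of a gamete at given positions on one chromosome.
gamete_origin <- function(gamete_chrom, pos) {
  (gamete_chrom$start + findInterval(pos, gamete_chrom$bps)) %% 2L
}

#' Simulate pooled bulk-segregant sequencing evidence
#'
#' Generates marker maps, simulates F2 (outcross) or BC1 (backcross)
#' individuals as crossover mosaics, selects them into a mutant pool
#' (homozygous mutant at the causative locus) and a background pool
#' (phenotypically wild type, i.e. everything else), pools gametes, and
#' samples reads per site: depth ~ Poisson(coverage), alternative reads ~
#' Binomial(depth, pooled allele frequency). The causative mutation itself
#' is always included as a marker, so the mutant-pool truth allele
#' frequency at the locus is exactly 1.
#'
#' @param design A [cross_design()].
#' @return A list with `markers` (chrom, pos, type, ref, alt), `truth`
#'   (per-marker true pooled allele frequencies `af_mut`, `af_bg`),
#'   `mut_counts` and `bg_counts` (counts data frames in genome
#'   coordinates, `contig` = chromosome), and the `design`.
#' @export
simulate_bulks <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  set.seed(design$seed)
  cl <- design$chrom_lengths

  induced <- place_markers(cl, design$induced_density)
  induced$type <- "induced"
  markers <- induced
  if (design$snp_density > 0) {
    snps <- place_markers(cl, design$snp_density)
    snps$type <- "accession_snp"
    markers <- rbind(markers, snps)
  }
  # plant the causative mutation itself
  markers <- markers[!(markers$chrom == design$causative_chrom &
                         markers$pos == design$causative_pos), , drop = FALSE]
  markers <- rbind(markers,
                   data.frame(chrom = design$causative_chrom,
                              pos = design$causative_pos, type = "causative",
                              stringsAsFactors = FALSE))
  markers <- markers[order(match(markers$chrom, names(cl)), markers$pos), ,
                     drop = FALSE]
  markers <- markers[!duplicated(paste(markers$chrom, markers$pos)), ,
                     drop = FALSE]
  rownames(markers) <- NULL
  nm <- nrow(markers)
  bases <- c("A", "C", "G", "T")
  markers$ref <- sample(bases, nm, replace = TRUE)
  markers$alt <- vapply(markers$ref,
                        function(r) sample(setdiff(bases, r), 1L), "")

  morgans_per_bp <- design$recomb_rate / 100 / 1e6
  marker_rows <- split(seq_len(nm), markers$chrom)

  # alt-allele dosage of one gamete across all markers
  gamete_dosage <- function(g) {
    d <- integer(nm)
    for (ch in names(marker_rows)) {
      rows <- marker_rows[[ch]]
      d[rows] <- gamete_origin(g[[ch]], markers$pos[rows])
    }
    d
  }

  n_mut <- design$n_mutant_pool
  n_bg <- design$n_background_pool
  mut_sum <- integer(nm); bg_sum <- integer(nm)
  got_mut <- 0L; got_bg <- 0L
  max_tries <- 1000L * (n_mut + n_bg)
  tries <- 0L
  backcross <- design$cross_type == "backcross"
  while ((got_mut < n_mut || got_bg < n_bg) && tries < max_tries) {
    tries <- tries + 1L
    g1 <- sim_gamete(cl, morgans_per_bp)
    loc1 <- gamete_origin(g1[[design$causative_chrom]], design$causative_pos)
    if (backcross) {
      loc2 <- 1L  # gamete from the recurrent mutant parent
    } else {
      g2 <- sim_gamete(cl, morgans_per_bp)
      loc2 <- gamete_origin(g2[[design$causative_chrom]], design$causative_pos)
    }
    is_mutant <- (loc1 + loc2) == 2L
    if (is_mutant && got_mut >= n_mut) next
    if (!is_mutant && got_bg >= n_bg) next
    d <- gamete_dosage(g1)
    d <- d + if (backcross) 1L else gamete_dosage(g2)
    if (is_mutant) {
      mut_sum <- mut_sum + d
      got_mut <- got_mut + 1L
    } else {
      bg_sum <- bg_sum + d
      got_bg <- got_bg + 1L
    }
  }
  if (got_mut < n_mut || got_bg < n_bg) {
    stop("could not fill the pools; check the design parameters")
  }

  truth <- data.frame(chrom = markers$chrom, pos = markers$pos,
                      type = markers$type,
                      af_mut = mut_sum / (2 * n_mut),
                      af_bg = bg_sum / (2 * n_bg),
                      stringsAsFactors = FALSE)

  sample_reads <- function(af) {
    depth <- stats::rpois(nm, design$coverage)
    alt <- stats::rbinom(nm, depth, af)
    data.frame(contig = markers$chrom, pos = markers$pos, ref = markers$ref,
               alt = markers$alt, ref_count = depth - alt, alt_count = alt,
               depth = depth, stringsAsFactors = FALSE)
  }
  list(markers = markers, truth = truth,
       mut_counts = sample_reads(truth$af_mut),
       bg_counts = sample_reads(truth$af_bg),
       design = design)
}

#' Exact pooled allele frequencies from the cross model
#'
#' Enumerates the genotype classes segregating at the causative locus for a
#' recessive allele (F2 selfed-F1 classes for an outcross: 1/4 mm, 1/2 Mm,
#' 1/4 MM; BC1 classes for a backcross: 1/2 mm, 1/2 Mm), conditions on the
#' pool's phenotype selection (mutant pool: mutant homozygotes; background
#' pool: everything else), and returns the expected pooled mutant-allele
#' frequency. The infinite-pool outcross values are 1 (mutant pool) and
#' 1/3 (background pool, a 2:1 heterozygote:wild-type mixture).
#'
#' @param cross_type `"outcross"` or `"backcross"`.
#' @param pool `"mutant"` or `"background"`.
#' @return The expected pooled mutant-allele frequency.
#' @examples
#' expected_pool_af("outcross", "mutant")      # 1
#' expected_pool_af("outcross", "background")  # 1/3
#' @export
expected_pool_af <- function(cross_type = c("outcross", "backcross"),
                             pool = c("mutant", "background")) {
  cross_type <- match.arg(cross_type)
  pool <- match.arg(pool)
  # genotype classes as (mutant-allele dosage, probability)
  classes <- if (cross_type == "outcross") {
    data.frame(dosage = c(2, 1, 0), prob = c(1 / 4, 1 / 2, 1 / 4))
  } else {
    data.frame(dosage = c(2, 1), prob = c(1 / 2, 1 / 2))
  }
  keep <- if (pool == "mutant") classes$dosage == 2 else classes$dosage < 2
  cls <- classes[keep, , drop = FALSE]
  w <- cls$prob / sum(cls$prob)
  sum(w * cls$dosage) / 2
}

#' Causative-fragment statistics over repeated fragmentations
#'
#' Repeats the fragmentation of a genome, assigns a fixed set of classified
#' variants to the fragments of each replicate, scores every fragment, and
#' records for the fragment containing the causative locus: its HMES, its
#' rank among fragments with HMES > 1 expressed as a percentage, and its
#' length. Substreams are derived deterministically from `seed`.
#'
#' @param n_iterations Number of fragmentations (>= 1).
#' @param chrom_lengths Named chromosome lengths.
#' @param variants Data frame with `chrom`, `pos`, `zygosity` (genome
#'   coordinates), e.g. derived from [simulate_bulks()] output.
#' @param causative_chrom,causative_pos The causative locus.
#' @param rho HMES ratio adjustment (default 0.5).
#' @param log_mean,log_sd,min_fragment_bp Fragmentation parameters (see
#'   [fragment_genome()]).
#' @param seed Base seed.
#' @return A list with `per_iteration` (data frame: iteration, hmes,
#'   rank_percent, length) and `summary` (means and medians).
#' @export
causative_fragment_stats <- function(n_iterations, chrom_lengths, variants,
                                     causative_chrom, causative_pos,
                                     rho = 0.5, log_mean = 7.88,
                                     log_sd = 1.56, min_fragment_bp = 300L,
                                     seed = 1L) {
  stopifnot(n_iterations >= 1)
  res <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    asm <- fragment_genome(chrom_lengths, log_mean, log_sd, min_fragment_bp,
                           seed = (seed + i - 1L) %% .Machine$integer.max)
    target <- fragment_at(asm, causative_chrom, causative_pos)
    hmes_i <- NA_real_; rank_pct <- NA_real_
    if (nrow(variants)) {
      av <- assign_variants(asm, variants)
      sc <- score_fragments(
        data.frame(contig = av$fragment_id, zygosity = av$zygosity,
                   stringsAsFactors = FALSE),
        stats::setNames(asm$length, asm$fragment_id), rho)
      row <- sc[sc$contig == target$fragment_id, , drop = FALSE]
      hmes_i <- if (nrow(row)) row$hmes else compute_hmes(0L, 0L, rho)
      enr <- filter_enriched(sc)
      if (nrow(enr) && hmes_i > 1) {
        rank_pct <- 100 * sum(enr$hmes >= hmes_i) / nrow(enr)
      }
    }
    res[[i]] <- data.frame(iteration = i, hmes = hmes_i,
                           rank_percent = rank_pct, length = target$length)
  }
  per <- do.call(rbind, res)
  rownames(per) <- NULL
  list(per_iteration = per,
       summary = list(
         mean_hmes = mean(per$hmes, na.rm = TRUE),
         median_hmes = stats::median(per$hmes, na.rm = TRUE),
         mean_rank_percent = mean(per$rank_percent, na.rm = TRUE),
         median_rank_percent = stats::median(per$rank_percent, na.rm = TRUE),
         mean_length = mean(per$length),
         median_length = stats::median(per$length)))
}

#' Convert genome-coordinate evidence to fragment coordinates
#'
#' Re-keys a counts data frame (contig = chromosome) onto the fragments of
#' a simulated assembly, so [hmes_map()] can consume simulator output.
#'
#' @param assembly A `sim_assembly`.
#' @param counts Counts data frame in genome coordinates.
#' @return Counts data frame with `contig` = fragment id and `pos` in
#'   fragment coordinates.
#' @export
counts_to_fragments <- function(assembly, counts) {
  av <- assign_variants(assembly,
                        data.frame(chrom = counts$contig, pos = counts$pos))
  counts$contig <- av$fragment_id
  counts$pos <- av$fragment_pos
  counts
}
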