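# Independent oracles used across the suite.

# Character-by-character mpileup base counter, written as a direct
# transcription of the format grammar and kept independent of count_bases().
oracle_count_bases <- function(bases, quals, min_bq = 15L) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1L]]
  q <- utf8ToInt(quals) - 33L
  ref <- 0L
  alts <- list()
  i <- 1L; qi <- 0L
  prev_pass <- FALSE
  while (i <= length(ch)) {
    c0 <- ch[i]
    if (c0 == "^") { i <- i + 2L; next }
    if (c0 == "$") { i <- i + 1L; next }
    if (c0 %in% c("+", "-")) {
      num <- ""
      j <- i + 1L
      while (grepl("[0-9]", ch[j])) { num <- paste0(num, ch[j]); j <- j + 1L }
      len <- as.integer(num)
      key <- paste0(c0, toupper(paste(ch[j:(j + len - 1L)], collapse = "")))
      if (prev_pass) alts[[key]] <- (alts[[key]] %||% 0L) + 1L
      i <- j + len
      next
    }
    if (c0 %in% c("<", ">")) { prev_pass <- FALSE; i <- i + 1L; next }
    qi <- qi + 1L
    pass <- q[qi] >= min_bq
    if (c0 %in% c(".", ",")) {
      if (pass) ref <- ref + 1L
      prev_pass <- pass
    } else if (toupper(c0) %in% c("A", "C", "G", "T")) {
      if (pass) {
        key <- toupper(c0)
        alts[[key]] <- (alts[[key]] %||% 0L) + 1L
      }
      prev_pass <- pass
    } else {
      prev_pass <- FALSE  # N / *
    }
    i <- i + 1L
  }
  list(ref_count = ref, alt_counts = unlist(alts),
       quals_consumed = qi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random grammar-valid mpileup base string with matching quality string.
random_pileup_string <- function(n_reads) {
  toks <- character(0)
  nq <- 0L
  for (k in seq_len(n_reads)) {
    t <- sample(c("ref", "alt", "N", "star"), 1L,
                prob = c(0.6, 0.25, 0.05, 0.1))
    base <- switch(t,
                   ref = sample(c(".", ","), 1L),
                   alt = sample(c("A", "C", "G", "T", "a", "c", "g", "t"), 1L),
                   N = sample(c("N", "n"), 1L),
                   star = "*")
    if (stats::runif(1) < 0.1) base <- paste0("^", intToUtf8(33L + sample(0:40, 1L)), base)
    if (stats::runif(1) < 0.1 && t %in% c("ref", "alt")) {
      len <- sample(1:3, 1L)
      ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      base <- paste0(base, sample(c("+", "-"), 1L), len, ins)
    }
    if (stats::runif(1) < 0.1) base <- paste0(base, "$")
    toks <- c(toks, base)
    nq <- nq + 1L
  }
  list(bases = paste(toks, collapse = ""),
       quals = intToUtf8(33L + sample(0:40, nq, replace = TRUE)))
}

# Brute-force centre-out arrangement: walk the descending sort, sending
# even ranks to the left flank and odd ranks (after the first) to the right.
oracle_center_out <- function(hmes) {
  ord <- order(-hmes)
  left <- integer(0); right <- integer(0)
  for (r in seq_along(ord)[-1L]) {
    if (r %% 2L == 0L) left <- c(ord[r], left) else right <- c(right, ord[r])
  }
  c(left, ord[1L], right)
}

# All permutations of 1:n as rows.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# Small synthetic mapping dataset shared by pipeline tests: two-chromosome
# outcross with a compressed map so linkage decays inside the genome.
tiny_outcross <- function(seed, coverage = 30) {
  design <- cross_design(
    cross_type = "outcross",
    chrom_lengths = c(cA = 4e6, cB = 3e6),
    causative_chrom = "cA", causative_pos = 1.5e6,
    recomb_rate = 25, n_mutant_pool = 40L, n_background_pool = 40L,
    coverage = coverage, induced_density = 20, snp_density = 150,
    seed = seed)
  sim <- simulate_bulks(design)
  asm <- fragment_genome(design$chrom_lengths, seed = seed + 5000L)
  list(design = design, sim = sim, asm = asm,
       mut = counts_to_fragments(asm, sim$mut_counts),
       bg = counts_to_fragments(asm, sim$bg_counts),
       lengths = stats::setNames(asm$length, asm$fragment_id))
}
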