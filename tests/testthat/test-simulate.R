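test_that("fragmentation tiles every chromosome exactly, for many seeds", {
  cl <- c(c1 = 3e6, c2 = 1.5e6)
  for (s in 1:100) {
    asm <- fragment_genome(cl, seed = s)
    for (ch in names(cl)) {
      fr <- asm[asm$chrom == ch, ]
      expect_equal(fr$start[1L], 1)
      expect_equal(fr$end[nrow(fr)], cl[[ch]])
      expect_true(all(fr$start[-1L] == fr$end[-nrow(fr)] + 1))
      expect_equal(sum(fr$length), cl[[ch]])
    }
    expect_true(all(asm$length >= 1L))
  }
  # deterministic given the seed
  expect_equal(fragment_genome(cl, seed = 3L), fragment_genome(cl, seed = 3L))
})

test_that("fragment lengths follow the log-normal closed forms", {
  # unbiased mean over many draws ~ exp(mu + sigma^2/2); use a long genome so
  # truncation and the 300 bp floor are negligible
  asm <- fragment_genome(c(c1 = 9e8), log_mean = 7.88, log_sd = 1.56,
                         seed = 10L)
  expect_equal(mean(asm$length), exp(7.88 + 1.56^2 / 2), tolerance = 0.05)
})

test_that("variants land in exactly the fragment containing them", {
  cl <- c(c1 = 1e5, c2 = 5e4)
  asm <- fragment_genome(cl, log_mean = 8.5, log_sd = 0.7, seed = 4L)
  set.seed(5)
  v <- data.frame(chrom = sample(names(cl), 200L, replace = TRUE))
  v$pos <- ifelse(v$chrom == "c1", sample.int(1e5, 200L, replace = TRUE),
                  sample.int(5e4, 200L, replace = TRUE))
  # include both chromosome boundaries and a fragment start
  v <- rbind(v, data.frame(chrom = c("c1", "c1", "c2"),
                           pos = c(1L, 1e5, asm$start[asm$chrom == "c2"][2L])))
  av <- assign_variants(asm, v)
  expect_equal(nrow(av), nrow(v))                     # conservation
  m <- match(av$fragment_id, asm$fragment_id)
  expect_true(all(asm$chrom[m] == av$chrom))
  expect_true(all(asm$start[m] <= av$pos & av$pos <= asm$end[m]))
  expect_equal(av$fragment_pos, as.integer(av$pos - asm$start[m] + 1))
  expect_equal(av$fragment_pos[nrow(av)], 1L)         # fragment first base
  expect_error(assign_variants(asm, data.frame(chrom = "c1", pos = 2e5)),
               "outside")
})

test_that("bulk simulation honours the cross model at the causative locus", {
  for (s in 1:5) {
    design <- cross_design(chrom_lengths = c(cA = 2e6), causative_chrom = "cA",
                           causative_pos = 1e6, n_mutant_pool = 25L,
                           n_background_pool = 25L, coverage = 20,
                           induced_density = 5, snp_density = 50, seed = s)
    sim <- simulate_bulks(design)
    cz <- sim$truth$type == "causative"
    expect_equal(sum(cz), 1L)
    # selection on mutant homozygotes fixes the allele exactly
    expect_equal(sim$truth$af_mut[cz], 1)
    expect_true(sim$truth$af_bg[cz] < 1)
    expect_true(all(sim$truth$af_mut >= 0 & sim$truth$af_mut <= 1))
    expect_equal(nrow(sim$mut_counts), nrow(sim$truth))
  }
  # determinism given the seed
  d <- cross_design(chrom_lengths = c(cA = 1e6), causative_chrom = "cA",
                    causative_pos = 5e5, n_mutant_pool = 10L,
                    n_background_pool = 10L, snp_density = 50, seed = 12L)
  expect_equal(simulate_bulks(d)$mut_counts, simulate_bulks(d)$mut_counts)
})

test_that("sampled read frequencies converge to the truth at high coverage", {
  design <- cross_design(chrom_lengths = c(cA = 3e6), causative_chrom = "cA",
                         causative_pos = 1.5e6, n_mutant_pool = 30L,
                         n_background_pool = 30L, coverage = 200,
                         induced_density = 10, snp_density = 100, seed = 8L)
  sim <- simulate_bulks(design)
  emp <- sim$mut_counts$alt_count / sim$mut_counts$depth
  expect_equal(mean(abs(emp - sim$truth$af_mut)), 0, tolerance = 0.03)
  emp_bg <- sim$bg_counts$alt_count / sim$bg_counts$depth
  expect_equal(mean(abs(emp_bg - sim$truth$af_bg)), 0, tolerance = 0.03)
})

test_that("backcross marker scarcity produces spurious enrichment away from the locus", {
  # the unlinked chromosome carries no true signal: score dispersion and
  # spurious HMES>1 calls there are driven purely by marker scarcity and
  # read-sampling noise, which is the backcross regime
  vars_bc <- vars_oc <- frac_bc <- frac_oc <- numeric(20)
  for (s in 1:20) {
    per_cross <- function(type) {
      design <- cross_design(cross_type = type,
                             chrom_lengths = c(cA = 4e6, cB = 3e6),
                             causative_chrom = "cA", causative_pos = 1.5e6,
                             recomb_rate = 25, n_mutant_pool = 30L,
                             n_background_pool = 30L, coverage = 20,
                             induced_density = 20, snp_density = 150,
                             seed = 100L + s)
      sim <- simulate_bulks(design)
      asm <- fragment_genome(design$chrom_lengths, seed = 200L + s)
      mut <- counts_to_fragments(asm, sim$mut_counts)
      vt <- build_variant_table(mut)
      sc <- score_fragments(vt, stats::setNames(asm$length, asm$fragment_id))
      far <- sc$hmes[sc$contig %in% asm$fragment_id[asm$chrom == "cB"]]
      c(v = stats::var(far), f = mean(far > 1))
    }
    bc <- per_cross("backcross"); oc <- per_cross("outcross")
    vars_bc[s] <- bc[["v"]]; vars_oc[s] <- oc[["v"]]
    frac_bc[s] <- bc[["f"]]; frac_oc[s] <- oc[["f"]]
  }
  expect_gte(mean(vars_bc), mean(vars_oc))
  expect_gte(mean(frac_bc), mean(frac_oc))
})

test_that("causative-fragment statistics summarise repeated fragmentations", {
  dat <- tiny_outcross(21L)
  vt <- build_variant_table(dat$sim$mut_counts, dat$sim$bg_counts)
  variants <- data.frame(chrom = vt$contig, pos = vt$pos,
                         zygosity = vt$zygosity, stringsAsFactors = FALSE)
  st <- causative_fragment_stats(10L, dat$design$chrom_lengths, variants,
                                 "cA", dat$design$causative_pos, seed = 77L)
  expect_equal(nrow(st$per_iteration), 10L)
  # enrichment by construction: causative fragment beats the genome median
  sc_all <- lapply(1:10, function(i) {
    asm <- fragment_genome(dat$design$chrom_lengths, seed = 77L + i - 1L)
    av <- assign_variants(asm, variants)
    sc <- score_fragments(data.frame(contig = av$fragment_id,
                                     zygosity = av$zygosity),
                          stats::setNames(asm$length, asm$fragment_id))
    stats::median(sc$hmes)
  })
  expect_gt(st$summary$mean_hmes, mean(unlist(sc_all)))

  # a single iteration's summary equals its only row
  st1 <- causative_fragment_stats(1L, dat$design$chrom_lengths, variants,
                                  "cA", dat$design$causative_pos, seed = 5L)
  expect_equal(st1$summary$median_length, st1$per_iteration$length[1L])
  expect_equal(st1$summary$mean_hmes, st1$per_iteration$hmes[1L])
})

test_that("exact pool frequencies come from genotype-class enumeration", {
  expect_equal(expected_pool_af("outcross", "mutant"), 1)
  expect_equal(expected_pool_af("outcross", "background"), 1 / 3)
  expect_equal(expected_pool_af("backcross", "mutant"), 1)
  expect_equal(expected_pool_af("backcross", "background"), 1 / 2)
})
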