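test_that("allele frequency is alt over filtered depth, undefined at zero depth", {
  expect_equal(allele_frequency(6L, 6L), 1)
  expect_equal(allele_frequency(2L, 6L), 1 / 3, tolerance = 1e-12)
  expect_equal(allele_frequency(0L, 5L), 0)
  expect_true(is.na(allele_frequency(0L, 0L)))
})

test_that("classification matches the recessive bulk expectations and partitions [0,1]", {
  thr <- zygosity_thresholds()
  expect_equal(classify_zygosity(1.0, thr), "homozygous")
  expect_equal(classify_zygosity(0.333, thr), "heterozygous")
  expect_equal(classify_zygosity(0.82, thr), "ambiguous")

  # every frequency maps to exactly one class; boundaries included
  af <- c(0, 1e-9, seq(0, 1, by = 0.001), 0.25, 0.75, 0.9, 1)
  cls <- classify_zygosity(af, thr)
  expect_true(all(cls %in% c("homozygous", "heterozygous", "ambiguous")))
  expect_equal(cls[af >= 0.9], rep("homozygous", sum(af >= 0.9)))
  expect_equal(cls[af >= 0.25 & af <= 0.75],
               rep("heterozygous", sum(af >= 0.25 & af <= 0.75)))
  expect_equal(cls[af < 0.25 | (af > 0.75 & af < 0.9)],
               rep("ambiguous", sum(af < 0.25 | (af > 0.75 & af < 0.9))))

  expect_error(zygosity_thresholds(hom_min_af = 0.7, het_max_af = 0.75),
               "het_min_af < het_max_af < hom_min_af")
})

test_that("background subtraction removes only homozygous matches, union over sets", {
  mut <- data.frame(contig = c("c1", "c1", "c2"), pos = c(100L, 100L, 50L),
                    alt = c("T", "G", "A"),
                    zygosity = "homozygous", stringsAsFactors = FALSE)
  bg_hom <- data.frame(contig = "c1", pos = 100L, alt = "T",
                       zygosity = "homozygous")
  bg_het <- data.frame(contig = "c1", pos = 100L, alt = "G",
                       zygosity = "heterozygous")
  p2 <- data.frame(contig = "c2", pos = 50L, alt = "A",
                   zygosity = "homozygous")

  out <- subtract_background(mut, bg_hom)
  expect_equal(nrow(out), 2L)          # exact-match removal only
  expect_false(any(out$alt == "T" & out$pos == 100L))

  # heterozygous background matches are retained (allele-aware)
  out <- subtract_background(mut, bg_het)
  expect_equal(nrow(out), 3L)

  # union semantics over multiple parental sets
  out <- subtract_background(mut, list(bg_hom, p2))
  expect_equal(out$alt, "G")

  # idempotent and order-independent
  expect_equal(subtract_background(out, list(bg_hom, p2)), out)
  expect_equal(subtract_background(mut, list(p2, bg_hom)),
               subtract_background(mut, list(bg_hom, p2)))
})

test_that("variant table applies filters, classifies, vetoes and subtracts", {
  thr <- zygosity_thresholds(min_depth = 6L)
  mut <- data.frame(contig = c("f1", "f1", "f2", "f2"),
                    pos = c(10L, 20L, 5L, 9L), ref = "A",
                    alt = c("T", "T", "G", "C"),
                    ref_count = c(1L, 0L, 10L, 1L),
                    alt_count = c(3L, 19L, 10L, 19L),
                    depth = c(4L, 19L, 20L, 20L), stringsAsFactors = FALSE)
  vt <- build_variant_table(mut, thresholds = thr)
  sc <- attr(vt, "stage_counts")
  expect_equal(sc$sites_in, 4L)
  expect_equal(sc$depth_ok, 3L)               # depth-4 site dropped
  expect_equal(vt$zygosity[vt$pos == 20L], "homozygous")
  expect_equal(vt$zygosity[vt$pos == 5L], "heterozygous")

  # homozygous in the background bulk -> vetoed as non-segregating
  bg <- data.frame(contig = "f1", pos = 20L, ref = "A", alt = "T",
                   ref_count = 0L, alt_count = 15L, depth = 15L)
  vt2 <- build_variant_table(mut, bg, thresholds = thr)
  expect_false(any(vt2$pos == 20L & vt2$contig == "f1"))
  expect_equal(attr(vt2, "stage_counts")$bg_vetoed, 1L)

  # homozygous in a parental set -> subtracted
  par <- data.frame(contig = "f2", pos = 9L, ref = "A", alt = "C",
                    ref_count = 0L, alt_count = 20L, depth = 20L)
  vt3 <- build_variant_table(mut, parental_sets = list(par), thresholds = thr)
  expect_false(any(vt3$pos == 9L))

  # evidence on unknown contigs is an error when the assembly is known
  expect_error(build_variant_table(mut, thresholds = thr,
                                   fragment_lengths = c(f1 = 100L)),
               "f2")
  expect_silent(build_variant_table(mut, thresholds = thr,
                                    fragment_lengths = c(f1 = 100L, f2 = 50L)))
})

test_that("pooled allele frequencies at the causative locus match cross expectations", {
  # high coverage so read sampling noise is small
  design <- cross_design(chrom_lengths = c(cA = 2e6), causative_chrom = "cA",
                         causative_pos = 1e6, recomb_rate = 4,
                         n_mutant_pool = 60L, n_background_pool = 60L,
                         coverage = 100, induced_density = 5,
                         snp_density = 50, seed = 31L)
  afs <- sapply(1:8, function(s) {
    design$seed <- 30L + s
    sim <- simulate_bulks(design)
    cz <- sim$truth$type == "causative"
    mc <- sim$mut_counts[cz, ]; bc <- sim$bg_counts[cz, ]
    c(mut = mc$alt_count / mc$depth, bg = bc$alt_count / bc$depth)
  })
  expect_equal(mean(afs["mut", ]), 1, tolerance = 0.05)
  expect_equal(mean(afs["bg", ]), 1 / 3, tolerance = 0.05)
})
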