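---
title: "Homozygosity-enrichment mapping on fragmented assemblies: model and methods"
author: "hmesmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity-enrichment mapping on fragmented assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmesmap)
```

## The mapping problem

Bulked segregant sequencing crosses a mutant to a mapping parent, selects two
pools of segregating offspring by phenotype, and sequences each pool. For a
recessive allele, every individual in the mutant pool is homozygous at the
causative locus, so the mutant-allele frequency there is exactly 1; in a
non-mutant outcross F2 pool the survivors are a 2:1 mixture of heterozygotes
and wild-type homozygotes, putting the expected frequency at 1/3. Reduced
recombination near the selected locus extends the region of (near-)fixation
outward, so the density of *homozygous* variant calls in the mutant pool decays
with distance from the mutation while *heterozygous* calls (unlinked markers
at frequency ~1/2) remain uniform.

The usual genome scan plots allele frequency along chromosomes — which
requires a chromosome-scale reference. Many species only have draft, de novo
assemblies: thousands of unordered contigs and scaffolds. `hmesmap` works
directly on such fragments. Each fragment is scored by its homozygosity
enrichment

$$\mathrm{HMES} = \frac{\alpha + \rho}{\beta + \rho},$$

where $\alpha$ and $\beta$ are the fragment's homozygous and heterozygous
variant counts and $\rho$ (default 0.5) is a small ratio adjustment that
avoids division of or by zero. HMES estimates the fragment's nearness to the
causative mutation without knowing where the fragment sits in the genome.

## The pipeline

`hmes_map()` composes:

1. **Evidence ingestion** (`read_pileup()`, `pileup_counts()`,
   `read_vcf_variants()`): per-site reference/alternative read counts from
   samtools mpileup text or VCF. The mpileup base column is parsed under the
   full grammar (read starts/ends, indels, deletion placeholders, reference
   skips), with each scored base gated by its Phred quality. BAM is not read
   directly; convert with `samtools mpileup` upstream.
2. **Zygosity classification** (`build_variant_table()`): the mutant-bulk
   allele frequency is `alt / filtered depth`; sites are *homozygous* when
   AF ≥ `hom_min_af`, *heterozygous* when `het_min_af` ≤ AF ≤ `het_max_af`,
   otherwise *ambiguous* and dropped (counted in the stage log).
3. **Background reduction**: a variant that is homozygous in a well-covered
   background bulk is vetoed as non-segregating, and homozygous calls from any
   number of parental variant sets are subtracted. Matching is allele-aware
   (contig, position, alternative allele): a genuine induced allele is not
   discarded merely for sharing a position with an accession SNP. Heterozygous
   background matches are retained — they are exactly the segregation signal.
4. **Scoring and selection** (`score_fragments()`, `filter_enriched()`,
   `select_top_percentile()`): fragments with HMES strictly greater than 1 are
   kept, their variants ranked by fragment score, and the top percentile
   (default 5%, computed over *variants*, size `ceiling(p/100 * N)`) reported.
5. **Presentation** (`center_out_order()`, `extract_flanks()`,
   `write_candidates()`): enriched fragments are arranged centre-out (largest
   score central, second to its left, third to its right, even ranks extending
   left, odd ranks right), and each candidate row carries up to `flank_len`
   (default 50) bases of flanking sequence for marker design. The ordering is
   a presentation aid; it does not alter selection.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hom_min_af` | 0.90 | minimum AF called homozygous |
| `het_min_af`, `het_max_af` | 0.25, 0.75 | heterozygous AF window |
| `min_depth` | 6 reads | minimum filtered depth per site |
| `min_base_quality` | 15 (Phred) | minimum base quality counted |
| `rho` | 0.5 | HMES ratio adjustment |
| `top_percent` | 5 % | variant percentile reported |
| `flank_len` | 50 bp | flanking sequence per side |

The ideal expectations (AF 1 and 1/3) are points; the windows absorb binomial
read-sampling noise at realistic 8–50× pool coverages. At 20×, a truly fixed
site falls below 0.90 only when ≥3 of 20 reads are errors or contaminants; a
1/2-frequency site exceeds 0.75 with probability ~2%, and exceeds 0.90 with
probability ~0.02%, which is what keeps false homozygous calls rare but not
absent. All thresholds are exposed in `hmes_map()` and the command line.
Classification uses the mutant-bulk frequency only; the background-bulk
frequency is recorded and acts purely as a veto.

## The simulation framework

Real case studies need external sequencing data. To make every stage testable
from nothing, the package ships a generative model of the whole experiment in
coordinate space — length statistics and HMES behaviour depend only on
coordinates, marker densities and the cross design, not on sequence content.

**Fragmentation** (`fragment_genome()`): fragment lengths are drawn from a
log-normal with log-mean 7.88 and log-sd 1.56 (a short-read de novo assembly
profile), rounded, floored at 300 bp (mirroring a ≥300 bp scaffold cutoff),
and laid left-to-right per chromosome, truncating the last fragment — so
fragments tile each chromosome exactly. A fixed genomic point lands in a
*size-biased* fragment: its length is log-normal with log-median shifted from
$\mu$ to $\mu + \sigma^2$, i.e. median $\exp(7.88 + 1.56^2) \approx 30$ kb
versus a plain median of 2.6 kb and mean of 8.9 kb. Over 1000 fragmentations
of the default five-chromosome, ~119 Mb genome the observed median is ~29 kb
(finite chromosomes truncate the heaviest tail).

**Cross model** (`cross_design()`, `simulate_bulks()`): gametes are crossover
mosaics of the two parental haplotypes under a Haldane (no-interference)
model — crossover counts Poisson with rate `recomb_rate` (default 4 cM/Mb,
Arabidopsis-like), breakpoints uniform. Outcross F2 individuals get two
recombinant F1 gametes; backcross (BC1) individuals get one recombinant gamete
plus a constant mutant-parent gamete. Individuals are selected into the mutant
pool (homozygous mutant at the causative locus) or the background pool
(everything else) until both pools are full. Markers are placed uniformly:
induced mutations at 10/Mb, accession SNPs at 500/Mb in an outcross (0 in a
backcross, where the parents share a background); the causative mutation is
always a marker, so the mutant-pool truth frequency there is exactly 1.
Evidence is expressed against a reference matching the accession haplotype, so
the mutant-parent allele is the alternative allele everywhere; read sampling
is depth ~ Poisson(`coverage`, default 20) and alternative reads ~
Binomial(depth, pooled AF). Defaults — pools of 80/80, coverage 20, the
five-chromosome genome with the causative locus at chr4:6,852,405 — are the
regime of a typical Arabidopsis outcross mapping experiment.

What the generator deliberately does **not** model: sequencing error and
contamination (false heterozygous calls in real data inflate β and false
homozygous calls create spurious peaks beyond the binomial noise modelled
here), alignment artefacts and repeat-induced mismapping, variant-caller
biases, crossover interference, segregation distortion, and X-ray-scale
deletions. Passing tests therefore demonstrate correctness of the scoring,
selection, ordering and I/O machinery and the cross-model statistics — not
robustness to every artefact of real pipelines.

## Numerical and design choices

- **Ties and determinism.** All rankings use (HMES desc, fragment length
  desc, contig id asc, position asc). Identical inputs give byte-identical
  reports; all simulator randomness flows from one seed, with per-iteration
  substreams derived arithmetically.
- **Percentile population.** The top-5% cut is computed over variants (each
  carrying its fragment's score), with size `ceiling(p/100 * N)`.
- **Fragments without variants** are omitted from scoring: their score would
  be exactly 1 and cannot pass the strict HMES > 1 filter either way.
- **Centre-out continuation.** Beyond the stated ranks (1 centre, 2 left,
  3 right, 4 extreme left, 5 extreme right), even ranks extend the left flank
  and odd ranks the right — the minimal continuation of the pattern. The
  tested contract is convention-independent: the centre holds the maximum and
  scores are non-increasing reading centre-outward.
- **Indels** are keyed `+SEQ`/`-SEQ`, counted alongside their anchor base, and
  classified by the same AF rules as substitutions. The filtered depth counts
  quality-passing base calls (reference plus substitutions), so depth never
  exceeds raw coverage.
- **Zero-depth or depth-free sites** (e.g. VCF records with no AD/DP4/DP
  evidence) are dropped and counted, never guessed.
- **Boundary behaviour.** AF windows are closed intervals; flanks truncate
  silently at contig ends; the classification ranges partition [0,1].
- **Background veto depth.** A background homozygous call vetoes a mutant
  variant only when the background site meets `min_depth`; a single stray read
  should not erase a candidate.
- **Problem sizes.** The shipped tests exercise the full default genome for
  the fragmentation statistics (1000 replicates) and the end-to-end recovery
  study (50 seeded datasets), and small two-chromosome genomes with compressed
  genetic maps (20–25 cM/Mb) elsewhere, chosen so each property is measured in
  seconds while preserving the linkage structure the property is about.

## Known limitations

- The causative *fragment* is usually not the single top-scoring fragment:
  within the near-fixed linked region every fragment is homozygous-enriched,
  so the top rank is a size lottery among linked fragments. Localization is
  the reliable product — in the recovery study the top-ranked fragment lies
  within 2 Mb of the planted locus in effectively every run — and the
  candidate list narrows the region, not the gene. This mirrors the behaviour
  of homozygosity scans on real draft assemblies, where the causative fragment
  typically sits in the top 10–30% of enriched fragments rather than the top
  few.
- With sparse markers (backcross), single false-homozygous calls create
  isolated high-scoring fragments far from the locus; the background pool and
  parental subtraction mitigate but do not remove them.
- Dominant alleles, polyploid dosage and multi-locus traits are out of scope.
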