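pileup_file <- function(lines) {
  f <- tempfile(fileext = ".pileup")
  writeLines(lines, f)
  f
}

test_that("mpileup parser decodes bases, strands, markers and offsets", {
  # ref G, bases ".,aA": G+, G-, A-, A+
  obs <- parse_mpileup(pileup_file("chr1\t100\tG\t4\t.,aA\tIIII"))
  expect_equal(nrow(obs), 4)
  expect_equal(obs$base, c("G", "G", "A", "A"))
  expect_equal(obs$strand, c("+", "-", "-", "+"))
  expect_true(all(is.na(obs$read_offset)))

  # start/end markers and an insertion field are not observations
  obs2 <- parse_mpileup(pileup_file("chr1\t5\tC\t3\t^~.+2AT,T$\tIII"))
  expect_equal(obs2$base, c("C", "C", "T"))

  # offsets column aligns with base symbols
  obs3 <- parse_mpileup(pileup_file("chr1\t9\tA\t3\t.Tt\tIII\t4,20,0"))
  expect_equal(obs3$read_offset, c(4L, 20L, 0L))

  # depth-0 line yields nothing
  expect_equal(nrow(parse_mpileup(pileup_file("chr1\t7\tA\t0\t*\t*"))), 0)

  # malformed lines are reported with their line number
  expect_error(parse_mpileup(pileup_file(c("chr1\t1\tA\t2\t..\tII",
                                           "chr1\t2\tA\t5\t..\tII"))),
               "line 2")
})

test_that("generated pileup depth equals base-symbol count on every line", {
  st <- small_study()
  for (f in c(st$pileups$pileups$bwa[1], st$pileups$pileups$tophat[1])) {
    for (ln in readLines(f)) {
      fields <- strsplit(ln, "\t")[[1]]
      obs <- parse_mpileup(pileup_file(ln))
      expect_equal(nrow(obs), as.integer(fields[4]))
    }
  }
})

test_that("allele summaries: counts, ratio, tie-break, omission", {
  # 11 ref G reads + 14 alt A reads -> alt ratio 14/25
  bases <- paste0(paste(rep(".", 6), collapse = ""),
                  paste(rep(",", 5), collapse = ""),
                  paste(rep("A", 7), collapse = ""),
                  paste(rep("a", 7), collapse = ""))
  s <- summarize_alleles(parse_mpileup(pileup_file(
    paste("chr16", 133064, "G", 25, bases, paste(rep("I", 25), collapse = ""),
          sep = "\t"))))
  expect_equal(s$ref_depth, 11)
  expect_equal(s$alt_depth, 14)
  expect_equal(s$alt_ratio, 14 / 25)
  expect_equal(s$alt, "A")

  # ref C 53, alt G 79 summarized as C->G
  bases2 <- paste0(paste(rep(".", 53), collapse = ""),
                   paste(rep("G", 79), collapse = ""))
  s2 <- summarize_alleles(parse_mpileup(pileup_file(
    paste("chr3", 131220447, "C", 132, bases2,
          paste(rep("I", 132), collapse = ""), sep = "\t"))))
  expect_equal(s2$alt, "G")
  expect_equal(s2$ref_depth, 53)
  expect_equal(s2$alt_depth, 79)

  # lexicographic tie-break between equally supported alts
  s3 <- summarize_alleles(parse_mpileup(pileup_file(
    "chr1\t10\tG\t6\t..TTCC\tIIIIII")))
  expect_equal(s3$alt, "C")

  # all-reference site omitted
  expect_equal(nrow(summarize_alleles(parse_mpileup(pileup_file(
    "chr1\t11\tA\t4\t..,,\tIIII")))), 0)
})

test_that("candidate filter: depth, ratio and confidence classes", {
  mk <- function(ref_d, alt_d) {
    data.frame(chrom = "c", pos = 1L, ref = "A", alt = "G",
               ref_depth = ref_d, alt_depth = alt_d,
               total_depth = ref_d + alt_d,
               alt_ratio = alt_d / (ref_d + alt_d),
               alt_fwd = alt_d, alt_rev = 0L, third_depth = 0L,
               stringsAsFactors = FALSE)
  }
  expect_equal(candidate_filter(mk(4, 6))$confidence, "high")   # depth 10, ratio .6
  expect_equal(candidate_filter(mk(95, 5))$confidence, "reject") # ratio 0.05
  expect_equal(candidate_filter(mk(18, 2))$confidence, "low")
  expect_equal(candidate_filter(mk(1, 2))$confidence, "reject")  # depth 3 < 4
  expect_equal(candidate_filter(mk(10, 1))$confidence, "reject") # single alt read
})

test_that("strand-bias filter requires both strands and ratio > 0.1", {
  expect_true(strand_bias_filter(5, 4))       # ratio 0.8
  expect_false(strand_bias_filter(9, 0))
  expect_false(strand_bias_filter(20, 1))     # 0.05 <= 0.1 -> fail
  expect_false(strand_bias_filter(10, 1))     # exactly 0.1 -> fail (strict >)
  expect_true(strand_bias_filter(9, 1))       # 1/9 > 0.1
})

test_that("consensus equals the set-intersection oracle", {
  set.seed(5)
  mk_sites <- function(n) {
    data.frame(chrom = "chr1", pos = sample(1:40, n),
               alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  for (r in 1:10) {
    a <- mk_sites(15); b <- mk_sites(15)
    cons <- consensus_calls(a, b)
    oracle <- intersect(paste(a$chrom, a$pos, a$alt),
                        paste(b$chrom, b$pos, b$alt))
    expect_setequal(paste(cons$chrom, cons$pos, cons$alt), oracle)
  }
  # same position, different alt -> dropped
  a <- data.frame(chrom = "c", pos = 1L, alt = "A", stringsAsFactors = FALSE)
  b <- data.frame(chrom = "c", pos = 1L, alt = "G", stringsAsFactors = FALSE)
  expect_equal(nrow(consensus_calls(a, b)), 0)
})

test_that("known-site filtering is allele-aware and equals the set-difference oracle", {
  v <- data.frame(chrom = "chr1", pos = c(5L, 5L, 9L),
                  alt = c("A", "T", "C"), stringsAsFactors = FALSE)
  known <- data.frame(chrom = "chr1", pos = 5L, alt = "A",
                      stringsAsFactors = FALSE)
  out <- filter_known(v, known)
  expect_equal(paste(out$pos, out$alt), c("5 T", "9 C"))  # different alt kept
  out2 <- filter_known(v, known, by_allele = FALSE)
  expect_equal(out2$pos, 9L)                              # position-only mode
  set.seed(6)
  v2 <- data.frame(chrom = "chr1", pos = sample(50, 20, TRUE),
                   alt = sample(c("A", "C"), 20, TRUE),
                   stringsAsFactors = FALSE)
  k2 <- data.frame(chrom = "chr1", pos = sample(50, 10, TRUE),
                   alt = sample(c("A", "C"), 10, TRUE),
                   stringsAsFactors = FALSE)
  out3 <- filter_known(v2, k2)
  oracle <- setdiff(paste(v2$pos, v2$alt), paste(k2$pos, k2$alt))
  expect_setequal(unique(paste(out3$pos, out3$alt)), oracle)
})

test_that("end-bias filter fails only all-terminal alternate reads", {
  expect_false(end_bias_filter(c(0, 1, 2))$pass)
  expect_true(end_bias_filter(c(1, 20, 24))$pass)
  unknown <- end_bias_filter(c(NA, NA))
  expect_true(unknown$pass)
  expect_true(unknown$offset_unknown)
  expect_true(end_bias_filter(c(NA, 7))$pass)
  expect_false(end_bias_filter(c(4, 4, 4), end_window = 5)$pass)
  expect_true(end_bias_filter(c(5), end_window = 5)$pass)
})

test_that("codon annotation classifies consequences on both strands", {
  mm <- manual_gene_models()
  # CDS sense: ATG GAC CAA TGG TAA
  # plus gene: codon 2 GAC -> CAC, missense D2H
  a <- annotate_variant("chrP", 9, "G", "C", mm$refflat, mm$genome)
  expect_equal(a$consequence, "missense")
  expect_equal(a$aa_change, "D2H")
  expect_equal(a$gene, "PLUSG")
  # codon 3 CAA -> TAA, stopgain
  expect_equal(annotate_variant("chrP", 12, "C", "T", mm$refflat,
                                mm$genome)$consequence, "stopgain")
  # codon 3 CAA -> CAG, synonymous
  expect_equal(annotate_variant("chrP", 14, "A", "G", mm$refflat,
                                mm$genome)$consequence, "synonymous")
  # final TAA -> TCA, stoploss (exon2 holds CDS 10..15 at pos 23..28)
  expect_equal(annotate_variant("chrP", 27, "A", "C", mm$refflat,
                                mm$genome)$consequence, "stoploss")
  # intron position
  expect_equal(annotate_variant("chrP", 17, "T", "A", mm$refflat,
                                mm$genome)$consequence, "non-exonic")
  # minus-strand gene: same codon-2 missense through the reverse complement
  cds_pos_minus <- c(28:20, 11:6)      # genomic positions in sense order
  gpos <- cds_pos_minus[4]             # first base of codon 2 (sense G)
  a2 <- annotate_variant("chrM", gpos, "C", "G", mm$refflat, mm$genome)
  expect_equal(a2$consequence, "missense")
  expect_equal(a2$aa_change, "D2H")
  expect_equal(a2$gene, "MINUSG")
})

test_that("annotation agrees with generator truth on planted variants", {
  st <- small_study()
  rf <- read_refflat(st$pileups$refflat)
  gen <- read_genome(st$pileups$genome)
  tr <- st$pileups$truth
  for (i in seq_len(nrow(tr))) {
    a <- annotate_variant(tr$chrom[i], tr$pos[i], tr$ref[i], tr$alt[i],
                          rf, gen)
    expect_equal(a$consequence, tr$consequence[i])
    expect_equal(a$gene, tr$gene[i])
  }
})

test_that("VCF output round-trips", {
  calls <- data.frame(
    chrom = c("chr1", "chr2"), pos = c(100L, 250L), ref = c("G", "C"),
    alt = c("A", "T"), gene = c("TGENE01", "TGENE02"),
    consequence = c("missense", "stopgain"), alt_depth = c(14L, 6L),
    total_depth = c(25L, 10L), confidence = c("high", "high"),
    sample = c("H1", "H2"), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".vcf")
  write_esnv_vcf(calls, f)
  back <- read_esnv_vcf(f)
  expect_equal(back, calls[, names(back)])
  # empty set round-trips too
  write_esnv_vcf(calls[0, ], f)
  expect_equal(nrow(read_esnv_vcf(f)), 0)
})
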