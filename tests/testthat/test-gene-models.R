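test_that("GFF3 written by the simulator round-trips through loadGeneModels", {
  sim <- tinySim()
  dir <- withr::local_tempdir()
  writeGFF3(geneModels(sim), file.path(dir, "genes.gff3"))
  reload <- loadGeneModels(file.path(dir, "genes.gff3"), genome = sim@genome,
                           flankWidth = sim@config$flank_width)
  orig <- geneModels(sim)
  ids <- geneIds(orig)
  expect_setequal(geneIds(reload), ids)
  gtO <- geneTable(orig); gtR <- geneTable(reload)
  gtR <- gtR[match(gtO$gene_id, gtR$gene_id), ]
  expect_equal(gtR$tss, gtO$tss)
  expect_equal(gtR$polya, gtO$polya)
  expect_equal(gtR$strand, gtO$strand)
  # CDS extraction reproduces the emitted coding sequences byte for byte
  cds <- cdsSequences(reload, sim@genome)
  expect_equal(as.character(cds[ids]), as.character(sim@cds[ids]))
})

test_that("single-exon gene models behave on both strands", {
  dir <- withr::local_tempdir()
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("T", 100), "ATGAAATAA", strrep("T", 100))))
  gff <- file.path(dir, "one.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t101\t109\t.\t+\t.\tID=gplus",
    "chr1\tx\tmRNA\t101\t109\t.\t+\t.\tID=gplus.t;Parent=gplus",
    "chr1\tx\tCDS\t101\t109\t.\t+\t0\tParent=gplus.t"), gff)
  m <- loadGeneModels(gff, genome = genome)
  expect_equal(length(cdsIntervals(m)[["gplus"]]), 1L)
  expect_equal(length(intronIntervals(m)[["gplus"]]), 0L)
  plusCounts <- counts(codonCounts(cdsSequences(m, genome)[["gplus"]]))

  # same CDS encoded on the minus strand: reverse-complement the chromosome
  genome2 <- Biostrings::DNAStringSet(c(
    chr1 = as.character(Biostrings::reverseComplement(genome[[1]]))))
  gff2 <- file.path(dir, "two.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t101\t109\t.\t-\t.\tID=gminus",
    "chr1\tx\tmRNA\t101\t109\t.\t-\t.\tID=gminus.t;Parent=gminus",
    "chr1\tx\tCDS\t101\t109\t.\t-\t0\tParent=gminus.t"), gff2)
  m2 <- loadGeneModels(gff2, genome = genome2)
  minusCounts <- counts(codonCounts(cdsSequences(m2, genome2)[["gminus"]]))
  expect_equal(minusCounts, plusCounts)
})

test_that("non-multiple-of-3 CDS is excluded with a logged reason", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "bad.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t7\t.\t+\t.\tID=gbad",
    "chr1\tx\tmRNA\t1\t7\t.\t+\t.\tID=gbad.t;Parent=gbad",
    "chr1\tx\tCDS\t1\t7\t.\t+\t0\tParent=gbad.t",
    "chr1\tx\tgene\t11\t19\t.\t+\t.\tID=gok",
    "chr1\tx\tmRNA\t11\t19\t.\t+\t.\tID=gok.t;Parent=gok",
    "chr1\tx\tCDS\t11\t19\t.\t+\t0\tParent=gok.t"), gff)
  expect_message(m <- loadGeneModels(gff), "gbad.*not divisible by 3")
  expect_equal(geneIds(m), "gok")
})

test_that("mitochondrial contigs are dropped and canonical transcripts chosen", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "canon.gff3")
  writeLines(c(
    "##gff-version 3",
    # two transcripts: t2 has the longer CDS and must win
    "chr1\tx\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\tx\tmRNA\t1\t50\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tx\tCDS\t1\t9\t.\t+\t0\tParent=g1.t1",
    "chr1\tx\tmRNA\t1\t100\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chr1\tx\tCDS\t1\t18\t.\t+\t0\tParent=g1.t2",
    # tie on CDS length: lexicographically first transcript id wins
    "chr1\tx\tgene\t201\t300\t.\t+\t.\tID=g2",
    "chr1\tx\tmRNA\t201\t300\t.\t+\t.\tID=g2.tB;Parent=g2",
    "chr1\tx\tCDS\t201\t209\t.\t+\t0\tParent=g2.tB",
    "chr1\tx\tmRNA\t201\t300\t.\t+\t.\tID=g2.tA;Parent=g2",
    "chr1\tx\tCDS\t211\t219\t.\t+\t0\tParent=g2.tA",
    # mitochondrial gene: dropped entirely
    "MT\tx\tgene\t1\t9\t.\t+\t.\tID=gmt",
    "MT\tx\tmRNA\t1\t9\t.\t+\t.\tID=gmt.t;Parent=gmt",
    "MT\tx\tCDS\t1\t9\t.\t+\t0\tParent=gmt.t"), gff)
  m <- loadGeneModels(gff)
  expect_setequal(geneIds(m), c("g1", "g2"))
  expect_equal(sum(IRanges::width(cdsIntervals(m)[["g1"]])), 18L)
  expect_equal(IRanges::start(cdsIntervals(m)[["g2"]]), 211L)  # g2.tA
})

test_that("codon statistics are invariant under genome reflection", {
  # reverse-complement the genome, mirror all coordinates and flip strands:
  # every usage table and GC statistic must be unchanged
  sim <- tinySim()
  models <- geneModels(sim)
  sub <- models[1:15]
  L <- sim@config$chrom_length
  genomeR <- Biostrings::reverseComplement(sim@genome)
  g <- transcriptionUnits(sub)
  mirror <- function(irl) {
    methods::as(IRanges::IRangesList(lapply(irl, function(ir) {
      out <- IRanges::IRanges(L - IRanges::end(ir) + 1L,
                              L - IRanges::start(ir) + 1L)
      out[order(IRanges::start(out))]
    })), "CompressedIRangesList")
  }
  gR <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(g),
    IRanges::IRanges(L - IRanges::end(g) + 1L, L - IRanges::start(g) + 1L),
    strand = ifelse(as.character(GenomicRanges::strand(g)) == "+", "-", "+"),
    seqlengths = GenomeInfoDb::seqlengths(g))
  names(gR) <- names(g)
  subR <- gbgcCodon:::.newGeneModelSet(gR, mirror(cdsIntervals(sub)),
                                       mirror(intronIntervals(sub)),
                                       mirror(flankIntervals(sub)),
                                       sub@flankWidth)
  f <- geneFeatures(sub, sim@genome)
  fR <- geneFeatures(subR, genomeR)
  expect_equal(fR$gc3, f$gc3)
  expect_equal(fR$gci, f$gci)
  expect_equal(fR$gc_flank, f$gc_flank)
  expect_equal(fR$n_codons, f$n_codons)
})
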