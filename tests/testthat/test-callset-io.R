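writeToyVcf <- function(path, body,
                        reference = "GRCh38",
                        infoExtra = character()) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##reference=%s", reference),
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
           '##INFO=<ID=AF,Number=1,Type=Float,Description="af">',
           '##INFO=<ID=N_HOMALT,Number=1,Type=Integer,Description="nh">',
           infoExtra,
           "##contig=<ID=chr1>", "##contig=<ID=chr17>",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, body), path)
  path
}

test_that("VCF reader converts POS/END, keeps only INV, honours FILTER policy", {
  p <- writeToyVcf(tempfile(fileext = ".vcf"), c(
    "chr17\t75576925\tinv1\tN\t<INV>\t.\tPASS\tEND=75829482;SVTYPE=INV;AF=0.00006345;N_HOMALT=0",
    "chr1\t101\tdel1\tN\t<DEL>\t.\tPASS\tEND=200;SVTYPE=DEL",
    "chr1\t501\tinv2\tN\t<INV>\t.\tLOWQUAL\tEND=600;SVTYPE=INV",
    "chr1\t1001\tinv3\tN\t<INV>\t.\t.\tSVLEN=100;SVTYPE=INV"))
  cs <- readVcfInversions(p, "toy")
  expect_equal(nCalls(cs), 2L)
  # printed browser coordinates are 0-based half-open: chr17:75576924-75829482
  i <- match("inv1", invIds(cs))
  expect_equal(start0(cs)[i], 75576924)
  expect_equal(end0(cs)[i], 75829482)
  expect_equal(invLengths(cs)[i], 252558)
  expect_equal(alleleFrequency(cs)[i], 6.345e-5, tolerance = 1e-9)
  expect_equal(nHomalt(cs)[i], 0L)
  # SVLEN fallback when END is absent: length 100 from POS 1001
  j <- match("inv3", invIds(cs))
  expect_equal(end0(cs)[j] - start0(cs)[j], 100)
  rc <- provenance(cs)$reader
  expect_equal(rc$dropped_type, 1L)    # the DEL
  expect_equal(rc$dropped_filter, 1L)  # LOWQUAL
  expect_equal(rc$input, 4L)
})

test_that("VCF reader anchoring flag, empty input, and hard errors", {
  p <- writeToyVcf(tempfile(fileext = ".vcf"),
                   "chr1\t101\tinv\tN\t<INV>\t.\tPASS\tEND=200;SVTYPE=INV")
  firstBase <- readVcfInversions(p, "a")
  preceding <- readVcfInversions(p, "b", posAnchor = "preceding_base")
  expect_equal(start0(firstBase), 100)
  expect_equal(start0(preceding), 101)
  expect_equal(end0(firstBase), end0(preceding))

  empty <- writeToyVcf(tempfile(fileext = ".vcf"), character())
  expect_equal(nCalls(readVcfInversions(empty, "e")), 0L)

  noEnd <- writeToyVcf(tempfile(fileext = ".vcf"),
                       "chr1\t101\tbad\tN\t<INV>\t.\tPASS\tSVTYPE=INV")
  expect_error(readVcfInversions(noEnd, "x"), "END")

  hg19 <- writeToyVcf(tempfile(fileext = ".vcf"),
                      "chr1\t101\tinv\tN\t<INV>\t.\tPASS\tEND=200;SVTYPE=INV",
                      reference = "GRCh37")
  expect_error(readVcfInversions(hg19, "x"), "build mismatch")
})

test_that("DGV reader filters by subtype, converts 1-based coordinates, counts drops", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("variantaccession\tchr\tstart\tend\tvariantsubtype",
               "v1\t17\t100\t200\tinversion",
               "v2\t1\t300\t400\tduplication",
               "v3\t17_random\t10\t20\tinversion",
               "v4\t2\tNA\t50\tInversion"), p)
  expect_warning(cs <- readDgvTable(p, "dgv"), "unparseable")
  expect_equal(nCalls(cs), 1L)
  expect_equal(as.character(GenomicRanges::seqnames(calls(cs))), "chr17")
  expect_equal(start0(cs), 99)
  expect_equal(end0(cs), 200)
  expect_equal(provenance(cs)$reader$dropped_type, 1L)
  expect_equal(provenance(cs)$reader$malformed_coord, 1L)
  expect_equal(provenance(cs)$harmonization$dropped_contig, 1L)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chr\tstart\tend", "1\t1\t2"), bad)
  expect_error(readDgvTable(bad, "x"), "missing column")
})

test_that("BED reader ingests half-open records verbatim and rejects empty spans", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\ta", "chr1\t100\t100\tzero", "chr2\t5\t10\tb",
               "chr1\t50\t60\tc"), p)
  cs <- readBedInversions(p, "bed")
  expect_equal(nCalls(cs), 3L)
  expect_equal(start0(cs)[1], 0)
  expect_equal(end0(cs)[1], 100)
  expect_equal(provenance(cs)$harmonization$dropped_invalid_span, 1L)
  # sorted by (chrom, start)
  expect_equal(invIds(cs), c("a", "c", "b"))
})

test_that("harmonization collapses exact duplicates and partitions counters", {
  cs <- InversionCallset("d", c("chr1", "chr1", "chr3_alt", "chr1", "chr1"),
                         c(10, 10, 5, 30, 100), c(20, 20, 50, 30, 200))
  h <- provenance(cs)$harmonization
  expect_equal(h$kept, 2L)
  expect_equal(h$dropped_duplicate, 1L)
  expect_equal(h$dropped_contig, 1L)
  expect_equal(h$dropped_invalid_span, 1L)
  expect_equal(h$kept + h$dropped_contig + h$dropped_invalid_span +
                 h$dropped_duplicate, h$input)
})

test_that("write -> read round-trips coordinates exactly in both formats", {
  cs <- InversionCallset("rt", c("chr2", "chr1", "chr1"),
                         c(75576924, 0, 999), c(75829482, 100, 2000),
                         alleleFrequency = c(0.01, NA, 0.2),
                         nHomalt = c(0L, NA, 3L))
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  writeCallset(cs, tsv, "tsv")
  writeCallset(cs, bed, "bed", sidecar = FALSE)

  back <- readCallsetTsv(tsv)
  expect_equal(start0(back), start0(cs))
  expect_equal(end0(back), end0(cs))
  expect_equal(invIds(back), invIds(cs))
  expect_equal(alleleFrequency(back), alleleFrequency(cs))
  expect_equal(nHomalt(back), nHomalt(cs))

  bedBack <- readBedInversions(bed, "rt")
  expect_equal(start0(bedBack), start0(cs))
  expect_equal(end0(bedBack), end0(cs))
  expect_equal(invIds(bedBack), invIds(cs))

  # display conventions: BED keeps 0-based half-open, TSV shows 1-based start
  bedLines <- readLines(bed)
  expect_true("chr2\t75576924\t75829482\trt_00001" %in% bedLines)
  tab <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(tab$start[tab$chrom == "chr2"], 75576925)

  # provenance sidecar carries the filter counters
  side <- jsonlite::read_json(paste0(tsv, ".prov.json"))
  expect_equal(side$n_calls, 3L)
  expect_equal(side$provenance$harmonization$kept, 3L)
})

test_that("VCF emitter round-trips through the VCF reader", {
  cs <- InversionCallset("sim", c("chr1", "chr17"), c(100, 5000), c(600, 9000),
                         alleleFrequency = c(0.001, 0.3), nHomalt = c(0L, 5L))
  p <- tempfile(fileext = ".vcf")
  writeCallsetVcf(cs, p)
  back <- readVcfInversions(p, "sim")
  expect_equal(start0(back), start0(cs))
  expect_equal(end0(back), end0(cs))
  expect_equal(alleleFrequency(back), alleleFrequency(cs), tolerance = 1e-6)
  expect_equal(nHomalt(back), nHomalt(cs))
})

test_that("empty writes give header-only (or empty) files that read back empty", {
  cs <- InversionCallset("none", character(), numeric(), numeric())
  tsv <- tempfile(fileext = ".tsv")
  writeCallset(cs, tsv, "tsv", sidecar = FALSE)
  expect_equal(length(readLines(tsv)), 1L)
  expect_equal(nCalls(readCallsetTsv(tsv)), 0L)
})
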