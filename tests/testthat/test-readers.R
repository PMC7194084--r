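# Per-caller dialect parsing and filter gates, on small hand-written
# fixture files.

bd_line <- function(chrom, p1, p2, type, size, score, pe, chrom2 = chrom)
  sprintf("%s\t%d\t5+5-\t%s\t%d\t5+5-\t%s\t%d\t%d\t%d",
          chrom, p1, chrom2, p2, type, size, score, pe)

test_that("read_breakdancer applies score/support/size gates", {
  f <- tempfile()
  writeLines(c("#Chr1\tPos1\tOrientation1\tChr2\tPos2\tOrientation2\tType\tSize\tScore\tnum_Reads",
               bd_line("chr05", 65575L, 65949L, "DEL", 375L, 88L, 5L),
               bd_line("chr05", 100000L, 101000L, "DEL", 1001L, 59L, 10L),
               bd_line("chr05", 200000L, 201000L, "DEL", 1001L, 99L, 2L),
               bd_line("chr05", 1291603L, 1291649L, "INV", -105L, 99L, 3L),
               bd_line("chr05", 300000L, 300050L, "DEL", 51L, 99L, 9L),
               bd_line("chr05", 400000L, 400500L, "CTX", 501L, 99L, 9L),
               bd_line("chr05", 500000L, 700000L, "DEL", 200001L, 99L,
                       9L, chrom2 = "chr06")), f)
  cs <- read_breakdancer(f)
  expect_s3_class(cs, "CallSet")
  expect_equal(names(cs), c("del", "inv"))
  expect_equal(nrow(cs$del), 1L)
  expect_equal(cs$del$pos1, 65575L)
  expect_equal(cs$del$info, "score=88;PE=5")
  # the negative-size inversion is retained: |size| = 105 passes even
  # though the coordinate span is only 47
  expect_equal(nrow(cs$inv), 1L)
  expect_equal(cs$inv$size, -105)
  expect_equal(cs$inv$info, "score=99;PE=3")

  rep <- reader_report(cs)
  expect_equal(unname(rep$raw_count["del"]), 4L)
  expect_equal(unname(rep$kept_count["del"]), 1L)
  # conservation: every typed record is kept or skipped exactly once
  # (parse-level skips carry no sv_type and sit outside the raw counts)
  expect_equal(sum(rep$raw_count), sum(rep$kept_count) +
                 sum(!is.na(rep$skipped$sv_type)))
  expect_true(any(grepl("score below", rep$skipped$reason)))
  expect_true(any(grepl("read-pair support", rep$skipped$reason)))
  expect_true(any(grepl("size outside", rep$skipped$reason)))
  expect_true(any(grepl("interchromosomal", rep$skipped$reason)))
  expect_true(any(grepl("unsupported SV type 'CTX'", rep$skipped$reason)))

  # swapped coordinates are normalised
  writeLines(c(bd_line("chr01", 900L, 200L, "DEL", 701L, 90L, 6L)), f)
  cs2 <- read_breakdancer(f)
  expect_equal(cs2$del$pos1, 200L)
  expect_equal(cs2$del$pos2, 900L)

  writeLines("chr01\t100\tonly-three-columns", f)
  expect_error(read_breakdancer(f), class = "sv_data_error")
  expect_error(read_breakdancer(tempfile()), class = "sv_data_error")
})

pindel_block <- function(i, type, chrom, pos1, pos2, sr, score = 12L)
  c(strrep("#", 30),
    sprintf("%d\t%s %d\tNT 0 \"\"\tChrID %s\tBP %d\t%d\tBP_range %d\t%d\tSupports %d\t%d\tS1 %d",
            i, type, pos2 - pos1 + 1L, chrom, pos1 - 1L, pos2 + 1L,
            pos1 - 1L, pos2 + 1L, sr, sr, score),
    "ACGTACGT supporting read line ignored by the parser")

test_that("read_pindel parses blocks and filters on split reads and size", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c(pindel_block(0L, "D", "chr05", 100000L, 101623L, 11L),
               pindel_block(1L, "D", "chr05", 200000L, 200500L, 2L),
               "##########", "garbage header without keywords"),
             file.path(dir, "sample_D"))
  writeLines(pindel_block(0L, "TD", "chr05", 300000L, 300049L, 5L),
             file.path(dir, "sample_TD"))
  writeLines(pindel_block(0L, "INV", "chr10", 400000L, 401000L, 7L),
             file.path(dir, "sample_INV"))
  cs <- read_pindel(dir)
  expect_equal(names(cs), c("del", "dup", "inv"))
  expect_equal(nrow(cs$del), 1L)
  expect_equal(cs$del$pos1, 100000L)
  expect_equal(cs$del$pos2, 101623L)
  expect_equal(cs$del$info, "SR=11;score=12")
  expect_equal(nrow(cs$dup), 0L)  # span 50 < 100 bp
  expect_equal(nrow(cs$inv), 1L)
  rep <- reader_report(cs)
  expect_true(any(grepl("malformed block header", rep$skipped$reason)))
  expect_true(any(grepl("split-read support", rep$skipped$reason)))
  expect_true(any(grepl("size outside", rep$skipped$reason)))

  empty <- tempfile(); dir.create(empty)
  expect_warning(cs0 <- read_pindel(empty))
  expect_equal(sum(vapply(cs0, nrow, 1L)), 0L)
})

test_that("read_cnvnator recomputes sizes and hard-errors on stray files", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("deletion\tchr05:104101-110700\t6600\t0.31\t0.0100681\t1386200000\t10.1189\t1690690000\t0",
               "duplication\tchr05:405001-408900\t3900\t1.9\t0.0169421\t0\t0.00545604\t0\t0"),
             file.path(dir, "chr05.txt"))
  writeLines("deletion\tchr10:1000001-13000001\t12000000\t0.1\t1e-5\t1e-5\t1e-5\t1e-5\t0",
             file.path(dir, "chr10.txt"))
  cs <- read_cnvnator(dir)
  expect_equal(names(cs), c("del", "dup"))
  expect_equal(nrow(cs$del), 1L)   # the 12 Mb deletion exceeds 10 Mb
  expect_equal(cs$del$pos1, 104101L)
  expect_equal(cs$del$pos2, 110700L)
  expect_equal(cs$del$size, 6599)
  expect_match(cs$dup$info, "^eval1=0.0169421;")
  rep <- reader_report(cs)
  expect_equal(unname(rep$raw_count), c(2L, 1L))
  expect_true(any(grepl("size outside", rep$skipped$reason)))

  writeLines("this is not CNVnator output", file.path(dir, "stray.txt"))
  expect_error(read_cnvnator(dir), class = "sv_data_error",
               regexp = "stray")
})

sv_vcf <- function(path, rows, info_defs) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
           info_defs,
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, rows), path)
  path
}

test_that("read_delly sums PE and SR support and respects the size window", {
  f <- tempfile(fileext = ".vcf")
  sv_vcf(f,
         c("chr05\t9999\td1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=15000;PE=5;SR=2",
           "chr05\t49999\td2\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=51000;PE=2;SR=0",
           "chr05\t79999\td3\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP;END=80063;PE=9;SR=9",
           "chr05\t99999\td4\tN\t<BND>\t.\tPASS\tSVTYPE=BND;END=100500;PE=9;SR=9"),
         c("##INFO=<ID=PE,Number=1,Type=Integer,Description=\"p\">",
           "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"s\">"))
  cs <- read_delly(f)
  expect_equal(nrow(cs$del), 1L)
  expect_equal(cs$del$pos1, 10000L)  # POS is the base before the event
  expect_equal(cs$del$pos2, 15000L)
  expect_equal(cs$del$info, "PE=5;SR=2")
  expect_equal(nrow(cs$inv), 0L)     # PE + SR = 2 < 3
  expect_equal(nrow(cs$dup), 0L)     # span 64 < 100
  rep <- reader_report(cs)
  expect_true(any(grepl("unsupported SV type 'BND'", rep$skipped$reason)))

  # VCF without SVTYPE/END definitions is a hard parse error
  f2 <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr01\t100\tx\tN\t<DEL>\t.\t.\tFOO=1"), f2)
  expect_error(read_delly(f2), class = "sv_data_error")
})

test_that("read_svseq keeps well-supported deletions of legal size", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("10000\t10499\t4", "20000\t20500\t2", "30000\t30089\t8"),
             file.path(dir, "chr07.del"))
  cs <- read_svseq(dir)
  expect_equal(names(cs), "del")
  expect_equal(nrow(cs$del), 1L)
  expect_equal(cs$del$chromosome, "chr07")
  expect_equal(cs$del$info, "SR=4")
  rep <- reader_report(cs)
  expect_equal(unname(rep$raw_count["del"]), 3L)
  expect_equal(nrow(rep$skipped), 2L)
})

test_that("read_lumpy handles VCF and BEDPE dialects", {
  f <- tempfile(fileext = ".vcf")
  sv_vcf(f,
         c("chr05\t9999\tl1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=11000;SU=21",
           "chr05\t49999\tl2\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=51000;SU=2",
           "chr05\t79999\tl3\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=10090000;SU=30"),
         "##INFO=<ID=SU,Number=1,Type=Integer,Description=\"u\">")
  cs <- read_lumpy(f)
  expect_equal(nrow(cs$del), 1L)  # the 10 Mb+ deletion is filtered
  expect_equal(cs$del$info, "SU=21")
  expect_equal(nrow(cs$inv), 0L)

  bedpe <- tempfile(fileext = ".bedpe")
  writeLines(c(paste("chr02", "999", "1100", "chr02", "5000", "5100", "1",
                     "9", "+", "-", "TYPE:DELETION", "IDS:pe,5;sr,3",
                     sep = "\t"),
               paste("chr02", "7000", "7100", "chr03", "9000", "9100", "2",
                     "9", "+", "-", "TYPE:DELETION", "IDS:pe,9",
                     sep = "\t")), bedpe)
  cs2 <- read_lumpy(bedpe)
  expect_equal(nrow(cs2$del), 1L)
  expect_equal(cs2$del$pos1, 1000L)  # BEDPE start is 0-based
  expect_equal(cs2$del$pos2, 5100L)
  expect_equal(cs2$del$info, "SU=8")
  expect_true(any(grepl("interchromosomal",
                        reader_report(cs2)$skipped$reason)))
})

test_that("read_softsearch requires both split-read and pair support", {
  f <- tempfile(fileext = ".vcf")
  sv_vcf(f,
         c("chr05\t9999\ts1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=11000;nSC=4;nRP=5",
           "chr05\t49999\ts2\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=51000;nSC=4;nRP=2",
           "chr05\t79999\ts3\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP;END=81000;nSC=2;nRP=9"),
         c("##INFO=<ID=nSC,Number=1,Type=Integer,Description=\"c\">",
           "##INFO=<ID=nRP,Number=1,Type=Integer,Description=\"r\">"))
  cs <- read_softsearch(f)
  expect_equal(nrow(cs$del), 1L)
  expect_equal(cs$del$info, "nSC=4;nRP=5")
  expect_equal(nrow(cs$dup), 0L)
  reasons <- reader_report(cs)$skipped$reason
  expect_true(any(grepl("read-pair support", reasons)))
  expect_true(any(grepl("split-read support", reasons)))
})

test_that("readers are insensitive to input line order", {
  lines <- c(bd_line("chr05", 65575L, 65949L, "DEL", 375L, 88L, 5L),
             bd_line("chr05", 100000L, 101000L, "DEL", 1001L, 59L, 10L),
             bd_line("chr02", 5000L, 6000L, "DEL", 1001L, 70L, 4L),
             bd_line("chr05", 1291603L, 1291649L, "INV", -105L, 99L, 3L))
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(lines, f1)
  set.seed(3); writeLines(sample(lines), f2)
  cs1 <- read_breakdancer(f1); cs2 <- read_breakdancer(f2)
  expect_equal(cs1$del, cs2$del)
  expect_equal(cs1$inv, cs2$inv)
})

test_that("resolve_self_overlaps keeps the best-supported record", {
  # two identical deletions, supports 5 and 9 -> support 9 survives
  cs <- mk_callset("lumpy",
                   del = rbind(rec("chr01", 1000, 1999, info = "SU=5"),
                               rec("chr01", 1000, 1999, info = "SU=9")))
  out <- resolve_self_overlaps(cs)
  expect_equal(nrow(out$del), 1L)
  expect_equal(out$del$info, "SU=9")

  # RO = 0.5 stays below the threshold: both kept
  cs2 <- mk_callset("lumpy",
                    del = rbind(rec("chr01", 100, 199, info = "SU=5"),
                                rec("chr01", 150, 249, info = "SU=9")))
  expect_equal(nrow(resolve_self_overlaps(cs2)$del), 2L)

  # single record unchanged
  cs3 <- mk_callset("lumpy", del = rec("chr01", 100, 900))
  expect_equal(resolve_self_overlaps(cs3)$del, cs3$del)
})

test_that("resolve_self_overlaps agrees with exhaustive enumeration", {
  # oracle: in every overlap-component, the max-support record (ties:
  # smaller pos1, then pos2) survives — enumerated independently
  set.seed(21)
  for (case in 1:40) {
    n <- sample.int(5L, 1L)
    df <- rand_records(n, n_chrom = 1L, max_pos = 400L)
    cs <- mk_callset("lumpy", del = df)
    out <- resolve_self_overlaps(cs)$del
    comp <- oracle_components(sort_df <- cs$del, 0.8)
    sup <- as.numeric(sub("SU=", "", sort_df$info))
    expected <- do.call(rbind, lapply(split(seq_along(comp), comp),
      function(ix) {
        ord <- order(-sup[ix], sort_df$pos1[ix], sort_df$pos2[ix])
        sort_df[ix[ord[1L]], ]
      }))
    expected <- expected[order(expected$chromosome, expected$pos1,
                               expected$pos2), ]
    rownames(expected) <- NULL
    expect_equal(out, expected)
  }
})

test_that("retained records always satisfy their caller's gates", {
  fx <- fixture_dir(seed = 99L, sub_threshold_frac = 0.4,
                    callers = c("breakdancer", "pindel", "cnvnator",
                                "delly", "lumpy", "softsearch", "svseq"))
  css <- read_simulated(fx$dir, fx$callers)
  for (cs in css) expect_true(audit_callset(cs))
})
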