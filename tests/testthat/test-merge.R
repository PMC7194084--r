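test_that("build_distance_matrix is 0/1 with a strict threshold", {
  df <- rbind(rec("chr01", 100, 199), rec("chr01", 100, 199),
              rec("chr02", 100, 199), rec("chr01", 120, 219))
  d <- build_distance_matrix(df, 0.8)
  expect_equal(dim(d), c(4L, 4L))
  expect_equal(diag(d), rep(0, 4))
  expect_equal(d, t(d))
  expect_equal(d[1, 2], 0)  # identical pair
  expect_equal(d[1, 3], 1)  # different chromosomes
  # RO exactly 0.8 is NOT linked: the threshold is strict
  expect_equal(reciprocal_overlap(100, 199, 120, 219), 0.8)
  expect_equal(d[1, 4], 1)
})

test_that("cluster_svs equals connected components of the overlap graph", {
  expect_equal(cluster_svs(rec("chr01", 5, 10)), 1L)

  # A~B overlap 0.9, C apart -> {A,B},{C}
  df <- rbind(rec("chr01", 100, 199), rec("chr01", 110, 209),
              rec("chr01", 400, 499))
  expect_equal(reciprocal_overlap(100, 199, 110, 209), 0.9)
  expect_equal(cluster_svs(df), c(1L, 1L, 2L))

  # chained single-linkage transitivity: A~B and B~C link A with C even
  # though RO(A, C) is only 0.64
  ch <- rbind(rec("chr01", 100, 199), rec("chr01", 110, 209),
              rec("chr01", 118, 217))
  expect_equal(reciprocal_overlap(100, 199, 118, 217), 0.82)
  ch2 <- rbind(rec("chr01", 100, 199), rec("chr01", 118, 217),
               rec("chr01", 136, 235))
  expect_equal(cluster_svs(ch2), c(1L, 1L, 1L))
  expect_lt(reciprocal_overlap(100, 199, 136, 235), 0.8)
})

test_that("union-find, hclust and the BFS oracle give the same partition", {
  set.seed(31)
  for (case in 1:60) {
    df <- rand_records(sample.int(30L, 1L))
    cc <- cluster_svs(df, 0.8, linkage = "components")
    hc <- cluster_svs(df, 0.8, linkage = "hclust")
    or <- oracle_components(df, 0.8)
    expect_true(same_partition(cc, or))
    expect_true(same_partition(hc, or))
    # labels are first-appearance ordered, so the two routes agree exactly
    expect_identical(cc, as.integer(factor(hc, levels = unique(hc))))
  }
})

test_that("merge_cluster takes rounded mean coordinates and joins methods", {
  members <- data.frame(chromosome = "chr01", pos1 = c(100, 110),
                        pos2 = c(200, 210),
                        info = c("score=88;PE=5", "SU=5"),
                        method = c("BreakDancer", "Lumpy"),
                        caller = c("breakdancer", "lumpy"),
                        source_order = c(1L, 2L), stringsAsFactors = FALSE)
  m <- merge_cluster(members, 2L)
  expect_equal(m$pos1, 105)
  expect_equal(m$pos2, 205)
  expect_equal(m$methods, "BreakDancer:Lumpy")
  expect_equal(m$info, "score=88;PE=5:SU=5")

  # a one-method cluster is discarded regardless of its size
  members$method <- "BreakDancer"; members$caller <- "breakdancer"
  members$source_order <- 1L
  expect_null(merge_cluster(members, 2L))

  # a caller contributing two members is listed once (best-supported
  # info) but both members' coordinates enter the means
  tri <- data.frame(chromosome = "chr01", pos1 = c(100, 104, 111),
                    pos2 = c(200, 204, 211),
                    info = c("SU=5", "SU=9", "score=70;PE=4"),
                    method = c("Lumpy", "Lumpy", "BreakDancer"),
                    caller = c("lumpy", "lumpy", "breakdancer"),
                    source_order = c(2L, 2L, 1L), stringsAsFactors = FALSE)
  m2 <- merge_cluster(tri, 2L)
  expect_equal(m2$pos1, 105)  # mean(100, 104, 111) = 105
  expect_equal(m2$methods, "BreakDancer:Lumpy")
  expect_equal(m2$info, "score=70;PE=4:SU=9")
})

test_that("methods_merge integrates call sets per type", {
  bd <- mk_callset("breakdancer",
                   del = rec("chr01", 1000, 1999, info = "score=90;PE=8"),
                   inv = rec("chr02", 5000, 5999, info = "score=70;PE=4"))
  lp <- mk_callset("lumpy",
                   del = rec("chr01", 1010, 2009, info = "SU=6"),
                   inv = rec("chr03", 5000, 5999, info = "SU=6"))
  merged <- methods_merge(bd, lp)
  expect_s3_class(merged, "MergedSVList")
  expect_equal(nrow(merged$del), 1L)
  expect_equal(merged$del$pos1, 1005)
  expect_equal(merged$del$methods, "BreakDancer:Lumpy")
  expect_equal(merged$del$info, "score=90;PE=8:SU=6")
  # inversions on different chromosomes stay singletons -> discarded
  expect_equal(nrow(merged$inv), 0L)
  expect_equal(nrow(merged$dup), 0L)

  # disjoint predictions give an empty integration
  lp2 <- mk_callset("lumpy", del = rec("chr09", 1, 2000, info = "SU=6"))
  m2 <- methods_merge(bd, lp2)
  expect_equal(sum(vapply(m2, nrow, 1L)), 0L)

  expect_error(methods_merge(bd), class = "sv_config_error")
  expect_error(methods_merge(bd, list(1)), class = "sv_config_error")
})

test_that("SV types never merge across type lists", {
  a <- mk_callset("delly", del = rec("chr01", 100, 1000, info = "PE=5;SR=1"))
  b <- mk_callset("lumpy", dup = rec("chr01", 100, 1000, info = "SU=5"))
  m <- methods_merge(a, b)
  expect_equal(sum(vapply(m, nrow, 1L)), 0L)
})

test_that("write_merged round-trips TSV and converts VCF/BED coordinates", {
  bd <- mk_callset("breakdancer",
                   del = rec("chr01", 1000, 1999, info = "score=90;PE=8"),
                   inv = rec("chr02", 5000, 5999, info = "score=70;PE=4"))
  lp <- mk_callset("lumpy",
                   del = rec("chr01", 1010, 2009, info = "SU=6"),
                   inv = rec("chr02", 5004, 6003, info = "SU=6"))
  merged <- methods_merge(bd, lp)

  tsv <- tempfile(fileext = ".tsv")
  write_merged(merged, tsv, "tsv")
  back <- read_merged(tsv)
  for (tp in c("del", "dup", "inv"))
    expect_equal(back[[tp]], merged[[tp]], ignore_attr = TRUE)

  vcf <- tempfile(fileext = ".vcf")
  write_merged(merged, vcf, "vcf")
  v <- VariantAnnotation::readVcf(vcf, genome = "unknown")
  inf <- VariantAnnotation::info(v)
  expect_equal(sort(inf$END),
               sort(c(merged$del$pos2, merged$inv$pos2)))
  expect_setequal(inf$METHODS, "BreakDancer:Lumpy")

  bed <- tempfile(fileext = ".bed")
  write_merged(merged, bed, "bed")
  b <- read.table(bed, sep = "\t")
  expect_equal(sort(b$V2), sort(c(merged$del$pos1, merged$inv$pos1) - 1))
  expect_equal(sort(b$V3), sort(c(merged$del$pos2, merged$inv$pos2)))

  expect_error(write_merged(merged, tempfile(), "xlsx"),
               class = "sv_config_error")
})

test_that("merged output is invariant to caller order up to methods order", {
  set.seed(47)
  for (case in 1:25) {
    css <- lapply(c("breakdancer", "delly", "lumpy"), function(cl) {
      df <- rand_records(sample.int(12L, 1L), n_chrom = 2L)
      df$info <- switch(cl,
                        breakdancer = sprintf("score=%d;PE=%d",
                                              sample(60:99, nrow(df), TRUE),
                                              sample(3:30, nrow(df), TRUE)),
                        delly = sprintf("PE=%d;SR=%d",
                                        sample(3:30, nrow(df), TRUE),
                                        sample(0:9, nrow(df), TRUE)),
                        sprintf("SU=%d", sample(3:40, nrow(df), TRUE)))
      mk_callset(cl, del = df)
    })
    m1 <- methods_merge(css[[1]], css[[2]], css[[3]])$del
    m2 <- methods_merge(css[[3]], css[[1]], css[[2]])$del
    expect_equal(m1[, c("chromosome", "pos1", "pos2")],
                 m2[, c("chromosome", "pos1", "pos2")])
    canon <- function(x) lapply(strsplit(x, ":"), sort)
    expect_equal(canon(m1$methods), canon(m2$methods))
  }
})

test_that("raising overlap_frac never coarsens the partition", {
  set.seed(53)
  for (case in 1:30) {
    df <- rand_records(sample.int(40L, 1L))
    lo <- cluster_svs(df, 0.6)
    hi <- cluster_svs(df, 0.9)
    # every high-threshold cluster must sit inside one low-threshold one
    expect_true(all(vapply(split(lo, hi), function(x)
      length(unique(x)) == 1L, TRUE)))
    expect_gte(length(unique(hi)), length(unique(lo)))
  }
})
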