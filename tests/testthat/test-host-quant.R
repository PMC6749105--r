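test_that("alignment reports all minimal-mismatch placements", {
  set.seed(10)
  refs <- c(refA = randSeqChr(200), refB = randSeqChr(200))
  # exact 22-nt substring -> single hit, 0 mismatches
  rd <- substr(refs[["refA"]], 41, 62)
  a <- alignReads(setNames(rd, "r1"), refs)
  expect_equal(nrow(a), 1)
  expect_equal(a$ref_id, "refA")
  expect_equal(a$ref_start, 40)
  expect_equal(a$ref_end, 62)
  expect_equal(a$mismatches, 0)

  # read matching two references with 1 mismatch each and none with 0
  core <- randSeqChr(24)
  refs2 <- c(x = paste0(randSeqChr(30), mutateSeq(core, 3), randSeqChr(30)),
             y = paste0(randSeqChr(50), mutateSeq(core, 17), randSeqChr(10)))
  a2 <- alignReads(setNames(core, "r2"), refs2)
  expect_equal(sort(a2$ref_id), c("x", "y"))
  expect_equal(a2$mismatches, c(1, 1))

  # >= 3 mismatches everywhere -> unmapped
  a3 <- alignReads(setNames(mutateSeq(core, c(2, 9, 20)), "r3"),
                   c(z = paste0(randSeqChr(20), core, randSeqChr(20))))
  expect_equal(nrow(a3), 0)
})

test_that("seeded alignment agrees with the exhaustive-scan oracle", {
  set.seed(77)
  refs <- setNames(vapply(c(150, 90, 60, 200, 120), randSeqChr, character(1)),
                   paste0("ref", 1:5))
  cases <- list()
  for (i in 1:60) {
    src <- sample(5, 1)
    l <- sample(14:40, 1)
    p <- sample(nchar(refs[[src]]) - l + 1, 1)
    rd <- substr(refs[[src]], p, p + l - 1)
    nerr <- sample(0:3, 1)
    if (nerr) rd <- mutateSeq(rd, sample(l, nerr))
    if (runif(1) < 0.3) rd <- oracleRevComp(rd)
    cases[[i]] <- rd
  }
  cases <- c(cases, replicate(15, randSeqChr(25), simplify = FALSE))
  reads <- setNames(unlist(cases), paste0("q", seq_along(cases)))
  for (bs in c(FALSE, TRUE)) {
    got <- alignReads(reads, refs, max_mismatches = 2, both_strands = bs)
    for (id in names(reads)) {
      want <- oracleAlign(reads[[id]], refs, 2, bs)
      sub <- got[got$read_id == id, c("ref_id", "ref_start", "ref_end",
                                      "strand", "mismatches")]
      if (is.null(want)) {
        expect_equal(nrow(sub), 0)
      } else {
        o1 <- sub[order(sub$ref_id, sub$ref_start, sub$strand), ]
        o2 <- want[order(want$ref_id, want$ref_start, want$strand), ]
        rownames(o1) <- rownames(o2) <- NULL
        expect_equal(o1, o2)
      }
    }
  }
})

test_that("knowledge-based arm assignment follows majority overlap", {
  b <- fixtureSmallBundle()
  arms <- armAnnotations(b)
  pid <- arms$precursor_id[!is.na(arms$arm5_start)][1]
  a <- arms[arms$precursor_id == pid, ]
  pre <- as.character(precursorSequences(b))[[pid]]

  # read fully inside arm5
  r5 <- substr(pre, a$arm5_start + 1, a$arm5_start + 20)
  # read overlapping arm3 by 15 nt and arm5 by at most 5
  r3 <- substr(pre, a$arm3_start - 4, a$arm3_start + 15)
  aln <- alignReads(c(in5 = r5, ov3 = r3), setNames(pre, pid))
  se <- quantifyMirna(aln, b, sample = "s")
  cnt <- countsOf(se)[, 1]
  expect_equal(unname(cnt[paste0(pid, "-5p")]), 1)
  expect_equal(unname(cnt[paste0(pid, "-3p")]), 1)

  # explicit overlap tie goes to arm5: construct alignment table directly
  mid <- data.frame(read_id = "tie", ref_id = pid,
                    ref_start = a$arm5_end - 10, ref_end = a$arm5_end + 10,
                    strand = "+", mismatches = 0, stringsAsFactors = FALSE)
  cnt2 <- countsOf(quantifyMirna(mid, b, "s"))[, 1]
  expect_equal(unname(cnt2[paste0(pid, "-5p")]), 1)
})

test_that("position-based quantification names features by midpoint half", {
  b <- fixtureSmallBundle()
  arms <- armAnnotations(b)
  pid <- arms$precursor_id[is.na(arms$arm5_start)][1]
  pre <- as.character(precursorSequences(b))[[pid]]
  L <- nchar(pre)
  # midpoint at ~0.7 * L -> 3p Novel
  st <- floor(0.7 * L) - 10
  r <- substr(pre, st + 1, st + 20)
  aln <- alignReads(setNames(r, "r"), setNames(pre, pid))
  cnt <- countsOf(quantifyMirna(aln, b, "s"))[, 1]
  expect_equal(unname(cnt[paste0(pid, "_3p-Novel")]), 1)
  # midpoint in the 5' half -> 5p Novel
  r2 <- substr(pre, 3, 22)
  aln2 <- alignReads(setNames(r2, "r2"), setNames(pre, pid))
  cnt2 <- countsOf(quantifyMirna(aln2, b, "s"))[, 1]
  expect_equal(unname(cnt2[paste0(pid, "_5p-Novel")]), 1)
})

test_that("annotation counting gives each read exactly one count", {
  set.seed(5)
  feats <- c(fA = randSeqChr(60), fB = randSeqChr(60), fC = randSeqChr(60))
  reads <- c(setNames(rep(substr(feats[["fA"]], 10, 31), 5), paste0("r", 1:5)),
             dup = substr(feats[["fB"]], 1, 25))
  # a read matching two features equally: plant fB's prefix into fC
  feats[["fC"]] <- paste0(substr(feats[["fB"]], 1, 25),
                          substr(feats[["fC"]], 26, 60))
  aln <- alignReads(reads, feats)
  se <- quantifyAnnotationCounts(aln, names(feats), "s")
  cnt <- countsOf(se)[, 1]
  expect_equal(unname(cnt["fA"]), 5)
  expect_equal(unname(cnt["fB"]), 1) # tie broken to smaller feature id
  expect_equal(unname(cnt["fC"]), 0)
  expect_equal(sum(cnt), length(unique(aln$read_id)))

  empty <- quantifyAnnotationCounts(aln[0, ], names(feats), "s")
  expect_true(all(countsOf(empty) == 0))
})

test_that("triage classifies at the first mapping stage and conserves reads", {
  b <- fixtureSmallBundle()
  # a precursor is embedded in the host genome; its read must be hsa_srna
  pre1 <- as.character(precursorSequences(b))[[1]]
  loci <- b@hostFeatureLoci
  expect_true(names(precursorSequences(b))[1] %in% loci$id)
  rdPre <- substr(pre1, 11, 32)
  host <- as.character(hostGenome(b))
  expect_true(grepl(rdPre, host, fixed = TRUE))
  set.seed(8)
  # a genome window outside every embedded sRNA locus
  o <- loci[order(loci$start), ]
  gapStart <- o$end + 1            # first free 1-based position after a locus
  gapEnd <- c(o$start[-1], nchar(host))
  gi <- which(gapEnd - gapStart >= 60)[1]
  rdGenome <- substr(host, gapStart[gi] + 5, gapStart[gi] + 44)
  rdJunk <- randSeqChr(30)
  rdDiet <- as.character(dietSequences(b))[[2]]
  reads <- c(p = rdPre, g = rdGenome, j = rdJunk, d = rdDiet)
  tri <- triageReads(reads, b, sample = "t")
  cls <- setNames(tri@assignments$class, tri@assignments$read_id)
  expect_equal(unname(cls["p"]), "hsa_srna")
  expect_equal(unname(cls["g"]), "hsa_genome")
  expect_equal(unname(cls["j"]), "candidate_microbial")
  expect_equal(unname(cls["d"]), "diet")
  expect_equal(sum(triageCounts(tri)), length(reads))
  expect_equal(sum(triageFractions(tri)), 1)
})

test_that("triage fractions track truth within 2 points on a synthetic sample", {
  b <- fixtureSmallBundle()
  co <- fixtureSmallCohort()
  s <- "S01"
  prep <- preprocessReads(co$reads[[s]], co$config$adapter)
  tri <- triageReads(prep$reads, b, sample = s)
  truth <- table(co$truth$classes[[s]]$class) / nrow(co$truth$classes[[s]])
  fr <- triageFractions(tri)
  expect_lt(abs(fr[["hsa_srna"]] - truth[["human_srna"]]), 0.02)
  expect_lt(abs(fr[["hsa_genome"]] - truth[["human_genome"]]), 0.02)
  junk <- if ("junk" %in% names(truth)) truth[["junk"]] else 0
  expect_lt(abs(fr[["candidate_microbial"]] -
                  (truth[["bacterial"]] + junk)), 0.02)
})

test_that("knowledge-based counts equal generator truth on arm reads", {
  b <- fixtureSmallBundle()
  co <- fixtureSmallCohort()
  s <- "S02"
  prep <- preprocessReads(co$reads[[s]], co$config$adapter)
  tri <- triageReads(prep$reads, b, sample = s)
  best1 <- fecoduo:::.bestHits(tri@srnaAlignments)
  preIds <- names(precursorSequences(b))
  mirAln <- tri@srnaAlignments[
    tri@srnaAlignments$read_id %in% best1$read_id[best1$ref_id %in% preIds] &
      tri@srnaAlignments$ref_id %in% preIds, , drop = FALSE]
  cnt <- countsOf(quantifyMirna(mirAln, b, s))[, 1]
  truth <- co$truth$mirnaCounts[, s]
  expect_equal(cnt[names(truth)], truth)
  # column sum never exceeds the number of precursor-mapped reads
  expect_lte(sum(cnt), length(unique(mirAln$read_id)))
})
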