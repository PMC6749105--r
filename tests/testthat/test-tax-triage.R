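test_that("taxonomy validation rejects malformed trees", {
  tax <- tinyTax()
  expect_silent(validateTaxonomy(tax))
  orphan <- tax; orphan$parent_id[orphan$taxon_id == "sC"] <- "missing"
  expect_error(validateTaxonomy(orphan), "orphan")
  tworoots <- tax; tworoots$parent_id[tworoots$taxon_id == "p2"] <- "p2"
  expect_error(validateTaxonomy(tworoots), "exactly one root")
  badrank <- tax; badrank$parent_id[badrank$taxon_id == "p1"] <- "sC"
  expect_error(validateTaxonomy(badrank), "strictly deeper|species must be leaves")
})

test_that("k-mer LCA database maps shared k-mers to the LCA", {
  tax <- tinyTax()
  set.seed(31)
  shared <- randSeqChr(31)             # in sA and sB -> genus gAB
  sharedFar <- randSeqChr(31)          # in sA and sC -> kingdom root
  gA <- paste0(randSeqChr(200), shared, randSeqChr(200), sharedFar)
  gB <- paste0(shared, randSeqChr(400))
  gC <- paste0(randSeqChr(100), sharedFar, randSeqChr(300))
  db <- buildKmerLcaDb(c(sA = gA, sB = gB, sC = gC), tax, k = 31)
  km <- kmerMap(db)
  lookup <- setNames(km$taxon_id, km$kmer)
  canon <- function(x) min(x, oracleRevComp(x))
  expect_equal(unname(lookup[canon(shared)]), "gAB")
  expect_equal(unname(lookup[canon(sharedFar)]), "root")
  # a k-mer unique to sA maps to sA
  uniq <- canon(substr(gA, 50, 80))
  expect_equal(unname(lookup[uniq]), "sA")
  # empty genome set -> empty DB
  empty <- buildKmerLcaDb(setNames(character(), character()), tax)
  expect_length(empty@kmer, 0)
  # genome without a species node -> structural error
  expect_error(buildKmerLcaDb(c(gAB = gA), tax), "species")
})

test_that("classification follows the length rule and path-vote scoring", {
  tax <- tinyTax()
  set.seed(32)
  gA <- randSeqChr(3000); gB <- randSeqChr(3000); gC <- randSeqChr(3000)
  db <- buildKmerLcaDb(c(sA = gA, sB = gB, sC = gC), tax, k = 31)
  # reads shorter than 31 nt are unclassified regardless of content
  expect_true(is.na(classifyReads(substr(gA, 1, 30), db)))
  # a read whose k-mers all map to sA is assigned sA
  expect_equal(classifyReads(substr(gA, 101, 145), db), "sA")
  # zero-hit read is unclassified
  expect_true(is.na(classifyReads(randSeqChr(40), db)))

  # constructed vote split: 5 k-mers on sA, 2 on sB, 3 on gAB
  # path(root,gAB,sA) = 3 + 5 = 8 beats path(root,gAB,sB) = 3 + 2 = 5
  rd <- randSeqChr(40)                  # 10 k-mers at k = 31
  km <- oracleCanonical(oracleKmers(rd, 31))
  expect_equal(anyDuplicated(km), 0L)
  db2 <- methods::new("KmerLCADB", k = 31L, kmer = km,
                      taxon = c(rep("sA", 5), rep("sB", 2), rep("gAB", 3)),
                      taxonomy = tax)
  expect_equal(classifyReads(rd, db2), "sA")
  # equal-weight paths resolve to the LCA of the tied leaves
  db3 <- methods::new("KmerLCADB", k = 31L, kmer = km,
                      taxon = c(rep("sA", 4), rep("sB", 4), rep("gAB", 2)),
                      taxonomy = tax)
  expect_equal(classifyReads(rd, db3), "gAB")
})

test_that("classification agrees with the brute-force oracle", {
  tax <- tinyTax()
  set.seed(33)
  genomes <- c(sA = randSeqChr(4000), sB = randSeqChr(4000),
               sC = randSeqChr(4000))
  # make sA and sB sibling-like so genus-level LCAs occur
  genomes[["sB"]] <- paste0(substr(genomes[["sA"]], 1, 1000),
                            substr(genomes[["sB"]], 1001, 4000))
  db <- buildKmerLcaDb(genomes, tax, k = 31)
  oracle <- oracleClassifier(genomes, tax, k = 31)
  reads <- character(80)
  for (i in seq_along(reads)) {
    g <- genomes[[sample(3, 1)]]
    l <- sample(c(25, 31, 35, 45, 60), 1)
    p <- sample(nchar(g) - l + 1, 1)
    rd <- substr(g, p, p + l - 1)
    if (runif(1) < 0.3) rd <- oracleRevComp(rd)
    reads[i] <- rd
  }
  got <- classifyReads(reads, db)
  for (i in seq_along(reads)) {
    want <- oracle(reads[i])
    expect_equal(got[i], want$taxon, label = paste("read", i))
  }
})

test_that("profiles implement clade counts and rank-level normalization", {
  tax <- tinyTax()
  # 30 reads on sA, 70 on sC (distinct phyla)
  pr <- taxProfile(c(rep("sA", 30), rep("sC", 70)), tax, "s")
  expect_equal(unname(abundanceAt(pr, "species")[c("SpecA", "SpecC")]),
               c(30, 70))
  expect_equal(unname(abundanceAt(pr, "phylum")[c("PhyA", "PhyB")]),
               c(30, 70))
  # 10 reads at genus gAB, 90 at its species child sA
  pr2 <- taxProfile(c(rep("gAB", 10), rep("sA", 90)), tax, "s")
  expect_equal(unname(abundanceAt(pr2, "species")[["SpecA"]]), 90)
  expect_equal(unname(abundanceAt(pr2, "genus")[["GenAB"]]), 100)
  cl <- cladeTable(pr2)
  expect_equal(cl$clade_count[cl$taxon_id == "gAB"], 100)
  expect_equal(cl$clade_count[cl$taxon_id == "sA"], 90)
  # zero classified reads -> empty profile, no division by zero
  pr3 <- taxProfile(rep(NA_character_, 5), tax, "s")
  expect_equal(totalClassified(pr3), 0L)
  expect_equal(nrow(cladeTable(pr3)), 0)
  # monotonicity: adding sA reads never decreases sA's clade count
  before <- cladeTable(pr2)$clade_count[cladeTable(pr2)$taxon_id == "sA"]
  pr4 <- taxProfile(c(rep("gAB", 10), rep("sA", 95)), tax, "s")
  expect_gte(cladeTable(pr4)$clade_count[cladeTable(pr4)$taxon_id == "sA"],
             before)
})

test_that("mpa serialization is bit-exact and round-trips", {
  tax <- tinyTax()
  pr <- taxProfile(c(rep("sA", 24), rep("sC", 76)), tax, "s")
  f <- withr::local_tempfile(fileext = ".mpa")
  writeMpa(pr, tax, f)
  lines <- readLines(f)
  expect_true("k__Bacteria|p__PhyA|c__ClaA|o__OrdA|f__FamA|g__GenAB|s__SpecA\t24.00000"
              %in% lines)
  expect_true("k__Bacteria\t100.00000" %in% lines)
  back <- readMpa(f)
  sp <- back[back$rank == "species", ]
  expect_equal(setNames(sp$abundance, sp$name),
               abundanceAt(pr, "species")[sp$name])
})

test_that("abundance matrices agree between profiles and mpa files", {
  tax <- tinyTax()
  prs <- list(S1 = taxProfile(c(rep("sA", 3), rep("sB", 7)), tax, "S1"),
              S2 = taxProfile(rep("sC", 5), tax, "S2"))
  d <- withr::local_tempdir()
  paths <- c(S1 = file.path(d, "S1.mpa"), S2 = file.path(d, "S2.mpa"))
  writeMpa(prs$S1, tax, paths[["S1"]])
  writeMpa(prs$S2, tax, paths[["S2"]])
  m1 <- abundanceMatrix(prs, "species")
  m2 <- abundanceMatrix(paths, "species")
  expect_equal(m1, m2, tolerance = 1e-5)
  expect_equal(unname(m1["SpecB", "S1"]), 70)
})
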